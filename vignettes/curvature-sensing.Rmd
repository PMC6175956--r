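---
title: "Entropic curvature sensing by disordered polymers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropic curvature sensing by disordered polymers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Intrinsically disordered protein (IDP) domains behave like flexible
polymers. When such a domain is tethered by one end to a membrane, the
membrane acts as an excluded half-space that prunes chain conformations. A
convex surface (the outside of a small vesicle, the outer face of a
filopodium) prunes fewer conformations than a flat or concave one, so the
chain retains more conformational entropy there. If the binding enthalpy is
curvature-independent, this entropy difference alone makes the bound state
more favorable on more curved membranes — an entropic curvature-sensing
mechanism that needs no structural motif. `curvsense` implements both sides
of the comparison: the polymer simulation that predicts the effect, and the
tethered-vesicle fluorescence analysis that measures it, with synthetic-data
generators so the whole pipeline is testable without microscope data.

# Lattice chain models

A chain of $n+1$ beads ($n$ bonds) lives on the simple cubic lattice. A
model `nbrPQRexclX` allows as bond vectors every signed coordinate
permutation of $(P,Q,R)$ — 6 directions for $(0,0,1)$, 24 for $(1,1,2)$ —
and excludes, around every occupied site, the union of the $X$ nearest
shells of the lattice (6 sites for $X=1$, 18 for $X=2$). A model is
self-consistent only if the squared step length $P^2+Q^2+R^2$ exceeds the
largest excluded squared distance; `saw_model()` rejects the rest. Every
step represents one virtual bond of 0.38 nm (the C$\alpha$–C$\alpha$
spacing), so the lattice constant is $a = 0.38/\sqrt{P^2+Q^2+R^2}$ nm and a
chain of $m$ residues has $m-1$ bonds (569 residues $\to$ 216 nm of
contour). The membrane substrate is a solid region of excluded sites —
half-space, sphere (exterior or interior) or cylinder — and tethered chains
have their first bead frozen at the lattice site nearest the surface.

Sampling uses symmetric-proposal, accept-iff-valid Monte Carlo, which makes
every valid conformation equally likely. One MC step is $n$ local-move
attempts: a uniformly chosen bead proposes a site one random allowed
direction away from its predecessor (end beads from their single
neighbour), accepted iff all bond, exclusion and substrate constraints
hold. For *structural statistics* (`chain_stats()`), each MC step is
augmented by default with one pivot attempt — a uniformly random signed
coordinate permutation (an element of the 48-member octahedral group)
applied to the chain tail about a random bead. The pivot proposal is
symmetric and direction sets are closed under the group, so the uniform
target distribution is untouched; it is needed because pure single-bead
moves cannot displace the interior beads of a straight rod at all on the
(001) lattice, making equilibration from the extended start reptation-slow.
With pivots the measured radius-of-gyration scaling exponent over
$n \in \{16,32,64,128\}$ is $\nu \approx 0.59$ (the Flory value for a
3D self-avoiding walk); without them, finite runs report rod-contaminated
values near 0.86. `mc_run()` itself keeps the pure local-move set for
users who want those dynamics.

# Absolute entropy by hypothetical scanning

The entropy of the uniform ensemble of valid chains is $\ln Z$ with $Z$ the
number of conformations — directly countable only for tiny chains
(`enumerate_saws()`, the test oracle). The hypothetical scanning Monte
Carlo (HSMC) estimator rebuilds a chain bond by bond. At bond $j$ the
already-built past is frozen and the future segment (bonds $j..n$) is
simulated at equilibrium; the visit frequency $n_j^{(k)}/n_{\mathrm{MC}}$
of each candidate direction $k$ of bond $j$ estimates its conditional
construction probability $p_j$. The realized direction is then drawn from
that empirical table (the package default; a uniform-over-observed switch
exists for sensitivity checks), $p_j$ is recorded, and the product
$P^{\mathrm{HSMC}} = \prod_j p_j$ gives one reconstruction probability.
From $N_{\mathrm{obs}}$ reconstructions the upper bound is
$S^U = -\langle \ln P \rangle$, the lower bound is the
$P$-weighted analogue
$S^L = -\sum_i P_i \ln P_i / \sum_i P_i$, and the reported entropy is
their mean, with a jackknife standard error (the published method describes no error
model for $S$; its printed upper-bound formula also lacks the minus sign
carried by its exact counterpart, and we use the sign that makes entropy
positive).

Numerical choices that matter:

* **Scan length.** $n_{\mathrm{MC}}(j) = \bar n \cdot n_{\mathrm{nbr}}
  \cdot (n-j+1)$ MC steps, with one step defined as a sweep of $(n-j+1)$
  local-move attempts over the future segment (that is the published
  definition of an MC step; counting single attempts instead leaves a
  visible autocorrelation bias at small $\bar n$). Between bonds the
  future segment is rebuilt as an extended conformation (straight along the
  outward normal when possible, deterministic backtracking search
  otherwise) and re-equilibrated for $\bar n' \cdot n_{\mathrm{nbr}} \cdot
  (n-j+1)$ steps. Defaults $\bar n = 1000$, $\bar n' = 100$, 96
  reconstructions are production-scale (hours for 568-bond chains); the
  test suite runs $\bar n = 50$, $\bar n' = 20$, 24–32 reconstructions.
* **Scan mixing.** Each sweep also makes two pivot attempts on the future
  segment, one anchored at bead $j-1$ so the scanned bond itself is
  re-randomized. This is essential for the conditional frequencies to
  decorrelate at desk scale.
* **Estimator bias.** The plug-in estimator carries an $O(1/n_{\mathrm{MC}})$
  downward bias (convexity of $x \ln x$ applied to noisy frequencies). At
  $\bar n = 50$ it is $\approx 0.02$–$0.03\,k_B$ on 2–3-bond chains —
  about one standard error of a 24-reconstruction estimate, within the
  3-SE oracle tolerance — and is negligible by $\bar n \approx 200$.
* **Dead ends.** A frozen prefix whose future segment has no valid
  completion (possible for stiff models near substrates) aborts that
  reconstruction; it is resampled with a warning and the discard count is
  attached to the result.

# From entropy to curvature sensitivity

`entropy_vs_curvature()` sweeps exterior-sphere substrates whose lattice
radii discretize the requested vesicle diameters (the realized radius is
reported, not the requested one). With binding enthalpy assumed
curvature-independent, the partition-coefficient ratio between two
diameters is $\exp(\Delta\Delta S / k_B)$; entropies are carried in $k_B$
units so temperature cancels (it is stored on the prediction object for
interface clarity only). Normalizing at 200 nm yields a predicted
sensitivity profile directly comparable to the experimental pipeline's
output. `calibrate_kuhn_length()` ranks candidate models by agreement
between simulated and measured free-chain $R_g$ and reports each model's
implied Kuhn length $l_K = \langle R_{ee}^2 \rangle / L_c$, evaluated at
the chain's own contour length (a single-number mapping, not an asymptotic
extrapolation — at fixed contour the excluded-volume swelling is included,
so values exceed the nominal bond length).

A caveat established while building the package: at desk scale (32-bond
chains) every valid single-digit `nbrPQRexclX` model has nearly the same
*physical* $R_g$ at fixed contour, because the 0.38 nm step dominates and
shell-induced stiffening is worth only ~15–35% in implied $l_K$. The
published factor-of-two growth of the 40-vs-200 nm entropy difference
between $l_K = 0.36$ and $0.66$ nm chains is therefore reproducible only at
production scale (568 bonds); the acceptance suite asserts the directional
trend (stiffer model, larger $\Delta\Delta S$ between the same two
spheres) on short chains with small spheres, where the signal is a few
tenths of $k_B$.

# The tethered-vesicle pipeline

Inputs are per-punctum fluorescence tables (lipid and protein channel).
The stages and their conventions:

* **Diameter calibration.** Lipid brightness is taken proportional to
  membrane area, $I \propto d^{\,q}$ with exponent $q = 2$ by default (a
  config field). Diameters are $d = d_{\mathrm{DLS}} (I/I_0)^{1/q}$, where
  $I_0$ is the brightness whose size-scaled value $I^{1/q}$ sits at the
  kernel-density peak (Gaussian kernel, Silverman bandwidth). Estimating
  the peak on the size scale — rather than on raw intensity — is what makes
  the mode of the calibrated diameters equal the DLS value exactly; for a
  skewed brightness distribution the mode does not commute with the square
  root.
* **Protein counting.** Counts are protein intensity divided by the
  single-fluorophore modal brightness, left real-valued.
* **Binning.** 5-nm bins centred at 20, 25, …, 250 nm (half-open,
  $c \pm 2.5$), per-bin mean, 1.96 SEM and occupancy; empty bins omitted.
* **Density, coverage, sensitivity.** Density is mean count over
  $\pi d^2$; coverage multiplies by the protein footprint (115 nm$^2$ for
  569 residues, scaled linearly with chain length). Normalized sensitivity
  divides each bin's density by the occupancy-weighted 190–210 nm average,
  so the reference bin is 1. The population-average coverage is reported
  because sensitivities are only comparable between proteins at matched
  coverage.
* **Isotherm fitting.** `fit_langmuir()` does unweighted nonlinear least
  squares of $B_{\max} c / (K_D + c)$ on the binned means (no weighting
  scheme is prescribed for these data); parameter uncertainty is the SD
  of three fits (mean, upper, lower CI curves). `correct_bmax()` divides
  the apparent capacity by $(r_v + r_p)^2 / r_v^2$ ($r_p = 6$ nm default),
  the area ratio of the binding shell to the membrane.
* **Filopodia.** The partition coefficient per filopodium is the
  background-subtracted green filopodium/membrane ratio over the red one;
  filopodia with nonpositive background-subtracted membrane intensity are
  excluded (a package-defined QC rule; none is prescribed for these data).

# FCS

`fcs_model()` is the 2D anomalous-diffusion autocorrelation with a triplet
factor, $G(t) = 1 + (1 + A e^{-t/\tau_c}) N_p^{-1} (1 + (t/\tau_D)^\alpha)^{-1}$.
`fit_fcs()` fits $N_p$, $\tau_D$ and $\alpha \in [0.9, 1]$ with $A = 0.05$
and $\tau_c = 5\,\mu$s held fixed (echoed bit-exactly in the result).
Conversion to a hydrodynamic radius needs optical parameters that published studies rarely report;
`hydrodynamic_radius()` therefore takes an explicit beam waist (or
`calibrate_beam_waist()` from a reference of known $D$) and applies
$D = w^2/(4\tau_D)$ and Stokes–Einstein at 295 K in water by default. The
published radii are consequently not an acceptance quantity here.

# What the synthetic data does and does not emulate

`synth_config()` states the generator's world: three vesicle preparations
with log-normal diameter distributions whose modes sit at the DLS values
49, 67 and 147 nm and per-preparation CVs 0.5, 0.3, 0.25 (sonication is
far more polydisperse than extrusion; the CVs are set so the 20–250 nm
analysis window is populated the way the real per-bin occupancies were
reported, with tens of points in the 20 nm bin per thousand puncta — they
are part of the stated world, not tuning knobs). Reading the DLS numbers
as distribution modes keeps the peak-to-DLS calibration self-consistent;
DLS averages of polydisperse samples are themselves peak-weighted, but this
remains a modeling choice and is flagged as such. Binding follows a
Langmuir law whose $K_D$ falls with curvature as $K_D(d) = K_{D,\mathrm{ref}}
\, d / 200$ (ten-fold partitioning at 20 nm, $K_D = 160$ nM at 200 nm) and
whose capacity carries the geometric shell inflation around a single true
surface density of $2.7\times10^{-3}$ proteins nm$^{-2}$; counts are
Poisson; intensities get 5% multiplicative Gaussian noise. At the default
5 nM concentration the population-average coverage comes out near 3%, the
coverage at which the measured sensitivities were compared.
Simplifications worth knowing: each bound protein contributes exactly the
modal single-molecule brightness (the log-normal single-fluorophore
distribution is generated only for the calibration sample, so the
count-estimation step is unbiased by construction); there is no detection
limit, no colocalization failure, and no field-to-field illumination
variation. A green round-trip test therefore establishes that the
pipeline's estimators invert the generator's statistical structure — not
that they are robust to every artifact of real microscopy.

# Known limitations

* Desk-scale HSMC settings carry the $O(1/n_{\mathrm{MC}})$ bias noted
  above; quantitative entropy work should use $\bar n \ge 200$.
* The Kuhn-length menu spans only ~0.7–1.0 nm for short chains; matching
  the published 0.36–0.66 nm range requires production-scale chain lengths
  where implied $l_K$ is length-dependent.
* Cylinder substrates (filopodia geometry) are provided but experimental:
  the published two-fold theoretical filopodia value was derived by a
  method that is not printed anywhere reproducible, so no acceptance claim
  is made for it.
* The pipeline consumes puncta tables; image processing (detection,
  colocalization, focus selection) is upstream and out of scope.
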