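# curvsense

Membrane curvature sensing by intrinsically disordered proteins (IDPs),
treated as a polymer-entropy problem. Disordered domains tethered to a
membrane lose conformational entropy to the wall; a convex surface (a small
vesicle, the outside of a filopodium) costs less entropy than a flat one,
so — with curvature-independent binding enthalpy — the bound state is
favored on curved membranes by a factor
`exp(ΔΔS_curvature / k_B)`. The package is for quantitative membrane
biophysicists who want both halves of that argument in one place:

* **Simulation** — lattice self-avoiding-walk (SAW) chain models
  `nbrPQRexclX` (bond vectors: signed permutations of (P,Q,R); steric
  shell: the X nearest lattice shells; 0.38 nm per step), substrates as
  excluded lattice regions (plane, sphere, cylinder), uniform-ensemble
  Monte Carlo (local moves, optional pivots), absolute entropy by the
  hypothetical scanning Monte Carlo (HSMC) method — reconstruction
  probabilities `P = prod_j p_j` measured bond-by-bond with the future
  chain simulated and the past frozen, giving upper/lower entropy bounds
  `S^U = -<ln P>`, `S^L = -Σ P ln P / Σ P` — and the Boltzmann conversion
  of entropy differences into relative binding ("curvature sensitivity")
  predictions, plus Kuhn-length calibration against measured chain
  dimensions.
* **Analysis** — the tethered-vesicle fluorescence pipeline: brightness →
  vesicle diameter calibration (mode-matched to dynamic light scattering),
  single-molecule-normalized protein counts, 5-nm diameter binning, bound
  density / membrane coverage, sensitivity normalized to 200 nm vesicles,
  Langmuir isotherm fits `bound = B_max c / (K_D + c)` with the geometric
  capacity correction `(r_v + r_p)^2 / r_v^2`, filopodia partition
  coefficients, and FCS autocorrelation fitting (fixed triplet terms,
  bounded anomalous exponent).
* **Synthetic data** — seeded generators for every input the pipeline
  consumes, with ground-truth sidecars, so all stages are testable without
  microscope data.

## Worked example

Entropy of a tiny free chain against exact enumeration (the package's own
oracle), then a tethered sphere-vs-flat comparison:

```r
library(curvsense)
m <- saw_model("nbr001excl0")
enumerate_saws(m, 3)               # 150 conformations
tethered_entropy(m, 3, config = hsmc_config(50, 20, 24), seed = 1)
#> entropy (k_B): S = 5.019 +/- 0.035  [S_U = 5.034, S_L = 5.005, n = 24]
log(150)                           # 5.0106 -- HSMC agrees with ln Z

est_s <- tethered_entropy(m, 12, substrate("sphere_exterior", radius = 8),
                          hsmc_config(50, 20, 24), seed = 2)
est_f <- tethered_entropy(m, 12, substrate("plane"),
                          hsmc_config(50, 20, 24), seed = 3)
est_s$s_mean - est_f$s_mean        # 0.128 k_B more entropy on the sphere
exp(est_s$s_mean - est_f$s_mean)   # -> 1.14-fold binding preference
```

The same quantities from the experimental side, on synthetic vesicle data
(three preparations, curvature-dependent Langmuir binding, ten-fold
partitioning law at 20 nm):

```r
cfg <- synth_config(n_puncta = 5000)
g   <- gen_vesicle_puncta(cfg, seed = 7)
sm  <- estimate_mode(gen_single_molecule(cfg, 5000, seed = 8))
res <- analyze_vesicles(g$puncta, cfg$prep_means_nm, sm)
subset(as.data.frame(res$sensitivity),
       diameter_nm %in% c(20, 50, 100, 200))
#>  diameter_nm mean_count density normalized_sensitivity   n
#>           20       1.97 0.00156                  16.49  62
#>           50       3.59 0.00046                   4.81 680
#>          100       6.29 0.00020                   2.11 383
#>          200      11.61 0.00009                   0.97 142
res$avg_coverage                   # 0.034 -> ~3% membrane coverage
synth_true_sensitivity(cfg, 20)    # 17.9 = the generating truth at 20 nm
```

Reading the table: a 20 nm vesicle carries ~2 bound proteins and a 200 nm
vesicle ~12, but per membrane area the small vesicle is ~16-17x more
densely covered — the curvature-sensitivity signal the entropy model
predicts, recovered here within its sampling error (truth 17.9).

## Command line

```sh
Rscript -e 'curvsense::run_cli()' synth --what vesicles --seed 3 --out puncta.csv
Rscript -e 'curvsense::run_cli()' analyze-vesicles --puncta puncta.csv \
    --dls-means 49,67,147 --sm-intensity 100 --out sensitivity.csv
Rscript -e 'curvsense::run_cli()' entropy --model nbr001excl0 --bonds 32 \
    --substrate sphere_exterior --radius 4,8,16 --n-bar 50 --n-recon 24 \
    --seed 1 --out entropy.csv
```

Subcommands: `simulate-saw`, `entropy`, `predict-sensitivity`,
`analyze-vesicles`, `fit-binding`, `fit-fcs`, `filopodia`, `synth`. Every
run writes a JSON reproducibility record (seed, arguments, version) next
to its output.

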