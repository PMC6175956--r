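#' Configuration of the synthetic-data generators
#'
#' The stated world the generators emulate: three vesicle preparations
#' (sonicated, 30 nm-extruded, 200 nm-extruded) with log-normal diameter
#' distributions whose modes sit at the dynamic-light-scattering values 49,
#' 67 and 147 nm; lipid brightness proportional to membrane area (d^2);
#' bound-protein counts Poisson-distributed around a Langmuir law whose
#' dissociation constant falls with curvature (K_D(d) = kd_ref / fold(d),
#' fold normalized to 1 at the reference diameter) and whose capacity
#' carries the geometric shell correction; protein brightness proportional
#' to count; log-normal single-fluorophore brightness; and paired-channel
#' filopodia intensities with a set partition factor.
#'
#' @param prep_means_nm Modal diameters of the three preparations (nm).
#' @param prep_cvs Log-normal coefficient of variation per preparation
#'   (sonication is the most polydisperse).
#' @param n_puncta Puncta per preparation per condition.
#' @param diameter_range_nm Truncation range for diameter draws.
#' @param kd_ref_nM Dissociation constant at the reference diameter.
#' @param reference_diameter_nm Reference diameter (200 nm).
#' @param fold_law Function of diameter giving the (unnormalized)
#'   partitioning fold; default 200/d, i.e. 10-fold at 20 nm.
#' @param b_max_density True corrected saturation density (proteins nm^-2).
#' @param geometric_bmax Apply the (r_v + r_p)^2/r_v^2 capacity inflation.
#' @param r_p_nm Protein radius for the geometric factor.
#' @param concentration_nM Solution concentration of the default condition.
#' @param lipid_scale Lipid brightness per nm^2 of membrane area (a.u.).
#' @param intensity_cv Multiplicative Gaussian noise CV on intensities.
#' @param sm_intensity Modal single-molecule brightness (a.u.).
#' @param sm_cv Log-normal CV of the single-molecule distribution.
#' @param background Additive background on protein intensities (a.u.).
#' @param filopodia_factor True partition factor of the green channel.
#' @param filopodia_n Filopodia per synthetic set.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(prep_means_nm = c(49, 67, 147),
                         prep_cvs = c(0.5, 0.3, 0.25),
                         n_puncta = 1000,
                         diameter_range_nm = c(15, 300),
                         kd_ref_nM = 160,
                         reference_diameter_nm = 200,
                         fold_law = function(d) 200 / d,
                         b_max_density = 2.7e-3,
                         geometric_bmax = TRUE,
                         r_p_nm = 6,
                         concentration_nM = 5,
                         lipid_scale = 0.02,
                         intensity_cv = 0.05,
                         sm_intensity = 100,
                         sm_cv = 0.3,
                         background = 0,
                         filopodia_factor = 2.34,
                         filopodia_n = 94) {
  stopifnot(all(prep_means_nm > 0), all(prep_cvs > 0), n_puncta >= 1,
            kd_ref_nM > 0, b_max_density > 0, sm_intensity > 0,
            filopodia_factor > 0)
  structure(as.list(environment()), class = "synth_config")
}

# truncated log-normal with mode `mode_nm`
.draw_diameters <- function(n, mode_nm, cv, range_nm) {
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mode_nm) + sdlog^2
  d <- numeric(0)
  while (length(d) < n) {
    x <- stats::rlnorm(2 * n, meanlog, sdlog)
    d <- c(d, x[x >= range_nm[1] & x <= range_nm[2]])
  }
  d[seq_len(n)]
}

# model-implied per-vesicle quantities
.synth_law <- function(config, d, conc = config$concentration_nM) {
  fold <- config$fold_law(d) / config$fold_law(config$reference_diameter_nm)
  kd <- config$kd_ref_nM / fold
  geo <- if (config$geometric_bmax)
    ((d / 2 + config$r_p_nm) / (d / 2))^2 else rep(1, length(d))
  bmax_count <- config$b_max_density * geo * pi * d^2
  occ <- conc / (kd + conc)
  list(kd = kd, geo = geo, bmax_count = bmax_count, occ = occ,
       mean_count = bmax_count * occ,
       density = config$b_max_density * geo * occ)
}

#' Model-implied normalized sensitivity of a synthetic configuration
#'
#' Exact expected bound density (at the configured concentration) divided by
#' the density at the reference diameter; the ground truth against which the
#' pipeline's recovered normalized sensitivity is compared.
#'
#' @param config A `synth_config`.
#' @param diameters_nm Diameters at which to evaluate.
#' @return Data frame with `diameter_nm` and `true_sensitivity`.
#' @export
synth_true_sensitivity <- function(config, diameters_nm) {
  dens <- .synth_law(config, diameters_nm)$density
  dref <- .synth_law(config, config$reference_diameter_nm)$density
  data.frame(diameter_nm = diameters_nm, true_sensitivity = dens / dref)
}

#' Generate a synthetic tethered-vesicle puncta table
#'
#' Diameters per preparation from truncated log-normals; lipid intensity
#' c d^2 (1 + eps); bound counts Poisson around the curvature-dependent
#' Langmuir mean; protein intensity count x single-molecule brightness x
#' (1 + eps) + background. The ground truth (diameter, count, K_D) is
#' returned alongside.
#'
#' @param config A `synth_config`.
#' @param seed RNG seed.
#' @param concentration_nM Overrides the config concentration.
#' @return List with `puncta` (prep, lipid_intensity, protein_intensity)
#'   and `truth`.
#' @export
gen_vesicle_puncta <- function(config = synth_config(), seed = 1L,
                               concentration_nM = config$concentration_nM) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(seed)
  n_prep <- length(config$prep_means_nm)
  rows <- lapply(seq_len(n_prep), function(p) {
    d <- .draw_diameters(config$n_puncta, config$prep_means_nm[p],
                         config$prep_cvs[p], config$diameter_range_nm)
    law <- .synth_law(config, d, concentration_nM)
    count <- stats::rpois(length(d), law$mean_count)
    lipid <- config$lipid_scale * d^2 *
      (1 + stats::rnorm(length(d), 0, config$intensity_cv))
    prot <- count * config$sm_intensity *
      (1 + stats::rnorm(length(d), 0, config$intensity_cv)) +
      config$background
    list(puncta = data.frame(prep = p, lipid_intensity = pmax(lipid, 0),
                             protein_intensity = pmax(prot, 0)),
         truth = data.frame(prep = p, diameter_nm = d, count = count,
                            kd_nM = law$kd, mean_count = law$mean_count))
  })
  list(puncta = do.call(rbind, lapply(rows, `[[`, "puncta")),
       truth = do.call(rbind, lapply(rows, `[[`, "truth")))
}

#' Generate a concentration series from one vesicle population
#'
#' Draws the vesicle population once and rebinds it at each concentration,
#' so saturation follows the Langmuir law on fixed vesicles.
#'
#' @param config A `synth_config`.
#' @param concentrations_nM At least 3 concentrations.
#' @param seed RNG seed.
#' @return List with `tables` (one puncta data frame per concentration,
#'   named by concentration) and `truth` (the shared vesicle population).
#' @export
gen_binding_series <- function(config = synth_config(), concentrations_nM,
                               seed = 1L) {
  if (length(concentrations_nM) < 3) stop("need at least 3 concentrations")
  set.seed(seed)
  n_prep <- length(config$prep_means_nm)
  pop <- do.call(rbind, lapply(seq_len(n_prep), function(p) {
    data.frame(prep = p,
               diameter_nm = .draw_diameters(config$n_puncta,
                                             config$prep_means_nm[p],
                                             config$prep_cvs[p],
                                             config$diameter_range_nm))
  }))
  tables <- lapply(concentrations_nM, function(conc) {
    law <- .synth_law(config, pop$diameter_nm, conc)
    count <- stats::rpois(nrow(pop), law$mean_count)
    lipid <- config$lipid_scale * pop$diameter_nm^2 *
      (1 + stats::rnorm(nrow(pop), 0, config$intensity_cv))
    prot <- count * config$sm_intensity *
      (1 + stats::rnorm(nrow(pop), 0, config$intensity_cv)) +
      config$background
    data.frame(prep = pop$prep, lipid_intensity = pmax(lipid, 0),
               protein_intensity = pmax(prot, 0))
  })
  names(tables) <- as.character(concentrations_nM)
  list(tables = tables, truth = pop)
}

#' Generate a single-molecule brightness sample
#'
#' Log-normal draws whose mode sits at the configured single-molecule
#' intensity.
#'
#' @param config A `synth_config`.
#' @param n Sample size.
#' @param seed RNG seed.
#' @return Numeric intensities.
#' @export
gen_single_molecule <- function(config = synth_config(), n, seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  if (config$sm_cv == 0) return(rep(config$sm_intensity, n))
  sdlog <- sqrt(log(1 + config$sm_cv^2))
  meanlog <- log(config$sm_intensity) + sdlog^2
  stats::rlnorm(n, meanlog, sdlog)
}

#' Generate a noisy FCS trace
#'
#' Evaluates the autocorrelation model on a log-spaced lag grid and applies
#' multiplicative Gaussian noise to the correlation amplitude (G - 1), with
#' a mildly lag-dependent (shot-noise-like) variance.
#'
#' @param n_p,tau_d,alpha,a,tau_c Model parameters (see [fcs_model()]).
#' @param lag_s Lag grid (default 128 log-spaced points, 1 us to 1 s).
#' @param noise_cv Relative noise amplitude (0 gives the exact model).
#' @param seed RNG seed.
#' @return Data frame with `lag_s` and `g`.
#' @export
gen_fcs_trace <- function(n_p, tau_d, alpha = 1, a = 0.05, tau_c = 5e-6,
                          lag_s = 10^seq(-6, 0, length.out = 128),
                          noise_cv = 0.02, seed = 1L) {
  set.seed(seed)
  g <- fcs_model(lag_s, n_p, tau_d, alpha, a, tau_c)
  if (noise_cv > 0) {
    sdv <- noise_cv * sqrt(1 + lag_s / tau_d) / sqrt(2)
    g <- 1 + (g - 1) * (1 + stats::rnorm(length(g), 0, pmin(sdv, 0.5)))
  }
  data.frame(lag_s = lag_s, g = g)
}

#' Generate a paired-channel filopodia set
#'
#' Red-channel filopodium/membrane ratios scatter around 1; green ratios are
#' the configured partition factor times a correlated draw; backgrounds are
#' added so the analysis has to subtract them.
#'
#' @param config A `synth_config`.
#' @param n Number of filopodia (default `config$filopodia_n`).
#' @param factor True partition factor (default `config$filopodia_factor`).
#' @param seed RNG seed.
#' @return Data frame with the six intensity columns consumed by
#'   [filopodia_partition()].
#' @export
gen_filopodia <- function(config = synth_config(), n = config$filopodia_n,
                          factor = config$filopodia_factor, seed = 1L) {
  stopifnot(factor > 0, n >= 1)
  set.seed(seed)
  bg <- 50
  g_mem <- stats::rlnorm(n, log(500), 0.2)
  r_mem <- stats::rlnorm(n, log(500), 0.2)
  rho_r <- stats::rlnorm(n, -0.5 * 0.2^2, 0.2)          # mean 1
  rho_g <- factor * rho_r * (1 + stats::rnorm(n, 0, 0.15))
  data.frame(g_filo = bg + g_mem * rho_g, g_mem = bg + g_mem, g_bg = bg,
             r_filo = bg + r_mem * rho_r, r_mem = bg + r_mem, r_bg = bg)
}
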