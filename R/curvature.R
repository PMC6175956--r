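#' Contour length of a disordered domain
#'
#' Residues map to beads; a chain of n residues has n - 1 bonds of 0.38 nm
#' (the Calpha-Calpha spacing), so the contour length is
#' (n_residues - 1) * 0.38 nm.
#'
#' @param n_residues Number of amino acids (>= 2).
#' @param step_length_nm Length per bond in nm.
#' @return Contour length in nm.
#' @export
#' @examples
#' round(contour_length_nm(569)) # 216
contour_length_nm <- function(n_residues, step_length_nm = 0.38) {
  if (n_residues < 2) stop("need at least 2 residues")
  (n_residues - 1) * step_length_nm
}

#' Chain entropy versus substrate curvature
#'
#' Runs [tethered_entropy()] on exterior spheres whose lattice radii
#' discretize the requested vesicle diameters (radius = (d/2)/a rounded to
#' the nearest site), optionally adding the flat-substrate limit. The
#' number of bonds is round(contour_nm / step_length_nm).
#'
#' @param model A `saw_model`.
#' @param contour_nm Chain contour length (nm).
#' @param diameters_nm Vesicle diameters to sweep (nm).
#' @param config An `hsmc_config`.
#' @param include_flat Also compute the flat (plane) substrate.
#' @param n_bonds Override the bond count (otherwise from the contour).
#' @param seed Master seed.
#' @return An object of class `curvature_sweep`: a data frame of diameters,
#'   realized lattice radii and entropy estimates, plus metadata.
#' @export
entropy_vs_curvature <- function(model, contour_nm, diameters_nm,
                                 config = hsmc_config(), include_flat = TRUE,
                                 n_bonds = NULL, seed = 1L) {
  stopifnot(inherits(model, "saw_model"), contour_nm > 0,
            all(diameters_nm > 0))
  if (is.null(n_bonds)) n_bonds <- max(1L, round(contour_nm / model$step_length_nm))
  a <- model$lattice_nm
  radii <- round((diameters_nm / 2) / a)
  if (any(radii < 1))
    stop("diameter too small for the lattice discretization of this model")
  rows <- lapply(seq_along(diameters_nm), function(i) {
    sub <- substrate("sphere_exterior", radius = radii[i])
    est <- tethered_entropy(model, n_bonds, sub, config,
                            seed = seed + (i - 1L) * config$n_recon)
    data.frame(diameter_nm = diameters_nm[i], radius_lattice = radii[i],
               radius_nm = radii[i] * a, s_upper = est$s_upper,
               s_lower = est$s_lower, s_mean = est$s_mean, se = est$se,
               n_obs = est$n_obs)
  })
  tab <- do.call(rbind, rows)
  flat <- NULL
  if (include_flat) {
    est <- tethered_entropy(model, n_bonds, substrate("plane"), config,
                            seed = seed + length(diameters_nm) * config$n_recon)
    flat <- data.frame(diameter_nm = Inf, radius_lattice = Inf,
                       radius_nm = Inf, s_upper = est$s_upper,
                       s_lower = est$s_lower, s_mean = est$s_mean,
                       se = est$se, n_obs = est$n_obs)
  }
  structure(list(table = rbind(tab, flat), model = model$name,
                 n_bonds = n_bonds, contour_nm = contour_nm,
                 reference_diameter_nm = 200),
            class = "curvature_sweep")
}

#' @export
print.curvature_sweep <- function(x, ...) {
  cat(sprintf("curvature sweep: %s, %d bonds (contour %.4g nm)\n", x$model,
              x$n_bonds, x$contour_nm))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Relative binding partitioning from entropy differences
#'
#' Under curvature-independent binding enthalpy, the partition-coefficient
#' ratio between two substrates is exp(ddS / k_B) with ddS the chain-entropy
#' difference. Entropies are carried in k_B units so temperature cancels.
#'
#' @param sweep A `curvature_sweep`, or a data frame with `diameter_nm` and
#'   `s_mean` columns.
#' @param reference_diameter_nm The diameter whose partitioning is defined
#'   as 1 (default 200 nm; must be present in the sweep).
#' @param temperature_k Temperature (K), stored for interface clarity only.
#' @return An object of class `partitioning_prediction`: data frame of
#'   diameters, delta_delta_s (k_B) and k_ratio.
#' @export
relative_partitioning <- function(sweep, reference_diameter_nm = 200,
                                  temperature_k = 295) {
  tab <- if (inherits(sweep, "curvature_sweep")) sweep$table else sweep
  ref <- which(tab$diameter_nm == reference_diameter_nm)
  if (length(ref) != 1)
    stop(sprintf("reference diameter %g nm not present in the sweep",
                 reference_diameter_nm))
  dds <- tab$s_mean - tab$s_mean[ref]
  out <- data.frame(diameter_nm = tab$diameter_nm, delta_delta_s = dds,
                    k_ratio = exp(dds))
  structure(list(table = out,
                 reference_diameter_nm = reference_diameter_nm,
                 temperature_k = temperature_k),
            class = "partitioning_prediction")
}

#' @export
print.partitioning_prediction <- function(x, ...) {
  cat(sprintf("relative partitioning (reference %g nm):\n",
              x$reference_diameter_nm))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Predicted curvature-sensitivity profile
#'
#' Table of predicted bound-density ratios relative to the reference
#' diameter, directly comparable to the normalized sensitivity computed by
#' the vesicle-binding pipeline.
#'
#' @param prediction A `partitioning_prediction`.
#' @return Data frame with `diameter_nm` and `predicted_sensitivity`.
#' @export
predict_sensitivity_profile <- function(prediction) {
  stopifnot(inherits(prediction, "partitioning_prediction"))
  data.frame(diameter_nm = prediction$table$diameter_nm,
             predicted_sensitivity = prediction$table$k_ratio)
}

#' Calibrate the Kuhn length against a measured radius of gyration
#'
#' Simulates the free-chain Rg of each candidate model at the given contour
#' length, ranks candidates by |Rg_sim - Rg_target| and reports the implied
#' Kuhn length l_K = <Ree^2> / L_c of each.
#'
#' @param models List of `saw_model`s (>= 1).
#' @param contour_nm Contour length (nm).
#' @param target_rg_nm Measured radius of gyration (nm, > 0).
#' @param n_steps,n_traj,seed Passed to [chain_stats()].
#' @return An object of class `kuhn_calibration`: ranked data frame plus the
#'   selected model name.
#' @export
calibrate_kuhn_length <- function(models, contour_nm, target_rg_nm,
                                  n_steps = 20000L, n_traj = 8L, seed = 1L) {
  if (length(models) < 1) stop("empty model family")
  if (target_rg_nm <= 0) stop("target Rg must be positive")
  rows <- lapply(seq_along(models), function(i) {
    m <- models[[i]]
    nb <- max(1L, round(contour_nm / m$step_length_nm))
    st <- chain_stats(m, nb, n_steps = n_steps, n_traj = n_traj,
                      seed = seed + (i - 1L) * n_traj)
    data.frame(model = m$name, n_bonds = nb, rg_nm = st$rg_mean,
               rg_se = st$rg_se, l_k_nm = kuhn_length(st, contour_nm),
               abs_err = abs(st$rg_mean - target_rg_nm))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$abs_err), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, best_model = tab$model[1],
                 target_rg_nm = target_rg_nm, contour_nm = contour_nm),
            class = "kuhn_calibration")
}

#' @export
print.kuhn_calibration <- function(x, ...) {
  cat(sprintf("Kuhn calibration against Rg = %.4g nm (contour %.4g nm); best: %s\n",
              x$target_rg_nm, x$contour_nm, x$best_model))
  print(x$table, row.names = FALSE)
  invisible(x)
}
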