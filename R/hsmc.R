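#' HSMC run configuration
#'
#' Controls the hypothetical-scanning reconstruction: when building bond j of
#' an n-bond chain, the future segment (bonds j..n) is simulated with the
#' past frozen for n_MC(j) = n_bar * n_nbr * (n - j + 1) MC steps (after
#' n_bar_prime * n_nbr * (n - j + 1) equilibration steps from a fresh
#' extended conformation), one MC step being a sweep of (n - j + 1)
#' local-move attempts on the future segment. The visit frequency of each
#' candidate direction of bond j is tallied over the n_MC(j) steps.
#' Defaults match production-scale runs
#' (n_bar = 1000, n_bar_prime = 100, 96 reconstructions); tests use far
#' smaller values.
#'
#' @param n_bar Monte Carlo scaling base for the scan.
#' @param n_bar_prime Scaling base for equilibration between bonds.
#' @param n_recon Number of chain reconstructions per entropy estimate.
#' @param draw How the realized direction of bond j is drawn after the scan:
#'   "weighted" (from the empirical frequency table, the default) or
#'   "uniform" (uniformly over observed directions, for sensitivity checks).
#' @return An object of class `hsmc_config`.
#' @export
hsmc_config <- function(n_bar = 1000, n_bar_prime = 100, n_recon = 96,
                        draw = c("weighted", "uniform")) {
  draw <- match.arg(draw)
  stopifnot(n_bar > 0, n_bar_prime > 0, n_recon > 0)
  structure(list(n_bar = n_bar, n_bar_prime = n_bar_prime,
                 n_recon = as.integer(n_recon), draw = draw),
            class = "hsmc_config")
}

#' Scan the direction distribution of one bond
#'
#' Freezes the given prefix (beads 1..j of a chain that will have
#' `n_total_bonds` bonds), reinitializes the future segment to an allowed
#' extended conformation, equilibrates, then runs the scan and returns the
#' frequency with which each candidate direction of bond j was observed.
#'
#' @param past Integer matrix of frozen bead coordinates (the prefix; the
#'   scanned bond j equals `nrow(past)`), or a `conformation`.
#' @param model A `saw_model`.
#' @param substrate A `substrate` or NULL.
#' @param n_total_bonds Total bonds of the chain being reconstructed.
#' @param config An `hsmc_config`.
#' @param ideal Test mode: disable all exclusion and substrate constraints
#'   (unconstrained ideal walk).
#' @param seed Optional RNG seed.
#' @return List with `counts` (per direction, rows aligned with
#'   `model$directions`), `p` (counts / n_mc) and `n_mc`.
#' @export
scan_bond_distribution <- function(past, model, substrate = NULL,
                                   n_total_bonds, config = hsmc_config(),
                                   ideal = FALSE, seed = NULL) {
  coords <- if (inherits(past, "conformation")) past$coords else past
  storage.mode(coords) <- "integer"
  if (!is.null(seed)) set.seed(seed)
  sub <- .sub_args(substrate)
  res <- cpp_scan_bond(coords, model$directions, model$exclusion, sub$code,
                       sub$radius, as.integer(n_total_bonds), config$n_bar,
                       config$n_bar_prime, ideal)
  list(counts = res$counts, p = res$counts / res$n_mc, n_mc = res$n_mc)
}

#' Reconstruct one chain by hypothetical scanning
#'
#' Builds bonds 1..n sequentially. For each bond the future segment is
#' scanned (see [scan_bond_distribution()]), the realized direction is drawn
#' from the empirical frequency table (or uniformly over observed
#' directions), and its probability p_j is recorded. The reconstruction
#' probability is prod(p_j). Dead ends (no valid completion of a future
#' segment) are resampled with a warning, up to `max_retries` attempts.
#'
#' @inheritParams scan_bond_distribution
#' @param n_bonds Number of bonds to build.
#' @param max_retries Maximum dead-end resamples.
#' @return An object of class `reconstruction_record` with `log_p`,
#'   `per_bond_p`, `conformation` and `discards`.
#' @export
reconstruct_chain <- function(model, n_bonds, substrate = NULL,
                              config = hsmc_config(), ideal = FALSE,
                              seed = NULL, max_retries = 25L) {
  stopifnot(inherits(model, "saw_model"), n_bonds >= 1)
  if (!is.null(seed)) set.seed(seed)
  sub <- .sub_args(substrate)
  discards <- 0L
  repeat {
    res <- cpp_hsmc_reconstruct(model$directions, model$exclusion, sub$code,
                                sub$radius, as.integer(n_bonds),
                                sub$tether_site, config$n_bar,
                                config$n_bar_prime,
                                config$draw == "weighted", ideal)
    if (!res$dead_end) break
    discards <- discards + 1L
    warning(sprintf("dead-end reconstruction at bond %d; resampling",
                    res$at_bond))
    if (discards > max_retries)
      stop("too many dead-end reconstructions; chain/substrate combination may be jammed")
  }
  structure(list(log_p = res$log_p, per_bond_p = res$p_bond,
                 conformation = .as_conformation(res$coords, model,
                                                 sub$kind != "none"),
                 discards = discards),
            class = "reconstruction_record")
}

#' Entropy bounds from reconstruction records
#'
#' The upper bound is minus the mean log reconstruction probability; the
#' lower bound is the reconstruction-probability-weighted analogue. The
#' reported entropy is their mean (units of k_B), with a jackknife standard
#' error over reconstructions.
#'
#' @param records List of `reconstruction_record`s, or a numeric vector of
#'   log reconstruction probabilities.
#' @return An object of class `entropy_estimate` with `s_upper`, `s_lower`,
#'   `s_mean`, `se`, `n_obs`.
#' @export
entropy_from_samples <- function(records) {
  logp <- if (is.numeric(records)) records
          else vapply(records, function(r) r$log_p, numeric(1))
  n <- length(logp)
  if (n < 2) stop("need at least 2 reconstruction records")
  est <- function(l) {
    su <- -mean(l)
    w <- exp(l - max(l))
    sl <- -sum(w * l) / sum(w)
    c(su, sl, (su + sl) / 2)
  }
  full <- est(logp)
  jack <- vapply(seq_len(n), function(i) est(logp[-i])[3], numeric(1))
  se <- sqrt((n - 1) / n * sum((jack - mean(jack))^2))
  structure(list(s_upper = full[1], s_lower = full[2], s_mean = full[3],
                 se = se, n_obs = n),
            class = "entropy_estimate")
}

#' @export
print.entropy_estimate <- function(x, ...) {
  cat(sprintf("entropy (k_B): S = %.4g +/- %.2g  [S_U = %.4g, S_L = %.4g, n = %d]\n",
              x$s_mean, x$se, x$s_upper, x$s_lower, x$n_obs))
  invisible(x)
}

#' Absolute entropy of a (tethered) chain by HSMC
#'
#' Runs `config$n_recon` reconstructions (see [reconstruct_chain()]) and
#' combines them with [entropy_from_samples()]. With a substrate the chain
#' is anchored at the tether site; without one the first bead is held at the
#' origin, so the estimate targets log of the number of walks from a point.
#'
#' @inheritParams reconstruct_chain
#' @param seed Master seed; reconstruction k uses seed + k - 1.
#' @return An `entropy_estimate` (with attribute `discards`).
#' @export
tethered_entropy <- function(model, n_bonds, substrate = NULL,
                             config = hsmc_config(), seed = 1L) {
  recs <- vector("list", config$n_recon)
  discards <- 0L
  for (k in seq_len(config$n_recon)) {
    recs[[k]] <- reconstruct_chain(model, n_bonds, substrate, config,
                                   seed = seed + k - 1L)
    discards <- discards + recs[[k]]$discards
  }
  out <- entropy_from_samples(recs)
  attr(out, "discards") <- discards
  out
}
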