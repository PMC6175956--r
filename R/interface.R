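#' Constants registry
#'
#' The numeric defaults used across the package: 0.38 nm step length,
#' HSMC scaling bases, 5-nm diameter bins with the 190-210 nm reference
#' window, fixed FCS triplet parameters, 6.0 nm protein radius and the
#' 115 nm^2 footprint of a 569-residue disordered domain.
#'
#' @return Named list of constants.
#' @export
saw_constants <- function() {
  list(step_length_nm = 0.38, n_bar = 1000, n_bar_prime = 100,
       n_recon = 96, n_traj = 64, n_blocks = 10,
       bin_width_nm = 5, bin_range_nm = c(20, 250),
       reference_window_nm = c(190, 210), reference_diameter_nm = 200,
       fcs_triplet_a = 0.05, fcs_triplet_tau_c = 5e-6,
       r_p_nm = 6.0, footprint_nm2 = 115, footprint_residues = 569)
}

.log_msg <- function(level, ...) {
  message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                  sprintf(...)))
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.write_meta <- function(path, args, seed) {
  meta <- list(package = "curvsense",
               version = as.character(utils::packageVersion("curvsense")),
               seed = seed, args = args)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(NULL)
}

# minimal --flag value parser; returns named list or signals a usage error
.parse_flags <- function(argv, required = character(), optional = character()) {
  out <- list()
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--"))
      stop(sprintf("unexpected argument '%s'", a), call. = FALSE)
    key <- sub("^--", "", a)
    if (!key %in% c(required, optional))
      stop(sprintf("unknown flag '--%s'", key), call. = FALSE)
    if (i + 1 > length(argv))
      stop(sprintf("flag '--%s' needs a value", key), call. = FALSE)
    out[[key]] <- argv[i + 1]
    i <- i + 2
  }
  missing <- setdiff(required, names(out))
  if (length(missing))
    stop(sprintf("missing required flag(s): %s",
                 paste0("--", missing, collapse = ", ")), call. = FALSE)
  out
}

.num <- function(x) as.numeric(strsplit(x, ",")[[1]])

.cli_usage <- function() {
  paste(
    "usage: curvsense <subcommand> [--flag value ...]",
    "subcommands:",
    "  simulate-saw       --model --bonds --steps --out [--traj --seed]",
    "  entropy            --model --bonds --out [--substrate --radius --n-bar --n-bar-prime --n-recon --seed]",
    "  predict-sensitivity --model --contour --diameters --out [--n-bar --n-bar-prime --n-recon --seed]",
    "  analyze-vesicles   --puncta --dls-means --sm-intensity --out [--footprint]",
    "  fit-binding        --series --out",
    "  fit-fcs            --trace --out [--a --tau-c --alpha-min --alpha-max]",
    "  filopodia          --table --out",
    "  synth              --what vesicles|fcs|filopodia|single --out [--seed --n]",
    sep = "\n")
}

#' Command-line interface
#'
#' Dispatches the package's subcommands; every run writes its artifacts as
#' CSV plus a JSON reproducibility record (seed, arguments, version).
#' Returns (and, under `Rscript`, exits with) status 0 on success and 2 on
#' usage errors.
#'
#' @param argv Character vector of arguments (defaults to the command line).
#' @return Invisibly, the integer exit status.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(argv) == 0) stop("no subcommand given", call. = FALSE)
    cmd <- argv[1]
    rest <- argv[-1]
    switch(cmd,
      "simulate-saw" = .cli_simulate_saw(rest),
      "entropy" = .cli_entropy(rest),
      "predict-sensitivity" = .cli_predict_sensitivity(rest),
      "analyze-vesicles" = .cli_analyze_vesicles(rest),
      "fit-binding" = .cli_fit_binding(rest),
      "fit-fcs" = .cli_fit_fcs(rest),
      "filopodia" = .cli_filopodia(rest),
      "synth" = .cli_synth(rest),
      stop(sprintf("unknown subcommand '%s'", cmd), call. = FALSE))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    message(.cli_usage())
    2L
  })
  invisible(status)
}

.cli_simulate_saw <- function(argv) {
  fl <- .parse_flags(argv, required = c("model", "bonds", "steps", "out"),
                     optional = c("traj", "seed"))
  seed <- as.integer(fl$seed %||% 1)
  model <- saw_model(fl$model)
  st <- chain_stats(model, as.integer(fl$bonds),
                    n_steps = as.integer(fl$steps),
                    n_traj = as.integer(fl$traj %||% 8), seed = seed)
  .write_csv(data.frame(model = model$name, n_bonds = st$n_bonds,
                        rg_nm = st$rg_mean, rg_se = st$rg_se,
                        ree_sq_nm2 = st$ree_sq_mean,
                        ree_sq_se = st$ree_sq_se, seed = seed), fl$out)
  .write_meta(fl$out, fl, seed)
  .log_msg("INFO", "wrote chain stats to %s", fl$out)
}

.cli_entropy <- function(argv) {
  fl <- .parse_flags(argv, required = c("model", "bonds", "out"),
                     optional = c("substrate", "radius", "n-bar",
                                  "n-bar-prime", "n-recon", "seed"))
  seed <- as.integer(fl$seed %||% 1)
  model <- saw_model(fl$model)
  cfg <- hsmc_config(n_bar = as.numeric(fl[["n-bar"]] %||% 1000),
                     n_bar_prime = as.numeric(fl[["n-bar-prime"]] %||% 100),
                     n_recon = as.integer(fl[["n-recon"]] %||% 96))
  kind <- fl$substrate %||% "none"
  radii <- if (!is.null(fl$radius)) .num(fl$radius) else NA
  rows <- lapply(radii, function(r) {
    sub <- if (kind %in% c("none", "plane")) substrate(kind)
           else substrate(kind, radius = r)
    est <- tethered_entropy(model, as.integer(fl$bonds), sub, cfg, seed = seed)
    data.frame(model = model$name, n_bonds = as.integer(fl$bonds),
               substrate = kind, radius_lattice = sub$radius,
               radius_nm = sub$radius * model$lattice_nm,
               s_upper = est$s_upper, s_lower = est$s_lower,
               s_mean = est$s_mean, se = est$se, n_obs = est$n_obs,
               seed = seed)
  })
  .write_csv(do.call(rbind, rows), fl$out)
  .write_meta(fl$out, fl, seed)
  .log_msg("INFO", "wrote entropy table to %s", fl$out)
}

.cli_predict_sensitivity <- function(argv) {
  fl <- .parse_flags(argv, required = c("model", "contour", "diameters", "out"),
                     optional = c("n-bar", "n-bar-prime", "n-recon", "seed"))
  seed <- as.integer(fl$seed %||% 1)
  model <- saw_model(fl$model)
  cfg <- hsmc_config(n_bar = as.numeric(fl[["n-bar"]] %||% 1000),
                     n_bar_prime = as.numeric(fl[["n-bar-prime"]] %||% 100),
                     n_recon = as.integer(fl[["n-recon"]] %||% 96))
  sweep <- entropy_vs_curvature(model, as.numeric(fl$contour),
                                .num(fl$diameters), cfg,
                                include_flat = FALSE, seed = seed)
  pred <- relative_partitioning(sweep)
  .write_csv(pred$table, fl$out)
  .write_meta(fl$out, fl, seed)
  .log_msg("INFO", "wrote sensitivity prediction to %s", fl$out)
}

.cli_analyze_vesicles <- function(argv) {
  fl <- .parse_flags(argv, required = c("puncta", "dls-means",
                                        "sm-intensity", "out"),
                     optional = c("footprint"))
  puncta <- utils::read.csv(fl$puncta)
  res <- analyze_vesicles(puncta, .num(fl[["dls-means"]]),
                          as.numeric(fl[["sm-intensity"]]),
                          footprint_nm2 = as.numeric(fl$footprint %||% 115))
  .write_csv(as.data.frame(res$sensitivity), fl$out)
  .write_meta(fl$out, fl, NA)
  .log_msg("INFO", "wrote sensitivity profile to %s (average coverage %.3g)",
           fl$out, res$avg_coverage)
}

.cli_fit_binding <- function(argv) {
  fl <- .parse_flags(argv, required = c("series", "out"))
  df <- utils::read.csv(fl$series)
  fit <- fit_langmuir(df$concentration_nM, df$bound,
                      ci = if ("ci" %in% names(df)) df$ci else NULL)
  .write_csv(data.frame(kd_nM = fit$kd_nM, b_max = fit$b_max,
                        kd_sd = fit$kd_sd, b_max_sd = fit$b_max_sd), fl$out)
  .write_meta(fl$out, fl, NA)
  .log_msg("INFO", "K_D = %.4g nM, B_max = %.4g", fit$kd_nM, fit$b_max)
}

.cli_fit_fcs <- function(argv) {
  fl <- .parse_flags(argv, required = c("trace", "out"),
                     optional = c("a", "tau-c", "alpha-min", "alpha-max"))
  df <- utils::read.csv(fl$trace)
  fit <- fit_fcs(df$lag_s, df$g, a = as.numeric(fl$a %||% 0.05),
                 tau_c = as.numeric(fl[["tau-c"]] %||% 5e-6),
                 alpha_bounds = c(as.numeric(fl[["alpha-min"]] %||% 0.9),
                                  as.numeric(fl[["alpha-max"]] %||% 1.0)))
  jsonlite::write_json(unclass(fit), fl$out, auto_unbox = TRUE, digits = NA)
  .log_msg("INFO", "N_p = %.4g, tau_D = %.4g s", fit$n_p, fit$tau_d)
}

.cli_filopodia <- function(argv) {
  fl <- .parse_flags(argv, required = c("table", "out"))
  df <- utils::read.csv(fl$table)
  res <- filopodia_partition(df)
  .write_csv(data.frame(mean = res$mean, ci95 = res$ci95, n = res$n,
                        n_excluded = res$n_excluded), fl$out)
  .write_meta(fl$out, fl, NA)
  .log_msg("INFO", "partition coefficient %.3f +/- %.3f (n = %d)",
           res$mean, res$ci95, res$n)
}

.cli_synth <- function(argv) {
  fl <- .parse_flags(argv, required = c("what", "out"),
                     optional = c("seed", "n"))
  seed <- as.integer(fl$seed %||% 1)
  cfg <- synth_config()
  what <- fl$what
  if (what == "vesicles") {
    res <- gen_vesicle_puncta(cfg, seed = seed)
    .write_csv(res$puncta, fl$out)
    jsonlite::write_json(res$truth, paste0(fl$out, ".truth.json"),
                         digits = NA)
  } else if (what == "fcs") {
    tr <- gen_fcs_trace(n_p = 2, tau_d = 1e-3, seed = seed)
    .write_csv(tr, fl$out)
  } else if (what == "filopodia") {
    .write_csv(gen_filopodia(cfg, seed = seed), fl$out)
  } else if (what == "single") {
    .write_csv(data.frame(
      intensity = gen_single_molecule(cfg, as.integer(fl$n %||% 1000),
                                      seed = seed)), fl$out)
  } else stop(sprintf("unknown synth target '%s'", what), call. = FALSE)
  .write_meta(fl$out, fl, seed)
  .log_msg("INFO", "wrote synthetic %s to %s", what, fl$out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
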