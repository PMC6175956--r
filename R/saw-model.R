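#' Walk directions of a lattice step class
#'
#' A step class (P, Q, R) on the simple cubic lattice allows every distinct
#' signed coordinate permutation of the triple as a bond vector. The familiar
#' nearest-neighbour walk is (0, 0, 1) with 6 directions; (1, 1, 2) gives 24.
#'
#' @param p,q,r Non-negative integers, not all zero.
#' @return Integer matrix with one direction per row, three columns.
#' @export
#' @examples
#' nrow(step_directions(1, 1, 2)) # 24
step_directions <- function(p, q, r) {
  s <- c(p, q, r)
  if (any(s < 0) || any(s != round(s)))
    stop("step class components must be non-negative integers")
  if (all(s == 0)) stop("step class (0,0,0) is not a walk")
  perms <- unique(rbind(
    s[c(1, 2, 3)], s[c(1, 3, 2)], s[c(2, 1, 3)],
    s[c(2, 3, 1)], s[c(3, 1, 2)], s[c(3, 2, 1)]
  ))
  signs <- as.matrix(expand.grid(c(1L, -1L), c(1L, -1L), c(1L, -1L)))
  out <- do.call(rbind, lapply(seq_len(nrow(perms)), function(i) {
    sweep(signs, 2, perms[i, ], `*`)
  }))
  out <- unique(out)
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  out
}

#' Excluded offsets of a steric shell of order X
#'
#' Order X excludes the union of the X nearest-neighbour shells of the cubic
#' lattice, ranked by squared distance over the realizable values
#' (1, 2, 3, 4, ...). X = 0 excludes nothing beyond site coincidence,
#' X = 1 the 6 first neighbours, X = 2 adds the 12 second neighbours.
#'
#' @param x Non-negative integer shell order.
#' @return Integer matrix of nonzero excluded offsets (possibly 0 rows).
#' @export
exclusion_offsets <- function(x) {
  if (length(x) != 1 || x < 0 || x != round(x))
    stop("shell order X must be a single non-negative integer")
  if (x == 0) return(matrix(integer(0), ncol = 3))
  m <- ceiling(sqrt(x + 3))  # generous bounding cube
  g <- as.matrix(expand.grid(-m:m, -m:m, -m:m))
  d2 <- rowSums(g^2)
  g <- g[d2 > 0, , drop = FALSE]
  d2 <- d2[d2 > 0]
  shells <- sort(unique(d2))
  keep <- d2 <= shells[x]
  out <- g[keep, , drop = FALSE]
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  out[order(rowSums(out^2), out[, 1], out[, 2], out[, 3]), , drop = FALSE]
}

#' Construct and validate a lattice SAW model
#'
#' Models are named "nbrPQRexclX": bond vectors are the signed coordinate
#' permutations of (P, Q, R) and each occupied site excludes its neighbours
#' up to the X-th shell. A model is rejected when the squared step length
#' does not exceed the largest excluded squared distance (bonded beads would
#' violate the shell). The physical step length (default 0.38 nm, the
#' Calpha-Calpha spacing) sets the lattice constant
#' a = step_length_nm / sqrt(P^2 + Q^2 + R^2).
#'
#' @param name Canonical model string such as "nbr112excl2"; alternatively
#'   supply `p`, `q`, `r`, `x` directly.
#' @param p,q,r,x Step class and shell order (used when `name` is missing).
#' @param step_length_nm Physical length of one step in nm.
#' @return An object of class `saw_model`.
#' @export
#' @examples
#' m <- saw_model("nbr112excl2")
#' m$n_nbr # 24
saw_model <- function(name = NULL, p = NULL, q = NULL, r = NULL, x = NULL,
                      step_length_nm = 0.38) {
  if (!is.null(name)) {
    mt <- regmatches(name, regexec("^nbr([0-9])([0-9])([0-9])excl([0-9]+)$", name))[[1]]
    if (length(mt) != 5)
      stop("model name must have the form 'nbrPQRexclX' (single-digit P, Q, R)")
    p <- as.integer(mt[2]); q <- as.integer(mt[3]); r <- as.integer(mt[4])
    x <- as.integer(mt[5])
  }
  if (is.null(p) || is.null(q) || is.null(r) || is.null(x))
    stop("supply either a model name or all of p, q, r, x")
  if (step_length_nm <= 0 || !is.finite(step_length_nm))
    stop("step_length_nm must be positive and finite")
  dirs <- step_directions(p, q, r)
  excl <- exclusion_offsets(x)
  step_len_sq <- sum(c(p, q, r)^2)
  max_excl_sq <- if (nrow(excl)) max(rowSums(excl^2)) else 0L
  if (step_len_sq <= max_excl_sq)
    stop(sprintf(
      "invalid model nbr%d%d%dexcl%d: squared step length %d does not exceed the largest excluded squared distance %d, so bonded beads would sit inside the exclusion shell",
      p, q, r, x, step_len_sq, max_excl_sq))
  structure(list(
    p = p, q = q, r = r, x = x,
    name = sprintf("nbr%d%d%dexcl%d", p, q, r, x),
    directions = dirs,
    n_nbr = nrow(dirs),
    step_len_sq = step_len_sq,
    exclusion = excl,
    max_excl_sq = max_excl_sq,
    step_length_nm = step_length_nm,
    lattice_nm = step_length_nm / sqrt(step_len_sq)
  ), class = "saw_model")
}

#' @export
print.saw_model <- function(x, ...) {
  cat(sprintf("SAW model %s: %d directions, step %.3g nm (lattice constant %.4g nm), exclusion shell order %d (%d offsets)\n",
              x$name, x$n_nbr, x$step_length_nm, x$lattice_nm, x$x,
              nrow(x$exclusion)))
  invisible(x)
}

.substrate_kinds <- c(none = 0L, plane = 1L, sphere_exterior = 2L,
                      sphere_interior = 3L, cylinder_exterior = 4L)

#' Membrane substrate as excluded lattice sites
#'
#' The substrate is a solid region of the lattice whose sites are excluded
#' from occupancy: a half-space below the plane z = 0, the inside of a
#' sphere (`sphere_exterior`: chain lives outside), the outside of a sphere
#' (`sphere_interior`: chain lives inside), or the inside of an infinite
#' cylinder along z. A site is excluded iff it lies strictly inside the
#' solid region. The tether site is the non-excluded lattice site nearest
#' the surface on a coordinate axis.
#'
#' @param kind One of "none", "plane", "sphere_exterior", "sphere_interior",
#'   "cylinder_exterior".
#' @param radius Radius in lattice units (required for the curved kinds).
#' @return An object of class `substrate`.
#' @export
substrate <- function(kind = c("none", "plane", "sphere_exterior",
                               "sphere_interior", "cylinder_exterior"),
                      radius = NULL) {
  kind <- match.arg(kind)
  code <- .substrate_kinds[[kind]]
  if (kind %in% c("sphere_exterior", "sphere_interior", "cylinder_exterior")) {
    if (is.null(radius) || radius <= 0)
      stop("curved substrates need a positive radius (lattice units)")
  } else radius <- 0
  tether <- switch(kind,
    none = c(0L, 0L, 0L),
    plane = c(0L, 0L, 0L),
    sphere_exterior = c(0L, 0L, as.integer(ceiling(radius))),
    sphere_interior = c(0L, 0L, as.integer(floor(radius))),
    cylinder_exterior = c(as.integer(ceiling(radius)), 0L, 0L))
  structure(list(kind = kind, code = code, radius = radius,
                 tether_site = tether),
            class = "substrate")
}

#' @export
print.substrate <- function(x, ...) {
  if (x$kind %in% c("none", "plane"))
    cat(sprintf("substrate: %s\n", x$kind))
  else
    cat(sprintf("substrate: %s, radius %.4g lattice units\n", x$kind, x$radius))
  invisible(x)
}

.sub_args <- function(substrate) {
  if (is.null(substrate)) substrate <- substrate("none")
  stopifnot(inherits(substrate, "substrate"))
  substrate
}

.as_conformation <- function(coords, model, anchored) {
  structure(list(coords = coords, model = model$name, anchored = anchored,
                 anchor_index = 1L),
            class = "conformation")
}

#' Validity of a conformation under a model and substrate
#'
#' Checks that every bond is an allowed direction, that no bead coincides
#' with or lies within the exclusion shell of another bead, and that no bead
#' occupies a substrate-excluded site.
#'
#' @param conf A `conformation` or an integer coordinate matrix (beads x 3).
#' @param model A `saw_model`.
#' @param substrate A `substrate` or NULL.
#' @return Logical scalar.
#' @export
is_valid_conformation <- function(conf, model, substrate = NULL) {
  coords <- if (inherits(conf, "conformation")) conf$coords else conf
  storage.mode(coords) <- "integer"
  if (nrow(coords) < 1) stop("conformation is empty")
  sub <- .sub_args(substrate)
  cpp_is_valid(coords, model$directions, model$exclusion, sub$code, sub$radius)
}

#' Initial (extended) conformation
#'
#' Builds a valid conformation of `n_bonds` bonds, preferring a straight
#' line along the outward normal from the tether site; falls back to a
#' deterministic depth-first search when the straight placement is blocked.
#' With a substrate the first bead is anchored at the tether site.
#'
#' @inheritParams is_valid_conformation
#' @param n_bonds Number of bonds (>= 1).
#' @return A `conformation`.
#' @export
initial_conformation <- function(model, n_bonds, substrate = NULL) {
  stopifnot(inherits(model, "saw_model"), n_bonds >= 1)
  sub <- .sub_args(substrate)
  coords <- cpp_initial_conf(model$directions, model$exclusion, sub$code,
                             sub$radius, as.integer(n_bonds), sub$tether_site)
  .as_conformation(coords, model, anchored = sub$kind != "none")
}

#' Radius of gyration of a conformation (nm)
#'
#' Root-mean-square bead distance from the centroid, scaled by the model's
#' lattice constant.
#'
#' @inheritParams is_valid_conformation
#' @return Length in nm.
#' @export
radius_of_gyration <- function(conf, model) {
  coords <- if (inherits(conf, "conformation")) conf$coords else conf
  if (nrow(coords) < 1) stop("conformation is empty")
  cen <- colMeans(coords)
  rg_lat <- sqrt(mean(rowSums(sweep(coords, 2, cen)^2)))
  rg_lat * model$lattice_nm
}

#' Local-move Monte Carlo run over valid conformations
#'
#' One MC step is N local-move attempts (N bonds): a uniformly chosen bead
#' proposes a new site one random allowed direction away from its
#' predecessor (end beads from their single neighbour) and the move is
#' accepted iff the resulting chain is valid. The proposal is symmetric, so
#' sampling is uniform over valid conformations. The anchored bead never
#' moves.
#'
#' @inheritParams is_valid_conformation
#' @param n_steps Number of MC steps.
#' @param thin Keep one sample every `thin` MC steps.
#' @param seed Optional RNG seed.
#' @return List with `conformations` (list of `conformation`), `acceptance`,
#'   and `final`.
#' @export
mc_run <- function(conf, model, substrate = NULL, n_steps, thin = 1L,
                   seed = NULL) {
  stopifnot(inherits(conf, "conformation"))
  if (!is.null(seed)) set.seed(seed)
  sub <- .sub_args(substrate)
  res <- cpp_mc_run(conf$coords, model$directions, model$exclusion, sub$code,
                    sub$radius, conf$anchored, as.integer(n_steps),
                    as.integer(thin))
  arr <- res$samples
  n_samples <- dim(arr)[3]
  confs <- lapply(seq_len(n_samples), function(i)
    .as_conformation(t(arr[, , i]), model, conf$anchored))
  if (res$acceptance == 0)
    warning("zero acceptance over the run; chain may be jammed")
  list(conformations = confs, acceptance = res$acceptance,
       final = .as_conformation(res$final, model, conf$anchored))
}

#' Free-chain structural statistics (Rg, Ree^2) with block errors
#'
#' Runs `n_traj` independent trajectories of `n_steps` MC steps each (after
#' discarding `n_burn` steps), block-averages within trajectories, and
#' reports means with standard errors across trajectories.
#'
#' @inheritParams is_valid_conformation
#' @param n_bonds Number of bonds.
#' @param n_steps MC steps per trajectory (after burn-in).
#' @param n_traj Number of independent trajectories (default 64).
#' @param n_blocks Blocks per trajectory for within-trajectory averaging.
#' @param n_burn Burn-in MC steps discarded per trajectory.
#' @param measure_every Measure observables every this many MC steps.
#' @param use_pivot Augment each MC step with one pivot attempt (a random
#'   octahedral rotation of the chain tail about a random bead). Pivots
#'   target the same uniform distribution and are the standard cure for the
#'   slow relaxation of single-bead moves from extended states; disable to
#'   reproduce pure local-move dynamics.
#' @param seed Master seed; trajectory t uses seed + t - 1.
#' @return An object of class `chain_stats` with fields `rg_mean`, `rg_se`
#'   (nm), `ree_sq_mean`, `ree_sq_se` (nm^2) and `n_samples`.
#' @export
chain_stats <- function(model, n_bonds, n_steps, n_traj = 64L,
                        n_blocks = 10L, n_burn = n_steps %/% 2,
                        measure_every = 10L, use_pivot = TRUE, seed = 1L) {
  stopifnot(inherits(model, "saw_model"), n_bonds >= 1)
  if (n_traj < 2) stop("need at least 2 trajectories for a standard error")
  if (n_steps %% n_blocks != 0) stop("n_steps must be divisible by n_blocks")
  conf0 <- initial_conformation(model, n_bonds)
  sub <- substrate("none")
  per_traj <- t(vapply(seq_len(n_traj), function(t) {
    set.seed(seed + t - 1L)
    bm <- cpp_chain_observables(conf0$coords, model$directions,
                                model$exclusion, sub$code, sub$radius,
                                FALSE, as.integer(n_steps),
                                as.integer(n_burn),
                                as.integer(measure_every),
                                as.integer(n_blocks), use_pivot)$block_means
    c(mean(sqrt(bm[, 1])), mean(bm[, 2]))
  }, numeric(2)))
  a <- model$lattice_nm
  rg <- per_traj[, 1] * a
  ree2 <- per_traj[, 2] * a^2
  structure(list(
    rg_mean = mean(rg), rg_se = stats::sd(rg) / sqrt(n_traj),
    ree_sq_mean = mean(ree2), ree_sq_se = stats::sd(ree2) / sqrt(n_traj),
    n_samples = n_traj * n_blocks, model = model$name, n_bonds = n_bonds
  ), class = "chain_stats")
}

#' @export
print.chain_stats <- function(x, ...) {
  cat(sprintf("%s, %d bonds: Rg = %.4g +/- %.2g nm, <Ree^2> = %.4g +/- %.2g nm^2\n",
              x$model, x$n_bonds, x$rg_mean, x$rg_se, x$ree_sq_mean,
              x$ree_sq_se))
  invisible(x)
}

#' Kuhn length implied by chain dimensions
#'
#' Freely-jointed-chain mapping l_K = <Ree^2> / L_c evaluated at the chain's
#' own contour length.
#'
#' @param stats A `chain_stats` object (or a list with `ree_sq_mean`).
#' @param contour_nm Contour length in nm (> 0).
#' @return Kuhn length in nm.
#' @export
kuhn_length <- function(stats, contour_nm) {
  if (contour_nm <= 0) stop("contour length must be positive")
  ree2 <- stats$ree_sq_mean
  if (is.null(ree2) || ree2 < 0) stop("stats must supply a non-negative ree_sq_mean")
  ree2 / contour_nm
}

#' Exact count of valid walks by exhaustive enumeration
#'
#' Depth-first enumeration of all valid conformations of `n_bonds` bonds
#' starting from the tether site (or the origin for free chains). Used as
#' the independent oracle for the HSMC entropy estimates: the entropy of a
#' uniform ensemble is log of this count.
#'
#' @inheritParams initial_conformation
#' @param budget Maximum visited search nodes before aborting.
#' @return Exact count (double).
#' @export
enumerate_saws <- function(model, n_bonds, substrate = NULL, budget = 5e7) {
  stopifnot(inherits(model, "saw_model"), n_bonds >= 1)
  sub <- .sub_args(substrate)
  cpp_enumerate(model$directions, model$exclusion, sub$code, sub$radius,
                as.integer(n_bonds), sub$tether_site, budget)
}

#' Export a conformation as plain-text XYZ
#'
#' One bead per line: index x y z in lattice units.
#'
#' @inheritParams is_valid_conformation
#' @param path Output file path.
#' @export
write_conformation_xyz <- function(conf, path) {
  coords <- if (inherits(conf, "conformation")) conf$coords else conf
  df <- data.frame(index = seq_len(nrow(coords)) - 1L, x = coords[, 1],
                   y = coords[, 2], z = coords[, 3])
  utils::write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
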