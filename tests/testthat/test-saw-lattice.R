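test_that("direction sets match brute-force enumeration and stated counts", {
  cases <- list(c(0, 0, 1, 6), c(1, 1, 2, 24), c(1, 1, 1, 8), c(0, 1, 1, 12))
  for (cs in cases) {
    d <- step_directions(cs[1], cs[2], cs[3])
    expect_equal(nrow(d), cs[4])
    expect_setequal(vec_set(d), vec_set(brute_directions(cs[1], cs[2], cs[3])))
    # closed under negation
    expect_setequal(vec_set(d), vec_set(-d))
  }
  expect_error(step_directions(0, 0, 0), "not a walk")
  expect_error(step_directions(1, -1, 0), "non-negative")
})

test_that("exclusion shells match brute force and stated counts", {
  expect_equal(nrow(exclusion_offsets(0)), 0)
  for (x in 1:4) {
    off <- exclusion_offsets(x)
    expect_setequal(vec_set(off), vec_set(brute_exclusion(x)))
    expect_setequal(vec_set(off), vec_set(-off))
  }
  expect_equal(nrow(exclusion_offsets(1)), 6)
  expect_equal(nrow(exclusion_offsets(2)), 18) # 6 + 12
  expect_equal(nrow(exclusion_offsets(3)), 26)
  expect_error(exclusion_offsets(-1), "non-negative")
})

test_that("model validation accepts consistent step/shell pairs only", {
  expect_s3_class(saw_model("nbr112excl2"), "saw_model")
  expect_equal(saw_model("nbr112excl2")$name, "nbr112excl2")
  expect_error(saw_model("nbr001excl1"), "exclusion shell")
  expect_s3_class(saw_model("nbr001excl0"), "saw_model")
  m <- saw_model("nbr112excl2")
  expect_equal(m$lattice_nm, 0.38 / sqrt(6))
})

test_that("conformation validity predicate enforces all constraints", {
  m <- model_001
  rod <- cbind(0L, 0L, 0L:4L)
  expect_true(is_valid_conformation(rod, m))
  # revisiting a site
  loop <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 1, 1), c(0, 1, 0), c(0, 0, 0))
  expect_false(is_valid_conformation(loop, m))
  # bad bond
  jump <- rbind(c(0, 0, 0), c(0, 0, 2))
  expect_false(is_valid_conformation(jump, m))
  # substrate violation: bead below the plane
  below <- rbind(c(0, 0, 0), c(0, 0, -1))
  expect_false(is_valid_conformation(below, m, substrate("plane")))
  expect_true(is_valid_conformation(rod, m, substrate("plane")))
  # exclusion shell: beads at squared distance 2 under excl2
  m2 <- saw_model("nbr112excl2")
  close_pair <- rbind(c(0L, 0L, 0L), c(1L, 1L, 2L), c(1L, 0L, 1L))
  expect_false(is_valid_conformation(close_pair, m2))
})

test_that("initial conformation is valid, extended and anchored", {
  m <- model_001
  c0 <- initial_conformation(m, 10)
  expect_true(is_valid_conformation(c0, m))
  # straight rod along the preferred direction -> rod Rg formula
  n <- 11
  expect_equal(radius_of_gyration(c0, m),
               0.38 * sqrt(mean((0:10 - 5)^2)), tolerance = 1e-12)
  sub <- substrate("sphere_exterior", radius = 20)
  cs <- initial_conformation(m, 10, sub)
  expect_true(is_valid_conformation(cs, m, sub))
  expect_equal(cs$coords[1, ], sub$tether_site)
  expect_true(all(rowSums(cs$coords^2) >= 20^2))
})

test_that("radius of gyration closed forms", {
  m <- model_001
  expect_equal(radius_of_gyration(matrix(c(3L, 1L, 2L), 1), m), 0)
  expect_equal(radius_of_gyration(rbind(c(0L, 0L, 0L), c(0L, 0L, 1L)), m),
               0.38 / 2)
  rod4 <- cbind(0L, 0L, 0L:3L)
  expect_equal(radius_of_gyration(rod4, m), 0.38 * sqrt(1.25))
})

test_that("exact enumeration matches the independent R oracle", {
  m <- model_001
  expect_equal(enumerate_saws(m, 1), 6)
  expect_equal(enumerate_saws(m, 2), 30)
  expect_equal(enumerate_saws(m, 3), 150)
  for (sub in list(NULL, substrate("plane"),
                   substrate("sphere_exterior", radius = 3),
                   substrate("sphere_interior", radius = 5))) {
    expect_equal(enumerate_saws(m, 3, sub), brute_enumerate(m, 3, sub))
  }
  m2 <- saw_model("nbr011excl1")
  expect_equal(enumerate_saws(m2, 2), brute_enumerate(m2, 2))
  expect_error(enumerate_saws(m, 30, budget = 1000), "budget")
})

test_that("mc_run samples valid conformations uniformly (N = 2 oracle)", {
  m <- model_001
  c0 <- initial_conformation(m, 2)
  set.seed(99)
  run <- mc_run(c0, m, n_steps = 150000, thin = 10, seed = 99)
  expect_true(all(vapply(run$conformations[seq(1, 15000, by = 500)],
                         is_valid_conformation, logical(1), model = m)))
  # classify each sample by its two bond vectors; 30 equally likely walks
  key <- vapply(run$conformations, function(cf) {
    b <- diff(cf$coords)
    paste(b, collapse = ",")
  }, character(1))
  tab <- table(key)
  expect_equal(length(tab), 30)
  p_hat <- as.numeric(tab) / length(key)
  # 3 sigma multinomial band, inflated for residual autocorrelation
  tol <- 3 * sqrt((1 / 30) * (29 / 30) / (length(key) / 4))
  expect_true(all(abs(p_hat - 1 / 30) < tol))
})

test_that("anchored bead never moves and seeds give identical trajectories", {
  m <- model_001
  sub <- substrate("plane")
  c0 <- initial_conformation(m, 6, sub)
  r1 <- mc_run(c0, m, sub, n_steps = 500, thin = 10, seed = 7)
  r2 <- mc_run(c0, m, sub, n_steps = 500, thin = 10, seed = 7)
  expect_identical(r1$conformations, r2$conformations)
  anchors <- t(vapply(r1$conformations, function(cf) cf$coords[1, ],
                      integer(3)))
  expect_true(all(anchors[, 1] == c0$coords[1, 1] &
                  anchors[, 2] == c0$coords[1, 2] &
                  anchors[, 3] == c0$coords[1, 3]))
  expect_true(all(vapply(r1$conformations, is_valid_conformation,
                         logical(1), model = m, substrate = sub)))
})

test_that("chain_stats: exact N = 1 case, reproducibility, kuhn length", {
  m <- model_001
  st <- chain_stats(m, 1, n_steps = 1000, n_traj = 4, n_blocks = 10, seed = 2)
  expect_equal(st$rg_mean, 0.38 / 2, tolerance = 1e-12)
  expect_equal(st$ree_sq_mean, 0.38^2, tolerance = 1e-12)
  expect_equal(st$rg_se, 0)
  st2 <- chain_stats(m, 8, n_steps = 2000, n_traj = 4, seed = 5)
  st3 <- chain_stats(m, 8, n_steps = 2000, n_traj = 4, seed = 5)
  expect_identical(st2$rg_mean, st3$rg_mean)
  # self-avoidance swells the chain beyond the ideal-chain value
  expect_gt(kuhn_length(st2, 8 * 0.38), 0.38)
  # closed forms
  expect_equal(kuhn_length(list(ree_sq_mean = 100), 10), 10) # rigid rod L = 10
  expect_equal(kuhn_length(list(ree_sq_mean = 0.38 * 10), 10), 0.38)
  expect_error(kuhn_length(list(ree_sq_mean = 1), 0), "positive")
})

test_that("xyz export round-trips coordinates", {
  m <- model_001
  c0 <- initial_conformation(m, 4)
  f <- tempfile(fileext = ".xyz")
  write_conformation_xyz(c0, f)
  df <- read.table(f, header = TRUE)
  expect_equal(as.matrix(df[, c("x", "y", "z")]),
               c0$coords, ignore_attr = TRUE)
})
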