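test_that("scan of an unconstrained ideal walk is uniform over directions", {
  m <- model_001
  past <- matrix(c(0L, 0L, 0L), 1)
  s <- scan_bond_distribution(past, m, NULL, n_total_bonds = 3,
                              config = test_hsmc(), ideal = TRUE, seed = 4)
  expect_equal(sum(s$counts), s$n_mc)
  p <- s$p
  # 3 sigma binomial band with a generous autocorrelation inflation
  tol <- 3 * sqrt((1 / 6) * (5 / 6) / (s$n_mc / 20))
  expect_true(all(abs(p - 1 / 6) < tol))
})

test_that("last-bond scan reproduces exact single-step counts", {
  m <- model_001
  # prefix one step above a plane: bead (0,0,1) after (0,0,0); last bond of 2
  past <- rbind(c(0L, 0L, 0L), c(0L, 0L, 1L))
  cfg <- hsmc_config(n_bar = 1000, n_bar_prime = 50, n_recon = 1)
  s <- scan_bond_distribution(past, m, substrate("plane"), n_total_bonds = 2,
                              config = cfg, seed = 8)
  # valid completions: 5 of 6 directions (reversal forbidden); uniform
  expect_equal(sum(s$p > 0), 5)
  expect_true(all(abs(s$p[s$p > 0] - 1 / 5) < 0.04))
  # determinism
  s2 <- scan_bond_distribution(past, m, substrate("plane"), n_total_bonds = 2,
                               config = cfg, seed = 8)
  expect_identical(s$counts, s2$counts)
})

test_that("a flat substrate below the anchor removes one first-bond direction", {
  m <- model_001
  past <- matrix(c(0L, 0L, 0L), 1)
  free <- scan_bond_distribution(past, m, NULL, 1, test_hsmc(), seed = 3)
  teth <- scan_bond_distribution(past, m, substrate("plane"), 1, test_hsmc(),
                                 seed = 3)
  expect_equal(sum(free$p > 0), 6)
  expect_equal(sum(teth$p > 0), 5)
})

test_that("single-bond reconstruction gives p = 1/6 in expectation", {
  m <- model_001
  # all 6 directions are valid, so the scanned frequency of the drawn
  # direction concentrates at 1/6 as the scan lengthens
  r <- reconstruct_chain(m, 1, config = hsmc_config(n_bar = 2000,
                                                    n_bar_prime = 50,
                                                    n_recon = 1), seed = 1)
  expect_equal(r$per_bond_p, 1 / 6, tolerance = 0.05)
  expect_equal(r$log_p, log(r$per_bond_p), tolerance = 1e-12)
  expect_s3_class(r$conformation, "conformation")
})

test_that("entropy_from_samples implements the bound pair and jackknife", {
  # degenerate: all records with p = 1/Z -> both bounds equal ln Z
  est <- entropy_from_samples(rep(log(1 / 30), 5))
  expect_equal(est$s_upper, log(30))
  expect_equal(est$s_lower, log(30))
  expect_equal(est$s_mean, log(30))
  expect_equal(est$se, 0)
  # non-degenerate: upper bound above lower bound, mean in between
  set.seed(2)
  lp <- log(1 / 30) + rnorm(200, 0, 0.2)
  est2 <- entropy_from_samples(lp)
  expect_gt(est2$s_upper, est2$s_lower)
  expect_equal(est2$s_mean, (est2$s_upper + est2$s_lower) / 2)
  expect_gt(est2$se, 0)
  expect_error(entropy_from_samples(log(0.5)), "at least 2")
})

test_that("free-chain HSMC agrees with the enumeration oracle (N = 2, 3)", {
  m <- model_001
  for (cs in list(c(2, 30), c(3, 150))) {
    est <- tethered_entropy(m, cs[1], NULL, test_hsmc(), seed = 21 + cs[1])
    expect_lt(abs(est$s_mean - log(cs[2])), 3 * est$se + 1e-9)
    expect_gt(est$s_upper, est$s_lower - 3 * est$se)
  }
})

test_that("ideal-mode entropy is extensive: s = n ln(n_nbr)", {
  m <- model_001
  cfg <- test_hsmc()
  recs <- lapply(1:16, function(k)
    reconstruct_chain(m, 4, config = cfg, ideal = TRUE, seed = 40 + k))
  est <- entropy_from_samples(recs)
  expect_lt(abs(est$s_mean - 4 * log(6)), 4 * est$se + 0.05)
})

test_that("tethered HSMC matches enumeration on substrates and is seeded", {
  m <- model_001
  sub <- substrate("sphere_exterior", radius = 3)
  est <- tethered_entropy(m, 3, sub, test_hsmc(), seed = 77)
  expect_lt(abs(est$s_mean - log(enumerate_saws(m, 3, sub))), 3 * est$se)
  est2 <- tethered_entropy(m, 3, sub, test_hsmc(), seed = 77)
  expect_identical(est$s_mean, est2$s_mean)
})

test_that("curvature ordering by exact counts: sphere > flat > interior", {
  m <- model_001
  n <- 4
  z_ext <- enumerate_saws(m, n, substrate("sphere_exterior", radius = 3))
  z_flat <- enumerate_saws(m, n, substrate("plane"))
  z_int <- enumerate_saws(m, n, substrate("sphere_interior", radius = 4))
  expect_gt(z_ext, z_flat)
  expect_gt(z_flat, z_int)
  # large exterior sphere converges to the flat count
  z_big <- enumerate_saws(m, n, substrate("sphere_exterior", radius = 400))
  expect_equal(z_big, z_flat)
})

test_that("large-radius tethered entropy approaches the flat limit", {
  m <- model_001
  cfg <- test_hsmc()
  est_big <- tethered_entropy(m, 4, substrate("sphere_exterior", radius = 500),
                              cfg, seed = 55)
  est_flat <- tethered_entropy(m, 4, substrate("plane"), cfg, seed = 56)
  expect_lt(abs(est_big$s_mean - est_flat$s_mean),
            3 * sqrt(est_big$se^2 + est_flat$se^2) + 1e-9)
})
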