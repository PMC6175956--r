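test_that("contour length mapping", {
  expect_equal(contour_length_nm(569), 568 * 0.38)
  expect_equal(round(contour_length_nm(569)), 216)
  expect_error(contour_length_nm(1), "at least 2")
})

test_that("Boltzmann conversion closed forms", {
  tab <- data.frame(diameter_nm = c(40, 100, 200),
                    s_mean = c(log(2), 1, 0) + 5)
  pred <- relative_partitioning(tab)
  expect_equal(pred$table$k_ratio, c(2, exp(1), 1))
  expect_equal(pred$table$delta_delta_s, c(log(2), 1, 0))
  expect_error(relative_partitioning(tab, reference_diameter_nm = 150),
               "reference")
  # doubling ddS squares the ratio
  tab2 <- tab; tab2$s_mean <- 2 * (tab$s_mean - 5) + 5
  pred2 <- relative_partitioning(tab2)
  expect_equal(pred2$table$k_ratio, pred$table$k_ratio^2)
})

test_that("sensitivity profile is the k_ratio table, identity at reference", {
  tab <- data.frame(diameter_nm = c(40, 200), s_mean = c(1.2, 0))
  prof <- predict_sensitivity_profile(relative_partitioning(tab))
  expect_equal(prof$predicted_sensitivity[prof$diameter_nm == 200], 1)
  expect_equal(prof$predicted_sensitivity[prof$diameter_nm == 40], exp(1.2))
})

test_that("single-diameter sweep has ddS identically zero", {
  m <- model_001
  sw <- entropy_vs_curvature(m, contour_nm = 4 * 0.38, diameters_nm = 6,
                             config = test_hsmc(8), include_flat = FALSE,
                             seed = 12)
  expect_equal(nrow(sw$table), 1)
  pred <- relative_partitioning(sw, reference_diameter_nm = 6)
  expect_equal(pred$table$delta_delta_s, 0)
  expect_equal(pred$table$k_ratio, 1)
})

test_that("small-chain sweep: entropy higher on the smaller sphere", {
  m <- model_001
  # exact-count oracle at two sphere radii (lattice units via diameters)
  z_small <- enumerate_saws(m, 4, substrate("sphere_exterior", radius = 3))
  z_large <- enumerate_saws(m, 4, substrate("sphere_exterior", radius = 40))
  expect_gt(log(z_small), log(z_large))
  sw <- entropy_vs_curvature(m, contour_nm = 4 * 0.38,
                             diameters_nm = c(3 * 2 * m$lattice_nm,
                                              40 * 2 * m$lattice_nm),
                             config = test_hsmc(16), include_flat = FALSE,
                             seed = 31)
  expect_gt(sw$table$s_mean[1], sw$table$s_mean[2])
  expect_lt(abs(sw$table$s_mean[1] - log(z_small)), 3 * sw$table$se[1])
  expect_lt(abs(sw$table$s_mean[2] - log(z_large)), 3 * sw$table$se[2])
})

test_that("kuhn calibration recovers a family member from its own Rg", {
  fam <- list(model_001, saw_model("nbr011excl1"))
  contour <- 24 * 0.38
  target <- chain_stats(fam[[2]], 24, n_steps = 10000, n_traj = 4,
                        seed = 9)$rg_mean
  cal <- calibrate_kuhn_length(fam, contour, target, n_steps = 10000,
                               n_traj = 4, seed = 600)
  expect_equal(cal$best_model, "nbr011excl1")
  expect_true(all(cal$table$l_k_nm > 0))
  # family of one trivially selects itself
  cal1 <- calibrate_kuhn_length(fam[1], contour, 1.0, n_steps = 5000,
                                n_traj = 4, seed = 601)
  expect_equal(cal1$best_model, "nbr001excl0")
  expect_error(calibrate_kuhn_length(list(), contour, 1), "empty")
})

test_that("free-chain Rg grows with implied Kuhn length at fixed contour", {
  # within one calibration scan, model ranking by Rg equals ranking by l_K
  fam <- list(model_001, saw_model("nbr011excl1"))
  cal <- calibrate_kuhn_length(fam, 24 * 0.38, 1.0, n_steps = 10000,
                               n_traj = 4, seed = 71)
  tab <- cal$table
  expect_equal(order(tab$rg_nm), order(tab$l_k_nm))
})
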