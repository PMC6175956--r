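test_that("diameter calibration: modal punctum maps to the DLS mean", {
  set.seed(1)
  cfg <- synth_config(n_puncta = 4000, intensity_cv = 0)
  d_true <- curvsense:::.draw_diameters(4000, 67, 0.3, c(15, 300))
  intens <- 0.02 * d_true^2
  d_hat <- calibrate_diameters(intens, 67)
  # area scaling: 4x the modal intensity is twice the modal diameter
  i0 <- intens[which.min(abs(d_hat - 67))]
  expect_equal(calibrate_diameters(c(intens, 4 * i0), 67)[4001], 2 * 67,
               tolerance = 0.02)
  # round-trip recovery within 5% RMS
  expect_lt(sqrt(mean((d_hat / d_true - 1)^2)), 0.05)
  expect_error(calibrate_diameters(rep(5, 100), 67), "non-degenerate")
  expect_error(calibrate_diameters(1:10, 67), "at least 50")
})

test_that("protein counting is a plain intensity ratio", {
  expect_equal(proteins_per_vesicle(c(0, 500, 123), 100), c(0, 5, 1.23))
  expect_error(proteins_per_vesicle(1, 0), "positive")
})

test_that("binning: 5-nm half-open bins over 20-250 nm with 1.96 SEM CIs", {
  d <- c(rep(100, 40), rep(102, 10), 500, 10)
  x <- c(rep(2, 40), rep(4, 10), 9, 9)
  prof <- bin_profile(d, x)
  expect_equal(prof$diameter_nm, 100) # out-of-range dropped, one bin
  expect_equal(prof$n, 50)
  expect_equal(prof$mean_count, mean(c(rep(2, 40), rep(4, 10))))
  v <- c(rep(2, 40), rep(4, 10))
  expect_equal(prof$ci95, 1.96 * sd(v) / sqrt(50))
  # boundary: 22.5 belongs to the 25 bin, 22.49 to the 20 bin
  pb <- bin_profile(c(22.49, 22.5), c(1, 1))
  expect_equal(pb$diameter_nm, c(20, 25))
  # linear signal is reproduced by bin means
  d2 <- seq(30, 200, by = 0.5)
  prof2 <- bin_profile(d2, 2 * d2)
  expect_equal(prof2$mean_count, 2 * prof2$diameter_nm, tolerance = 0.05)
  expect_error(bin_profile(numeric(0), numeric(0)), "empty")
})

test_that("density, coverage and footprint arithmetic", {
  prof <- data.frame(diameter_nm = 200, mean_count = 327, ci95 = 1, n = 10)
  sens <- density_and_coverage(prof, footprint_nm2 = 115)
  expect_equal(sens$density, 327 / (pi * 200^2))
  expect_equal(sens$coverage, 327 * 115 / (pi * 200^2))
  expect_equal(sens$coverage, 0.2993, tolerance = 1e-3) # ~30% coverage
  # doubling the area halves the density at fixed count
  prof2 <- data.frame(diameter_nm = 200 * sqrt(2), mean_count = 327,
                      ci95 = 1, n = 10)
  expect_equal(density_and_coverage(prof2, 115)$density, sens$density / 2)
  expect_error(density_and_coverage(prof, 0), "positive")
  expect_equal(footprint_from_chain_length(569), 115)
  expect_equal(footprint_from_chain_length(432), 115 * 432 / 569) # ~87 nm2
  expect_error(footprint_from_chain_length(0), "positive")
})

test_that("normalized sensitivity: flat profile is 1, 1/d law gives 10 at 20 nm", {
  d <- seq(20, 250, by = 5)
  flat <- density_and_coverage(
    data.frame(diameter_nm = d, mean_count = 1e-4 * pi * d^2, ci95 = 0,
               n = 10), 115)
  nf <- normalized_sensitivity(flat)
  expect_equal(nf$normalized_sensitivity, rep(1, length(d)))
  inv <- density_and_coverage(
    data.frame(diameter_nm = d, mean_count = pi * d^2 / d, ci95 = 0, n = 10),
    115)
  ni <- normalized_sensitivity(inv)
  ref <- mean(1 / d[d >= 190 & d <= 210])
  expect_equal(ni$normalized_sensitivity[d == 20], (1 / 20) / ref)
  expect_equal(ni$normalized_sensitivity[d == 20], 10, tolerance = 0.01)
  small <- density_and_coverage(
    data.frame(diameter_nm = c(20, 40), mean_count = 1:2, ci95 = 0, n = 1),
    115)
  expect_error(normalized_sensitivity(small), "reference")
})

test_that("normalized sensitivity is invariant to a common intensity rescale", {
  cfg <- synth_config(n_puncta = 400)
  g <- gen_vesicle_puncta(cfg, seed = 5)
  sm <- 100
  r1 <- analyze_vesicles(g$puncta, cfg$prep_means_nm, sm)
  p2 <- g$puncta
  p2$lipid_intensity <- p2$lipid_intensity * 7.3
  p2$protein_intensity <- p2$protein_intensity * 7.3
  r2 <- analyze_vesicles(p2, cfg$prep_means_nm, sm * 7.3)
  expect_equal(r1$sensitivity$normalized_sensitivity,
               r2$sensitivity$normalized_sensitivity, tolerance = 1e-10)
})

test_that("Langmuir fit: noiseless recovery, isotherm identities, CI spread", {
  conc <- c(5, 20, 80, 320, 1280, 5120)
  kd <- 160; bmax <- 400
  bound <- bmax * conc / (kd + conc)
  fit <- fit_langmuir(conc, bound, ci = 0.05 * bound)
  expect_equal(fit$kd_nM, kd, tolerance = 1e-3)
  expect_equal(fit$b_max, bmax, tolerance = 1e-3)
  expect_true(is.finite(fit$kd_sd) && fit$kd_sd >= 0)
  # half-saturation at c = K_D by construction
  expect_equal(fit$b_max * kd / (fit$kd_nM + kd), bmax / 2, tolerance = 1e-3)
  expect_error(fit_langmuir(conc[1:2], bound[1:2]), "at least 3")
})

test_that("geometric capacity correction", {
  gc <- correct_bmax(5e-3, r_v_nm = 15, r_p_nm = 6)
  expect_equal(gc$area_ratio, (21 / 15)^2)
  expect_equal(gc$area_ratio, 1.96)
  expect_equal(gc$b_max_corrected, 5e-3 / 1.96)
  expect_equal(correct_bmax(5e-3, 15, 0)$area_ratio, 1)
  expect_equal(correct_bmax(1, 1e9, 6)$area_ratio, 1, tolerance = 1e-7)
  expect_error(correct_bmax(1, -1, 6), "positive")
  # a population generated at one true surface density collapses after
  # correction across diameters
  d <- c(30, 60, 100, 150, 200)
  true_density <- 2.7e-3
  apparent <- true_density * ((d / 2 + 6) / (d / 2))^2
  corrected <- vapply(seq_along(d), function(i)
    correct_bmax(apparent[i], d[i] / 2, 6)$b_max_corrected, numeric(1))
  expect_equal(corrected, rep(true_density, 5))
})

test_that("filopodia partition coefficients and exclusions", {
  base <- data.frame(g_filo = 250, g_mem = 150, g_bg = 50,
                     r_filo = 250, r_mem = 150, r_bg = 50)
  res <- filopodia_partition(rbind(base, base))
  expect_equal(res$mean, 1) # identical green and red ratios
  b2 <- base; b2$g_filo <- 50 + 2 * (base$g_filo - 50)
  expect_equal(filopodia_partition(rbind(b2, b2))$mean, 2)
  # degenerate membrane intensity excluded
  b3 <- base; b3$r_mem <- 40
  expect_message(res3 <- filopodia_partition(rbind(base, base, b3)),
                 "excluded")
  expect_equal(res3$n, 2)
  expect_equal(res3$n_excluded, 1)
})
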