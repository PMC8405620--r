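# SEC calibration fitting and the chromatogram Mn/Mw estimator.

test_that("calibration recovers exact exponential standards", {
  st <- exact_standards()
  cal <- fit_calibration(st, 8)
  expect_equal(cal$a, 1e5, tolerance = 1e-9)
  expect_equal(cal$b, -4, tolerance = 1e-9)
  # inverse mapping round-trips
  expect_equal(calibration_mass(cal, calibration_volume(cal, 500)), 500,
               tolerance = 1e-9)
})

test_that("two standards are interpolated exactly", {
  st <- data.frame(mass_kDa = c(1000, 10), Vr_mL = c(10, 16))
  cal <- fit_calibration(st, 8)
  expect_equal(calibration_mass(cal, st$Vr_mL), st$mass_kDa,
               tolerance = 1e-9)
})

test_that("noisy standards are fitted within a few relative sd", {
  st <- exact_standards()
  set.seed(42)
  st$mass_kDa <- st$mass_kDa * (1 + stats::rnorm(nrow(st), 0, 0.02))
  cal <- fit_calibration(st, 8)
  rel_err <- abs(cal$fitted_mass - st$mass_kDa) / st$mass_kDa
  expect_true(all(rel_err < 3 * 0.02))
})

test_that("degenerate standards tables are rejected", {
  expect_error(fit_calibration(exact_standards()[1, ], 8), "at least 2")
  st <- data.frame(mass_kDa = c(100, 10), Vr_mL = c(12, 12))
  expect_error(fit_calibration(st, 8), "distinct")
})

test_that("two-point hand example gives Mn = 75 and Mw = 83.33 kDa", {
  cal <- sec_test_calibration()
  v <- calibration_volume(cal, c(100, 50))  # increasing volume order
  chrom <- structure(list(volume_mL = v, absorbance = c(1, 1)),
                     class = "sec_chromatogram")
  res <- compute_mn_mw(chrom, cal)
  expect_equal(res$mn, 75, tolerance = 1e-9)
  expect_equal(res$mw, 250 / 3, tolerance = 1e-9)
  expect_true(res$dispersity >= 1)
})

test_that("a single narrow peak returns Mn = Mw = M", {
  cal <- sec_test_calibration()
  d <- gen_flory_distribution(0, 43)
  chrom <- gen_sec_chromatogram(d, cal, broadening_sd = 0, noise_sd = 0)
  res <- compute_mn_mw(chrom, cal)
  expect_equal(res$mn, 43, tolerance = 0.005 * 43)
  expect_equal(res$mw, 43, tolerance = 0.005 * 43)
  expect_equal(res$dispersity, 1, tolerance = 1e-4)
})

test_that("estimator matches the species-level oracle on fine grids", {
  cal <- sec_test_calibration()
  for (p in c(0, 0.5, 0.9648)) {
    d <- gen_flory_distribution(p, 43)
    chrom <- gen_sec_chromatogram(d, cal, broadening_sd = 0.01,
                                  noise_sd = 0, dv = 0.002)
    res <- compute_mn_mw(chrom, cal)
    oracle <- species_mw_oracle(d)
    expect_equal(res$mn, oracle$mn_signal, tolerance = 0.01)
    expect_equal(res$mw, oracle$mw_signal, tolerance = 0.01)
  }
})

test_that("result is invariant to signal rescaling and grid refinement", {
  cal <- sec_test_calibration()
  d <- gen_flory_distribution(0.5, 43)
  chrom <- gen_sec_chromatogram(d, cal, broadening_sd = 0.05, dv = 0.01)
  res1 <- compute_mn_mw(chrom, cal)
  chrom$absorbance <- chrom$absorbance * 17.3
  expect_equal(compute_mn_mw(chrom, cal)$mw, res1$mw, tolerance = 1e-12)
  fine <- gen_sec_chromatogram(d, cal, broadening_sd = 0.05, dv = 0.002)
  expect_equal(compute_mn_mw(fine, cal)$mw, res1$mw, tolerance = 0.005)
})

test_that("identical seeds give bit-identical noisy chromatograms", {
  cal <- sec_test_calibration()
  d <- gen_flory_distribution(0.5, 43)
  c1 <- gen_sec_chromatogram(d, cal, noise_sd = 0.01, seed = 11)
  c2 <- gen_sec_chromatogram(d, cal, noise_sd = 0.01, seed = 11)
  expect_identical(c1$absorbance, c2$absorbance)
  c3 <- gen_sec_chromatogram(d, cal, noise_sd = 0.01, seed = 12)
  expect_false(identical(c1$absorbance, c3$absorbance))
})

test_that("window and degenerate-signal errors are raised", {
  cal <- sec_test_calibration()
  chrom <- structure(list(volume_mL = c(10, 11), absorbance = c(1, 1)),
                     class = "sec_chromatogram")
  expect_error(compute_mn_mw(chrom, cal, mass_window = c(1e5, 2e5)),
               "does not overlap")
  chrom0 <- structure(list(volume_mL = c(10, 11), absorbance = c(0, 0)),
                      class = "sec_chromatogram")
  expect_error(compute_mn_mw(chrom0, cal), "zero everywhere")
})

test_that("Mw >= Mn for arbitrary non-negative signals", {
  cal <- sec_test_calibration()
  set.seed(5)
  for (rep in 1:10) {
    chrom <- structure(list(volume_mL = seq(9, 19, by = 0.1),
                            absorbance = stats::runif(101)),
                       class = "sec_chromatogram")
    res <- compute_mn_mw(chrom, cal)
    expect_true(res$mw >= res$mn)
  }
})
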