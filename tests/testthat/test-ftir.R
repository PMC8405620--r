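# Amide-I deconvolution: pure-component and mixture recovery, scaling
# invariance, and generator determinism.

test_that("a pure 1624.5 component returns 100 % beta-sheet", {
  x <- seq(1580, 1720, by = 0.5)
  s <- new_spectrum(x, lorentzian_peak(x, 1624.5, 18, 10))
  fit <- deconvolve_amide_I(s)
  expect_equal(fit$beta_sheet_pct, 100, tolerance = 1e-4)
})

test_that("a pure beta-sheet generator input is recovered as all beta", {
  s <- gen_ftir_spectrum(list(beta_sheet = 1), baseline_params = c(0, 0, 0))
  fit <- deconvolve_amide_I(s)
  expect_equal(unname(fit$fractions["beta_sheet"]), 1, tolerance = 1e-4)
})

test_that("noiseless 4-class mixtures are recovered within 3 points", {
  fr <- four_class_fractions()
  # baseline-free: the fit itself is essentially exact
  s0 <- gen_ftir_spectrum(fr, baseline_params = c(0, 0, 0))
  fit0 <- deconvolve_amide_I(s0)
  for (cl in names(fr))
    expect_equal(unname(fit0$fractions[cl]), fr[[cl]], tolerance = 1e-3)
  expect_lt(fit0$relative_residual, 1e-5)

  # with a convex baseline removed by the rubber band
  s1 <- gen_ftir_spectrum(fr)
  fit1 <- deconvolve_amide_I(convex_hull_baseline(s1, c(1580, 1720)))
  for (cl in names(fr))
    expect_lt(abs(unname(fit1$fractions[cl]) - fr[[cl]]), 0.03)
})

test_that("fractions sum to one and are invariant to intensity scaling", {
  s <- gen_ftir_spectrum(four_class_fractions(),
                         baseline_params = c(0, 0, 0))
  fit <- deconvolve_amide_I(s)
  expect_equal(sum(fit$fractions), 1, tolerance = 1e-6)
  s2 <- new_spectrum(s$wavenumber, s$intensity * 37)
  fit2 <- deconvolve_amide_I(s2)
  expect_equal(fit2$fractions, fit$fractions, tolerance = 1e-6)
})

test_that("generator validates fractions and is seed-deterministic", {
  expect_error(gen_ftir_spectrum(list(nonsense = 1)), "unknown structure")
  expect_error(gen_ftir_spectrum(list(beta_sheet = 0.7)), "sum to")
  a <- gen_ftir_spectrum(four_class_fractions(), noise_sd = 0.01, seed = 3)
  b <- gen_ftir_spectrum(four_class_fractions(), noise_sd = 0.01, seed = 3)
  expect_identical(a$intensity, b$intensity)
})

test_that("the 11-component model uses the fixed centers", {
  expect_identical(amide_centers(),
                   c(1610, 1618.5, 1624.5, 1632.5, 1642, 1651, 1659,
                     1666.5, 1678, 1690.5, 1700))
  asn <- amide_assignment()
  expect_setequal(unique(unname(asn)),
                  c("beta_sheet", "random_coil", "alpha_helix", "beta_turn"))
  expect_identical(as.numeric(names(asn)), amide_centers())
})
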