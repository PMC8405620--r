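# Profile extraction, peak deconvolution, and the closed-form crystal
# metrics (crystallinity, Scherrer chain, Herman's orientation).

test_that("crystallinity follows the equatorial area ratio", {
  comp <- data.frame(
    label = c("eq200", "eq120", "amorphous1", "amorphous2"),
    area = c(10, 8, 40, 42))
  expect_equal(crystallinity(comp), 0.18, tolerance = 1e-12)
  comp0 <- comp; comp0$area[1:2] <- 0
  expect_equal(crystallinity(comp0), 0)
  comp1 <- comp; comp1$area[3:4] <- 0
  expect_equal(crystallinity(comp1), 1)
  expect_error(crystallinity(comp[-1, ]), "missing components")
})

test_that("the Scherrer chain reproduces its independent evaluation", {
  # d = 2 pi / PC
  res <- analyze_peak(list(center = 0.582, fwhm = 0.2))
  expect_equal(res$d_nm, 1.080, tolerance = 1e-3)
  # full chain at the inter-sheet reflection: frozen from a direct
  # numeric evaluation of theta = arcsin(lambda PC / 4 pi),
  # beta = 2 arcsin(lambda FWHM / 4 pi), D = K lambda / (beta cos theta)
  res2 <- analyze_peak(list(center = 0.582, fwhm = 0.524),
                       wavelength_A = 0.886, K = 0.9)
  expect_equal(res2$D_nm, 1.0798, tolerance = 1e-3)
  # generator-side inversion is the exact inverse of the analysis chain
  fw <- fiberlab:::scherrer_fwhm_q(2.91, d_to_q(0.46), 0.886, 0.9)
  back <- analyze_peak(list(center = d_to_q(0.46), fwhm = fw))
  expect_equal(back$D_nm, 2.91, tolerance = 1e-9)
})

test_that("degenerate Scherrer inputs raise the documented errors", {
  expect_error(analyze_peak(list(center = 0.582, fwhm = 0)),
               "infinite")
  expect_error(analyze_peak(list(center = 0.582, fwhm = 20)),
               "arcsin domain")
})

test_that("Herman's orientation matches direct evaluation", {
  expect_equal(herman_orientation(0, 0)$f, 1, tolerance = 1e-12)
  # frozen from independent evaluation of
  # 1 - 0.8 sin^2(12 deg) - 1.2 sin^2(12 deg) -> f = 0.8703
  expect_equal(herman_orientation(30, 30)$f, 0.8703, tolerance = 1e-3)
  expect_error(herman_orientation(-1, 10), "admissible range")
  # radian-scale misuse drives f out of range
  expect_error(herman_orientation(160, 160), "outside")
})

test_that("f decreases monotonically with azimuthal width", {
  w <- seq(0, 90, by = 5)
  f <- vapply(w, function(wi) herman_orientation(wi, wi)$f, numeric(1))
  expect_true(all(diff(f) < 0))
})

test_that("sector integration of a uniform image is flat", {
  g <- detector_geometry()
  img <- structure(list(
    counts = matrix(100, 301, 301), background = NULL, geometry = g),
    class = "waxd_image")
  prof <- suppressWarnings(
    sector_integrate(img, "equator", subtract_background = FALSE))
  expect_true(all(abs(prof$intensity - 100) < 1e-9))
})

test_that("an isotropic ring appears at its q in the radial profile and
           flat in the azimuthal profile", {
  g <- detector_geometry(center_px = c(301, 301))
  m <- map_pixels(g, c(601, 601))
  q0 <- 1.0
  counts <- matrix(round(1000 * exp(-0.5 * ((m$q - q0) / 0.02)^2)),
                   601, 601)
  img <- structure(list(counts = counts, background = NULL, geometry = g),
                   class = "waxd_image")
  prof <- suppressWarnings(
    sector_integrate(img, "equator", subtract_background = FALSE))
  expect_equal(prof$q[which.max(prof$intensity)], q0, tolerance = 0.005)
  # isotropy: 20 and 30 degree sectors agree
  p20 <- suppressWarnings(
    sector_integrate(img, "equator", 20, subtract_background = FALSE))
  p30 <- suppressWarnings(
    sector_integrate(img, "equator", 30, subtract_background = FALSE))
  band <- p20$q > 0.9 & p20$q < 1.1
  expect_equal(p20$intensity[band], p30$intensity[band], tolerance = 0.02)
  # azimuthal profile across the ring is flat and Friedel-symmetric
  az <- azimuthal_profile(img, c(0.95, 1.05),
                          subtract_background = FALSE)
  expect_lt(stats::sd(az$intensity) / mean(az$intensity), 0.02)
})

test_that("azimuthal profiles obey Friedel symmetry for synthetic
           fiber images", {
  img <- small_waxd_image(dim = 512L)
  az <- azimuthal_profile(img, c(1.30, 1.45))
  half <- length(az$chi) / 2
  a <- az$intensity[seq_len(half)]
  b <- az$intensity[half + seq_len(half)]
  expect_equal(stats::cor(a, b), 1, tolerance = 0.01)
})

test_that("azimuthal deconvolution recovers narrow and broad widths", {
  chi <- seq(1, 359, by = 2)
  pair <- function(w) fiberlab:::azimuthal_pair(chi, 0, w)
  y <- 100 * pair(25) + 30 * pair(120) + 5
  prof <- structure(data.frame(chi = chi, intensity = y),
                    class = c("azimuthal_profile", "data.frame"))
  fit <- fit_azimuthal(prof)
  comp <- fit$components
  expect_equal(comp$fwhm[comp$label == "crystalline-azimuthal"], 25,
               tolerance = 0.05)
  expect_equal(comp$fwhm[comp$label == "amorphous-azimuthal"], 120,
               tolerance = 0.05)
  # adding (201) satellites leaves the main width recoverable
  y2 <- y + 20 * (fiberlab:::azimuthal_pair(chi, 35, 18) +
                    fiberlab:::azimuthal_pair(chi, -35, 18))
  prof2 <- structure(data.frame(chi = chi, intensity = y2),
                     class = c("azimuthal_profile", "data.frame"))
  fit2 <- fit_azimuthal(prof2, include_subsidiary = TRUE)
  comp2 <- fit2$components
  expect_equal(comp2$fwhm[comp2$label == "crystalline-azimuthal"], 25,
               tolerance = 0.05)
})

test_that("a single narrow azimuthal component leaves ~no amorphous
           area", {
  chi <- seq(1, 359, by = 2)
  y <- 100 * fiberlab:::azimuthal_pair(chi, 0, 30)
  prof <- structure(data.frame(chi = chi, intensity = y),
                    class = c("azimuthal_profile", "data.frame"))
  fit <- fit_azimuthal(prof)
  comp <- fit$components
  am <- comp$area[comp$label == "amorphous-azimuthal"]
  cr <- comp$area[comp$label == "crystalline-azimuthal"]
  expect_lt(am / cr, 0.01)
})

test_that("requested orientation outside Herman's range is rejected", {
  expect_error(waxd_truth(f = 1.2), "achievable range")
  expect_error(waxd_truth(f = -0.8), "achievable range")
})

test_that("the sampled image is an unbiased realization of the analytic
           surface", {
  truth <- waxd_truth(count_scale = 400, background_counts = 0, seed = 3)
  g <- detector_geometry(center_px = c(151, 151))
  img <- gen_waxd_image(truth, g, dim = c(301L, 301L))
  m <- map_pixels(g, c(301L, 301L))
  surf <- 400 * waxd_surface(truth, m$q, m$chi, g$wavelength_A)
  # high-intensity region: relative agreement of totals
  hi <- surf > 100
  expect_equal(sum(img$counts[hi]) / sum(surf[hi]), 1, tolerance = 0.01)
  expect_identical(img$counts,
                   gen_waxd_image(truth, g, dim = c(301L, 301L))$counts)
})
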