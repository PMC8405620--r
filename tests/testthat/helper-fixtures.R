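# Shared fixtures: a realistic SEC standards table and small helpers used
# across the module tests.

sec_standards <- function() {
  data.frame(mass_kDa = c(2000, 670, 158, 44, 17, 1.35),
             Vr_mL = c(9, 11, 13.5, 15.5, 17, 19.5))
}

sec_test_calibration <- function(void_volume = 8) {
  fit_calibration(sec_standards(), void_volume)
}

# Exact exponential standards for closed-form calibration checks
exact_standards <- function(a = 1e5, b = -4, v0 = 8,
                            vr = c(9, 11, 13, 15, 17)) {
  data.frame(mass_kDa = a * exp(b * vr / v0), Vr_mL = vr)
}

four_class_fractions <- function() {
  list(beta_sheet = 0.28, random_coil = 0.22,
       alpha_helix = 0.25, beta_turn = 0.25)
}

# Small, fast diffraction image with the default beta-sheet fiber truth
small_waxd_image <- function(dim = 640L, seed = 7, ...) {
  truth <- waxd_truth(seed = seed, ...)
  gen_waxd_image(truth, detector_geometry(), dim = c(dim, dim))
}

# Triangle hysteresis loop: load linearly to 100 MPa at 10 % strain,
# unload linearly to zero stress at 5 % strain
triangle_loop <- function() {
  structure(data.frame(strain = c(0, 0.10, 0.05),
                       stress = c(0, 100, 0)),
            class = c("stress_strain", "data.frame"))
}
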