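# Stress-strain conversion, tensile summary (90 %-drop rule), cyclic
# damping, and replicate aggregation.

test_that("stress-strain conversion applies the geometric identities", {
  tr <- structure(data.frame(time_s = 0:2,
                             displacement_mm = c(0, 0.25, 0.5),
                             force_N = c(0, 0, 7.854e-5)),
                  class = c("mech_trace", "data.frame"))
  cu <- to_stress_strain(tr, diameter_um = 10, gauge_mm = 5)
  expect_equal(cu$strain, c(0, 0.05, 0.10))
  expect_equal(attr(cu, "area_m2"), pi * (5e-6)^2, tolerance = 1e-12)
  # d = 10 um, F = 7.854e-5 N -> 1.000 MPa
  expect_equal(cu$stress[3], 1, tolerance = 1e-3)
  expect_error(to_stress_strain(tr, diameter_um = 0, gauge_mm = 5),
               "admissible range")
})

test_that("diameter replicates are averaged", {
  tr <- structure(data.frame(time_s = 0:1, displacement_mm = c(0, 0.5),
                             force_N = c(0, 1)),
                  class = c("mech_trace", "data.frame"))
  cu <- to_stress_strain(tr, diameter_um = c(9, 10, 11), gauge_mm = 5)
  expect_equal(attr(cu, "diameter_um"), 10)
})

test_that("a linear-elastic ramp gives the closed-form summary", {
  E <- 4200  # MPa
  eb <- 0.02
  eps <- seq(0, eb, length.out = 200)
  cu <- structure(data.frame(strain = c(eps, eb + 1e-9, eb + 2e-9),
                             stress = c(E * eps, 1, 0.5)),
                  class = c("stress_strain", "data.frame"))
  ts <- tensile_summary(cu)
  expect_equal(ts$modulus_gpa, 4.2, tolerance = 1e-6)
  expect_equal(ts$uts_mpa, E * eb, tolerance = 1e-9)
  expect_equal(ts$toughness, 0.5 * E * eb^2, tolerance = 1e-4)
  expect_false(ts$censored)
})

test_that("synthetic tensile traces are recovered within 2 %", {
  p <- mech_params(E = 4.2)
  tr <- gen_tensile_trace(p)
  truth <- attr(tr, "truth")
  ts <- tensile_summary(to_stress_strain(tr))
  expect_equal(ts$modulus_gpa, 4.2, tolerance = 0.02)
  expect_equal(ts$uts_mpa, truth$uts_mpa, tolerance = 0.02)
  expect_equal(ts$breaking_strain, truth$breaking_strain, tolerance = 0.02)
  expect_equal(ts$toughness, truth$toughness, tolerance = 0.02)
})

test_that("traces are seed-deterministic", {
  p <- mech_params(noise_sd = 0.01, seed = 9)
  expect_identical(gen_tensile_trace(p)$force_N,
                   gen_tensile_trace(p)$force_N)
})

test_that("the triangle loop gives DC = 50 % and DE = 2.5 MJ/m3", {
  res <- cycle_damping(triangle_loop())
  expect_equal(res$damping_capacity_pct, 50, tolerance = 1e-12)
  expect_equal(res$damping_energy, 2.5, tolerance = 1e-12)
  expect_equal(res$permanent_set, 0.05)
  expect_false(res$flagged)
})

test_that("an unload branch retracing the load branch gives zero
           damping", {
  eps <- seq(0, 0.1, length.out = 100)
  cu <- structure(data.frame(strain = c(eps, rev(eps)[-1]),
                             stress = c(1000 * eps, rev(1000 * eps)[-1])),
                  class = c("stress_strain", "data.frame"))
  res <- cycle_damping(cu)
  expect_equal(res$damping_capacity_pct, 0, tolerance = 1e-9)
  expect_equal(res$damping_energy, 0, tolerance = 1e-9)
})

test_that("cyclic traces match their attached closed-form truths", {
  p <- mech_params()
  cycles <- gen_cyclic_traces(p, c(0.05, 0.10, 0.20, 0.30),
                              recovery_fraction = 1)
  for (tr in cycles) {
    truth <- attr(tr, "truth")
    res <- cycle_damping(to_stress_strain(tr))
    expect_equal(res$damping_capacity_pct, truth$damping_capacity_pct,
                 tolerance = 0.005)
    expect_equal(res$damping_energy, truth$damping_energy,
                 tolerance = 0.005)
    expect_equal(res$permanent_set, truth$permanent_set, tolerance = 0.02)
    expect_true(res$damping_capacity_pct >= 0 &&
                  res$damping_capacity_pct <= 100)
  }
})

test_that("full recovery makes equal-peak cycles identical after the
           first", {
  p <- mech_params()
  cycles <- gen_cyclic_traces(p, rep(0.2, 4), recovery_fraction = 1)
  f2 <- cycles[[2]]$force_N
  for (k in 3:4) expect_equal(cycles[[k]]$force_N, f2, tolerance = 1e-12)
})

test_that("damping metrics are invariant to time resampling", {
  p <- mech_params()
  coarse <- gen_cyclic_traces(p, 0.2, rate_hz = 50)[[1]]
  fine <- gen_cyclic_traces(p, 0.2, rate_hz = 250)[[1]]
  rc <- cycle_damping(to_stress_strain(coarse))
  rf <- cycle_damping(to_stress_strain(fine))
  expect_equal(rc$damping_capacity_pct, rf$damping_capacity_pct,
               tolerance = 0.005)
  expect_equal(rc$damping_energy, rf$damping_energy, tolerance = 0.005)
})

test_that("aggregation reports mean, sd and n", {
  vals <- list(list(x = 1), list(x = 2), list(x = 3))
  agg <- aggregate_replicates(vals)
  expect_equal(agg$mean[agg$metric == "x"], 2)
  expect_equal(agg$sd[agg$metric == "x"], 1)
  expect_equal(agg$n[1], 3)
  one <- aggregate_replicates(list(list(x = 5)))
  expect_true(is.na(one$sd[1]))
  same <- aggregate_replicates(list(list(x = 2), list(x = 2)))
  expect_equal(same$sd[1], 0)
})

test_that("model parameter validation enforces physical ordering", {
  expect_error(mech_params(E_u = 3), "unload path")
  expect_error(mech_params(eps_y = 0.5, eps_b = 0.4), "admissible range")
  expect_error(gen_cyclic_traces(mech_params(), c(0.3, 0.2)), "ascending")
  expect_error(gen_cyclic_traces(mech_params(), 0.6),
               "below the breaking strain")
})
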