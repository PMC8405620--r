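# Step-growth distribution generator: closed forms, truncation control,
# and determinism of the attached truths.

test_that("p = 0 collapses to a single species", {
  d <- gen_flory_distribution(0, 43)
  expect_equal(d$i_max, 1L)
  expect_equal(d$number_fractions, 1)
  expect_equal(d$true_mn, 43)
  expect_equal(d$true_mw, 43)
})

test_that("closed forms match direct summation across p values", {
  for (p in c(0.2, 0.5, 0.9, 0.9648)) {
    d <- gen_flory_distribution(p, 43)
    # independent summation oracle over the retained species
    mn_sum <- sum(d$number_fractions * d$masses)
    mw_sum <- sum(d$number_fractions * d$masses^2) /
      sum(d$number_fractions * d$masses)
    expect_equal(d$true_mn, mn_sum, tolerance = 1e-12)
    expect_equal(d$true_mw, mw_sum, tolerance = 1e-12)
    expect_equal(d$true_mn, d$mn_closed, tolerance = 1e-6)
    expect_equal(d$true_mw, d$mw_closed, tolerance = 1e-6)
    expect_equal(d$mw_closed / d$mn_closed, 1 + p, tolerance = 1e-12)
  }
})

test_that("p = 0.5 and the megadalton operating point give known Mn/Mw", {
  d <- gen_flory_distribution(0.5, 43, i_max = 200)
  expect_equal(d$true_mn, 86, tolerance = 1e-9)
  expect_equal(d$true_mw, 129, tolerance = 1e-9)

  d2 <- gen_flory_distribution(0.9648, 43)
  expect_equal(d2$true_mw, 2400, tolerance = 1e-3)
})

test_that("number fractions sum to one and Mn <= Mw", {
  for (p in c(0, 0.3, 0.7, 0.95)) {
    d <- gen_flory_distribution(p, 50)
    expect_equal(sum(d$number_fractions), 1, tolerance = 1e-9)
    expect_true(d$true_mn <= d$true_mw + 1e-12)
  }
})

test_that("invalid parameters and insufficient truncation error clearly", {
  expect_error(gen_flory_distribution(1, 43), "admissible range")
  expect_error(gen_flory_distribution(-0.1, 43), "admissible range")
  expect_error(gen_flory_distribution(0.9648, 43, i_max = 50),
               "i_max >= ")
})
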