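# Pixel-to-(q, chi) mapping and geometry conventions.

test_that("the beam-center pixel maps to q = 0", {
  g <- detector_geometry(center_px = c(50, 50))
  m <- map_pixels(g, c(99, 99))
  expect_equal(m$q[50, 50], 0)
})

test_that("a d = 1.08 nm ring lands at ~16.4 mm radius", {
  g <- detector_geometry()  # 0.886 A, 200 mm
  expect_equal(ring_radius_mm(g, 1.08), 16.45, tolerance = 0.01)
  # and the mapped pixel at that radius carries q = 2 pi / d
  r_px <- ring_radius_mm(g, 1.08) / g$pixel_mm
  m <- map_pixels(detector_geometry(center_px = c(300, 300)), c(599, 599))
  q_at <- m$q[300, round(300 + r_px)]
  expect_equal(q_at, d_to_q(1.08), tolerance = 0.005)
})

test_that("pixels on the equator have chi = 0 (meridian vertical)", {
  g <- detector_geometry(center_px = c(101, 101))
  m <- map_pixels(g, c(201, 201))
  expect_equal(m$chi[101, 150], 0)          # +x: equator
  expect_equal(m$chi[101, 50], 180)         # -x: Friedel mate
  expect_equal(m$chi[50, 101], 90)          # up: meridian
})

test_that("rotating the meridian shifts chi accordingly", {
  g <- detector_geometry(center_px = c(101, 101), meridian_deg = 0)
  m <- map_pixels(g, c(201, 201))
  # fiber axis along +x, so +x is now the meridian (chi = 90)
  expect_equal(m$chi[101, 150], 90)
})

test_that("q increases monotonically with pixel radius", {
  g <- detector_geometry(center_px = c(1, 1))
  m <- map_pixels(g, c(1, 512))
  expect_true(all(diff(m$q[1, ]) > 0))
})

test_that("geometry validation rejects non-positive parameters", {
  expect_error(detector_geometry(wavelength_A = 0), "admissible range")
  expect_error(detector_geometry(distance_mm = -5), "admissible range")
})
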