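# End-to-end parameter recovery on a synthetic oriented semi-crystalline
# fiber pattern with the default beta-sheet truth.

test_that("the full WAXD chain recovers the generating truth", {
  img <- small_waxd_image(dim = 640L, seed = 7)
  truth <- img$truth
  res <- suppressWarnings(waxd_analyze(img))

  expect_equal(res$d200_nm, truth$d200_nm, tolerance = 0.01)
  expect_equal(res$d120_nm, truth$d120_nm, tolerance = 0.01)
  expect_equal(res$Da_nm, truth$Da_nm, tolerance = 0.05)
  expect_equal(res$Db_nm, truth$Db_nm, tolerance = 0.05)
  expect_lt(abs(res$crystallinity - truth$crystallinity), 0.02)
  expect_lt(abs(res$f_crystal - truth$f), 0.05)
})

test_that("a nearly perfectly oriented fiber recovers f near 1", {
  img <- small_waxd_image(dim = 512L, seed = 11, f = 0.98)
  res <- suppressWarnings(waxd_analyze(img))
  expect_gt(res$f_crystal, 0.93)
})

test_that("a nearly unoriented fiber recovers low orientation", {
  # near isotropy the crystalline azimuthal width (~87 deg at f = 0.02)
  # sits at the narrow/broad model boundary, so recovery is only
  # qualitative: far closer to isotropic than to the oriented fiber
  img <- small_waxd_image(dim = 512L, seed = 13, f = 0.02)
  res <- suppressWarnings(waxd_analyze(img))
  expect_lt(abs(res$f_crystal), 0.3)
})

test_that("image round-trips through the text format with geometry", {
  img <- small_waxd_image(dim = 96L, seed = 2)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "pattern.txt")
  write_waxd_image(img, path, background_path = file.path(dir, "bg.txt"))
  back <- read_waxd_image(path, background_path = file.path(dir, "bg.txt"))
  expect_equal(back$counts, img$counts)
  expect_equal(back$background, img$background)
  expect_equal(back$geometry$wavelength_A, img$geometry$wavelength_A)
  expect_equal(back$geometry$distance_mm, img$geometry$distance_mm)
})
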