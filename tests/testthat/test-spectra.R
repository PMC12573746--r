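test_that("Lorentzian convolution conserves area and peak height", {
  sp <- convolve_sticks(1500, 3, fwhm = 8, from = 0, to = 3000, by = 0.25)
  area <- sum(sp$intensity) * 0.25
  expect_equal(area, 3, tolerance = 0.01)           # finite-window tail
  peak <- sp$intensity[sp$wavenumber == 1500]
  expect_equal(peak, 2 * 3 / (pi * 8), tolerance = 1e-9)
  # linearity: spectrum of summed sticks = sum of spectra
  a <- convolve_sticks(c(900, 1100), c(1, 2), from = 0, to = 2000)
  b <- convolve_sticks(c(1300), c(-1), from = 0, to = 2000)
  ab <- convolve_sticks(c(900, 1100, 1300), c(1, 2, -1), from = 0, to = 2000)
  expect_equal(ab$intensity, a$intensity + b$intensity, tolerance = 1e-12)
  # mirror sticks convolve to exact negatives
  neg <- convolve_sticks(c(900, 1100), -c(1, 2), from = 0, to = 2000)
  expect_identical(neg$intensity, -a$intensity)
  expect_warning(convolve_sticks(c(500, 1500), c(1, 1), from = 0, to = 1000),
                 "outside the grid")
})

test_that("similarity is 1 for identical and rescaled spectra", {
  sp <- convolve_sticks(c(1000, 1450), c(2, -1), from = 700, to = 1800)
  res <- similarity(sp, sp)
  expect_equal(res$s, 1, tolerance = 1e-9)
  expect_equal(res$a, 1, tolerance = 1e-4)
  scaled <- sp; scaled$intensity <- 0.37 * scaled$intensity
  expect_equal(similarity(scaled, sp)$s, 1, tolerance = 1e-9)
})

test_that("the two-Lorentzian overlap matches the closed-form fixture", {
  # two unit-area Lorentzians (fwhm 8) centered 8 cm^-1 apart: the overlap
  # integrals are analytic (a Lorentzian of doubled width), giving s = 1/2
  a <- convolve_sticks(1000, 1, fwhm = 8, from = -3000, to = 5000, by = 0.1)
  b <- convolve_sticks(1008, 1, fwhm = 8, from = -3000, to = 5000, by = 0.1)
  res <- similarity(a, b)
  expect_equal(res$s_unscaled, 0.5, tolerance = 1e-6)
  # symmetric in its arguments at a = 1
  expect_equal(similarity(b, a)$s_unscaled, res$s_unscaled, tolerance = 1e-12)
})

test_that("frequency scaling is recovered by the search", {
  sticks <- c(1000, 1300, 1600); ints <- c(1, 2, 1.5)
  ref <- convolve_sticks(sticks, ints, from = 700, to = 2000, by = 0.5)
  stretched <- convolve_sticks(sticks * 1.02, ints, from = 700, to = 2100,
                               by = 0.5)
  res <- similarity(stretched, ref)
  expect_equal(res$a, 1.02, tolerance = 2e-3)
  expect_gt(res$s, 0.999)
  expect_lt(res$s_unscaled, res$s)
})

test_that("zero-norm spectra are refused", {
  sp <- convolve_sticks(1000, 1, from = 800, to = 1200)
  flat <- sp; flat$intensity[] <- 0
  expect_error(similarity(sp, flat), "zero norm")
})

test_that("spectrum files round-trip and malformed input is located", {
  sp <- convolve_sticks(c(950, 1200), c(1.5, -0.5), from = 900, to = 1300)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(sp, path)
  back <- read_spectrum(path)
  expect_equal(back$wavenumber, sp$wavenumber)
  expect_equal(back$intensity, sp$intensity, tolerance = 1e-9)
  # descending input is normalized to ascending
  rev_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# reversed", "1200 0.1", "1100 0.5", "1000 0.2"), rev_path)
  rs <- read_spectrum(rev_path)
  expect_equal(rs$wavenumber, c(1000, 1100, 1200))
  expect_equal(rs$intensity, c(0.2, 0.5, 0.1))
  bad_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1000 0.1", "oops"), bad_path)
  expect_error(read_spectrum(bad_path), "line 2")
})
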