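test_that("force constants are stored canonically and read through any permutation", {
  ff <- quartic_force_field(normal_modes(c(500, 1000, 1500)))
  ff <- ff_set_constant(ff, c(2, 1, 1), 5)
  expect_identical(canonical_index(c(3, 1, 2), 3), c(1L, 2L, 3L))
  expect_identical(canonical_index(c(1, 1, 2), 3), c(1L, 1L, 2L))
  expect_equal(ff_constant(ff, c(1, 2, 1)), 5)
  expect_equal(ff_constant(ff, c(1, 1, 2)), 5)
  expect_equal(ff_constant(ff, c(2, 1, 1)), 5)
  expect_equal(ff_constant(ff, c(1, 2, 3)), 0)
  expect_error(canonical_index(c(0, 1), 3), "out of range")
  expect_error(canonical_index(c(1, 4), 3), "out of range")
  # property-style: random tuples, all permutations agree
  set.seed(1)
  for (rep in 1:20) {
    idx <- sample(1:3, 3, replace = TRUE)
    val <- rnorm(1)
    ff2 <- ff_set_constant(ff, idx, val)
    for (p in 1:5) expect_equal(ff_constant(ff2, sample(idx)), val)
  }
})

test_that("fully off-diagonal quartics are rejected with a warning and read as zero", {
  ff <- quartic_force_field(normal_modes(c(500, 800, 1200, 1600)))
  expect_warning(ff <- ff_set_constant(ff, c(1, 2, 3, 4), 7), "off-diagonal")
  expect_equal(ff_constant(ff, c(1, 2, 3, 4)), 0)
  ff <- ff_set_constant(ff, c(1, 1, 3, 4), 7)  # semidiagonal is fine
  expect_equal(ff_constant(ff, c(3, 1, 4, 1)), 7)
})

test_that("the mass-weighted step converts to the reduced coordinate correctly", {
  # frozen from an independent dimensional-analysis calculation with CODATA
  # constants (0.01 amu^1/2 A at 1000 cm^-1)
  expect_equal(reduced_step_from_massweighted(0.01, 1000), 0.0544611432519,
               tolerance = 1e-10)
  # scaling law: doubling omega scales the step by sqrt(2)
  s1 <- reduced_step_from_massweighted(0.01, 750)
  s2 <- reduced_step_from_massweighted(0.01, 1500)
  expect_equal(s2 / s1, sqrt(2), tolerance = 1e-12)
  expect_error(reduced_step_from_massweighted(0.01, 0), "positive")
  expect_error(reduced_step_from_massweighted(-0.01, 1000), "positive")
})

test_that("container validity rules hold", {
  expect_error(normal_modes(c(100, -5)), "positive")
  expect_error(vib_state(c(2, 1)), "quanta <= 2")
  d2_bad <- array(0, c(3, 2, 2)); d2_bad[1, 1, 2] <- 1
  expect_error(property_surface("mu", 2, d2 = d2_bad), "symmetric")
  z <- array(0, c(3, 2, 2)); z[1, 1, 2] <- 0.3; z[1, 2, 1] <- 0.3
  expect_error(coriolis_data(z, c(1, 1, 1)), "antisymmetric")
  z[1, 2, 1] <- -0.3
  expect_silent(coriolis_data(z, c(1, 1, 1)))
})

test_that("model-system JSON round trip is lossless", {
  spec <- generator_spec(n_modes = 3, seed = 99)
  sys <- make_random_system(spec)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_system(sys, path)
  back <- read_model_system(path)
  expect_identical(back$force_field$modes$omega, sys$force_field$modes$omega)
  expect_identical(back$force_field$cubic[order(names(back$force_field$cubic))],
                   sys$force_field$cubic[order(names(sys$force_field$cubic))])
  expect_identical(back$force_field$quartic[order(names(back$force_field$quartic))],
                   sys$force_field$quartic[order(names(sys$force_field$quartic))])
  for (sn in names(sys$surfaces)) {
    expect_identical(back$surfaces[[sn]]$value0, sys$surfaces[[sn]]$value0)
    expect_identical(back$surfaces[[sn]]$d1, sys$surfaces[[sn]]$d1)
    expect_identical(back$surfaces[[sn]]$d2, sys$surfaces[[sn]]$d2)
    expect_identical(back$surfaces[[sn]]$d3[order(names(back$surfaces[[sn]]$d3))],
                     sys$surfaces[[sn]]$d3[order(names(sys$surfaces[[sn]]$d3))])
  }
})
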