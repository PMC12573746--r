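test_that("the Morse construction matches the symbolic Taylor expansion", {
  sys <- make_morse_system(3000, 50)
  ff <- sys$force_field
  # frozen from a computer-algebra expansion of D(1 - exp(-a q))^2 with
  # D, a eliminated via omega and omega_x
  expect_equal(ff_constant(ff, c(1, 1, 1)), -1643.167673, tolerance = 1e-9)
  expect_equal(ff_constant(ff, c(1, 1, 1, 1)), 700)
  expect_equal(ff_constant(ff, c(1, 1, 1)), -3 * sqrt(2 * 3000 * 50))
  # harmonic limit
  tiny <- make_morse_system(3000, 1e-8)
  expect_lt(abs(ff_constant(tiny$force_field, c(1, 1, 1))), 0.1)
  expect_lt(abs(ff_constant(tiny$force_field, c(1, 1, 1, 1))), 1e-6)
  expect_warning(make_morse_system(1000, 300), "omega_x")
})

test_that("generation is reproducible and honours its scales", {
  spec <- generator_spec(n_modes = 3, seed = 17)
  a <- make_random_system(spec)
  b <- make_random_system(spec)
  expect_identical(a$force_field, b$force_field)
  expect_identical(a$surfaces, b$surfaces)
  # harmonic when the scales vanish (diagonal quartics track the scale too)
  h <- make_random_system(generator_spec(n_modes = 2, cubic_scale = 0,
                                         quartic_scale = 0, seed = 3))
  expect_true(all(unlist(h$force_field$cubic) == 0))
  expect_true(all(unlist(h$force_field$quartic) == 0))
  # perturbative regime: |f|/omega small
  omin <- min(a$force_field$modes$omega)
  expect_true(all(abs(unlist(a$force_field$cubic)) <= 0.1 * omin))
})

test_that("planned Fermi resonances are realized and detected", {
  for (case in list(list(d = 10, f = 40, seed = 5),
                    list(d = 35, f = 90, seed = 6))) {
    sys <- fermi_dyad_system(case$d, case$f, case$seed)
    ff <- sys$force_field
    expect_equal(abs(ff$modes$omega[1] - 2 * ff$modes$omega[2]), case$d,
                 tolerance = 1)
    fer <- detect_fermi(ff)
    fl <- fer$fermi[fer$fermi$flagged, ]
    expect_equal(nrow(fl), 1L)
    expect_equal(unlist(fl[, c("i", "j", "k")]), c(i = 2, j = 2, k = 1))
    expect_equal(fl$f, case$f)
  }
  # infeasible plan: the detuning pushes the target frequency nonpositive
  bad <- generator_spec(n_modes = 2, omega_range = c(600, 650), seed = 1,
                        resonance_plan = list(list(type = "fermi", i = 1,
                                                   j = 1, k = 2,
                                                   detuning = 1300, f = 40)))
  expect_error(make_random_system(bad), "not achievable")
})

test_that("mirror_image is an involution with the correct parity", {
  sys <- make_random_system(generator_spec(n_modes = 2, seed = 8))
  mir <- mirror_image(sys)
  expect_identical(mir$force_field, sys$force_field)
  expect_identical(mirror_image(mir)$surfaces, sys$surfaces)
  expect_identical(mir$surfaces$mu, sys$surfaces$mu)
  expect_identical(mir$surfaces$alpha, sys$surfaces$alpha)
  expect_equal(mir$surfaces$m$d1, -sys$surfaces$m$d1)
  expect_equal(mir$surfaces$Gprime$value0, -sys$surfaces$Gprime$value0)
  expect_equal(mir$surfaces$Aquad$d2, -sys$surfaces$Aquad$d2)
})

test_that("nonresonant draws clear every proximity gate", {
  for (seed in 1:4) {
    sys <- make_random_system(generator_spec(n_modes = 3, seed = seed),
                              ensure_nonresonant = TRUE)
    fer <- detect_fermi(sys$force_field)
    expect_false(any(fer$fermi$pass_5a))
    dd <- detect_dd(sys$force_field, fermi = fer)
    expect_false(any(dd$dd11$flagged))
    expect_false(any(dd$dd22$flagged))
  }
})
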