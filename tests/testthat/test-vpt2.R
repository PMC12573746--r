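test_that("the Morse system reproduces its exact level formula", {
  sys <- make_morse_system(3000, 50)
  chi <- anharmonic_constants(sys$force_field)
  expect_equal(chi$chi[1, 1], -50, tolerance = 1e-12)
  expect_equal(state_energy(chi, 1L), 2900, tolerance = 1e-12)
  expect_equal(state_energy(chi, 2L), 5700, tolerance = 1e-12)
})

test_that("harmonic limits and algebraic identities of the level formula hold", {
  ff <- quartic_force_field(normal_modes(c(700, 1800)))
  chi <- anharmonic_constants(ff)
  expect_true(all(chi$chi == 0))
  expect_equal(state_energy(chi, c(1, 0)), 700)
  expect_equal(state_energy(chi, c(0, 1)), 1800)
  # combination = sum of fundamentals + chi_12, for any chi
  ff2 <- reference_2mode_ff()
  chi2 <- anharmonic_constants(ff2)
  expect_equal(chi2$chi, t(chi2$chi))
  expect_equal(state_energy(chi2, c(1, 1)),
               state_energy(chi2, c(1, 0)) + state_energy(chi2, c(0, 1)) +
                 chi2$chi[1, 2], tolerance = 1e-12)
  expect_error(state_energy(chi2, c(2, 1)), "quanta <= 2")
})

test_that("VPT2 energies track the variational oracle off resonance", {
  ff <- reference_2mode_ff()
  chi <- anharmonic_constants(ff)
  sol <- variational_solve(ff, max_quanta = 25)
  for (q in manifold_states(2)) {
    ev <- state_energy(chi, q)
    eo <- oracle_level(sol, q)
    shift <- eo - sum(ff$modes$omega * q)
    expect_lt(abs(ev - eo), 0.01 * abs(shift))
  }
})

test_that("Fermi detection evaluates the three criteria as stated", {
  ff <- quartic_force_field(normal_modes(c(2990, 1700, 1300)))
  ff <- ff_set_constant(ff, c(2, 3, 1), 40)
  fer <- detect_fermi(ff)
  row <- fer$fermi[fer$fermi$i == 2 & fer$fermi$j == 3 & fer$fermi$k == 1, ]
  expect_equal(row$value_5a, 10)
  expect_equal(row$value_5b, 40^4)
  expect_equal(row$threshold_5b, 64 * 100)
  expect_equal(row$threshold_5c, 0.02 * 100)
  expect_true(row$flagged)
  # zero coupling never flags off degeneracy
  ff0 <- quartic_force_field(normal_modes(c(2990, 1700, 1300)))
  fer0 <- detect_fermi(ff0)
  expect_false(any(fer0$fermi$flagged[fer0$fermi$detuning != 0]))
  # the proximity gate is absolute
  ffg <- quartic_force_field(normal_modes(c(3300, 1700, 1300)))
  ffg <- ff_set_constant(ffg, c(2, 3, 1), 500)
  ferg <- detect_fermi(ffg)
  expect_false(any(ferg$fermi$flagged))
  # every candidate row carries its criterion values
  expect_true(all(c("value_5a", "value_5b", "value_5c",
                    "threshold_5b", "threshold_5c") %in% names(fer$fermi)))
})

test_that("the doubled-index Kronecker rule weights overtone resonances", {
  ff <- clean_dyad_ff(1500, 20, 30)
  fer_doubled <- detect_fermi(ff, delta_rule = "doubled")
  fer_printed <- detect_fermi(ff, delta_rule = "printed")
  row_d <- fer_doubled$fermi[fer_doubled$fermi$i == 2 & fer_doubled$fermi$j == 2, ]
  row_p <- fer_printed$fermi[fer_printed$fermi$i == 2 & fer_printed$fermi$j == 2, ]
  expect_equal(row_d$threshold_5b, 4 * row_p$threshold_5b)
  expect_equal(row_d$threshold_5c, 2 * row_p$threshold_5c)
})

test_that("DD couplings behave as contact-transformed matrix elements", {
  # harmonic: zero coupling
  ffh <- quartic_force_field(normal_modes(c(1500, 1530)))
  expect_equal(dd_coupling(ffh, c(1, 0), c(0, 1)), 0)
  # constructed 1-1 coupling: f_iiij = 8K with no cubics gives exactly K
  ff <- quartic_force_field(normal_modes(c(1500, 1530, 2900)))
  ff <- ff_set_constant(ff, c(1, 1, 1, 2), 8 * 15)
  expect_equal(dd_coupling(ff, c(1, 0, 0), c(0, 1, 0)), 15)
  # symmetry in the two states
  ff2 <- reference_2mode_ff()
  expect_equal(dd_coupling(ff2, c(1, 0), c(0, 1)),
               dd_coupling(ff2, c(0, 1), c(1, 0)))
  # oracle block inversion: effective 2x2 coupling from the two eigenvalues
  # and the known diagonal of a contrived near-degenerate pair
  ffo <- quartic_force_field(normal_modes(c(1500, 1520)))
  ffo <- ff_set_constant(ffo, c(1, 1, 1, 2), 8 * 12)
  K <- dd_coupling(ffo, c(1, 0), c(0, 1))
  sol <- variational_solve(ffo, max_quanta = 24)
  e1 <- oracle_level(sol, c(1, 0)); e2 <- oracle_level(sol, c(0, 1))
  gv <- gvpt2_solve(ffo)
  d1 <- gv$states$energy_vpt2[gv$states$key == "1,0"]
  d2 <- gv$states$energy_vpt2[gv$states$key == "0,1"]
  K_inv <- sqrt(abs((e2 - e1)^2 - (d2 - d1)^2)) / 2
  expect_equal(abs(K), K_inv, tolerance = 0.05 * abs(K))
})

test_that("DD detection applies its gates", {
  ff <- quartic_force_field(normal_modes(c(1500, 1750, 2900)))
  ff <- ff_set_constant(ff, c(1, 1, 1, 2), 8 * 15)
  dd <- detect_dd(ff)
  expect_false(dd$dd11$flagged[dd$dd11$i == 1 & dd$dd11$j == 2])  # gap 250
  ff2 <- quartic_force_field(normal_modes(c(1500, 1530, 2900)))
  ff2 <- ff_set_constant(ff2, c(1, 1, 1, 2), 8 * 5)
  dd2 <- detect_dd(ff2)
  expect_false(any(dd2$dd11$flagged))  # coupling 5 < 10
})

test_that("deperturbed wavefunction coefficients of flagged partners vanish", {
  sys <- fermi_dyad_system(10, 40, 5)
  ff <- sys$force_field
  res <- detect_dd(ff, fermi = detect_fermi(ff))
  wf <- vpt2_wavefunction(ff, c(1, 0), resonances = res)
  expect_equal(anharmvoa:::.hv_coef(wf$psi1, "0,2"), 0)
  expect_equal(anharmvoa:::.hv_coef(wf$psi2, "0,2"), 0)
  expect_gte(wf$norm, 1)
  # without deperturbation the coefficient is large (that is the resonance)
  wf_raw <- vpt2_wavefunction(ff, c(1, 0))
  expect_gt(abs(anharmvoa:::.hv_coef(wf_raw$psi1, "0,2")), 0.2)
})

test_that("GVPT2 reduces to VPT2 without resonances and shows level repulsion", {
  sys <- make_random_system(generator_spec(n_modes = 3, seed = 12),
                            ensure_nonresonant = TRUE)
  gv <- gvpt2_solve(sys)
  expect_equal(gv$states$energy, gv$states$energy_vpt2)
  expect_length(gv$blocks, 0)
  # dyad: variational splitting >= deperturbed splitting
  dy <- fermi_dyad_system(15, 50, 9)
  gvd <- gvpt2_solve(dy)
  b <- gvd$blocks[[1]]
  expect_equal(sort(b$members), sort(c("1,0", "0,2")))
  expect_gte(diff(range(b$eigenvalues)), abs(diff(diag(b$matrix))))
  # the block eigensystem is consistent with its stored matrix
  expect_equal(sort(eigen(b$matrix, symmetric = TRUE)$values),
               sort(b$eigenvalues))
  U <- b$eigenvectors
  expect_equal(t(U) %*% U, diag(2), tolerance = 1e-12)
})

test_that("Fermi dyads match the variational oracle and stay continuous at threshold", {
  cases <- list(list(d = 8, f = 35, seed = 21), list(d = 30, f = 80, seed = 22))
  for (case in cases) {
    sys <- fermi_dyad_system(case$d, case$f, case$seed)
    ff <- sys$force_field
    gv <- gvpt2_solve(sys)
    sol <- variational_solve(ff, max_quanta = 30)
    e_or <- sort(c(oracle_level(sol, c(1, 0)), oracle_level(sol, c(0, 2))))
    e_gv <- sort(gv$states$energy[gv$states$key %in% c("1,0", "0,2")])
    expect_lt(max(abs(e_gv - e_or)), 2)
  }
  # continuity across the 5b threshold (detuning 20 -> f* ~ 17.89)
  E_of <- function(f) {
    gv <- gvpt2_solve(clean_dyad_ff(1500, 20, f))
    sort(gv$states$energy[gv$states$key %in% c("1,0", "0,2")])
  }
  fstar <- (64 * 4 * 20^2)^0.25
  jump <- max(abs(E_of(fstar * 1.001) - E_of(fstar * 0.999)))
  expect_lt(jump, 0.5)
})

test_that("an unflagged exact degeneracy is a hard error, and big blocks are capped", {
  ff <- clean_dyad_ff(1500, 0, 0.001)  # exact degeneracy, coupling too weak
  fer <- detect_fermi(ff, gate = -1)   # force the flag off
  expect_error(anharmonic_constants(ff, resonances = fer), "thresholds")
  dy <- fermi_dyad_system(10, 40, 5)
  expect_error(gvpt2_solve(dy, block_cap = 1L), "cap")
})
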