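harmonic_system_with <- function(value0 = c(0, 0, 0), d1 = NULL, d2 = NULL,
                                 d3 = list(), omega = c(900, 1700)) {
  ff <- quartic_force_field(normal_modes(omega))
  mu <- property_surface("mu", length(omega), value0 = value0, d1 = d1,
                         d2 = d2, d3 = d3)
  model_system(ff, surfaces = list(mu))
}

test_that("harmonic moments reproduce the textbook matrix elements", {
  d1 <- matrix(c(0.3, -0.2, 0.1, 0, 0.25, 0), 3, 2)
  sys <- harmonic_system_with(d1 = d1)
  tr <- vpt2_transitions(sys)
  expect_equal(tr$moments[["1,0"]]$mu, d1[, 1] / sqrt(2), tolerance = 1e-12)
  expect_equal(tr$moments[["0,1"]]$mu, d1[, 2] / sqrt(2), tolerance = 1e-12)
  # harmonic wavefunction + first derivatives only: terms 2-11 vanish
  d <- tr$decompositions[["1,0"]]$mu
  expect_equal(max(abs(d$terms[2:11, ])), 0)
  expect_equal(colSums(d$terms), d$moment)
  # d2-only overtone: <0|X1|2_i> = d2_ii/(2 sqrt 2)
  d2 <- array(0, c(3, 2, 2)); d2[1, 1, 1] <- 0.04; d2[2, 2, 2] <- -0.02
  sys2 <- harmonic_system_with(d2 = d2)
  tr2 <- vpt2_transitions(sys2)
  expect_equal(tr2$moments[["2,0"]]$mu, d2[, 1, 1] / (2 * sqrt(2)),
               tolerance = 1e-12)
  # and the whole overtone moment lives in term 2
  dd <- tr2$decompositions[["2,0"]]$mu
  expect_equal(dd$terms[2, ], dd$moment)
})

test_that("the eleven terms always sum to the reported moment", {
  sys <- make_random_system(generator_spec(n_modes = 3, seed = 31),
                            ensure_nonresonant = TRUE)
  tr <- vpt2_transitions(sys)
  for (k in names(tr$decompositions)) {
    for (sn in names(tr$decompositions[[k]])) {
      d <- tr$decompositions[[k]][[sn]]
      expect_equal(colSums(d$terms), d$moment, tolerance = 1e-12)
      # the full nonlinear ratio differs only by beyond-second-order pieces,
      # which are small on the absolute scale of these surfaces
      expect_lt(max(abs(d$residual)), 1e-3)
    }
  }
})

test_that("the normalized moment is invariant under wavefunction rescaling", {
  sys <- make_random_system(generator_spec(n_modes = 2, seed = 7),
                            ensure_nonresonant = TRUE)
  ff <- sys$force_field
  wf0 <- vpt2_wavefunction(ff, c(0, 0))
  wfF <- vpt2_wavefunction(ff, c(1, 0))
  base <- transition_moment(sys$surfaces$mu, wf0, wfF)
  scaled <- wfF
  cf <- 3.7
  scaled$psi0$c <- scaled$psi0$c * cf
  scaled$psi1$c <- scaled$psi1$c * cf
  scaled$psi2$c <- scaled$psi2$c * cf
  scaled$norm <- scaled$norm * cf^2
  after <- transition_moment(sys$surfaces$mu, wf0, scaled)
  expect_equal(after$full_ratio, base$full_ratio, tolerance = 1e-12)
})

test_that("VPT2 moments agree with exact variational matrix elements", {
  sys <- make_random_system(generator_spec(n_modes = 2, seed = 11),
                            ensure_nonresonant = TRUE)
  tr <- vpt2_transitions(sys)
  sol <- variational_solve(sys$force_field, max_quanta = 24)
  for (sn in names(sys$surfaces)) {
    for (q in manifold_states(2)) {
      om <- oracle_transition_moment(sol, sys$surfaces[[sn]], c(0, 0), q)
      d <- tr$decompositions[[skey(q)]][[sn]]
      expect_lt(max(abs(d$full_ratio - om)), 0.02 * max(abs(om)))
    }
  }
})

test_that("IR/VCD observables follow their definitions and parity", {
  obs <- ir_vcd_observables(c(0.2, 0, 0), c(0.05, 0, 0), 1000,
                            include_freq_factor = FALSE)
  expect_equal(obs$D, 0.04)
  expect_equal(obs$R, 0.01)
  expect_equal(obs$g, 1)  # 4R/D with collinear unit-direction moments
  zero <- ir_vcd_observables(c(0.2, 0, 0), c(0, 0, 0), 1000)
  expect_equal(zero$R, 0)
  expect_equal(zero$vcd_stick, 0)
  flip <- ir_vcd_observables(c(0.2, 0, 0), -c(0.05, 0, 0), 1000)
  expect_equal(flip$R, -obs$R)
  expect_equal(flip$D, obs$D)
  none <- ir_vcd_observables(c(0.2, 0, 0), NULL, 1000)
  expect_true(is.na(none$R) && is.na(none$vcd_stick) && !is.na(none$D))
})

test_that("Raman/ROA invariants match a brute-force tensor contraction", {
  set.seed(4)
  al <- matrix(rnorm(9), 3, 3); al <- (al + t(al)) / 2
  G <- matrix(rnorm(9), 3, 3)
  A <- array(rnorm(27), c(3, 3, 3))
  A <- (A + aperm(A, c(1, 3, 2))) / 2
  obs <- raman_roa_observables(as.numeric(al), as.numeric(G), as.numeric(A),
                               energy = 1200, include_nu4 = FALSE)
  # independent contraction with explicit Cartesian sums
  tr_a <- sum(diag(al)); tr_G <- sum(diag(G))
  beta_a <- 0
  for (i in 1:3) for (j in 1:3) beta_a <- beta_a + 0.5 * (3 * al[i, j]^2)
  beta_a <- beta_a - 0.5 * tr_a^2
  expect_equal(obs$a2, (tr_a / 3)^2)
  expect_equal(obs$beta_alpha2, beta_a)
  expect_equal(obs$aG, tr_a * tr_G / 9)
  eps <- function(i, j, k) (i - j) * (j - k) * (k - i) / 2
  s <- 0
  for (a in 1:3) for (b in 1:3) for (cc in 1:3) for (d in 1:3)
    s <- s + al[a, b] * eps(a, cc, d) * A[cc, d, b]
  omega_au <- 45.56335252907657 / 532
  expect_equal(obs$beta_A2, 0.5 * omega_au * s)
  # isotropic polarizability: no anisotropy, no ROA
  iso <- raman_roa_observables(as.numeric(diag(3) * 2),
                               rep(0, 9), rep(0, 27), 1200)
  expect_equal(iso$beta_alpha2, 0)
  expect_equal(iso$roa_stick, 0)
  expect_gt(iso$raman_stick, 0)
})

test_that("mirror pairs negate VCD and ROA exactly and preserve IR and Raman", {
  sys <- make_random_system(generator_spec(n_modes = 3, seed = 42),
                            ensure_nonresonant = TRUE)
  mir <- mirror_image(sys)
  s1 <- vpt2_spectra(sys, by = 4)
  s2 <- vpt2_spectra(mir, by = 4)
  expect_identical(s1$spectra$VCD$intensity, -s2$spectra$VCD$intensity)
  expect_identical(s1$spectra$ROA$intensity, -s2$spectra$ROA$intensity)
  expect_identical(s1$spectra$IR$intensity, s2$spectra$IR$intensity)
  expect_identical(s1$spectra$Raman$intensity, s2$spectra$Raman$intensity)
})

test_that("band assignment follows the leading-weight rule", {
  sys <- make_random_system(generator_spec(n_modes = 2, seed = 3),
                            ensure_nonresonant = TRUE)
  tr <- assign_bands(vpt2_transitions(sys))
  expect_true(all(tr$table$leading_weight == 1))
  expect_equal(tr$table$assignment, tr$table$label)
  # a strongly mixed Fermi dyad is labeled mixed below the threshold
  dy <- fermi_dyad_system(2, 60, 13)
  trd <- assign_bands(vpt2_transitions(dy))
  dyad_rows <- trd$table$key %in% c("1,0", "0,2")
  expect_true(all(grepl("^mixed:", trd$table$assignment[dyad_rows])))
  expect_true(all(trd$table$leading_weight[dyad_rows] < 0.8))
  # a weakly mixed dyad keeps its label (constructed ~19 degree mixing:
  # W = f/4 = 8, deperturbed gap ~20, tan 2theta ~ 0.8)
  ffw <- clean_dyad_ff(1500, 20, 32)
  gvw <- gvpt2_solve(ffw)
  b <- gvw$blocks[[1]]
  expect_gt(max(b$eigenvectors[, 1]^2), 0.8)
})

test_that("anharmonic VOA bands are carried by the property second derivatives", {
  # weak mechanical anharmonicity, sizeable d2: overtone/combination VCD and
  # ROA moments must be dominated by term 2
  spec <- generator_spec(n_modes = 2, cubic_scale = 2, quartic_scale = 1,
                         seed = 19,
                         property_plan = list(d2_scale = 0.03, d3_scale = 0.001))
  sys <- make_random_system(spec, ensure_nonresonant = TRUE)
  tr <- vpt2_transitions(sys)
  for (k in c("2,0", "0,2", "1,1")) {
    for (sn in c("m", "Gprime")) {
      d <- tr$decompositions[[k]][[sn]]
      expect_gt(sqrt(sum(d$terms[2, ]^2)) / sqrt(sum(d$moment^2)), 0.9)
    }
  }
})

test_that("derivative-order contributions partition the intensity", {
  sys <- make_random_system(generator_spec(n_modes = 2, seed = 23),
                            ensure_nonresonant = TRUE)
  contrib <- derivative_order_contributions(sys, by = 4)
  ok <- !is.na(contrib$n_first)
  expect_true(any(ok))
  expect_equal(contrib$n_first[ok] + contrib$n_second[ok] + contrib$n_third[ok],
               rep(100, sum(ok)))
  # a purely harmonic-property system is 100% first derivatives
  d1 <- matrix(c(0.3, -0.2, 0.1, 0, 0.25, 0), 3, 2)
  hsys <- harmonic_system_with(d1 = d1)
  hc <- derivative_order_contributions(hsys, by = 4)
  hok <- !is.na(hc$n_first)
  expect_equal(hc$n_first[hok], rep(100, sum(hok)))
})
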