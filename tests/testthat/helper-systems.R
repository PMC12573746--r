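# Shared fixture builders.  Everything is generated in code; no stored data.

# a two-mode overtone Fermi dyad: omega_1 ~ 2*omega_2 - detuning, cubic
# coupling f on (1,2,2), with mild background anharmonicity from the
# generator defaults
fermi_dyad_system <- function(detuning, f, seed) {
  spec <- generator_spec(
    n_modes = 2, omega_range = c(1400, 1550), seed = seed,
    resonance_plan = list(list(type = "fermi", i = 2, j = 2, k = 1,
                               detuning = detuning, f = f)))
  make_random_system(spec)
}

# bare two-mode force field with a single planned coupling, no noise
clean_dyad_ff <- function(omega2 = 1500, detuning = 20, f = 30) {
  modes <- normal_modes(c(2 * omega2 - detuning, omega2))
  ff <- quartic_force_field(modes)
  ff_set_constant(ff, c(1, 2, 2), f)
}

# hand-built 2-mode anharmonic force field used for oracle cross-checks
reference_2mode_ff <- function() {
  ff <- quartic_force_field(normal_modes(c(950, 2150)))
  ff <- ff_set_constant(ff, c(1, 1, 1), -18)
  ff <- ff_set_constant(ff, c(1, 1, 2), 12)
  ff <- ff_set_constant(ff, c(1, 2, 2), -9)
  ff <- ff_set_constant(ff, c(2, 2, 2), -25)
  ff <- ff_set_constant(ff, c(1, 1, 1, 1), 6)
  ff <- ff_set_constant(ff, c(2, 2, 2, 2), 9)
  ff <- ff_set_constant(ff, c(1, 1, 2, 2), 3)
  ff <- ff_set_constant(ff, c(1, 1, 1, 2), 2)
  ff <- ff_set_constant(ff, c(1, 2, 2, 2), -1.5)
  ff
}

# states of the <=2-quanta manifold as quanta vectors
manifold_states <- function(nm) {
  out <- list()
  for (i in seq_len(nm)) { v <- integer(nm); v[i] <- 1L; out <- c(out, list(v)) }
  for (i in seq_len(nm)) { v <- integer(nm); v[i] <- 2L; out <- c(out, list(v)) }
  if (nm >= 2) for (i in 1:(nm - 1)) for (j in (i + 1):nm) {
    v <- integer(nm); v[i] <- 1L; v[j] <- 1L; out <- c(out, list(v))
  }
  out
}

skey <- function(q) paste(q, collapse = ",")
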