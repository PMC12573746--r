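# Synthetic model systems: controlled anharmonicity, contrived
# near-resonances, enantiomer mirror images.  Property surfaces are exact
# polynomials of order <= 3 in the reduced coordinates, so finite-difference
# recovery and operator matrix elements can be tested without truncation
# ambiguity.

#' Generator specification for random model systems
#'
#' @param n_modes number of modes (default 3).
#' @param omega_range range of harmonic wavenumbers in cm^-1 from which modes
#'   are drawn (default 600--3200, the mid-infrared span of typical rigid
#'   organic molecules).
#' @param cubic_scale,quartic_scale standard deviations (cm^-1) of the random
#'   cubic and semidiagonal quartic constants.  Defaults (25 and 8 cm^-1)
#'   keep the perturbative ratios |f|/omega well below 0.1 so that
#'   second-order perturbation theory is in its validity regime.
#' @param resonance_plan list of requested near-degeneracies.  Each entry is
#'   a list with `type` (`"fermi"` or `"dd11"`), the participating mode
#'   indices (`i`, `j`, `k` for Fermi with `omega_k ~ omega_i + omega_j`;
#'   `i`, `j` for 1-1 Darling-Dennison), `detuning` (cm^-1, >= 0) and the
#'   requested coupling magnitude (`f` for Fermi cubic constants,
#'   `coupling` for DD).
#' @param property_plan list of coefficient scales for the five tensors:
#'   `value0_scale`, `d1_scale`, `d2_scale`, `d3_scale` (atomic units per
#'   reduced coordinate power) and `tensors`, the subset to generate.
#' @param seed integer seed driving a Mersenne-Twister stream; recorded in
#'   the system metadata.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(n_modes = 3L,
                           omega_range = c(600, 3200),
                           cubic_scale = 25,
                           quartic_scale = 8,
                           resonance_plan = list(),
                           property_plan = list(),
                           seed = 1L) {
  stopifnot(n_modes >= 1L, length(omega_range) == 2L,
            omega_range[1] > 0, diff(omega_range) >= 0,
            cubic_scale >= 0, quartic_scale >= 0)
  pp <- utils::modifyList(list(
    tensors = c("mu", "m", "alpha", "Gprime", "Aquad"),
    value0_scale = 0.5, d1_scale = 0.1, d2_scale = 0.02, d3_scale = 0.005
  ), property_plan)
  for (r in resonance_plan) {
    if (!r$type %in% c("fermi", "dd11")) stop("unknown resonance type ", r$type)
    if (!is.null(r$detuning) && r$detuning < 0) stop("detunings must be >= 0")
  }
  structure(list(n_modes = as.integer(n_modes), omega_range = omega_range,
                 cubic_scale = cubic_scale, quartic_scale = quartic_scale,
                 resonance_plan = resonance_plan, property_plan = pp,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' One-mode Morse validation system
#'
#' Builds the quartic Taylor truncation of a Morse oscillator with harmonic
#' wavenumber `omega` and anharmonicity `omega_x`:
#' \eqn{f_{iii} = -3\sqrt{2\,\omega\,\omega_x}}, \eqn{f_{iiii} = 14\,\omega_x}.
#' The exact Morse levels \eqn{E_v = \omega(v + 1/2) - \omega_x (v + 1/2)^2}
#' are recorded in the metadata; second-order perturbation theory on the
#' quartic truncation reproduces them exactly
#' (\eqn{\chi_{11} = -\omega_x}), which makes this the package's closed-form
#' benchmark.
#'
#' A default linear-plus-quadratic dipole surface is attached so the system
#' can flow through the intensity machinery.
#'
#' @param omega harmonic wavenumber (cm^-1).
#' @param omega_x anharmonicity constant (cm^-1), `0 < omega_x << omega`.
#' @param mu_d1,mu_d2 dipole first/second derivative magnitudes (a.u.).
#' @return A one-mode [model_system()].
#' @examples
#' sys <- make_morse_system(3000, 50)
#' ff_constant(sys$force_field, c(1, 1, 1))
#' @export
make_morse_system <- function(omega, omega_x, mu_d1 = 0.1, mu_d2 = 0.01) {
  stopifnot(omega > 0, omega_x > 0)
  if (omega_x >= omega / 4)
    warning("omega_x >= omega/4: the Morse well supports too few bound ",
            "states for the v <= 2 manifold to be meaningful")
  modes <- normal_modes(omega, "morse")
  ff <- quartic_force_field(modes)
  ff <- ff_set_constant(ff, c(1, 1, 1), -3 * sqrt(2 * omega * omega_x))
  ff <- ff_set_constant(ff, c(1, 1, 1, 1), 14 * omega_x)
  mu <- property_surface("mu", 1L,
                         value0 = c(0.2, 0, 0),
                         d1 = matrix(c(mu_d1, 0, 0), 3, 1),
                         d2 = array(c(mu_d2, 0, 0), c(3, 1, 1)))
  model_system(ff, surfaces = list(mu),
               metadata = list(
                 generator = "make_morse_system",
                 omega = omega, omega_x = omega_x,
                 level_formula = "E_v = omega*(v+1/2) - omega_x*(v+1/2)^2"))
}

# draw frequencies satisfying the plan (or, for an empty plan with
# ensure_nonresonant, staying away from every 200 cm^-1 proximity gate)
.draw_omega <- function(spec, ensure_nonresonant, margin = 220) {
  nm <- spec$n_modes
  rng <- spec$omega_range
  plan <- spec$resonance_plan
  for (attempt in 1:2000) {
    omega <- sort(stats::runif(nm, rng[1], rng[2]))
    ok_plan <- TRUE
    for (r in plan) {
      if (r$type == "fermi") {
        tgt <- omega[r$i] + omega[r$j] - r$detuning
        # achievable: positive and within twice the stated ceiling
        if (tgt <= 0 || tgt > 2 * rng[2]) { ok_plan <- FALSE; break }
        omega[r$k] <- tgt
      } else if (r$type == "dd11") {
        tgt <- omega[r$i] - r$detuning
        if (tgt <= 0) { ok_plan <- FALSE; break }
        omega[r$j] <- tgt
      }
    }
    if (!ok_plan || any(omega <= 0)) next
    planned <- length(plan) > 0L
    if (planned) {
      return(omega)
    } else if (ensure_nonresonant) {
      ok <- TRUE
      for (i in seq_len(nm)) for (j in i:nm) {
        if (i != j && abs(omega[i] - omega[j]) < margin) ok <- FALSE
        for (k in seq_len(nm)) {
          if (k != i && k != j &&
              abs(omega[k] - (omega[i] + omega[j])) < margin) ok <- FALSE
          # three-quanta (1:3, 1:2+1) near-degeneracies enter the
          # perturbative sums at higher order; keep clear of them too
          for (l in j:nm) {
            if (!(k %in% c(i, j, l)) &&
                abs(omega[k] - (omega[i] + omega[j] + omega[l])) < margin * 0.7)
              ok <- FALSE
          }
        }
      }
      if (ok) return(omega)
    } else return(omega)
  }
  stop("could not realize the resonance plan within 'omega_range': ",
       "the requested detunings are not achievable")
}

.sym_alpha_comp <- function(v) {
  m <- matrix(v, 3, 3)
  as.numeric((m + t(m)) / 2)
}
.sym_A_comp <- function(v) {
  arr <- array(v, c(3, 3, 3))
  (as.numeric(arr) + as.numeric(aperm(arr, c(1, 3, 2)))) / 2
}
.sym_tensor <- function(name, v) {
  switch(name, alpha = .sym_alpha_comp(v), Aquad = .sym_A_comp(v), v)
}

#' Random model system with controlled anharmonicity
#'
#' Draws a reproducible random system: harmonic wavenumbers from
#' `omega_range`, zero-mean cubic and semidiagonal quartic constants at the
#' requested scales (diagonal quartics forced positive so every single-mode
#' direction of the truncated potential is bounded), polynomial property
#' surfaces for the requested tensors, and any planned near-resonances
#' realized exactly at their stated detunings.
#'
#' @param spec a [generator_spec()].
#' @param ensure_nonresonant when `TRUE` (and the plan is empty) frequencies
#'   are redrawn until every Fermi and Darling-Dennison proximity gate
#'   (200 cm^-1) is cleared by a margin, so the system is guaranteed
#'   resonance-free at the detection thresholds.
#' @return A [model_system()]; metadata records the seed and stream.
#' @export
make_random_system <- function(spec, ensure_nonresonant = FALSE) {
  stopifnot(inherits(spec, "generator_spec"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed, kind = "Mersenne-Twister")

  nm <- spec$n_modes
  omega <- .draw_omega(spec, ensure_nonresonant)
  modes <- normal_modes(omega)
  ff <- quartic_force_field(modes)

  # cubic constants, clamped to the perturbative regime |f| <= 0.1 min(omega)
  clamp <- 0.1 * min(omega)
  for (i in seq_len(nm)) for (j in i:nm) for (k in j:nm) {
    f <- stats::rnorm(1, 0, spec$cubic_scale)
    ff <- ff_set_constant(ff, c(i, j, k), max(-clamp, min(clamp, f)))
  }
  if (ensure_nonresonant && !length(spec$resonance_plan)) {
    # being resonance-free means clearing the strength criteria with margin,
    # not just the proximity gates: cap each cubic at half the Fermi
    # strength threshold for its actual detuning (factor 0.25 on f^4)
    for (i in seq_len(nm)) for (j in i:nm) for (k in seq_len(nm)) {
      if (k == i || k == j) next
      det <- abs(omega[k] - omega[i] - omega[j])
      fmax <- (0.25 * 64 * (1 + (i == j))^2 * det^2)^0.25
      f <- ff_constant(ff, c(i, j, k))
      if (abs(f) > fmax) ff <- ff_set_constant(ff, c(i, j, k), sign(f) * fmax)
    }
  }
  # semidiagonal quartics; diagonal entries positive
  for (i in seq_len(nm)) {
    ff <- ff_set_constant(ff, rep(i, 4L),
                          abs(stats::rnorm(1, 0, spec$quartic_scale)) +
                            0.25 * spec$quartic_scale)
  }
  four <- .semidiagonal_quartic_keys(nm)
  for (key in four) {
    idx <- .key_idx(key)
    if (length(unique(idx)) == 1L) next  # diagonal handled above
    ff <- ff_set_constant(ff, idx, stats::rnorm(1, 0, spec$quartic_scale))
  }
  # planned couplings overwrite the random draws
  for (r in spec$resonance_plan) {
    if (r$type == "fermi") {
      ff <- ff_set_constant(ff, c(r$i, r$j, r$k), r$f)
    } else if (r$type == "dd11") {
      # a 1-1 coupling is injected through the semidiagonal quartic
      # f_iiij, whose direct contact matrix element is f/8
      ff <- ff_set_constant(ff, c(r$i, r$i, r$i, r$j), 8 * r$coupling)
    }
  }

  pp <- spec$property_plan
  surfaces <- lapply(pp$tensors, function(tn) {
    nc <- .surface_shapes[[tn]]
    value0 <- .sym_tensor(tn, stats::rnorm(nc, 0, pp$value0_scale))
    d1 <- matrix(stats::rnorm(nc * nm, 0, pp$d1_scale), nc, nm)
    for (m in seq_len(nm)) d1[, m] <- .sym_tensor(tn, d1[, m])
    d2 <- array(0, c(nc, nm, nm))
    for (i in seq_len(nm)) for (j in i:nm) {
      v <- .sym_tensor(tn, stats::rnorm(nc, 0, pp$d2_scale))
      d2[, i, j] <- v; d2[, j, i] <- v
    }
    d3 <- list()
    for (key in .semidiagonal_cubic_keys(nm)) {
      d3[[key]] <- .sym_tensor(tn, stats::rnorm(nc, 0, pp$d3_scale))
    }
    property_surface(tn, nm, value0 = value0, d1 = d1, d2 = d2, d3 = d3)
  })

  model_system(ff, surfaces = surfaces,
               metadata = list(generator = "make_random_system", version = 1L,
                               seed = spec$seed, rng = "Mersenne-Twister",
                               n_modes = nm,
                               resonance_plan = spec$resonance_plan))
}

# canonical sorted tuples with at least two equal indices
.semidiagonal_cubic_keys <- function(nm) {
  keys <- character()
  for (i in seq_len(nm)) for (j in i:nm) for (k in j:nm) {
    if (any(duplicated(c(i, j, k)))) keys <- c(keys, .idx_key(c(i, j, k)))
  }
  keys
}
.semidiagonal_quartic_keys <- function(nm) {
  keys <- character()
  for (i in seq_len(nm)) for (j in i:nm) for (k in j:nm) for (l in k:nm) {
    if (any(duplicated(c(i, j, k, l)))) keys <- c(keys, .idx_key(c(i, j, k, l)))
  }
  keys
}

#' Enantiomer (mirror image) of a model system
#'
#' Applies the parity rule for reflection: the force field and the true
#' tensors (electric dipole, polarizability) are unchanged; the magnetic
#' dipole, G' and A surfaces change sign at every derivative order.  VCD and
#' ROA spectra of the mirror pair are therefore exact negatives while IR and
#' Raman are identical, and `mirror_image()` is an involution.
#'
#' @param system a [model_system()] carrying chiroptical surfaces.
#' @return The mirrored [model_system()].
#' @export
mirror_image <- function(system) {
  stopifnot(inherits(system, "model_system"))
  flip <- c("m", "Gprime", "Aquad")
  if (!any(names(system$surfaces) %in% flip))
    stop("system has no chiroptical surfaces (m, Gprime or Aquad) to mirror")
  system$surfaces <- lapply(system$surfaces, function(s) {
    if (s$name %in% flip) {
      s$value0 <- -s$value0
      s$d1 <- -s$d1
      s$d2 <- -s$d2
      s$d3 <- lapply(s$d3, function(v) -v)
    }
    s
  })
  system$metadata$mirrored <- !isTRUE(system$metadata$mirrored)
  system
}

#' Analytic evaluator for a model system's stored polynomial surfaces
#'
#' Returns the callable contract consumed by the finite-difference module:
#' a function of a reduced-coordinate displacement vector that yields the
#' analytic Hessian of the stored quartic potential and the analytic
#' first-derivative tensors of every stored property surface.  Because the
#' stored surfaces are exact polynomials, the two-step differentiation of
#' [cubic_quartic_from_hessians()] and [property_higher_derivatives()]
#' recovers the stored constants to roundoff.
#'
#' @param system a [model_system()].
#' @return A function `f(q)` returning `list(hessian = <n x n matrix in
#'   cm^-1>, d1 = <named list of [n_comp, n_modes] first-derivative
#'   matrices>)`.
#' @export
system_evaluator <- function(system) {
  stopifnot(inherits(system, "model_system"))
  ff <- system$force_field
  nm <- ff$modes$n_modes
  omega <- ff$modes$omega
  surfaces <- system$surfaces
  function(q) {
    stopifnot(length(q) == nm)
    H <- diag(omega, nm)
    for (j in seq_len(nm)) for (k in j:nm) {
      acc <- 0
      for (i in seq_len(nm)) {
        acc <- acc + ff_constant(ff, c(i, j, k)) * q[i]
        for (l in seq_len(nm)) {
          idx <- sort(c(i, j, k, l))
          if (.is_semidiagonal(idx))
            acc <- acc + 0.5 * ff_constant(ff, idx) * q[i] * q[l]
        }
      }
      H[j, k] <- H[j, k] + acc
      if (j != k) H[k, j] <- H[j, k]
    }
    d1 <- lapply(surfaces, function(s) {
      out <- s$d1
      for (i in seq_len(nm)) {
        for (j in seq_len(nm)) out[, i] <- out[, i] + s$d2[, i, j] * q[j]
        # 0.5 * sum_jk d3_ijk q_j q_k with totally symmetric d3
        for (key in names(s$d3)) {
          idx <- .key_idx(key)
          val <- s$d3[[key]]
          for (p in .all_perms3(idx)) {
            if (p[1L] == i) out[, i] <- out[, i] + 0.5 * val * q[p[2L]] * q[p[3L]]
          }
        }
      }
      out
    })
    list(hessian = H, d1 = d1)
  }
}
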