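# Second-order vibrational perturbation theory: anharmonic constants,
# resonance detection, deperturbation and the variational (GVPT2) step.
#
# The chi-matrix closed forms below are the standard second-order constants
# for the quartic normal-coordinate potential, written in partial-fraction
# form so that each Fermi-resonant denominator 1/(omega_i + omega_j -
# omega_k) is an isolated additive piece that can be removed when the triple
# (i,j;k) is flagged.  The removed piece equals, to second order, the energy
# shift that the variational step puts back -- which is what makes GVPT2
# energies continuous as a coupling crosses the detection threshold.  The
# full formulas with this bookkeeping are documented in the methods
# vignette.

# ---------------------------------------------------------------------------
# state enumeration

.states_leq2 <- function(nm) {
  qs <- list(integer(nm) * 0L)
  for (i in seq_len(nm)) { v <- integer(nm); v[i] <- 1L; qs[[length(qs) + 1L]] <- v }
  for (i in seq_len(nm)) { v <- integer(nm); v[i] <- 2L; qs[[length(qs) + 1L]] <- v }
  if (nm >= 2L) for (i in seq_len(nm - 1L)) for (j in (i + 1L):nm) {
    v <- integer(nm); v[i] <- 1L; v[j] <- 1L; qs[[length(qs) + 1L]] <- v
  }
  keys <- vapply(qs, paste, "", collapse = ",")
  labels <- vapply(qs, .state_label, "")
  list(quanta = qs, keys = keys, labels = labels)
}

# ---------------------------------------------------------------------------
# Fermi resonance detection (criteria 5a-5c)

#' Detect Fermi resonances
#'
#' Scans every triple `omega_k ~ omega_i + omega_j` (`i <= j`, `k` distinct
#' from both) against the three detection criteria: an energy-proximity gate
#' (detuning at most `gate` cm^-1), an energy-based strength test
#' `f_ijk^4 >= c5b * (1+delta)^2 * detuning^2`, and an intensity-oriented
#' test `|f_ijk| >= c5c * detuning^2 * (1+delta)`.  The Kronecker delta is
#' applied to the doubled combination index (`i == j`, the overtone case) by
#' default; `delta_rule = "printed"` reproduces the literal `delta_jk`
#' placement, which never fires because `k` is always distinct.
#'
#' Every candidate row carries the numeric value of each criterion, not just
#' the pass flag, so threshold reviews can be audited.
#'
#' @param ff a [quartic_force_field()].
#' @param gate proximity gate in cm^-1 (default 200).
#' @param c5b strength-test prefactor (default 64).
#' @param c5c intensity-test prefactor (default 0.02); the test mixes cm^-1
#'   against cm^-2 exactly as conventionally stated.
#' @param use_5c set `FALSE` to disable the third criterion.
#' @param delta_rule `"doubled"` (default) or `"printed"`.
#' @return A `resonance_set` whose `fermi` element is a data frame of all
#'   candidate triples with criterion values and flags.
#' @export
detect_fermi <- function(ff, gate = 200, c5b = 64, c5c = 0.02,
                         use_5c = TRUE, delta_rule = c("doubled", "printed")) {
  stopifnot(inherits(ff, "quartic_force_field"))
  delta_rule <- match.arg(delta_rule)
  omega <- ff$modes$omega
  nm <- length(omega)
  rows <- list()
  for (i in seq_len(nm)) for (j in i:nm) for (k in seq_len(nm)) {
    if (k == i || k == j) next
    f <- ff_constant(ff, c(i, j, k))
    detuning <- omega[k] - (omega[i] + omega[j])
    delta <- if (delta_rule == "doubled") as.numeric(i == j) else 0
    rhs5b <- c5b * (1 + delta)^2 * detuning^2
    rhs5c <- c5c * abs(detuning^2 * (1 + delta))
    p5a <- abs(detuning) <= gate
    p5b <- f^4 >= rhs5b
    p5c <- abs(f) >= rhs5c
    rows[[length(rows) + 1L]] <- data.frame(
      i = i, j = j, k = k, f = f, detuning = detuning,
      value_5a = abs(detuning), pass_5a = p5a,
      value_5b = f^4, threshold_5b = rhs5b, pass_5b = p5b,
      value_5c = abs(f), threshold_5c = rhs5c, pass_5c = p5c,
      flagged = p5a && p5b && (p5c || !use_5c))
  }
  fermi <- if (length(rows)) do.call(rbind, rows) else
    data.frame(i = integer(), j = integer(), k = integer(), f = numeric(),
               detuning = numeric(), value_5a = numeric(), pass_5a = logical(),
               value_5b = numeric(), threshold_5b = numeric(), pass_5b = logical(),
               value_5c = numeric(), threshold_5c = numeric(), pass_5c = logical(),
               flagged = logical())
  structure(list(fermi = fermi, dd11 = NULL, dd22 = NULL,
                 thresholds = list(gate = gate, c5b = c5b, c5c = c5c,
                                   use_5c = use_5c, delta_rule = delta_rule)),
            class = "resonance_set")
}

#' @export
print.resonance_set <- function(x, ...) {
  nf <- if (!is.null(x$fermi)) sum(x$fermi$flagged) else 0L
  n1 <- if (!is.null(x$dd11)) sum(x$dd11$flagged) else 0L
  n2 <- if (!is.null(x$dd22)) sum(x$dd22$flagged) else 0L
  cat("<resonance_set> flagged: ", nf, " Fermi, ", n1, " DD 1-1, ",
      n2, " DD 2-2\n", sep = "")
  invisible(x)
}

# flagged Fermi triples as a lookup set of "i,j,k" keys (i <= j)
.fermi_flag_env <- function(resonances) {
  env <- new.env(parent = emptyenv())
  if (!is.null(resonances) && !is.null(resonances$fermi)) {
    fl <- resonances$fermi[resonances$fermi$flagged, , drop = FALSE]
    for (r in seq_len(nrow(fl)))
      assign(paste(fl$i[r], fl$j[r], fl$k[r], sep = ","), TRUE, env)
  }
  env
}
.fermi_flagged <- function(env, i, j, k) {
  isTRUE(env[[paste(min(i, j), max(i, j), k, sep = ",")]])
}

# ---------------------------------------------------------------------------
# anharmonic constants

#' Anharmonic constant matrix
#'
#' Builds the symmetric chi matrix (cm^-1) of second-order vibrational
#' perturbation theory from cubic and semidiagonal quartic constants, with
#' optional Coriolis contributions and with every flagged Fermi-resonant
#' denominator removed (deperturbation).  Removed pieces are logged in the
#' result.  An exact zero denominator that is not covered by a flagged
#' resonance is a hard error instructing a threshold review.
#'
#' @param ff a [quartic_force_field()].
#' @param coriolis optional [coriolis_data()]; enters the energies only.
#' @param resonances a `resonance_set` from [detect_fermi()] (or `NULL` for
#'   no deperturbation).
#' @return A `chi_matrix` object: the symmetric matrix in `$chi`, a
#'   `deperturbed` flag and a data frame `removed` naming every dropped
#'   resonant denominator.
#' @export
anharmonic_constants <- function(ff, coriolis = NULL, resonances = NULL) {
  stopifnot(inherits(ff, "quartic_force_field"))
  omega <- ff$modes$omega
  nm <- length(omega)
  flags <- .fermi_flag_env(resonances)
  removed <- list()
  tiny <- 1e-6
  denom <- function(val, i, j, k, what) {
    # resonant denominator guard: flagged -> drop (return NA), tiny -> error
    if (.fermi_flagged(flags, i, j, k)) {
      removed[[length(removed) + 1L]] <<- data.frame(
        i = min(i, j), j = max(i, j), k = k, denominator = val, term = what)
      return(NA_real_)
    }
    if (abs(val) < tiny)
      stop(sprintf(paste0(
        "denominator omega_%d + omega_%d - omega_%d = %.3g cm^-1 is ",
        "singular but the triple is not flagged as a Fermi resonance; ",
        "review the detection thresholds"), min(i, j), max(i, j), k, val))
    val
  }
  chi <- matrix(0, nm, nm)
  for (i in seq_len(nm)) {
    acc <- ff_constant(ff, rep(i, 4L)) / 16
    for (j in seq_len(nm)) {
      f <- ff_constant(ff, c(i, i, j))
      if (f == 0) next
      d <- denom(2 * omega[i] - omega[j], i, i, j, "chi_ii")
      res_piece <- if (is.na(d)) 0 else -0.5 / d
      acc <- acc - (f^2 / 16) *
        (2 / omega[j] + res_piece + 0.5 / (2 * omega[i] + omega[j]))
    }
    chi[i, i] <- acc
  }
  if (nm >= 2L) for (i in seq_len(nm - 1L)) for (j in (i + 1L):nm) {
    acc <- ff_constant(ff, c(i, i, j, j)) / 4
    for (k in seq_len(nm)) {
      fik <- ff_constant(ff, c(i, i, k))
      fjk <- ff_constant(ff, c(j, j, k))
      if (fik != 0 && fjk != 0) acc <- acc - fik * fjk / (4 * omega[k])
      f <- ff_constant(ff, c(i, j, k))
      if (f != 0) {
        d1 <- omega[i] + omega[j] + omega[k]
        d2 <- denom(omega[j] + omega[k] - omega[i], j, k, i, "chi_ij")
        d3 <- denom(omega[i] + omega[k] - omega[j], i, k, j, "chi_ij")
        d4 <- denom(omega[i] + omega[j] - omega[k], i, j, k, "chi_ij")
        s <- 1 / d1
        if (!is.na(d2)) s <- s + 1 / d2
        if (!is.na(d3)) s <- s + 1 / d3
        if (!is.na(d4)) s <- s - 1 / d4
        acc <- acc - (f^2 / 8) * s
      }
    }
    if (!is.null(coriolis) && isTRUE(coriolis$present)) {
      B <- coriolis$rotational_constants
      zet2 <- sum(B * coriolis$zeta[, i, j]^2)
      acc <- acc + zet2 * (omega[i] / omega[j] + omega[j] / omega[i])
    }
    chi[i, j] <- chi[j, i] <- acc
  }
  removed_df <- if (length(removed)) do.call(rbind, removed) else
    data.frame(i = integer(), j = integer(), k = integer(),
               denominator = numeric(), term = character())
  structure(list(chi = chi, deperturbed = nrow(removed_df) > 0L,
                 removed = removed_df, omega = omega),
            class = "chi_matrix")
}

#' @export
print.chi_matrix <- function(x, ...) {
  cat("<chi_matrix> ", nrow(x$chi), " mode(s)",
      if (x$deperturbed) paste0("; ", nrow(x$removed),
                                " resonant denominator(s) removed"),
      "\n", sep = "")
  print(round(x$chi, 4))
  invisible(x)
}

#' VPT2 level energy relative to the zero-point level
#'
#' \eqn{E(v) - E(0) = \sum_i \omega_i v_i + \sum_{i \le j} \chi_{ij}
#'   [(v_i + 1/2)(v_j + 1/2) - 1/4]}.
#'
#' @param chi a `chi_matrix` from [anharmonic_constants()].
#' @param quanta integer quanta vector (total at most 2) or a [vib_state()].
#' @return Energy in cm^-1.
#' @export
state_energy <- function(chi, quanta) {
  stopifnot(inherits(chi, "chi_matrix"))
  if (inherits(quanta, "vib_state")) quanta <- quanta$quanta
  quanta <- as.integer(quanta)
  nm <- length(chi$omega)
  stopifnot(length(quanta) == nm, all(quanta >= 0))
  if (sum(quanta) > 2L) stop("VPT2 transition manifold covers total quanta <= 2")
  e <- sum(chi$omega * quanta)
  for (i in seq_len(nm)) for (j in i:nm) {
    e <- e + chi$chi[i, j] *
      ((quanta[i] + 0.5) * (quanta[j] + 0.5) - 0.25)
  }
  e
}

# ---------------------------------------------------------------------------
# VPT2 wavefunctions (Rayleigh-Schroedinger coefficients in the HO basis)

# partner states to exclude (deperturb) for a given target state key,
# from the flagged rows of a resonance set
.resonance_partners <- function(resonances, nm) {
  pairs <- list()
  push <- function(ka, kb) pairs[[length(pairs) + 1L]] <<- c(ka, kb)
  skey <- function(v) paste(v, collapse = ",")
  mk1 <- function(i) { v <- integer(nm); v[i] <- 1L; skey(v) }
  mk2 <- function(i, j) { v <- integer(nm); v[i] <- v[i] + 1L; v[j] <- v[j] + 1L; skey(v) }
  if (!is.null(resonances$fermi)) {
    fl <- resonances$fermi[resonances$fermi$flagged, , drop = FALSE]
    for (r in seq_len(nrow(fl))) push(mk1(fl$k[r]), mk2(fl$i[r], fl$j[r]))
  }
  if (!is.null(resonances$dd11)) {
    fl <- resonances$dd11[resonances$dd11$flagged, , drop = FALSE]
    for (r in seq_len(nrow(fl))) push(mk1(fl$i[r]), mk1(fl$j[r]))
  }
  if (!is.null(resonances$dd22)) {
    fl <- resonances$dd22[resonances$dd22$flagged, , drop = FALSE]
    for (r in seq_len(nrow(fl))) push(fl$key_a[r], fl$key_b[r])
  }
  env <- new.env(parent = emptyenv())
  for (p in pairs) {
    env[[p[1L]]] <- c(env[[p[1L]]], p[2L])
    env[[p[2L]]] <- c(env[[p[2L]]], p[1L])
  }
  env
}

#' VPT2 wavefunction coefficients of a target state
#'
#' First- and second-order Rayleigh-Schroedinger coefficients of the target
#' state over the harmonic-oscillator basis, computed with exact ladder
#' matrix elements of the cubic (first-order) and semidiagonal quartic
#' (second-order) potential terms.  Coefficients of states belonging to a
#' flagged resonant pair with the target are set exactly to zero
#' (deperturbation); those interactions are reinstated by the variational
#' step of [gvpt2_solve()].
#'
#' @param ff a [quartic_force_field()].
#' @param quanta integer quanta vector of the target state.
#' @param resonances optional `resonance_set`; flagged partners of the
#'   target are deperturbed.
#' @param singular_action what to do about a near-zero unflagged
#'   denominator: `"error"` (default) or `"inf"` (return an infinite
#'   coefficient; used internally by the intensity-based detection
#'   criterion).
#' @return A `vpt2_wavefunction`: sparse vectors `psi0`, `psi1`, `psi2`
#'   (intermediate normalization, `<psi0|psi> = 1`), the squared norms of
#'   the correction vectors and the full `norm = <psi|psi> >= 1`.
#' @export
vpt2_wavefunction <- function(ff, quanta, resonances = NULL,
                              singular_action = c("error", "inf")) {
  stopifnot(inherits(ff, "quartic_force_field"))
  singular_action <- match.arg(singular_action)
  nm <- ff$modes$n_modes
  omega <- ff$modes$omega
  quanta <- as.integer(quanta)
  stopifnot(length(quanta) == nm)
  terms <- .ff_terms(ff)
  partners_env <- if (!is.null(resonances))
    .resonance_partners(resonances, nm) else new.env(parent = emptyenv())
  nkey <- paste(quanta, collapse = ",")
  excluded <- c(nkey, partners_env[[nkey]])
  En <- sum(omega * quanta)
  psi0 <- .hv(matrix(quanta, 1L), 1)

  project <- function(w) {
    # divide by (En - Es), drop target + deperturbed partners
    if (nrow(w$q) == 0L) return(w)
    keys <- .hv_keys(w)
    keep <- !(keys %in% excluded)
    w$q <- w$q[keep, , drop = FALSE]; w$c <- w$c[keep]
    if (nrow(w$q) == 0L) return(w)
    dE <- En - .hv_energies(w, omega)
    bad <- abs(dE) < 1e-6
    if (any(bad)) {
      if (singular_action == "error")
        stop("degenerate unflagged state ", .hv_keys(w)[which(bad)[1L]],
             " in the perturbative sum for target ", nkey,
             "; review the resonance thresholds")
      dE[bad] <- 0  # gives +-Inf coefficients downstream
    }
    w$c <- w$c / dE
    w
  }

  w1 <- .hv_apply_terms(psi0, terms$cubic)
  psi1 <- project(w1)
  w2 <- .hv_add(.hv_apply_terms(psi1, terms$cubic),
                .hv_apply_terms(psi0, terms$quartic))
  psi2 <- project(w2)
  n1 <- sum(psi1$c^2)
  n2 <- sum(psi2$c^2)
  cross <- .hv_dot(psi1, psi2)
  structure(list(quanta = quanta, key = nkey,
                 psi0 = psi0, psi1 = psi1, psi2 = psi2,
                 norm1 = n1, norm2 = n2,
                 norm = 1 + n1 + 2 * cross + n2,
                 deperturbed_partners = setdiff(excluded, nkey)),
            class = "vpt2_wavefunction")
}

#' @export
print.vpt2_wavefunction <- function(x, ...) {
  cat("<vpt2_wavefunction> target (", x$key, "): ",
      nrow(x$psi1$q), " first-order and ", nrow(x$psi2$q),
      " second-order coefficients; <psi|psi> = ",
      format(x$norm, digits = 8), "\n", sep = "")
  invisible(x)
}

# coefficient of basis state `key` in a sparse vector
.hv_coef <- function(v, key) {
  keys <- .hv_keys(v)
  m <- match(key, keys)
  if (is.na(m)) 0 else v$c[m]
}

# ---------------------------------------------------------------------------
# Darling-Dennison couplings and detection (criteria 6a-6c)

#' Darling-Dennison coupling constant
#'
#' Off-diagonal matrix element of the second-order contact-transformed
#' Hamiltonian between two near-degenerate states (two fundamentals for a
#' 1-1 resonance; two-quanta states for a 2-2 resonance):
#' \deqn{K_{ab} = \langle a|V_4|b\rangle + \tfrac12 \sum_c
#'   \langle a|V_3|c\rangle\langle c|V_3|b\rangle
#'   \left[\frac{1}{E_a - E_c} + \frac{1}{E_b - E_c}\right]}
#' evaluated with exact harmonic-oscillator ladder elements (the sums are
#' finite).  Intermediate states listed in `exclude` -- typically states that
#' are themselves in a flagged resonance with `a` or `b`, hence members of
#' the same variational block -- are omitted.
#'
#' @param ff a [quartic_force_field()].
#' @param quanta_a,quanta_b integer quanta vectors of the two states.
#' @param exclude character vector of basis-state keys (comma-separated
#'   quanta) to omit from the intermediate sum.
#' @return Coupling constant in cm^-1 (symmetric in the two states).
#' @export
dd_coupling <- function(ff, quanta_a, quanta_b, exclude = character()) {
  stopifnot(inherits(ff, "quartic_force_field"))
  omega <- ff$modes$omega
  qa <- as.integer(quanta_a); qb <- as.integer(quanta_b)
  ka <- paste(qa, collapse = ","); kb <- paste(qb, collapse = ",")
  if (identical(ka, kb)) stop("states must differ")
  terms <- .ff_terms(ff)
  va <- .hv(matrix(qa, 1L), 1)
  vb <- .hv(matrix(qb, 1L), 1)
  direct <- .hv_coef(.hv_apply_terms(vb, terms$quartic), ka)
  wa <- .hv_apply_terms(va, terms$cubic)
  wb <- .hv_apply_terms(vb, terms$cubic)
  Ea <- sum(omega * qa); Eb <- sum(omega * qb)
  keys_a <- .hv_keys(wa)
  keys_b <- .hv_keys(wb)
  common <- setdiff(intersect(keys_a, keys_b), c(ka, kb, exclude))
  second <- 0
  for (k in common) {
    Ec <- sum(omega * .key_idx(k))
    da <- Ea - Ec; db <- Eb - Ec
    if (abs(da) < 1e-6 || abs(db) < 1e-6)
      stop("intermediate state ", k, " is degenerate with a resonant pair ",
           "member; exclude it or review the thresholds")
    second <- second + 0.5 * wa$c[match(k, keys_a)] * wb$c[match(k, keys_b)] *
      (1 / da + 1 / db)
  }
  direct + second
}

#' Detect Darling-Dennison resonances
#'
#' 1-1 resonances between fundamentals are flagged when the frequency gap is
#' within `gate`, the contact-transformed coupling reaches `min_coupling`,
#' and the intensity-oriented criterion on the second-order wavefunction
#' coefficients `max(c2_ij, c2_ji) >= c6c` holds; 2-2 resonances between
#' two-quanta states use the first two criteria only.
#'
#' @param ff a [quartic_force_field()].
#' @param fermi a `resonance_set` from [detect_fermi()]; flagged Fermi
#'   partners are deperturbed from the wavefunctions entering the
#'   coefficient criterion and excluded from coupling intermediates.
#' @param gate proximity gate (cm^-1, default 200).
#' @param min_coupling coupling threshold (cm^-1, default 10).
#' @param c6c wavefunction-coefficient threshold (default 0.03).
#' @return A `resonance_set` with `fermi` (carried over), `dd11` and `dd22`
#'   candidate tables including all criterion values.
#' @export
detect_dd <- function(ff, fermi = NULL, gate = 200, min_coupling = 10,
                      c6c = 0.03) {
  stopifnot(inherits(ff, "quartic_force_field"))
  omega <- ff$modes$omega
  nm <- length(omega)
  if (is.null(fermi)) fermi <- detect_fermi(ff)
  partners_env <- .resonance_partners(fermi, nm)
  skey <- function(v) paste(v, collapse = ",")

  # second-order coefficient of fundamental j inside the wavefunction of
  # fundamental i (Fermi-deperturbed)
  c2_of <- function(i, j) {
    qi <- integer(nm); qi[i] <- 1L
    qj <- integer(nm); qj[j] <- 1L
    wf <- vpt2_wavefunction(ff, qi, resonances = fermi,
                            singular_action = "inf")
    abs(.hv_coef(wf$psi2, skey(qj)))
  }

  rows11 <- list()
  if (nm >= 2L) for (i in seq_len(nm - 1L)) for (j in (i + 1L):nm) {
    gap <- abs(omega[i] - omega[j])
    qi <- integer(nm); qi[i] <- 1L
    qj <- integer(nm); qj[j] <- 1L
    excl <- unique(c(partners_env[[skey(qi)]], partners_env[[skey(qj)]]))
    K <- dd_coupling(ff, qi, qj, exclude = excl)
    c2m <- max(c2_of(i, j), c2_of(j, i))
    p6a <- gap <= gate; p6b <- abs(K) >= min_coupling; p6c <- c2m >= c6c
    rows11[[length(rows11) + 1L]] <- data.frame(
      i = i, j = j, gap = gap, coupling = K, c2max = c2m,
      pass_6a = p6a, pass_6b = p6b, pass_6c = p6c,
      flagged = p6a && p6b && p6c)
  }
  dd11 <- if (length(rows11)) do.call(rbind, rows11) else
    data.frame(i = integer(), j = integer(), gap = numeric(),
               coupling = numeric(), c2max = numeric(), pass_6a = logical(),
               pass_6b = logical(), pass_6c = logical(), flagged = logical())

  # 2-2: all pairs of distinct two-quanta states (overtones + combinations)
  st <- .states_leq2(nm)
  two <- which(vapply(st$quanta, sum, 0L) == 2L)
  rows22 <- list()
  if (length(two) >= 2L) {
    for (ai in seq_along(two)[-length(two)]) for (bi in (ai + 1L):length(two)) {
      qa <- st$quanta[[two[ai]]]; qb <- st$quanta[[two[bi]]]
      gap <- abs(sum(omega * qa) - sum(omega * qb))
      excl <- unique(c(partners_env[[skey(qa)]], partners_env[[skey(qb)]]))
      K <- dd_coupling(ff, qa, qb, exclude = excl)
      p6a <- gap <= gate; p6b <- abs(K) >= min_coupling
      rows22[[length(rows22) + 1L]] <- data.frame(
        key_a = skey(qa), key_b = skey(qb), gap = gap, coupling = K,
        pass_6a = p6a, pass_6b = p6b, flagged = p6a && p6b)
    }
  }
  dd22 <- if (length(rows22)) do.call(rbind, rows22) else
    data.frame(key_a = character(), key_b = character(), gap = numeric(),
               coupling = numeric(), pass_6a = logical(), pass_6b = logical(),
               flagged = logical())

  structure(list(fermi = fermi$fermi, dd11 = dd11, dd22 = dd22,
                 thresholds = c(fermi$thresholds,
                                list(dd_gate = gate,
                                     dd_min_coupling = min_coupling,
                                     dd_c6c = c6c))),
            class = "resonance_set")
}

# ---------------------------------------------------------------------------
# GVPT2: deperturbed energies + variational blocks

# Fermi first-order coupling: <1i 1j|V3|1k> = f/(2 sqrt 2), <2i|V3|1k> = f/4
.fermi_W <- function(f, i, j) if (i == j) f / 4 else f / (2 * sqrt(2))

#' Generalized VPT2 solution
#'
#' Computes deperturbed VPT2 energies for all states with total quanta <= 2,
#' groups flagged resonant interactions into connected blocks (transitive
#' closure, so chained resonances form polyads), and diagonalizes each
#' block's symmetric matrix -- deperturbed energies on the diagonal, cubic
#' Fermi couplings and Darling-Dennison contact couplings off the diagonal.
#' Non-resonant states keep their plain VPT2 energies.  Block eigenvectors
#' are retained for the intensity mixing of [vpt2_transitions()].
#'
#' @param system a [model_system()] (or a bare [quartic_force_field()]).
#' @param resonances optional precomputed `resonance_set` (from
#'   [detect_dd()]); computed at default thresholds when missing.
#' @param block_cap largest admissible block size (default 30); a larger
#'   connected block is an error advising threshold tightening.
#' @param ... thresholds forwarded to [detect_fermi()] and [detect_dd()].
#' @return A `gvpt2_result`: per-state table (`states`), the `chi_matrix`,
#'   the `resonance_set` and the list of variational `blocks` (members,
#'   matrix, eigenvalues, eigenvectors).
#' @export
gvpt2_solve <- function(system, resonances = NULL, block_cap = 30L, ...) {
  ff <- if (inherits(system, "model_system")) system$force_field else system
  coriolis <- if (inherits(system, "model_system")) system$coriolis else NULL
  stopifnot(inherits(ff, "quartic_force_field"))
  nm <- ff$modes$n_modes
  if (is.null(resonances)) {
    dots <- list(...)
    fermi_args <- dots[names(dots) %in% c("gate", "c5b", "c5c", "use_5c",
                                          "delta_rule")]
    resonances <- do.call(detect_fermi, c(list(ff), fermi_args))
    resonances <- detect_dd(ff, fermi = resonances)
  }
  chi <- anharmonic_constants(ff, coriolis = coriolis, resonances = resonances)
  st <- .states_leq2(nm)
  ns <- length(st$keys)
  evpt2 <- vapply(st$quanta, function(q) state_energy(chi, q), 0)

  # resonance graph over state indices
  adj <- vector("list", ns)
  names(adj) <- st$keys
  edges <- list()
  add_edge <- function(ka, kb, w) {
    edges[[length(edges) + 1L]] <<- list(a = ka, b = kb, w = w)
    adj[[ka]] <<- c(adj[[ka]], kb)
    adj[[kb]] <<- c(adj[[kb]], ka)
  }
  skey <- function(v) paste(v, collapse = ",")
  if (!is.null(resonances$fermi)) {
    fl <- resonances$fermi[resonances$fermi$flagged, , drop = FALSE]
    for (r in seq_len(nrow(fl))) {
      qk <- integer(nm); qk[fl$k[r]] <- 1L
      qij <- integer(nm); qij[fl$i[r]] <- qij[fl$i[r]] + 1L
      qij[fl$j[r]] <- qij[fl$j[r]] + 1L
      add_edge(skey(qk), skey(qij), .fermi_W(fl$f[r], fl$i[r], fl$j[r]))
    }
  }
  if (!is.null(resonances$dd11)) {
    fl <- resonances$dd11[resonances$dd11$flagged, , drop = FALSE]
    for (r in seq_len(nrow(fl))) {
      qi <- integer(nm); qi[fl$i[r]] <- 1L
      qj <- integer(nm); qj[fl$j[r]] <- 1L
      add_edge(skey(qi), skey(qj), fl$coupling[r])
    }
  }
  if (!is.null(resonances$dd22)) {
    fl <- resonances$dd22[resonances$dd22$flagged, , drop = FALSE]
    for (r in seq_len(nrow(fl)))
      add_edge(fl$key_a[r], fl$key_b[r], fl$coupling[r])
  }

  # connected components over states that appear in any edge
  block_id <- stats::setNames(rep(NA_integer_, ns), st$keys)
  nb <- 0L
  for (k in st$keys) {
    if (!is.na(block_id[[k]]) || is.null(adj[[k]])) next
    nb <- nb + 1L
    queue <- k
    while (length(queue)) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      if (!is.na(block_id[[cur]])) next
      block_id[[cur]] <- nb
      queue <- c(queue, setdiff(adj[[cur]], names(which(!is.na(block_id)))))
    }
  }

  blocks <- vector("list", nb)
  e_gvpt2 <- evpt2
  state_block <- rep(NA_integer_, ns)
  for (b in seq_len(nb)) {
    members <- names(which(block_id == b))
    if (length(members) > block_cap)
      stop("resonant block of ", length(members), " states exceeds the cap (",
           block_cap, "); tighten the detection thresholds")
    mi <- match(members, st$keys)
    W <- diag(evpt2[mi], length(members))
    dimnames(W) <- list(members, members)
    for (e in edges) {
      if (e$a %in% members && e$b %in% members)
        W[e$a, e$b] <- W[e$b, e$a] <- e$w
    }
    es <- eigen((W + t(W)) / 2, symmetric = TRUE)
    ord <- order(es$values)
    blocks[[b]] <- list(members = members, matrix = W,
                        eigenvalues = es$values[ord],
                        eigenvectors = es$vectors[, ord, drop = FALSE])
    # assign each member the eigenvalue of the eigenvector it dominates
    U <- blocks[[b]]$eigenvectors
    taken <- rep(FALSE, length(members))
    for (m in seq_along(members)) {
      wts <- U[m, ]^2; wts[taken] <- -1
      pick <- which.max(wts)
      taken[pick] <- TRUE
      e_gvpt2[mi[m]] <- blocks[[b]]$eigenvalues[pick]
    }
    state_block[mi] <- b
  }

  states <- data.frame(
    key = st$keys, label = st$labels,
    total_quanta = vapply(st$quanta, sum, 0L),
    energy_vpt2 = evpt2, energy = e_gvpt2, block = state_block,
    stringsAsFactors = FALSE)
  structure(list(states = states, chi = chi, resonances = resonances,
                 blocks = blocks, ff = ff, quanta = st$quanta),
            class = "gvpt2_result")
}

#' @export
print.gvpt2_result <- function(x, ...) {
  cat("<gvpt2_result> ", nrow(x$states), " states, ",
      length(x$blocks), " variational block(s)\n", sep = "")
  print(utils::head(x$states[order(x$states$energy), ], 10L))
  invisible(x)
}
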