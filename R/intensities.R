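# Transition moments with the eleven-term decomposition, and conversion to
# IR / VCD / Raman / ROA observables.
#
# A property operator is expanded to derivative order 3 in the reduced
# coordinates (momentum-expanded for the magnetic-type tensors); the VPT2
# transition moment between target states is assembled term by term from
# exact harmonic-oscillator matrix elements of the monomials, using the
# wavefunction orders psi0/psi1/psi2.  The reported moment is the
# through-second-order sum of the eleven terms (term 11 carries the
# second-order piece of the normalization); the full nonlinear
# normalization ratio is kept alongside as a diagnostic.

# operator split by derivative order:
#   X0 = value0 + sum_i d1_i q_i            (conjugate: sum_i d1_i P_i)
#   X1 = 1/2 sum_ij d2_ij q_i q_j           (conjugate: sum_ij d2_ij P_i q_j)
#   X2 = 1/6 sum_ijk d3_ijk q_i q_j q_k     (conjugate: 1/2 sum d3 P_i q_j q_k)
# Same-mode P q products are symmetrized, (Pq + qP)/2.

# -- monomial bookkeeping ----------------------------------------------------

.mono_list <- function(surface, order_cap) {
  nm <- surface$n_modes
  conj <- surface$conjugate
  monos <- list()
  add <- function(key, apply_fun, nP) monos[[key]] <<- list(f = apply_fun, nP = nP)
  if (!conj) {
    add("1", function(v) v, 0L)
    for (i in seq_len(nm)) {
      local({ ii <- i
        add(paste0("q:", ii), function(v) .hv_apply1(v, ii, "q"), 0L) })
    }
    if (order_cap >= 2L) for (i in seq_len(nm)) for (j in i:nm) {
      local({ ii <- i; jj <- j
        add(paste0("qq:", ii, ",", jj),
            function(v) .hv_apply1(.hv_apply1(v, jj, "q"), ii, "q"), 0L) })
    }
    if (order_cap >= 3L) for (key in names(surface$d3)) {
      idx <- .key_idx(key)
      local({ i1 <- idx[1]; i2 <- idx[2]; i3 <- idx[3]
        add(paste0("qqq:", key), function(v)
          .hv_apply1(.hv_apply1(.hv_apply1(v, i3, "q"), i2, "q"), i1, "q"), 0L) })
    }
  } else {
    for (i in seq_len(nm)) {
      local({ ii <- i
        add(paste0("P:", ii), function(v) .hv_apply1(v, ii, "P"), 1L) })
    }
    if (order_cap >= 2L) for (i in seq_len(nm)) for (j in seq_len(nm)) {
      local({ ii <- i; jj <- j
        add(paste0("Pq:", ii, ",", jj),
            function(v) .hv_apply_Pq(v, ii, jj), 1L) })
    }
    if (order_cap >= 3L) for (key in names(surface$d3)) {
      for (p in .all_perms3(.key_idx(key))) {
        qs <- sort(p[2:3])
        mkey <- paste0("Pqq:", p[1], ",", qs[1], ",", qs[2])
        if (!is.null(monos[[mkey]])) next
        local({ ii <- p[1]; q1 <- qs[1]; q2 <- qs[2]
          add(mkey, function(v) .hv_apply_Pq(v, ii, c(q1, q2)), 1L) })
      }
    }
  }
  monos
}

# <bra| mono |ket> for every mono; the operator is applied to the smaller
# support side (q-monomials are symmetric, each P factor flips sign under
# transposition)
.mono_values <- function(monos, bra, ket) {
  vals <- numeric(length(monos))
  names(vals) <- names(monos)
  nb <- nrow(bra$q); nk <- nrow(ket$q)
  if (nb == 0L || nk == 0L) return(vals)
  for (key in names(monos)) {
    m <- monos[[key]]
    if (nk <= nb) {
      vals[[key]] <- .hv_dot(bra, m$f(ket))
    } else {
      vals[[key]] <- (-1)^m$nP * .hv_dot(ket, m$f(bra))
    }
  }
  vals
}

# contract monomial values with the surface coefficients at one derivative
# order; returns the n_comp component vector
.contract_order <- function(surface, order, vals, order_cap) {
  nc <- surface$n_comp
  nm <- surface$n_modes
  conj <- surface$conjugate
  out <- numeric(nc)
  if (order == 0L) {
    if (!conj) {
      out <- out + surface$value0 * vals[["1"]]
      for (i in seq_len(nm)) out <- out + surface$d1[, i] * vals[[paste0("q:", i)]]
    } else {
      for (i in seq_len(nm)) out <- out + surface$d1[, i] * vals[[paste0("P:", i)]]
    }
  } else if (order == 1L) {
    if (order_cap < 2L) return(out)
    if (!conj) {
      for (i in seq_len(nm)) for (j in i:nm) {
        w <- if (i == j) 0.5 else 1
        out <- out + w * surface$d2[, i, j] * vals[[paste0("qq:", i, ",", j)]]
      }
    } else {
      for (i in seq_len(nm)) for (j in seq_len(nm)) {
        out <- out + surface$d2[, i, j] * vals[[paste0("Pq:", i, ",", j)]]
      }
    }
  } else if (order == 2L) {
    if (order_cap < 3L) return(out)
    for (key in names(surface$d3)) {
      val <- surface$d3[[key]]
      idx <- .key_idx(key)
      if (!conj) {
        out <- out + val * (.perm_mult(idx) / 6) * vals[[paste0("qqq:", key)]]
      } else {
        for (p in .all_perms3(idx)) {
          qs <- sort(p[2:3])
          out <- out + 0.5 * val * vals[[paste0("Pqq:", p[1], ",", qs[1], ",", qs[2])]]
        }
      }
    }
  }
  out
}

.term_names <- paste0("term", 1:11)

#' VPT2 transition moment with eleven-term decomposition
#'
#' Assembles the transition moment of a property surface between two VPT2
#' wavefunctions, split into the eleven contributions that classify how
#' mechanical (wavefunction) and electrical (property-derivative)
#' anharmonicity mix: term 1 is the harmonic-oscillator moment; terms 3, 4,
#' 6, 7, 10 and 11 carry the harmonic property through anharmonic
#' wavefunctions; terms 2 and 5 are pure electrical anharmonicity (second
#' and third derivatives); terms 8 and 9 are mixed.  Term 11 is the
#' second-order normalization correction
#' \eqn{-\tfrac12\langle F^{(0)}|X^{(0)}|I^{(0)}\rangle
#'  (\langle F^{(1)}|F^{(1)}\rangle + \langle I^{(1)}|I^{(1)}\rangle)}.
#'
#' The reported `moment` is the sum of the eleven terms -- the consistent
#' through-second-order expansion of the normalized moment.  The full
#' nonlinear ratio (complete numerator over the exact normalization) is
#' returned as `full_ratio`, with the residual against the term sum as a
#' truncation diagnostic.
#'
#' For momentum-expanded tensors the returned components are the real
#' factors `M` of the physical moment `i*M`.
#'
#' @param surface a [property_surface()].
#' @param wf_I,wf_F [vpt2_wavefunction()]s of the initial and final states.
#' @param order_cap highest property-derivative order included: 1 (harmonic
#'   property), 2 (+second derivatives) or 3 (+semidiagonal third
#'   derivatives).
#' @return A `term_decomposition`: `moment` (n_comp vector), `terms`
#'   (11 x n_comp matrix), `full_ratio`, `residual`.
#' @export
transition_moment <- function(surface, wf_I, wf_F, order_cap = 3L) {
  stopifnot(inherits(surface, "property_surface"),
            inherits(wf_I, "vpt2_wavefunction"),
            inherits(wf_F, "vpt2_wavefunction"))
  order_cap <- as.integer(order_cap)
  stopifnot(order_cap %in% 1:3)
  monos <- .mono_list(surface, order_cap)
  partsI <- list(wf_I$psi0, wf_I$psi1, wf_I$psi2)
  partsF <- list(wf_F$psi0, wf_F$psi1, wf_F$psi2)
  # monomial values per (bra order a, ket order c)
  V <- vector("list", 9L)
  dim(V) <- c(3L, 3L)
  for (a in 0:2) for (c in 0:2) {
    V[[a + 1L, c + 1L]] <- .mono_values(monos, partsF[[a + 1L]], partsI[[c + 1L]])
  }
  X <- function(b, a, c) .contract_order(surface, b, V[[a + 1L, c + 1L]], order_cap)
  nc <- surface$n_comp
  terms <- matrix(0, 11L, nc, dimnames = list(.term_names, NULL))
  terms[1, ]  <- X(0L, 0L, 0L)
  terms[2, ]  <- X(1L, 0L, 0L)
  terms[3, ]  <- X(0L, 1L, 0L)
  terms[4, ]  <- X(0L, 0L, 1L)
  terms[5, ]  <- X(2L, 0L, 0L)
  terms[6, ]  <- X(0L, 2L, 0L)
  terms[7, ]  <- X(0L, 0L, 2L)
  terms[8, ]  <- X(1L, 1L, 0L)
  terms[9, ]  <- X(1L, 0L, 1L)
  terms[10, ] <- X(0L, 1L, 1L)
  terms[11, ] <- -0.5 * terms[1, ] * (wf_F$norm1 + wf_I$norm1)
  moment <- colSums(terms)
  # full nonlinear ratio: every (a, b, c) product over the exact norms
  num <- numeric(nc)
  for (a in 0:2) for (c in 0:2) for (b in 0:2) {
    num <- num + X(b, a, c)
  }
  full_ratio <- num / sqrt(wf_F$norm * wf_I$norm)
  structure(list(moment = moment, terms = terms, full_ratio = full_ratio,
                 residual = full_ratio - moment,
                 surface = surface$name, order_cap = order_cap),
            class = "term_decomposition")
}

#' @export
print.term_decomposition <- function(x, ...) {
  cat("<term_decomposition> ", x$surface, " (order cap ", x$order_cap,
      ")\n  |moment| = ", format(sqrt(sum(x$moment^2)), digits = 6),
      ", max |full-ratio residual| = ",
      format(max(abs(x$residual)), digits = 3), "\n", sep = "")
  invisible(x)
}

# -- observables -------------------------------------------------------------

#' IR and VCD observables from dipole moments
#'
#' Dipole strength `D = |<mu>|^2`, rotational strength `R = <mu> . M` (where
#' the magnetic transition moment is `i*M` under the package's phase
#' convention, making `R` real), the dimensionless dissymmetry factor
#' `g = 4R/D`, and stick intensities proportional to `nu*D` (absorption)
#' and `nu*R` (VCD).
#'
#' @param mu_moment electric-dipole transition moment (length-3, a.u.).
#' @param m_moment magnetic-dipole transition moment factor `M` (length-3),
#'   or `NULL` when the surface is unavailable.
#' @param energy transition wavenumber (cm^-1).
#' @param include_freq_factor multiply sticks by the transition wavenumber
#'   (the absorption-coefficient convention); default `TRUE`.
#' @return A list with `D`, `R`, `g`, `ir_stick`, `vcd_stick` (`NA` for
#'   observables whose tensors are unavailable).
#' @export
ir_vcd_observables <- function(mu_moment, m_moment, energy,
                               include_freq_factor = TRUE) {
  fac <- if (include_freq_factor) energy else 1
  D <- if (is.null(mu_moment)) NA_real_ else sum(mu_moment^2)
  R <- if (is.null(mu_moment) || is.null(m_moment)) NA_real_ else
    sum(mu_moment * m_moment)
  g <- if (is.na(D) || is.na(R) || D == 0) NA_real_ else 4 * R / D
  list(D = D, R = R, g = g,
       ir_stick = if (is.na(D)) NA_real_ else fac * D,
       vcd_stick = if (is.na(R)) NA_real_ else fac * R)
}

.levi_civita <- local({
  e <- array(0, c(3, 3, 3))
  e[1, 2, 3] <- e[2, 3, 1] <- e[3, 1, 2] <- 1
  e[3, 2, 1] <- e[1, 3, 2] <- e[2, 1, 3] <- -1
  e
})

#' Raman and ROA observables from polarizability moments
#'
#' Far-from-resonance SCP backscattering invariants and stick intensities:
#' isotropic `a^2` and anisotropic `beta(alpha)^2` from the transition
#' polarizability, the chiral cross invariants `aG'`, `beta(G')^2` and
#' `beta(A)^2`, the backscattered Raman stick `4(45a^2 + 7 beta(alpha)^2)`,
#' the ROA stick `(96/c)(beta(G')^2 + beta(A)^2/3)` and their ratio, the
#' circular intensity difference.  The overall scale is arbitrary
#' (instrument-specific); ratios and relative intensities are the
#' contract-bearing output.  A `((nu0 - nu)/nu0)^4` scattered-frequency
#' factor is applied to both sticks by default (it cancels in the CID);
#' thermal populations are not applied (0 K sticks).
#'
#' @param alpha_moment transition polarizability (length-9, a.u.,
#'   column-major 3x3).
#' @param G_moment G' transition moment factor (length-9), or `NULL`.
#' @param A_moment A-tensor transition moment (length-27), or `NULL`.
#' @param energy transition wavenumber (cm^-1).
#' @param excitation_nm excitation wavelength (default 532 nm).
#' @param include_nu4 apply the scattered-frequency factor (default `TRUE`).
#' @return A list with the five invariants, `raman_stick`, `roa_stick`,
#'   `cid`.
#' @export
raman_roa_observables <- function(alpha_moment, G_moment, A_moment, energy,
                                  excitation_nm = 532, include_nu4 = TRUE) {
  if (is.null(alpha_moment))
    return(list(a2 = NA_real_, beta_alpha2 = NA_real_, aG = NA_real_,
                beta_G2 = NA_real_, beta_A2 = NA_real_,
                raman_stick = NA_real_, roa_stick = NA_real_, cid = NA_real_))
  al <- matrix(alpha_moment, 3, 3)
  tr_a <- sum(diag(al))
  a2 <- (tr_a / 3)^2
  beta_alpha2 <- 0.5 * (3 * sum(al * al) - tr_a^2)
  nu0 <- 1e7 / excitation_nm
  nu4 <- if (include_nu4) ((nu0 - energy) / nu0)^4 else 1
  raman <- nu4 * 4 * (45 * a2 + 7 * beta_alpha2)
  aG <- beta_G2 <- beta_A2 <- NA_real_
  roa <- cid <- NA_real_
  if (!is.null(G_moment) && !is.null(A_moment)) {
    G <- matrix(G_moment, 3, 3)
    tr_G <- sum(diag(G))
    aG <- tr_a * tr_G / 9
    beta_G2 <- 0.5 * (3 * sum(al * G) - tr_a * tr_G)
    A <- array(A_moment, c(3, 3, 3))
    omega_au <- .const$nm_to_omega_au / excitation_nm
    s <- 0
    for (a in 1:3) for (b in 1:3) for (cc in 1:3) for (d in 1:3) {
      if (.levi_civita[a, cc, d] != 0)
        s <- s + al[a, b] * .levi_civita[a, cc, d] * A[cc, d, b]
    }
    beta_A2 <- 0.5 * omega_au * s
    roa <- nu4 * (96 / .const$c_au) * (beta_G2 + beta_A2 / 3)
    cid <- if (raman != 0) roa / raman else NA_real_
  }
  list(a2 = a2, beta_alpha2 = beta_alpha2, aG = aG,
       beta_G2 = beta_G2, beta_A2 = beta_A2,
       raman_stick = raman, roa_stick = roa, cid = cid)
}

# -- full transition table ---------------------------------------------------

#' All GVPT2 transitions from the ground state
#'
#' Computes VPT2 wavefunctions (deperturbed where resonances are flagged)
#' for the ground state and every state with one or two quanta, assembles
#' per-surface transition moments with their eleven-term decompositions,
#' rotates the moments of block members by the variational eigenvectors
#' ("intensities introduced back through the variational step"), and
#' derives the spectroscopic observables for each final (eigen)state.
#'
#' @param system a [model_system()] with at least one property surface.
#' @param gvpt2 optional precomputed [gvpt2_solve()] result.
#' @param order_cap property-derivative orders included (1, 2 or 3).
#' @param excitation_nm Raman/ROA excitation wavelength (nm).
#' @param include_freq_factor,include_nu4 stick-intensity conventions, see
#'   [ir_vcd_observables()] and [raman_roa_observables()].
#' @param ... forwarded to [gvpt2_solve()] when `gvpt2` is missing.
#' @return A `transition_set`: `table` (one row per transition: energy,
#'   kind, label, D, R, g, Raman/ROA invariants and sticks, CID, leading
#'   weight), `moments` and `decompositions` keyed by state, and the
#'   underlying `gvpt2` result.
#' @export
vpt2_transitions <- function(system, gvpt2 = NULL, order_cap = 3L,
                             excitation_nm = 532,
                             include_freq_factor = TRUE, include_nu4 = TRUE,
                             ...) {
  stopifnot(inherits(system, "model_system"))
  if (is.null(gvpt2)) gvpt2 <- gvpt2_solve(system, ...)
  ff <- gvpt2$ff
  nm <- ff$modes$n_modes
  st_keys <- gvpt2$states$key
  quanta <- gvpt2$quanta
  res <- gvpt2$resonances
  wfs <- lapply(quanta, function(q)
    vpt2_wavefunction(ff, q, resonances = res))
  names(wfs) <- st_keys
  wf0 <- wfs[[1L]]
  surfaces <- system$surfaces

  # deperturbed-state moments and decompositions
  decomp <- list()
  moments <- list()
  for (k in st_keys[-1L]) {
    decomp[[k]] <- lapply(surfaces, function(s)
      transition_moment(s, wf0, wfs[[k]], order_cap = order_cap))
    moments[[k]] <- lapply(decomp[[k]], function(d) d$moment)
  }

  # variational mixing: eigenstate moments are eigenvector combinations of
  # the deperturbed member moments
  final_keys <- st_keys[-1L]
  energy <- gvpt2$states$energy[-1L]
  names(energy) <- final_keys
  leading_weight <- stats::setNames(rep(1, length(final_keys)), final_keys)
  leading_label <- stats::setNames(gvpt2$states$label[-1L], final_keys)
  mixed_moments <- moments
  mixing <- list()
  for (b in gvpt2$blocks) {
    U <- b$eigenvectors
    members <- b$members
    # one eigenstate per member, greedily by dominant weight -- the same
    # rule gvpt2_solve() uses to report per-state energies
    taken <- rep(FALSE, length(members))
    for (m in seq_along(members)) {
      wts <- U[m, ]^2; wts[taken] <- -1
      pick <- which.max(wts)
      taken[pick] <- TRUE
      mix <- lapply(names(surfaces), function(sn) {
        acc <- 0
        for (jm in seq_along(members))
          acc <- acc + U[jm, pick] * moments[[members[jm]]][[sn]]
        acc
      })
      names(mix) <- names(surfaces)
      mixed_moments[[members[m]]] <- mix
      energy[[members[m]]] <- b$eigenvalues[pick]
      leading_weight[[members[m]]] <- max(U[, pick]^2)
      leading_label[[members[m]]] <-
        gvpt2$states$label[match(members[which.max(U[, pick]^2)], st_keys)]
      mixing[[members[m]]] <- stats::setNames(U[, pick]^2, members)
    }
  }

  rows <- lapply(final_keys, function(k) {
    mm <- mixed_moments[[k]]
    e <- energy[[k]]
    irvcd <- ir_vcd_observables(mm$mu, mm$m, e,
                                include_freq_factor = include_freq_factor)
    rro <- raman_roa_observables(mm$alpha, mm$Gprime, mm$Aquad, e,
                                 excitation_nm = excitation_nm,
                                 include_nu4 = include_nu4)
    q <- quanta[[match(k, st_keys)]]
    kind <- c("fundamental", "overtone_or_combination")[1 + (sum(q) == 2)]
    if (sum(q) == 2) kind <- if (max(q) == 2) "overtone" else "combination"
    data.frame(key = k, label = .state_label(q), kind = kind, energy = e,
               D = irvcd$D, R = irvcd$R, g = irvcd$g,
               ir_stick = irvcd$ir_stick, vcd_stick = irvcd$vcd_stick,
               a2 = rro$a2, beta_alpha2 = rro$beta_alpha2, aG = rro$aG,
               beta_G2 = rro$beta_G2, beta_A2 = rro$beta_A2,
               raman_stick = rro$raman_stick, roa_stick = rro$roa_stick,
               cid = rro$cid,
               leading_weight = leading_weight[[k]],
               leading_label = leading_label[[k]],
               block = gvpt2$states$block[match(k, st_keys)],
               stringsAsFactors = FALSE)
  })
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  structure(list(table = table, moments = mixed_moments,
                 decompositions = decomp, mixing = mixing, gvpt2 = gvpt2,
                 order_cap = order_cap),
            class = "transition_set")
}

#' @export
print.transition_set <- function(x, ...) {
  cat("<transition_set> ", nrow(x$table), " transitions (derivative order cap ",
      x$order_cap, ")\n", sep = "")
  cols <- c("label", "kind", "energy", "D", "R", "raman_stick", "roa_stick")
  print(utils::head(x$table[order(-abs(x$table$ir_stick)), cols], 8L))
  invisible(x)
}

#' Label transitions by their leading configuration
#'
#' An eigenstate is assigned to its leading zeroth-order configuration
#' (fundamental `F_i`, overtone `O_i`, combination `C_i,j`) when the squared
#' eigenvector weight of that configuration exceeds the threshold; otherwise
#' it is labeled `"mixed"` with the top contributors listed.
#'
#' @param transitions a [vpt2_transitions()] result.
#' @param threshold leading-weight threshold (default 0.80).
#' @return The `transition_set` with an `assignment` column added.
#' @export
assign_bands <- function(transitions, threshold = 0.80) {
  stopifnot(inherits(transitions, "transition_set"))
  tab <- transitions$table
  gv <- transitions$gvpt2
  assignment <- character(nrow(tab))
  for (r in seq_len(nrow(tab))) {
    if (tab$leading_weight[r] > threshold) {
      assignment[r] <- tab$leading_label[r]
    } else {
      wts <- transitions$mixing[[tab$key[r]]]
      ord <- order(-wts)
      top <- paste0(
        vapply(names(wts)[ord[1:2]], function(k)
          gv$states$label[match(k, gv$states$key)], ""),
        "(", round(100 * wts[ord[1:2]]), "%)", collapse = "+")
      assignment[r] <- paste0("mixed:", top)
    }
  }
  transitions$table$assignment <- assignment
  transitions
}
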