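# Brute-force variational solver in a harmonic-oscillator product basis.
#
# This module is the package's independent reference: it shares no matrix
# element code with the VPT2 engine.  One-dimensional q and P matrices are
# built as explicit tridiagonal matrices and raised to powers by matrix
# multiplication; the Hamiltonian is assembled from them over a
# total-quanta-truncated product basis and diagonalized exactly.

# 1-D matrices <n'|q^p|n> and <n'|P^p|n> on 0..nmax, via matrix powers of the
# tridiagonal ladder representations (q = (a + a^dag)/sqrt2, P = (a^dag - a)/sqrt2)
.ho_1d_matrices <- function(nmax, max_pow = 4L) {
  n <- 0:(nmax - 1L)
  Q <- matrix(0, nmax + 1L, nmax + 1L)
  Q[cbind(n + 2L, n + 1L)] <- sqrt((n + 1) / 2)  # raising part
  Q[cbind(n + 1L, n + 2L)] <- sqrt((n + 1) / 2)  # lowering part
  P <- matrix(0, nmax + 1L, nmax + 1L)
  P[cbind(n + 2L, n + 1L)] <- sqrt((n + 1) / 2)
  P[cbind(n + 1L, n + 2L)] <- -sqrt((n + 1) / 2)
  pows <- vector("list", max_pow)
  pows[[1L]] <- Q
  for (p in 2:max_pow) pows[[p]] <- pows[[p - 1L]] %*% Q
  list(Q = pows, P = P)
}

# basis of quanta vectors with total quanta <= cap
.oracle_basis <- function(n_modes, cap) {
  grids <- rep(list(0:cap), n_modes)
  b <- as.matrix(expand.grid(grids))
  b <- b[rowSums(b) <= cap, , drop = FALSE]
  dimnames(b) <- NULL
  # stable order: by total quanta, then lexicographic
  b[order(rowSums(b), apply(b, 1L, paste, collapse = ",")), , drop = FALSE]
}

#' Variational reference solution for a quartic force field
#'
#' Diagonalizes the vibrational Hamiltonian of the quartic potential exactly
#' within a harmonic-oscillator product basis truncated at a total number of
#' quanta.  Intended as an independent oracle for systems of up to three
#' modes; energies are reported relative to the variational ground state.
#'
#' @param ff a [quartic_force_field()] with at most 3 modes.
#' @param max_quanta basis truncation: all product states with total quanta
#'   `<= max_quanta` are included (default 20).
#' @param assert_convergence when `TRUE`, the problem is re-solved with
#'   `max_quanta + convergence_step` and the low-lying levels are required to
#'   move by less than `convergence_tol`; the larger-basis solution is
#'   returned.  An error advising smaller quartic scales is raised otherwise
#'   (variational collapse of an unbounded quartic truncation).
#' @param convergence_step,convergence_tol plateau test parameters
#'   (default +5 quanta, 0.1 cm^-1).
#' @return An object of class `variational_solution` with the basis (quanta
#'   matrix), ascending `eigenvalues` (cm^-1, absolute within the truncated
#'   problem), `eigenvectors` (columns, orthonormal) and the mode count.
#' @export
variational_solve <- function(ff, max_quanta = 20L, assert_convergence = FALSE,
                              convergence_step = 5L, convergence_tol = 0.1) {
  stopifnot(inherits(ff, "quartic_force_field"))
  nm <- ff$modes$n_modes
  if (nm > 3L) stop("the variational oracle is limited to 3 modes")
  for (i in seq_len(nm)) {
    if (ff_constant(ff, c(i, i, i, i)) < 0)
      stop("diagonal quartic of mode ", i, " is negative: the truncated ",
           "potential is unbounded and the variational oracle cannot converge")
  }
  sol <- .variational_solve_once(ff, max_quanta)
  if (assert_convergence) {
    big <- .variational_solve_once(ff, max_quanta + convergence_step)
    ncmp <- min(choose(nm + 2L, 2L) + nm + 1L, length(sol$eigenvalues))
    drift <- max(abs((sol$eigenvalues[seq_len(ncmp)] - sol$eigenvalues[1L]) -
                     (big$eigenvalues[seq_len(ncmp)] - big$eigenvalues[1L])))
    if (drift > convergence_tol)
      stop(sprintf(paste0(
        "variational levels moved by %.3g cm^-1 on basis growth ",
        "(tolerance %.3g); reduce the cubic/quartic scales or enlarge the basis"),
        drift, convergence_tol))
    sol <- big
    sol$convergence_drift <- drift
  }
  sol
}

.variational_solve_once <- function(ff, cap) {
  nm <- ff$modes$n_modes
  omega <- ff$modes$omega
  basis <- .oracle_basis(nm, cap)
  nb <- nrow(basis)
  ho <- .ho_1d_matrices(cap + 4L)
  # delta masks for inactive modes of a term
  deltas <- lapply(seq_len(nm), function(m)
    1 * outer(basis[, m], basis[, m], "=="))
  H <- diag(as.numeric(basis %*% omega))
  terms <- .ff_terms(ff)
  for (t in c(terms$cubic, terms$quartic)) {
    pow <- tabulate(t$idx, nbins = nm)
    M <- NULL
    for (m in seq_len(nm)) {
      fac <- if (pow[m] > 0L) {
        ho$Q[[pow[m]]][basis[, m] + 1L, basis[, m] + 1L]
      } else deltas[[m]]
      M <- if (is.null(M)) fac else M * fac
    }
    H <- H + t$coef * M
  }
  es <- eigen((H + t(H)) / 2, symmetric = TRUE)
  ord <- order(es$values)
  structure(list(basis = basis, max_quanta = cap,
                 eigenvalues = es$values[ord],
                 eigenvectors = es$vectors[, ord, drop = FALSE],
                 n_modes = nm, omega = omega),
            class = "variational_solution")
}

#' @export
print.variational_solution <- function(x, ...) {
  cat("<variational_solution> ", x$n_modes, " mode(s), basis of ",
      nrow(x$basis), " states (total quanta <= ", x$max_quanta, ")\n",
      "  lowest levels (cm^-1, relative): ",
      paste(format(utils::head(x$eigenvalues - x$eigenvalues[1L], 6L),
                   digits = 6), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Locate the eigenstate dominated by a given zeroth-order configuration
#'
#' @param sol a [variational_solve()] result.
#' @param quanta integer quanta vector of the target configuration.
#' @return The eigenstate column index (largest squared overlap with the
#'   requested basis state).
#' @export
oracle_state_index <- function(sol, quanta) {
  key <- paste(as.integer(quanta), collapse = ",")
  keys <- apply(sol$basis, 1L, paste, collapse = ",")
  row <- match(key, keys)
  if (is.na(row)) stop("configuration ", key, " outside the oracle basis")
  which.max(sol$eigenvectors[row, ]^2)
}

#' Variational level relative to the ground state
#'
#' @inheritParams oracle_state_index
#' @return Energy in cm^-1 of the eigenstate dominated by `quanta`, relative
#'   to the variational ground state.
#' @export
oracle_level <- function(sol, quanta) {
  sol$eigenvalues[oracle_state_index(sol, quanta)] - sol$eigenvalues[1L]
}

# row lookup of quanta vectors in the oracle basis (NA when outside)
.oracle_lookup <- function(sol, qm) {
  keys <- apply(qm, 1L, paste, collapse = ",")
  env <- attr(sol, "lookup")
  if (is.null(env)) {
    all_keys <- apply(sol$basis, 1L, paste, collapse = ",")
    env <- new.env(parent = emptyenv(), size = length(all_keys))
    for (i in seq_along(all_keys)) assign(all_keys[i], i, envir = env)
    attr(sol, "lookup") <- env
  }
  vapply(keys, function(k) {
    v <- env[[k]]
    if (is.null(v)) NA_integer_ else v
  }, 1L, USE.NAMES = FALSE)
}

#' Exact operator matrix element between variational eigenstates
#'
#' Computes the matrix element of a property-surface operator (a polynomial
#' in the reduced coordinates, or in mixed momentum/coordinate products for
#' the momentum-expanded tensors) between two eigenstates of the variational
#' solution.  Eigenvector phases are fixed so that the dominant zeroth-order
#' configuration enters with a positive coefficient.
#'
#' For momentum-expanded tensors the returned components are the real
#' factors `M` of the physical moment `i * M`, matching the convention of
#' [transition_moment()].
#'
#' @param sol a [variational_solve()] result.
#' @param surface a [property_surface()].
#' @param quanta_I,quanta_F quanta vectors of the initial and final
#'   configurations (their dominant eigenstates are used).
#' @param order_cap include derivative orders up to this value (1, 2 or 3).
#' @return Numeric vector of `n_comp` transition-moment components.
#' @export
oracle_transition_moment <- function(sol, surface, quanta_I, quanta_F,
                                     order_cap = 3L) {
  stopifnot(inherits(sol, "variational_solution"),
            inherits(surface, "property_surface"))
  iI <- oracle_state_index(sol, quanta_I)
  iF <- oracle_state_index(sol, quanta_F)
  vI <- sol$eigenvectors[, iI]
  vF <- sol$eigenvectors[, iF]
  # phase convention: dominant configuration coefficient > 0
  rI <- .oracle_lookup(sol, matrix(as.integer(quanta_I), 1L))
  rF <- .oracle_lookup(sol, matrix(as.integer(quanta_F), 1L))
  if (vI[rI] < 0) vI <- -vI
  if (vF[rF] < 0) vF <- -vF
  ho <- .ho_1d_matrices(sol$max_quanta + 4L, max_pow = 3L)
  shifts <- .oracle_shift_maps(sol)
  apply_q <- function(v, m) .oracle_shift_apply(sol, v, m, ho$Q[[1L]], shifts)
  apply_P <- function(v, m) .oracle_shift_apply(sol, v, m, ho$P, shifts)
  moment_of <- function(opfun) sum(vF * opfun(vI))
  nm <- surface$n_modes
  out <- numeric(surface$n_comp)
  conj <- surface$conjugate
  # constant term (electric tensors only; see vignette on the phase of the
  # momentum expansion)
  if (!conj) out <- out + surface$value0 * sum(vF * vI)
  # first derivatives
  for (i in seq_len(nm)) {
    w <- if (conj) apply_P(vI, i) else apply_q(vI, i)
    out <- out + surface$d1[, i] * sum(vF * w)
  }
  if (order_cap >= 2L) {
    for (i in seq_len(nm)) for (j in seq_len(nm)) {
      w <- if (conj) {
        if (i == j) 0.5 * (apply_P(apply_q(vI, j), i) +
                           apply_q(apply_P(vI, i), j))
        else apply_P(apply_q(vI, j), i)
      } else apply_q(apply_q(vI, j), i)
      pref <- if (conj) 1 else 0.5
      out <- out + pref * surface$d2[, i, j] * sum(vF * w)
    }
  }
  if (order_cap >= 3L) {
    for (k in names(surface$d3)) {
      idx <- .key_idx(k)
      val <- surface$d3[[k]]
      perms <- unique(.all_perms3(idx))
      for (p in perms) {
        w <- if (conj) {
          qs <- p[2:3]
          if (p[1L] %in% qs) {
            w1 <- apply_P(apply_q(apply_q(vI, qs[2L]), qs[1L]), p[1L])
            w2 <- apply_q(apply_q(apply_P(vI, p[1L]), qs[2L]), qs[1L])
            0.5 * (w1 + w2)
          } else apply_P(apply_q(apply_q(vI, qs[2L]), qs[1L]), p[1L])
        } else apply_q(apply_q(apply_q(vI, p[3L]), p[2L]), p[1L])
        pref <- if (conj) 0.5 else 1 / 6
        out <- out + pref * val * sum(vF * w)
      }
    }
  }
  out
}

.all_perms3 <- function(idx) {
  pm <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
              c(3, 1, 2), c(3, 2, 1))
  lst <- lapply(seq_len(6L), function(r) idx[pm[r, ]])
  lst[!duplicated(vapply(lst, paste, "", collapse = ","))]
}

# shift maps: row index of the state reached by n_m -> n_m + s, NA outside
.oracle_shift_maps <- function(sol) {
  env <- attr(sol, "shiftmaps")
  if (!is.null(env)) return(env)
  nm <- sol$n_modes
  maps <- vector("list", nm)
  for (m in seq_len(nm)) {
    maps[[m]] <- lapply(stats::setNames(-1:1, as.character(-1:1)), function(s) {
      tgt <- sol$basis
      tgt[, m] <- tgt[, m] + s
      tgt[tgt[, m] < 0L, m] <- -1L  # forces NA lookup
      suppressWarnings(.oracle_lookup(sol, tgt))
    })
  }
  maps
}

# apply a tridiagonal single-mode operator via shift maps
.oracle_shift_apply <- function(sol, v, mode, Mat1d, shifts) {
  idx <- sol$basis[, mode] + 1L
  w <- numeric(length(v))
  for (s in c(-1L, 1L)) {
    map <- shifts[[mode]][[as.character(s)]]
    ok <- !is.na(map)
    if (!any(ok)) next
    amp <- Mat1d[cbind(idx[ok] + s, idx[ok])]
    w[map[ok]] <- w[map[ok]] + amp * v[ok]
  }
  w
}
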