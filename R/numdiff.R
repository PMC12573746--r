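# Two-step numerical differentiation along normal modes: cubic and
# semidiagonal quartic force constants from analytic Hessians, and second /
# semidiagonal-third property derivatives from analytic first-derivative
# tensors.  Displacements are specified in mass-weighted units
# (amu^1/2 A, default 0.01) and converted per mode to the reduced
# coordinate via reduced_step_from_massweighted(); this mirrors the fixed
# mass-weighted protocol, so step-sensitivity studies are faithful.
#
# Only single-mode displacements are used: central differences of the
# Hessian give f_ijk, symmetric second differences give f_iijk -- the
# minimal scheme consistent with a two-step protocol.  Fully off-diagonal
# third property derivatives are not obtainable this way and are not
# computed.

.check_finite <- function(x, what, disp) {
  if (!all(is.finite(unlist(x))))
    stop("non-finite ", what, " at displacement [",
         paste(format(disp, digits = 6), collapse = ", "), "]")
  x
}

#' Cubic and semidiagonal quartic constants by Hessian differencing
#'
#' Displaces each mode by plus/minus one step, evaluates the analytic
#' Hessian of the potential (cm^-1 over reduced coordinates), and forms
#' \eqn{f_{ijk} = \partial H_{jk}/\partial q_i} by central differences and
#' \eqn{f_{iijk} = \partial^2 H_{jk}/\partial q_i^2} by symmetric second
#' differences.  Estimates of the same constant from different displaced
#' modes are averaged (full permutation symmetrization); the largest
#' pre-symmetrization spread is reported as a diagnostic.
#'
#' @param evaluator function of a reduced-coordinate displacement vector
#'   returning `list(hessian = ...)`; the evaluator contract of
#'   [system_evaluator()].
#' @param modes a [normal_modes()] (step conversion and result container).
#' @param step_Q mass-weighted step in amu^1/2 Angstrom (default 0.01).
#' @return A list: `force_field` (a [quartic_force_field()]),
#'   `asymmetry_cubic` and `asymmetry_quartic` (largest spread among
#'   permutation-equivalent estimates before averaging).
#' @export
cubic_quartic_from_hessians <- function(evaluator, modes, step_Q = 0.01) {
  stopifnot(inherits(modes, "normal_modes"), step_Q > 0)
  nm <- modes$n_modes
  steps <- vapply(modes$omega, function(w)
    reduced_step_from_massweighted(step_Q, w), 0)
  H0 <- .check_finite(evaluator(numeric(nm))$hessian, "Hessian", numeric(nm))
  dH <- vector("list", nm)   # dH[[i]][j,k] ~ f_ijk
  d2H <- vector("list", nm)  # d2H[[i]][j,k] ~ f_iijk
  for (i in seq_len(nm)) {
    dp <- numeric(nm); dp[i] <- steps[i]
    Hp <- .check_finite(evaluator(dp)$hessian, "Hessian", dp)
    Hm <- .check_finite(evaluator(-dp)$hessian, "Hessian", -dp)
    dH[[i]] <- (Hp - Hm) / (2 * steps[i])
    d2H[[i]] <- (Hp - 2 * H0 + Hm) / steps[i]^2
  }
  ff <- quartic_force_field(modes)
  asym3 <- 0
  for (i in seq_len(nm)) for (j in i:nm) for (k in j:nm) {
    ests <- c(dH[[i]][j, k], dH[[j]][i, k], dH[[k]][i, j],
              dH[[i]][k, j], dH[[j]][k, i], dH[[k]][j, i])
    asym3 <- max(asym3, diff(range(ests)))
    val <- mean(ests)
    if (val != 0) ff <- ff_set_constant(ff, c(i, j, k), val)
  }
  asym4 <- 0
  for (key in .semidiagonal_quartic_keys(nm)) {
    idx <- .key_idx(key)
    # every "doubled mode" reading of the tuple provides one estimate
    ests <- numeric()
    tab <- table(idx)
    for (d in as.integer(names(tab)[tab >= 2L])) {
      rest <- idx[-which(idx == d)[1:2]]
      ests <- c(ests, d2H[[d]][rest[1L], rest[2L]])
    }
    asym4 <- max(asym4, if (length(ests) > 1L) diff(range(ests)) else 0)
    val <- mean(ests)
    if (val != 0) ff <- ff_set_constant(ff, idx, val)
  }
  list(force_field = ff, asymmetry_cubic = asym3, asymmetry_quartic = asym4)
}

#' Second and semidiagonal third property derivatives by differencing
#'
#' Applies the same two-point scheme to the analytic first-derivative
#' tensors of each property surface: central differences give the full
#' second-derivative array, symmetric second differences along each mode
#' give the semidiagonal third derivatives.
#'
#' @inheritParams cubic_quartic_from_hessians
#' @param evaluator function returning `list(d1 = <named list of
#'   first-derivative matrices>)` at a displacement.
#' @return Named list per surface: `d2` (`[n_comp, n, n]`, symmetrized),
#'   `d3` (named list over semidiagonal canonical keys), `asymmetry` (the
#'   largest pre-symmetrization d2 spread).
#' @export
property_higher_derivatives <- function(evaluator, modes, step_Q = 0.01) {
  stopifnot(inherits(modes, "normal_modes"), step_Q > 0)
  nm <- modes$n_modes
  steps <- vapply(modes$omega, function(w)
    reduced_step_from_massweighted(step_Q, w), 0)
  at0 <- .check_finite(evaluator(numeric(nm))$d1, "first derivatives",
                       numeric(nm))
  sn <- names(at0)
  plus <- vector("list", nm); minus <- vector("list", nm)
  for (j in seq_len(nm)) {
    dp <- numeric(nm); dp[j] <- steps[j]
    plus[[j]] <- .check_finite(evaluator(dp)$d1, "first derivatives", dp)
    minus[[j]] <- .check_finite(evaluator(-dp)$d1, "first derivatives", -dp)
  }
  out <- lapply(sn, function(s) {
    nc <- nrow(at0[[s]])
    raw2 <- array(0, c(nc, nm, nm))  # [comp, i (d1 column), j (displaced)]
    raw3 <- array(0, c(nc, nm, nm))  # d3_{i,j,j}
    for (j in seq_len(nm)) {
      raw2[, , j] <- (plus[[j]][[s]] - minus[[j]][[s]]) / (2 * steps[j])
      raw3[, , j] <- (plus[[j]][[s]] - 2 * at0[[s]] + minus[[j]][[s]]) /
        steps[j]^2
    }
    d2 <- array(0, c(nc, nm, nm))
    asym <- 0
    for (i in seq_len(nm)) for (j in i:nm) {
      v <- (raw2[, i, j] + raw2[, j, i]) / 2
      asym <- max(asym, max(abs(raw2[, i, j] - raw2[, j, i])))
      d2[, i, j] <- d2[, j, i] <- v
    }
    d3 <- list()
    for (key in .semidiagonal_cubic_keys(nm)) {
      idx <- .key_idx(key)
      tab <- table(idx)
      dbl <- as.integer(names(tab)[tab >= 2L])[1L]
      other <- if (max(tab) == 3L) dbl else idx[-which(idx == dbl)[1:2]]
      v <- raw3[, other, dbl]
      if (any(v != 0)) d3[[key]] <- v
    }
    list(d2 = d2, d3 = d3, asymmetry = asym)
  })
  names(out) <- sn
  out
}
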