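# Sparse ladder algebra over the harmonic-oscillator product basis.
#
# A state vector is a list(q = integer matrix [n_states, n_modes],
# c = numeric coefficients).  The reduced-coordinate convention is
# q = (a + a^dag)/sqrt(2), so <0|q|1> = 1/sqrt(2); the conjugate momentum is
# p = i (a^dag - a)/sqrt(2) = i P with P real.  All operator applications
# below work with the real operators q and P; the i carried by
# momentum-expanded tensors is reattached at the observable level.

.hv <- function(q, c) {
  if (!is.matrix(q)) q <- matrix(q, nrow = 1L)
  list(q = q, c = as.numeric(c))
}

.hv_zero <- function(n_modes) {
  list(q = matrix(integer(), 0L, n_modes), c = numeric())
}

.hv_keys <- function(v) {
  if (nrow(v$q) == 0L) return(character())
  apply(v$q, 1L, paste, collapse = ",")
}

# merge duplicate basis states, drop (near-)zeros
.hv_collect <- function(v, drop_tol = 0) {
  if (nrow(v$q) <= 1L) return(v)
  keys <- .hv_keys(v)
  agg <- rowsum(v$c, keys)
  ukeys <- rownames(agg)
  keep <- abs(agg[, 1L]) > drop_tol
  if (!any(keep)) return(.hv_zero(ncol(v$q)))
  qm <- do.call(rbind, lapply(ukeys[keep], .key_idx))
  .hv(qm, agg[keep, 1L])
}

# apply q_mode (op = "q") or P_mode (op = "P") to a state vector
.hv_apply1 <- function(v, mode, op = "q") {
  n <- v$q[, mode]
  up <- v$q; up[, mode] <- n + 1L
  cu <- v$c * sqrt((n + 1) / 2)
  keep <- n > 0L
  dn <- v$q[keep, , drop = FALSE]; dn[, mode] <- n[keep] - 1L
  cd <- v$c[keep] * sqrt(n[keep] / 2)
  if (op == "P") cd <- -cd
  .hv_collect(.hv(rbind(up, dn), c(cu, cd)))
}

# apply a product of single-mode factors given as a data.frame-ish list
# with integer vector `mode` and character vector `op` (right factor first)
.hv_apply_seq <- function(v, mode, op) {
  for (t in seq_along(mode)) v <- .hv_apply1(v, mode[t], op[t])
  v
}

# symmetrized application of P_i * (q_{j1} q_{j2} ...):
# (P M + M P)/2, which matters only when i appears among the q indices
.hv_apply_Pq <- function(v, i, qs) {
  if (!(i %in% qs)) {
    return(.hv_apply1(.hv_apply_seq(v, rev(qs), rep("q", length(qs))), i, "P"))
  }
  w1 <- .hv_apply1(.hv_apply_seq(v, rev(qs), rep("q", length(qs))), i, "P")
  w2 <- .hv_apply_seq(.hv_apply1(v, i, "P"), rev(qs), rep("q", length(qs)))
  .hv_collect(.hv(rbind(w1$q, w2$q), c(w1$c / 2, w2$c / 2)))
}

.hv_add <- function(u, v, fu = 1, fv = 1) {
  .hv_collect(.hv(rbind(u$q, v$q), c(fu * u$c, fv * v$c)))
}

.hv_dot <- function(u, v) {
  if (nrow(u$q) == 0L || nrow(v$q) == 0L) return(0)
  ku <- .hv_keys(u); kv <- .hv_keys(v)
  m <- match(ku, kv)
  ok <- !is.na(m)
  if (!any(ok)) return(0)
  sum(u$c[ok] * v$c[m[ok]])
}

# harmonic energy relative to the ZPE
.hv_energies <- function(v, omega) as.numeric(v$q %*% omega)

# permutation multiplicity of a sorted index tuple
.perm_mult <- function(idx) {
  factorial(length(idx)) / prod(factorial(table(idx)))
}

# Expand the cubic (1/6 sum f q q q) and semidiagonal quartic
# (1/24 sum f q q q q) potential terms into a list of monomials with
# coefficients; used to apply the perturbation to sparse state vectors.
.ff_terms <- function(ff) {
  cubic <- lapply(names(ff$cubic), function(k) {
    idx <- .key_idx(k)
    list(idx = idx, coef = ff$cubic[[k]] * .perm_mult(idx) / 6)
  })
  quartic <- lapply(names(ff$quartic), function(k) {
    idx <- .key_idx(k)
    list(idx = idx, coef = ff$quartic[[k]] * .perm_mult(idx) / 24)
  })
  list(cubic = cubic, quartic = quartic)
}

# apply one potential order (list of terms) to a state vector
.hv_apply_terms <- function(v, terms) {
  if (length(terms) == 0L || nrow(v$q) == 0L) return(.hv_zero(ncol(v$q)))
  parts_q <- list(); parts_c <- list()
  for (t in terms) {
    w <- .hv_apply_seq(v, t$idx, rep("q", length(t$idx)))
    if (nrow(w$q)) {
      parts_q[[length(parts_q) + 1L]] <- w$q
      parts_c[[length(parts_c) + 1L]] <- w$c * t$coef
    }
  }
  if (!length(parts_q)) return(.hv_zero(ncol(v$q)))
  .hv_collect(.hv(do.call(rbind, parts_q), unlist(parts_c)), drop_tol = 0)
}
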