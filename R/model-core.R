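#' Normal-mode set
#'
#' Harmonic description of the vibrational problem: the number of modes and
#' their harmonic wavenumbers in cm^-1.  All other containers in the package
#' reference one of these.
#'
#' @param omega numeric vector of harmonic wavenumbers (cm^-1), one per mode;
#'   all entries must be strictly positive.
#' @param labels optional character vector of free-text mode labels.
#' @return An object of class `normal_modes` with fields `n_modes`, `omega`
#'   and `labels`.
#' @examples
#' normal_modes(c(2990, 1700, 1300))
#' @export
normal_modes <- function(omega, labels = NULL) {
  omega <- as.numeric(omega)
  if (length(omega) < 1L) stop("at least one mode is required")
  if (any(!is.finite(omega)) || any(omega <= 0))
    stop("harmonic wavenumbers must be finite and strictly positive")
  if (is.null(labels)) labels <- paste0("mode", seq_along(omega))
  if (length(labels) != length(omega))
    stop("'labels' must have one entry per mode")
  structure(list(n_modes = length(omega), omega = omega,
                 labels = as.character(labels)),
            class = "normal_modes")
}

#' @export
print.normal_modes <- function(x, ...) {
  cat("<normal_modes> ", x$n_modes, " mode(s): ",
      paste(format(x$omega, digits = 6), collapse = ", "), " cm^-1\n", sep = "")
  invisible(x)
}

#' Canonical (sorted) index tuple
#'
#' Force constants and semidiagonal property derivatives are totally symmetric
#' under permutation of their mode indices; they are stored once under the
#' sorted tuple and expanded symmetrically on access.
#'
#' @param idx integer vector of 1-based mode indices.
#' @param n_modes number of modes; indices are validated against it.
#' @return The sorted integer tuple.
#' @examples
#' canonical_index(c(3, 1, 2), 3)
#' @export
canonical_index <- function(idx, n_modes) {
  idx <- as.integer(idx)
  if (any(idx < 1L) || any(idx > n_modes))
    stop("mode index out of range 1..", n_modes)
  sort(idx)
}

.idx_key <- function(idx) paste(idx, collapse = ",")
.key_idx <- function(key) as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])

#' Quartic force field in reduced normal coordinates
#'
#' Holds the harmonic wavenumbers together with cubic \eqn{f_{ijk}} and
#' semidiagonal quartic \eqn{f_{ijkl}} force constants, all in cm^-1, for the
#' potential
#' \deqn{V = \tfrac12\sum_i \omega_i q_i^2 + \tfrac16\sum_{ijk} f_{ijk}
#'   q_i q_j q_k + \tfrac1{24}\sum_{ijkl} f_{ijkl} q_i q_j q_k q_l.}
#' Constants are stored under canonical (sorted) index tuples; any entry not
#' stored reads as zero.  Only semidiagonal quartics (at least two equal
#' indices) are representable: these are the constants obtainable from
#' single-mode displacement differencing.  Requests to store a fully
#' off-diagonal quartic raise a warning and are ignored.
#'
#' @param modes a [normal_modes] object.
#' @param cubic named numeric vector of cubic constants, names like `"1,1,2"`
#'   (any index order accepted).
#' @param quartic named numeric vector of semidiagonal quartic constants.
#' @return An object of class `quartic_force_field`.
#' @seealso [ff_constant()], [ff_set_constant()]
#' @export
quartic_force_field <- function(modes, cubic = numeric(), quartic = numeric()) {
  stopifnot(inherits(modes, "normal_modes"))
  ff <- structure(list(modes = modes, cubic = numeric(), quartic = numeric()),
                  class = "quartic_force_field")
  for (k in names(cubic))  ff <- ff_set_constant(ff, .key_idx(k), cubic[[k]])
  for (k in names(quartic)) ff <- ff_set_constant(ff, .key_idx(k), quartic[[k]])
  ff
}

.is_semidiagonal <- function(idx) any(duplicated(idx))

#' Store a force constant
#'
#' @param ff a [quartic_force_field()].
#' @param idx index tuple of length 3 (cubic) or 4 (quartic), any order.
#' @param value constant in cm^-1.
#' @return The updated force field.
#' @export
ff_set_constant <- function(ff, idx, value) {
  idx <- canonical_index(idx, ff$modes$n_modes)
  key <- .idx_key(idx)
  if (length(idx) == 3L) {
    ff$cubic[[key]] <- as.numeric(value)
  } else if (length(idx) == 4L) {
    if (!.is_semidiagonal(idx)) {
      warning("fully off-diagonal quartic ", key,
              " is outside the semidiagonal storage scheme; ignored")
      return(ff)
    }
    ff$quartic[[key]] <- as.numeric(value)
  } else stop("index tuple must have length 3 or 4")
  ff
}

#' Read a force constant (zero when absent)
#'
#' Retrieval is invariant under any permutation of the indices.
#'
#' @inheritParams ff_set_constant
#' @return The stored constant, or 0 when no entry exists.
#' @export
ff_constant <- function(ff, idx) {
  idx <- canonical_index(idx, ff$modes$n_modes)
  key <- .idx_key(idx)
  store <- if (length(idx) == 3L) ff$cubic else ff$quartic
  if (key %in% names(store)) store[[key]] else 0
}

#' @export
print.quartic_force_field <- function(x, ...) {
  cat("<quartic_force_field> ", x$modes$n_modes, " mode(s), ",
      length(x$cubic), " cubic, ", length(x$quartic),
      " semidiagonal quartic constant(s)\n", sep = "")
  invisible(x)
}

#' Coriolis coupling data
#'
#' Antisymmetric Coriolis zeta constants per rotational axis and mode pair,
#' plus the three equilibrium rotational constants (cm^-1).  These enter the
#' second-order energy correction only; they never touch intensities.
#'
#' @param zeta numeric array `[3, n_modes, n_modes]`, antisymmetric in the
#'   two mode indices.
#' @param rotational_constants numeric length-3 vector (cm^-1).
#' @return An object of class `coriolis_data`.
#' @export
coriolis_data <- function(zeta, rotational_constants) {
  zeta <- as.array(zeta)
  if (length(dim(zeta)) != 3L || dim(zeta)[1] != 3L || dim(zeta)[2] != dim(zeta)[3])
    stop("'zeta' must be a 3 x n x n array")
  for (a in 1:3) {
    if (max(abs(zeta[a, , ] + t(zeta[a, , ]))) > 1e-10)
      stop("zeta must be antisymmetric in its mode indices")
  }
  rotational_constants <- as.numeric(rotational_constants)
  if (length(rotational_constants) != 3L || any(rotational_constants < 0))
    stop("'rotational_constants' must be three nonnegative values (cm^-1)")
  structure(list(zeta = zeta, rotational_constants = rotational_constants,
                 present = TRUE),
            class = "coriolis_data")
}

.surface_shapes <- c(mu = 3L, m = 3L, alpha = 9L, Gprime = 9L, Aquad = 27L)
.conjugate_surfaces <- c("m", "Gprime")

#' Property surface over reduced normal coordinates
#'
#' One electromagnetic tensor -- electric dipole `mu`, magnetic dipole `m`,
#' polarizability `alpha`, electric-magnetic dipole polarizability `Gprime`
#' or electric dipole-quadrupole polarizability `Aquad` -- with its
#' equilibrium value and first, second and semidiagonal third derivatives
#' over the reduced normal coordinates, all in atomic units.
#'
#' The magnetic-type tensors (`m`, `Gprime`) are momentum-expanded: their
#' expansion runs over the conjugate momenta \eqn{p_i} in the first slot
#' rather than \eqn{q_i}, and the package stores the real coefficient arrays
#' with the understanding that the physical operator carries a factor
#' \eqn{i} (see the methods vignette for the phase convention).
#'
#' @param name one of `"mu"`, `"m"`, `"alpha"`, `"Gprime"`, `"Aquad"`.
#' @param value0 numeric vector of equilibrium tensor components (length 3,
#'   9 or 27 depending on `name`; `Aquad` components are ordered as a
#'   flattened `[alpha, beta, gamma]` array and must be symmetric under
#'   beta/gamma exchange).
#' @param d1 numeric matrix `[n_comp, n_modes]` of first derivatives.
#' @param d2 numeric array `[n_comp, n_modes, n_modes]`, symmetric in the
#'   two mode indices.
#' @param d3 named list of semidiagonal third derivatives: names are
#'   canonical index keys (e.g. `"1,1,2"`, at least two equal indices),
#'   values numeric vectors of length `n_comp`.  Values are totally
#'   symmetric in the mode indices.
#' @param n_modes number of modes the surface spans.
#' @return An object of class `property_surface`.
#' @export
property_surface <- function(name, n_modes, value0 = NULL, d1 = NULL,
                             d2 = NULL, d3 = list()) {
  name <- match.arg(name, names(.surface_shapes))
  nc <- .surface_shapes[[name]]
  if (is.null(value0)) value0 <- numeric(nc)
  if (is.null(d1)) d1 <- matrix(0, nc, n_modes)
  if (is.null(d2)) d2 <- array(0, c(nc, n_modes, n_modes))
  value0 <- as.numeric(value0)
  d1 <- as.matrix(d1)
  d2 <- as.array(d2)
  if (length(value0) != nc) stop("value0 must have ", nc, " components")
  if (!all(dim(d1) == c(nc, n_modes))) stop("d1 must be [", nc, ", n_modes]")
  if (!all(dim(d2) == c(nc, n_modes, n_modes)))
    stop("d2 must be [", nc, ", n_modes, n_modes]")
  for (b in seq_len(nc)) {
    if (max(abs(d2[b, , ] - t(d2[b, , ]))) > 1e-10 * (1 + max(abs(d2))))
      stop("d2 must be symmetric in its mode indices")
  }
  d3c <- list()
  for (k in names(d3)) {
    idx <- canonical_index(.key_idx(k), n_modes)
    if (length(idx) != 3L || !.is_semidiagonal(idx))
      stop("d3 keys must be semidiagonal triples, got ", k)
    v <- as.numeric(d3[[k]])
    if (length(v) != nc) stop("d3 entries must have ", nc, " components")
    d3c[[.idx_key(idx)]] <- v
  }
  if (name == "Aquad") .check_A_symmetry(value0, d1, d2, d3c)
  structure(list(name = name, n_comp = nc, n_modes = n_modes,
                 value0 = value0, d1 = d1, d2 = d2, d3 = d3c,
                 conjugate = name %in% .conjugate_surfaces),
            class = "property_surface")
}

# A_{alpha,beta gamma} must be symmetric under beta <-> gamma at every
# derivative order; component index = alpha + 3(beta-1) + 9(gamma-1).
.A_comp <- function(a, b, g) a + 3L * (b - 1L) + 9L * (g - 1L)
.check_A_symmetry <- function(value0, d1, d2, d3) {
  for (a in 1:3) for (b in 1:3) for (g in 1:3) {
    i <- .A_comp(a, b, g); j <- .A_comp(a, g, b)
    ok <- isTRUE(all.equal(value0[i], value0[j], tolerance = 1e-9)) &&
      isTRUE(all.equal(d1[i, ], d1[j, ], tolerance = 1e-9)) &&
      isTRUE(all.equal(d2[i, , ], d2[j, , ], tolerance = 1e-9)) &&
      all(vapply(names(d3), function(k)
        isTRUE(all.equal(d3[[k]][i], d3[[k]][j], tolerance = 1e-9)), TRUE))
    if (!ok) stop("Aquad components must be symmetric under beta/gamma swap")
  }
}

#' Retrieve a semidiagonal third property derivative
#'
#' @param surface a [property_surface()].
#' @param idx mode-index triple (any order, at least two equal).
#' @return Numeric vector of `n_comp` components (zero when absent).
#' @export
surface_d3 <- function(surface, idx) {
  idx <- canonical_index(idx, surface$n_modes)
  key <- .idx_key(idx)
  if (key %in% names(surface$d3)) surface$d3[[key]] else numeric(surface$n_comp)
}

#' @export
print.property_surface <- function(x, ...) {
  cat("<property_surface> ", x$name, " (", x$n_comp, " components, ",
      x$n_modes, " modes", if (x$conjugate) ", momentum-expanded", "), ",
      length(x$d3), " semidiagonal third-derivative entries\n", sep = "")
  invisible(x)
}

#' Vibrational model system
#'
#' Self-contained description of one vibrational problem: the quartic force
#' field, optional Coriolis data, any subset of the five property surfaces,
#' and provenance metadata.
#'
#' @param force_field a [quartic_force_field()].
#' @param surfaces named list of [property_surface()] objects (names must
#'   match the surface names).
#' @param coriolis optional [coriolis_data()].
#' @param metadata free-form list (seed, generator versions, analytic level
#'   formulas for closed-form systems, ...).
#' @return An object of class `model_system`.
#' @export
model_system <- function(force_field, surfaces = list(), coriolis = NULL,
                         metadata = list()) {
  stopifnot(inherits(force_field, "quartic_force_field"))
  nm <- force_field$modes$n_modes
  for (s in surfaces) {
    stopifnot(inherits(s, "property_surface"))
    if (s$n_modes != nm)
      stop("surface ", s$name, " spans ", s$n_modes,
           " modes but the force field has ", nm)
  }
  if (length(surfaces)) names(surfaces) <-
    vapply(surfaces, function(s) s$name, "")
  if (!is.null(coriolis)) {
    stopifnot(inherits(coriolis, "coriolis_data"))
    if (dim(coriolis$zeta)[2] != nm)
      stop("Coriolis zeta dimensions do not match the mode count")
  }
  structure(list(force_field = force_field, surfaces = surfaces,
                 coriolis = coriolis, metadata = metadata),
            class = "model_system")
}

#' @export
print.model_system <- function(x, ...) {
  cat("<model_system> ", x$force_field$modes$n_modes, " mode(s); surfaces: ",
      if (length(x$surfaces)) paste(names(x$surfaces), collapse = ", ")
      else "(none)",
      if (!is.null(x$coriolis)) "; Coriolis data present", "\n", sep = "")
  invisible(x)
}

#' Vibrational state
#'
#' Quanta vector for the transition manifold: total quanta 0 (ground), 1
#' (fundamentals) or 2 (overtones and binary combinations).
#'
#' @param quanta nonnegative integer vector, one entry per mode.
#' @return An object of class `vib_state`.
#' @export
vib_state <- function(quanta) {
  quanta <- as.integer(quanta)
  if (any(quanta < 0)) stop("quanta must be nonnegative")
  if (sum(quanta) > 2L)
    stop("transition enumeration covers total quanta <= 2")
  structure(list(quanta = quanta), class = "vib_state")
}

# Short human label: F_i fundamental, O_i overtone, C_ij combination, G ground.
.state_label <- function(quanta) {
  nz <- which(quanta > 0L)
  if (length(nz) == 0L) return("G")
  if (length(nz) == 1L && quanta[nz] == 1L) return(paste0("F", nz))
  if (length(nz) == 1L && quanta[nz] == 2L) return(paste0("O", nz))
  paste0("C", nz[1], ",", nz[2])
}

#' Reduced-coordinate step from a mass-weighted step
#'
#' Converts a displacement step expressed in mass-weighted normal coordinates
#' (amu^1/2 A) into the dimensionless reduced coordinate of a mode with
#' harmonic wavenumber `omega`:
#' \eqn{\delta q = \delta Q \sqrt{4\pi^2 c\,\omega/h}}.
#' The reduced coordinate is defined so that the harmonic potential reads
#' \eqn{(\omega/2) q^2} and \eqn{\langle 0|q|1\rangle = 1/\sqrt2}.
#'
#' @param step_Q step in amu^1/2 Angstrom (must be positive).
#' @param omega harmonic wavenumber of the mode in cm^-1 (positive).
#' @return The dimensionless step in the reduced coordinate.
#' @examples
#' reduced_step_from_massweighted(0.01, 1000)
#' @export
reduced_step_from_massweighted <- function(step_Q, omega) {
  if (!is.numeric(step_Q) || any(step_Q <= 0) || any(!is.finite(step_Q)))
    stop("'step_Q' must be positive and finite")
  if (!is.numeric(omega) || any(omega <= 0) || any(!is.finite(omega)))
    stop("'omega' must be positive and finite")
  # step_Q [amu^1/2 A] -> SI kg^1/2 m
  step_si <- step_Q * sqrt(.const$amu) * 1e-10
  step_si * sqrt(4 * pi^2 * .const$c_cm * omega / .const$h)
}
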