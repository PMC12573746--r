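# Stick-to-band convolution, spectrum I/O, the spectral similarity
# statistic, and the simulation pipeline tying the engine together.

#' Spectrum container
#'
#' A sampled spectrum on an ascending, uniform wavenumber grid.
#'
#' @param wavenumber ascending, uniformly spaced grid (cm^-1), length >= 2.
#' @param intensity intensity at each grid point (may be signed, e.g. VCD
#'   and ROA).
#' @param kind one of `"IR"`, `"VCD"`, `"Raman"`, `"ROA"` or `"generic"`.
#' @param units free-text intensity units label.
#' @return An object of class `spectrum_band`.
#' @export
spectrum_band <- function(wavenumber, intensity, kind = "generic",
                          units = "arb.") {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) < 2L) stop("grid must have at least two points")
  if (length(wavenumber) != length(intensity))
    stop("grid and intensity lengths differ")
  d <- diff(wavenumber)
  if (any(d <= 0)) stop("grid must be strictly ascending")
  if (max(d) - min(d) > 1e-6 * mean(d)) stop("grid must be uniform")
  kind <- match.arg(kind, c("IR", "VCD", "Raman", "ROA", "generic"))
  structure(list(wavenumber = wavenumber, intensity = intensity,
                 kind = kind, units = units),
            class = "spectrum_band")
}

#' @export
print.spectrum_band <- function(x, ...) {
  cat("<spectrum_band> ", x$kind, ", ", length(x$wavenumber), " points, ",
      format(min(x$wavenumber)), "-", format(max(x$wavenumber)),
      " cm^-1\n", sep = "")
  invisible(x)
}

#' Lorentzian band convolution
#'
#' Each stick contributes a Lorentzian of unit-normalized shape scaled by
#' the stick intensity: area equals the stick intensity and the peak height
#' is `2 I / (pi * fwhm)`.
#'
#' @param energies stick positions (cm^-1).
#' @param intensities stick intensities (signed allowed).
#' @param fwhm full width at half maximum (cm^-1), default 8.
#' @param from,to,by grid specification (cm^-1); defaults cover the sticks
#'   with a 10*fwhm margin at 1 cm^-1 spacing.
#' @param kind passed to [spectrum_band()].
#' @return A [spectrum_band()].  Sticks outside the grid still contribute
#'   their tails; sticks whose centers fall outside the grid raise a
#'   warning naming them.
#' @export
convolve_sticks <- function(energies, intensities, fwhm = 8,
                            from = NULL, to = NULL, by = 1,
                            kind = "generic") {
  stopifnot(length(energies) == length(intensities), fwhm > 0)
  if (length(energies) == 0L) stop("no sticks to convolve")
  if (is.null(from)) from <- max(0, floor(min(energies) - 10 * fwhm))
  if (is.null(to)) to <- ceiling(max(energies) + 10 * fwhm)
  grid <- seq(from, to, by = by)
  outside <- energies < from | energies > to
  if (any(outside))
    warning("stick(s) at ", paste(format(energies[outside]), collapse = ", "),
            " cm^-1 lie outside the grid and are truncated")
  gamma <- fwhm / 2
  inten <- numeric(length(grid))
  for (s in seq_along(energies)) {
    inten <- inten + intensities[s] * (gamma / pi) /
      ((grid - energies[s])^2 + gamma^2)
  }
  spectrum_band(grid, inten, kind = kind)
}

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Spectral similarity with optimal frequency scaling
#'
#' Normalized overlap of two spectra,
#' \deqn{s(a) = \frac{\int S_{cal}(a\omega) S_{exp}(\omega)\, d\omega}
#'  {\sqrt{\int S_{cal}^2(a\omega) d\omega \int S_{exp}^2(\omega) d\omega}},}
#' maximized over the frequency scaling factor `a` by golden-section search
#' on `a_bounds` refined to `tol`.  `s = 1` indicates identical spectra (up
#' to a positive overall scale); sign-carrying spectra (VCD, ROA) use the
#' same formula without absolute values, so wrong signs reduce `s`.
#' Both the optimum and the unscaled value `s(1)` are returned.
#'
#' @param calc,exp [spectrum_band()] objects (overlapping support).
#' @param a_bounds search interval for `a` (default `c(0.95, 1.05)`).
#' @param tol golden-section tolerance (default 1e-4).
#' @return A `similarity_result`: `s`, `a`, `s_unscaled`, and the `s(a)`
#'   evaluations explored.
#' @export
similarity <- function(calc, exp, a_bounds = c(0.95, 1.05), tol = 1e-4) {
  stopifnot(inherits(calc, "spectrum_band"), inherits(exp, "spectrum_band"))
  wexp <- exp$wavenumber
  norm_exp <- .trapz(wexp, exp$intensity^2)
  if (norm_exp == 0) stop("experimental spectrum has zero norm")
  s_of <- function(a) {
    # S_cal(a * omega) sampled on the experimental grid
    scal <- stats::approx(calc$wavenumber / a, calc$intensity,
                          xout = wexp, yleft = 0, yright = 0)$y
    ncal <- .trapz(wexp, scal^2)
    if (ncal == 0) return(0)
    .trapz(wexp, scal * exp$intensity) / sqrt(ncal * norm_exp)
  }
  evals <- data.frame(a = numeric(), s = numeric())
  f <- function(a) {
    s <- s_of(a)
    evals <<- rbind(evals, data.frame(a = a, s = s))
    s
  }
  gr <- (sqrt(5) - 1) / 2
  lo <- min(a_bounds); hi <- max(a_bounds)
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- f(x1); f2 <- f(x2)
  while (hi - lo > tol) {
    if (f1 < f2) {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo); f2 <- f(x2)
    } else {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo); f1 <- f(x1)
    }
  }
  a_best <- (lo + hi) / 2
  s_best <- f(a_best)
  s1 <- f(1)
  if (s1 >= s_best) { s_best <- s1; a_best <- 1 }
  structure(list(s = s_best, a = a_best, s_unscaled = s1, evaluations = evals),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("<similarity_result> s = %.6f at a = %.5f (s(1) = %.6f)\n",
              x$s, x$a, x$s_unscaled))
  invisible(x)
}

#' Read a two-column spectrum file
#'
#' Whitespace- or tab-separated wavenumber/intensity text, `#` comments.
#' A descending grid is normalized to ascending.
#'
#' @param path file path.
#' @param kind passed to [spectrum_band()].
#' @return A [spectrum_band()].
#' @export
read_spectrum <- function(path, kind = "generic") {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (!length(rows)) stop("no data rows in ", path)
  parsed <- lapply(rows, function(r) {
    fields <- strsplit(trimws(lines[r]), "[ \t]+")[[1L]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2L || any(is.na(vals[1:2])))
      stop("malformed spectrum row at line ", r, " of ", path)
    vals[1:2]
  })
  m <- do.call(rbind, parsed)
  if (all(diff(m[, 1L]) < 0)) m <- m[nrow(m):1L, , drop = FALSE]
  spectrum_band(m[, 1L], m[, 2L], kind = kind)
}

#' Write a spectrum as two-column text
#'
#' @param spectrum a [spectrum_band()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "spectrum_band"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", spectrum$kind, " spectrum (cm^-1, ",
                    spectrum$units, ")"), con)
  writeLines(sprintf("%.6f\t%.10g", spectrum$wavenumber,
                     spectrum$intensity), con)
  invisible(path)
}

# -- pipeline ----------------------------------------------------------------

#' Simulate the four anharmonic spectra of a model system
#'
#' Full pipeline: resonance detection, GVPT2 energies and eigenvectors,
#' transition moments with variational intensity mixing, observables, and
#' Lorentzian convolution of the IR, VCD, Raman and ROA sticks.
#'
#' @inheritParams vpt2_transitions
#' @param fwhm Lorentzian full width at half maximum (cm^-1, default 8).
#' @param from,to,by spectral grid (cm^-1).
#' @param ... forwarded to [vpt2_transitions()].
#' @return A list: `transitions` (the [vpt2_transitions()] result) and
#'   `spectra`, a named list of [spectrum_band()]s for the kinds whose
#'   tensors are available.
#' @export
vpt2_spectra <- function(system, fwhm = 8, from = NULL, to = NULL, by = 1,
                         order_cap = 3L, ...) {
  tr <- vpt2_transitions(system, order_cap = order_cap, ...)
  tab <- tr$table
  spectra <- list()
  sticks <- list(IR = tab$ir_stick, VCD = tab$vcd_stick,
                 Raman = tab$raman_stick, ROA = tab$roa_stick)
  for (kind in names(sticks)) {
    v <- sticks[[kind]]
    if (all(is.na(v))) next
    spectra[[kind]] <- convolve_sticks(tab$energy, ifelse(is.na(v), 0, v),
                                       fwhm = fwhm, from = from, to = to,
                                       by = by, kind = kind)
  }
  list(transitions = tr, spectra = spectra)
}

.default_regions <- list(
  fundamental = rbind(c(0, 2000), c(2750, 3100)),
  anharmonic  = rbind(c(2000, 2750), c(3100, 4000)))

#' Contributions of the property-derivative orders to spectral intensity
#'
#' Simulates each spectrum kind three times with derivative-order caps 1,
#' 1+2 and 1+2+3 over identical states and resonance treatment, integrates
#' the absolute spectra over the requested regions, and reports
#' \eqn{n(third) = (I_{123} - I_{12})/I_{123} \times 100},
#' \eqn{n(second) = (I_{12} - I_1)/I_{123} \times 100},
#' \eqn{n(first) = 100 - n(second) - n(third)}.
#' The three always sum to 100 by construction.  A region with
#' \eqn{I_{123} = 0} is undefined and reported as `NA`.
#'
#' @param system a [model_system()].
#' @param regions named list of two-column matrices of wavenumber windows
#'   (cm^-1); the default splits a fundamental region (0--2000 and
#'   2750--3100) from an anharmonic region (2000--2750 and 3100--4000).
#' @param fwhm,by convolution parameters.
#' @param ... forwarded to [vpt2_spectra()].
#' @return Data frame with columns `kind`, `region`, `I1`, `I12`, `I123`,
#'   `n_first`, `n_second`, `n_third`.
#' @export
derivative_order_contributions <- function(system,
                                           regions = .default_regions,
                                           fwhm = 8, by = 1, ...) {
  gv <- gvpt2_solve(system)
  sims <- lapply(1:3, function(cap)
    vpt2_spectra(system, fwhm = fwhm, by = by, order_cap = cap,
                 gvpt2 = gv, ...))
  kinds <- names(sims[[3]]$spectra)
  rows <- list()
  for (kind in kinds) {
    for (rn in names(regions)) {
      win <- regions[[rn]]
      integ <- vapply(sims, function(sm) {
        sp <- sm$spectra[[kind]]
        tot <- 0
        for (w in seq_len(nrow(win))) {
          sel <- sp$wavenumber >= win[w, 1] & sp$wavenumber <= win[w, 2]
          if (sum(sel) >= 2L)
            tot <- tot + .trapz(sp$wavenumber[sel], abs(sp$intensity[sel]))
        }
        tot
      }, 0)
      I1 <- integ[1]; I12 <- integ[2]; I123 <- integ[3]
      if (I123 == 0) {
        n3 <- n2 <- n1 <- NA_real_
      } else {
        n3 <- (I123 - I12) / I123 * 100
        n2 <- (I12 - I1) / I123 * 100
        n1 <- 100 - n3 - n2
      }
      rows[[length(rows) + 1L]] <- data.frame(
        kind = kind, region = rn, I1 = I1, I12 = I12, I123 = I123,
        n_first = n1, n_second = n2, n_third = n3,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the transition table as TSV
#'
#' @param transitions a [vpt2_transitions()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transitions <- function(transitions, path) {
  stopifnot(inherits(transitions, "transition_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# anharmvoa transition table v1", con)
  utils::write.table(transitions$table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
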