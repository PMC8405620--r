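## Rubber-band (lower convex hull) baseline subtraction, the standard
## pre-processing step before band deconvolution of FTIR/Raman spectra.

# Indices of the lower convex hull of (x, y), x strictly increasing
# (Andrew monotone chain, lower branch only).
lower_hull_idx <- function(x, y) {
  n <- length(x)
  hull <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    while (k >= 2L) {
      a <- hull[k - 1L]; b <- hull[k]
      # keep turns that are strictly convex (counter-clockwise)
      cross <- (x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a])
      if (cross <= 0) k <- k - 1L else break
    }
    k <- k + 1L
    hull[k] <- i
  }
  hull[seq_len(k)]
}

#' Convex-hull (rubber-band) baseline subtraction
#'
#' Computes the lower convex hull of the spectrum points over `region`,
#' evaluates the baseline by linear interpolation between hull vertices, and
#' returns the baseline-subtracted spectrum restricted to the region. The
#' corrected intensity is non-negative up to floating-point round-off, and
#' the operation is idempotent.
#'
#' @param spec a `spectrum` object or data frame with columns
#'   `wavenumber` and `intensity`
#' @param region length-2 wavenumber interval to process; `NULL` uses the
#'   full range
#' @return a `spectrum` over `region` with the baseline removed; the removed
#'   baseline is attached as attribute `baseline`
#' @export
convex_hull_baseline <- function(spec, region = NULL) {
  x <- spec$wavenumber
  y <- spec$intensity
  if (is.null(region)) region <- range(x)
  if (length(region) != 2L || region[1] >= region[2])
    stop_invalid("`region` must be an increasing (lo, hi) interval")
  keep <- x >= region[1] & x <= region[2]
  if (sum(keep) < 3L)
    stop_invalid("region [%g, %g] contains %d points; need at least 3",
                 region[1], region[2], sum(keep))
  x <- x[keep]; y <- y[keep]

  h <- lower_hull_idx(x, y)
  baseline <- stats::approx(x[h], y[h], xout = x)$y
  corrected <- y - baseline
  corrected[corrected < 0 & corrected > -1e-9] <- 0

  out <- new_spectrum(x, corrected, modality = spec$modality,
                      orientation = spec$orientation)
  attr(out, "baseline") <- baseline
  out
}

#' Construct a spectrum object
#'
#' A sampled one-dimensional signal on a strictly increasing abscissa,
#' shared by the FTIR, Raman and diffraction-profile stages.
#'
#' @param wavenumber abscissa in cm-1 (or other increasing units), strictly
#'   increasing
#' @param intensity finite intensities, same length
#' @param modality optional label, e.g. "ftir" or "raman"
#' @param orientation optional polarization label ("X" or "Y")
#' @return object of class `spectrum` (a list with the fields above)
#' @export
new_spectrum <- function(wavenumber, intensity, modality = NULL,
                         orientation = NULL) {
  if (length(wavenumber) != length(intensity))
    stop_invalid("wavenumber and intensity lengths differ")
  if (any(diff(wavenumber) <= 0))
    stop_invalid("wavenumber axis must be strictly increasing")
  if (!all(is.finite(intensity)))
    stop_invalid("intensities must all be finite")
  structure(list(wavenumber = wavenumber, intensity = intensity,
                 modality = modality, orientation = orientation),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("spectrum%s: %d points, %.6g-%.6g\n",
              if (is.null(x$modality)) "" else paste0(" (", x$modality, ")"),
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}
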