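#' @keywords internal
"_PACKAGE"

## Shared numerical helpers and argument checks.

# FWHM of a Gaussian = 2*sqrt(2*log(2)) * sd
FWHM_TO_SD <- 1 / (2 * sqrt(2 * log(2)))

#' Area-normalized Gaussian line shape
#'
#' @param x abscissa vector
#' @param center peak center (same units as `x`)
#' @param fwhm full width at half maximum (> 0)
#' @param area integrated area (default 1)
#' @return vector of intensities with analytic area `area`
#' @export
gaussian_peak <- function(x, center, fwhm, area = 1) {
  sd <- fwhm * FWHM_TO_SD
  area * stats::dnorm(x, mean = center, sd = sd)
}

#' Area-normalized Lorentzian line shape
#'
#' @inheritParams gaussian_peak
#' @return vector of intensities; analytic (full-line) area is `area`
#' @export
lorentzian_peak <- function(x, center, fwhm, area = 1) {
  g <- fwhm / 2
  area * g / (pi * ((x - center)^2 + g^2))
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("`%s` must be a single finite number", name)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_invalid("`%s` = %g is outside the admissible range %s%g, %g%s",
                 name, x,
                 if (strict_lower) "(" else "[", lower, upper,
                 if (strict_upper) ")" else "]")
  invisible(x)
}

# Signed angular difference in degrees, wrapped to (-180, 180]
angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}

# Trapezoidal area under y(x); 0 for fewer than 2 points
trapz_area <- function(x, y) {
  if (length(x) < 2L) return(0)
  pracma::trapz(x, y)
}
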