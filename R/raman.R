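## Polarized Raman orientation sensitivity. Spectra recorded with the fiber
## parallel (X) and perpendicular (Y) to the laser polarization are each
## normalized to the conformation-insensitive 1450 cm-1 CH2-bending band;
## the ratio I = Y/X of the normalized amide-I (1670 cm-1) intensities
## reports molecular alignment (I = 1 for an isotropic fiber).

#' Simulate a polarized Raman spectrum pair with known orientation ratio
#'
#' Both spectra carry an identical 1450 cm-1 reference band and minor
#' conformation bands; the amide-I (1670 cm-1) band heights are set so that
#' the 1450-normalized heights differ by exactly `true_ratio` (Y over X).
#' Gaussian line shapes keep cross-band tail leakage negligible. The X
#' spectrum is globally rescaled by `x_scale` to exercise normalization
#' invariance.
#'
#' @param true_ratio target orientation ratio Y/X (> 0)
#' @param noise_sd additive noise sd relative to the reference-band height
#' @param seed integer RNG seed
#' @param wavenumber sampling grid in cm-1 (default 1100-1800 by 1)
#' @param amide_height 1450-normalized amide-I height in the X spectrum
#' @param x_scale overall multiplicative scale applied to the X spectrum
#' @return list with elements `Y` and `X` (each a `spectrum`), attribute
#'   `truth` carrying `true_ratio`
#' @export
gen_raman_pair <- function(true_ratio, noise_sd = 0, seed = 1,
                           wavenumber = seq(1100, 1800, by = 1),
                           amide_height = 0.8, x_scale = 1) {
  check_scalar(true_ratio, "true_ratio", lower = 0, strict_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(x_scale, "x_scale", lower = 0, strict_lower = TRUE)

  base_bands <- function(x) {
    gaussian_height(x, 1450, 18, 1) +          # CH2 bending reference
      gaussian_height(x, 1250, 30, 0.35) +     # amide III
      gaussian_height(x, 1605, 14, 0.15)       # aromatic ring mode
  }
  spec_one <- function(amide_h, scale, sub_seed) {
    y <- base_bands(wavenumber) +
      gaussian_height(wavenumber, 1670, 22, amide_h)
    if (noise_sd > 0) {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(sub_seed)
      y <- y + stats::rnorm(length(y), 0, noise_sd)
    }
    scale * y
  }

  out <- list(
    Y = new_spectrum(wavenumber,
                     spec_one(amide_height * true_ratio, 1, seed),
                     modality = "raman", orientation = "Y"),
    X = new_spectrum(wavenumber,
                     spec_one(amide_height, x_scale, seed + 1L),
                     modality = "raman", orientation = "X"))
  attr(out, "truth") <- list(true_ratio = true_ratio)
  out
}

# Gaussian parameterized by height rather than area
gaussian_height <- function(x, center, fwhm, height) {
  height * exp(-4 * log(2) * ((x - center) / fwhm)^2)
}

#' Polarized-Raman orientation ratio I = Y/X
#'
#' Normalizes each baseline-subtracted spectrum to its maximum intensity
#' within 1450 +/- 10 cm-1, locates the amide-I peak as the maximum within
#' 1670 +/- 10 cm-1 (same window for both spectra), and returns the ratio of
#' the normalized amide-I heights, perpendicular over parallel.
#'
#' @param spec_Y spectrum recorded with the fiber perpendicular to the laser
#'   polarization
#' @param spec_X spectrum recorded with the fiber parallel
#' @param ref_window reference band search window in cm-1
#'   (default `c(1440, 1460)`)
#' @param amide_window amide-I search window in cm-1
#'   (default `c(1660, 1680)`)
#' @return object of class `raman_ratio`: list with `ratio`,
#'   `normalized_Y`, `normalized_X` (amide-I heights after normalization)
#' @export
raman_orientation_ratio <- function(spec_Y, spec_X,
                                    ref_window = c(1440, 1460),
                                    amide_window = c(1660, 1680)) {
  norm_height <- function(spec) {
    x <- spec$wavenumber; y <- spec$intensity
    if (min(x) > ref_window[1] || max(x) < amide_window[2])
      stop_invalid("spectrum must cover %g-%g cm-1",
                   ref_window[1], amide_window[2])
    ref <- max(y[x >= ref_window[1] & x <= ref_window[2]])
    if (!is.finite(ref) || ref <= 0)
      stop_invalid("reference band intensity at 1450 cm-1 is not positive")
    amide <- max(y[x >= amide_window[1] & x <= amide_window[2]])
    amide / ref
  }
  ny <- norm_height(spec_Y)
  nx <- norm_height(spec_X)
  if (nx <= 0)
    stop_invalid("normalized amide-I intensity of the X spectrum is zero")
  structure(list(ratio = ny / nx, normalized_Y = ny, normalized_X = nx),
            class = "raman_ratio")
}

#' @export
print.raman_ratio <- function(x, ...) {
  cat(sprintf("Raman orientation ratio I = Y/X = %.4f (Y %.4f / X %.4f)\n",
              x$ratio, x$normalized_Y, x$normalized_X))
  invisible(x)
}
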