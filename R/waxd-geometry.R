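## Flat-detector geometry for wide-angle fiber diffraction. Pixels are
## mapped to scattering coordinates (q, chi): for a pixel at radius r (mm)
## from the beam center, 2*theta = arctan(r/L) and q = 4 pi sin(theta) /
## lambda; the azimuth chi is measured from the equator (chi = 0 is
## perpendicular to the fiber axis / meridian).

#' Construct a detector geometry
#'
#' @param wavelength_A X-ray wavelength in Angstrom (default 0.886, i.e.
#'   14 keV synchrotron radiation)
#' @param distance_mm sample-to-detector distance in mm (default 200)
#' @param pixel_mm square pixel edge in mm (default 0.172, a Pilatus-class
#'   detector)
#' @param center_px beam center as (row, col) pixel coordinates; `NULL`
#'   (default) places it at the image center at mapping time
#' @param meridian_deg detector azimuth of the meridian (fiber axis) in
#'   degrees, measured counter-clockwise from the +x (column) axis;
#'   default 90 (fiber vertical)
#' @return object of class `detector_geometry`
#' @export
detector_geometry <- function(wavelength_A = 0.886, distance_mm = 200,
                              pixel_mm = 0.172, center_px = NULL,
                              meridian_deg = 90) {
  check_scalar(wavelength_A, "wavelength_A", lower = 0, strict_lower = TRUE)
  check_scalar(distance_mm, "distance_mm", lower = 0, strict_lower = TRUE)
  check_scalar(pixel_mm, "pixel_mm", lower = 0, strict_lower = TRUE)
  check_scalar(meridian_deg, "meridian_deg")
  if (!is.null(center_px) && length(center_px) != 2L)
    stop_invalid("`center_px` must be (row, col) or NULL")
  structure(list(wavelength_A = wavelength_A, distance_mm = distance_mm,
                 pixel_mm = pixel_mm, center_px = center_px,
                 meridian_deg = meridian_deg),
            class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf(
    "detector: lambda %.4g A, L %.4g mm, pixel %.4g mm, meridian %g deg\n",
    x$wavelength_A, x$distance_mm, x$pixel_mm, x$meridian_deg))
  invisible(x)
}

#' Map detector pixels to scattering coordinates
#'
#' @param geometry a `detector_geometry`
#' @param dim image dimensions `(nrow, ncol)`
#' @return list of two `dim`-shaped matrices: `q` (A-1) and `chi`
#'   (degrees in `[0, 360)`, 0 on the equator), plus the resolved
#'   `center_px`
#' @export
map_pixels <- function(geometry, dim) {
  if (length(dim) != 2L || any(dim < 1))
    stop_invalid("`dim` must be (nrow, ncol)")
  center <- geometry$center_px
  if (is.null(center)) center <- (dim + 1) / 2

  row_off <- (seq_len(dim[1]) - center[1])             # +down in matrix
  col_off <- (seq_len(dim[2]) - center[2])
  dx <- matrix(col_off, dim[1], dim[2], byrow = TRUE)
  dy <- matrix(-row_off, dim[1], dim[2])               # +y points up
  r_mm <- sqrt(dx^2 + dy^2) * geometry$pixel_mm

  theta <- atan(r_mm / geometry$distance_mm) / 2
  q <- 4 * pi * sin(theta) / geometry$wavelength_A
  alpha <- atan2(dy, dx) * 180 / pi
  chi <- (alpha - (geometry$meridian_deg - 90)) %% 360
  list(q = q, chi = chi, center_px = center)
}

#' q value of a lattice spacing, and its detector radius
#'
#' @param d_nm lattice spacing in nm
#' @return scattering vector magnitude q = 2 pi / d in A-1
#' @export
d_to_q <- function(d_nm) 2 * pi / (d_nm * 10)

#' Detector radius of a diffraction ring
#'
#' @param geometry a `detector_geometry`
#' @param d_nm lattice spacing in nm
#' @return ring radius on the detector in mm
#' @export
ring_radius_mm <- function(geometry, d_nm) {
  two_theta <- 2 * asin(geometry$wavelength_A / (2 * d_nm * 10))
  geometry$distance_mm * tan(two_theta)
}
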