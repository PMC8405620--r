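## Synthetic oriented semi-crystalline fiber diffraction. The analytic
## intensity surface is
##   I(q, chi) = sum_k a_k G(q; q_k, w_k) h_k(chi)   (crystalline)
##             + sum_j b_j G(q; q_j, w_j)            (isotropic amorphous)
## with G area-normalized Gaussians in q, and h_k an equator-centered
## azimuthal Gaussian pair (unit height). Radial widths are obtained by
## inverting the Scherrer relation for the requested crystallite sizes;
## the azimuthal width is obtained by inverting Herman's orientation
## function for the requested f. Counts are Poisson-sampled on top of a
## flat air background.

#' Ground-truth parameter set for a synthetic fiber diffraction image
#'
#' Defaults parameterize a beta-sheet fiber: inter-sheet (200) spacing
#' 1.08 nm with crystallite size 1.08 nm along a, inter-strand (120)
#' spacing 0.46 nm with size 2.91 nm along b, 18 % crystallinity and
#' orientation parameter 0.76.
#'
#' @param d200_nm,d120_nm equatorial d-spacings in nm
#' @param Da_nm,Db_nm crystallite sizes along the a and b axes in nm
#' @param crystallinity crystalline area fraction in `[0, 1]` as measured
#'   on the equatorial sector profile at `sector_width_ref`
#' @param f orientation parameter in `[-0.5, 1]`
#' @param crystal_ratio relative (200):(120) measured areas
#' @param amorphous_centers,amorphous_fwhm,amorphous_areas two isotropic
#'   amorphous halos (q in A-1, relative areas)
#' @param orientation_iso_weight weight in `[0, 1)` of an isotropic
#'   (unoriented) crystalline term mixed into the azimuthal shape
#' @param scherrer_K Scherrer shape factor used for the width inversion
#' @param sector_width_ref sector width (degrees) at which `crystallinity`
#'   is defined
#' @param count_scale expected counts per unit model intensity
#' @param background_counts expected flat air-background counts per pixel
#' @param seed integer RNG seed
#' @return object of class `waxd_truth` (list of the above)
#' @export
waxd_truth <- function(d200_nm = 1.08, d120_nm = 0.46,
                       Da_nm = 1.08, Db_nm = 2.91,
                       crystallinity = 0.18, f = 0.76,
                       crystal_ratio = c(10, 8),
                       amorphous_centers = c(0.80, 1.60),
                       amorphous_fwhm = c(0.90, 0.90),
                       amorphous_areas = c(40, 42),
                       orientation_iso_weight = 0,
                       scherrer_K = 0.9,
                       sector_width_ref = 25,
                       count_scale = 40,
                       background_counts = 10,
                       seed = 1) {
  for (nm in c("d200_nm", "d120_nm", "Da_nm", "Db_nm"))
    check_scalar(get(nm), nm, lower = 0, strict_lower = TRUE)
  check_scalar(crystallinity, "crystallinity", lower = 0, upper = 1)
  if (f < -0.5 || f > 1)
    stop_invalid(paste0("requested f = %g is outside the achievable range ",
                        "[-0.5, 1] of Herman's orientation function"), f)
  check_scalar(orientation_iso_weight, "orientation_iso_weight",
               lower = 0, upper = 1, strict_upper = TRUE)
  check_scalar(count_scale, "count_scale", lower = 0, strict_lower = TRUE)
  check_scalar(background_counts, "background_counts", lower = 0)
  structure(as.list(environment())[c(
    "d200_nm", "d120_nm", "Da_nm", "Db_nm", "crystallinity", "f",
    "crystal_ratio", "amorphous_centers", "amorphous_fwhm",
    "amorphous_areas", "orientation_iso_weight", "scherrer_K",
    "sector_width_ref", "count_scale", "background_counts", "seed")],
    class = "waxd_truth")
}

# Radial FWHM (A-1) that the Scherrer chain assigns to a crystallite of
# size D (nm) diffracting at q (A-1): inverse of analyze_peak().
scherrer_fwhm_q <- function(D_nm, q, wavelength_A, K = 0.9) {
  theta <- asin(wavelength_A * q / (4 * pi))
  beta <- K * wavelength_A / (D_nm * 10 * cos(theta))
  (4 * pi / wavelength_A) * sin(beta / 2)
}

# Azimuthal FWHM (degrees) for orientation parameter f, assuming equal
# (200)/(120) widths in Herman's relation: f = 1 - 3 sin^2(0.4 w).
herman_fwhm_deg <- function(f) {
  s <- (1 - f) / 3
  asin(sqrt(s)) / 0.4 * 180 / pi
}

# Unit-height equatorial azimuthal shape (lobes at chi = 0 and 180),
# optionally mixed with an isotropic term.
azimuthal_shape <- function(chi, fwhm_deg, iso_weight = 0) {
  if (fwhm_deg <= 0) return(as.numeric(chi %% 180 == 0))
  lobes <- exp(-4 * log(2) * (angle_diff(chi, 0) / fwhm_deg)^2) +
    exp(-4 * log(2) * (angle_diff(chi, 180) / fwhm_deg)^2)
  (1 - iso_weight) * lobes + iso_weight
}

# Component table of the analytic surface: per-component q center, radial
# FWHM, surface amplitude a (area per unit azimuthal height), measured
# sector area, and azimuthal FWHM for crystalline rows.
waxd_model_components <- function(truth, wavelength_A) {
  q200 <- d_to_q(truth$d200_nm)
  q120 <- d_to_q(truth$d120_nm)
  fw200 <- scherrer_fwhm_q(truth$Da_nm, q200, wavelength_A,
                           truth$scherrer_K)
  fw120 <- scherrer_fwhm_q(truth$Db_nm, q120, wavelength_A,
                           truth$scherrer_K)
  w_chi <- herman_fwhm_deg(truth$f)

  # mean azimuthal height inside the reference equatorial sector
  chi_fine <- seq(-truth$sector_width_ref / 2, truth$sector_width_ref / 2,
                  length.out = 501)
  m_sector <- mean(azimuthal_shape(chi_fine, w_chi,
                                   truth$orientation_iso_weight))

  b <- truth$amorphous_areas
  c_total <- if (truth$crystallinity >= 1) Inf else
    truth$crystallinity / (1 - truth$crystallinity) * sum(b)
  c_meas <- c_total * truth$crystal_ratio / sum(truth$crystal_ratio)

  data.frame(
    label = c("eq200", "eq120", "amorphous1", "amorphous2"),
    crystalline = c(TRUE, TRUE, FALSE, FALSE),
    q_center = c(q200, q120, truth$amorphous_centers),
    fwhm_q = c(fw200, fw120, truth$amorphous_fwhm),
    amplitude = c(c_meas / m_sector, b),
    sector_area = c(c_meas, b),
    chi_fwhm = c(w_chi, w_chi, NA, NA)
  )
}

#' Analytic intensity surface of a synthetic fiber pattern
#'
#' Evaluates the noise-free model intensity (per unit `count_scale`,
#' background excluded) at given scattering coordinates. This is the exact
#' surface that [gen_waxd_image()] Poisson-samples.
#'
#' @param truth a `waxd_truth`
#' @param q scattering vector magnitudes (A-1)
#' @param chi azimuths in degrees (0 = equator)
#' @param wavelength_A X-ray wavelength used for the Scherrer inversion
#' @return model intensities, same shape as `q`
#' @export
waxd_surface <- function(truth, q, chi, wavelength_A = 0.886) {
  comp <- waxd_model_components(truth, wavelength_A)
  out <- 0 * q
  for (k in seq_len(nrow(comp))) {
    radial <- gaussian_peak(q, comp$q_center[k], comp$fwhm_q[k],
                            comp$amplitude[k])
    if (comp$crystalline[k])
      radial <- radial * azimuthal_shape(chi, comp$chi_fwhm[k],
                                         truth$orientation_iso_weight)
    out <- out + radial
  }
  out
}

#' Simulate a 2D fiber diffraction image
#'
#' Poisson-samples the analytic surface of `truth` onto a detector grid,
#' together with a separately sampled flat air-background exposure. The
#' generator is a pure function of `(truth, geometry, dim)`: identical
#' inputs give bit-identical images.
#'
#' @param truth a `waxd_truth`
#' @param geometry a `detector_geometry`
#' @param dim image dimensions `(nrow, ncol)`, default 1024 x 1024
#' @return object of class `waxd_image`: list with `counts` and
#'   `background` matrices, `geometry`, and the generating `truth`
#' @export
gen_waxd_image <- function(truth, geometry = detector_geometry(),
                           dim = c(1024L, 1024L)) {
  coords <- map_pixels(geometry, dim)
  lambda <- truth$count_scale *
    waxd_surface(truth, coords$q, coords$chi, geometry$wavelength_A) +
    truth$background_counts

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(truth$seed)
  counts <- matrix(stats::rpois(length(lambda), lambda), dim[1], dim[2])
  set.seed(truth$seed + 1L)
  background <- matrix(
    stats::rpois(length(lambda), truth$background_counts), dim[1], dim[2])

  structure(list(counts = counts, background = background,
                 geometry = geometry, truth = truth),
            class = "waxd_image")
}

#' @export
print.waxd_image <- function(x, ...) {
  cat(sprintf("waxd_image: %d x %d pixels, total %.3g counts\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  print(x$geometry)
  invisible(x)
}
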