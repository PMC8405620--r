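## Peak deconvolution of 1D diffraction profiles and the derived crystal
## metrics: crystallinity from equatorial component areas, d-spacings and
## Scherrer crystallite sizes from radial peak centers/widths, Herman's
## orientation parameter from azimuthal crystalline widths.

# Generic bounded multi-Gaussian least squares. `comp` is a data frame with
# columns label, center, fwhm, area and matching *_lo / *_hi bounds.
fit_gaussian_mixture <- function(x, y, comp, offset = TRUE) {
  scale <- max(abs(y))
  if (scale <= 0) stop_invalid("profile has no signal to fit")
  ys <- y / scale
  n <- nrow(comp)

  pack <- function(centers, fwhms, areas, off)
    c(centers, fwhms, areas, if (offset) off)
  model <- function(par) {
    ctr <- par[seq_len(n)]
    fw <- par[n + seq_len(n)]
    ar <- par[2 * n + seq_len(n)]
    off <- if (offset) par[3 * n + 1L] else 0
    out <- rep(off, length(x))
    for (k in seq_len(n)) out <- out + gaussian_peak(x, ctr[k], fw[k], ar[k])
    out
  }
  objective <- function(par) sum((model(par) - ys)^2)

  init <- pack(comp$center, comp$fwhm, comp$area / scale, 0)
  lower <- pack(comp$center_lo, comp$fwhm_lo, rep(0, n), -0.2)
  upper <- pack(comp$center_hi, comp$fwhm_hi, rep(Inf, n), 0.2)
  opt <- stats::optim(init, objective, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 1000, factr = 1e4))
  if (!is.finite(opt$value))
    stop_invalid("profile fit did not converge (residual %g)", opt$value)

  par <- opt$par
  list(
    components = data.frame(
      label = comp$label,
      center = par[seq_len(n)],
      fwhm = par[n + seq_len(n)],
      area = par[2 * n + seq_len(n)] * scale,
      height = par[2 * n + seq_len(n)] * scale /
        (par[n + seq_len(n)] * FWHM_TO_SD * sqrt(2 * pi))
    ),
    offset = if (offset) par[3 * n + 1L] * scale else 0,
    rss = opt$value * scale^2,
    relative_residual = sqrt(opt$value / sum(ys^2)),
    fitted = model(par) * scale
  )
}

# Default component tables for radial fits (q in A-1). Crystalline centers
# start from the beta-sheet spacings d = 1.08 and 0.46 nm and are bounded
# within +/- 15 %; amorphous components are forced broader than any
# admissible crystalline peak.
radial_component_table <- function(axis, total_area) {
  q200 <- d_to_q(1.08)
  q120 <- d_to_q(0.46)
  tab <- data.frame(
    label = c("eq200", "eq120", "amorphous1", "amorphous2"),
    center = c(q200, q120, 0.80, 1.60),
    center_lo = c(q200 * 0.85, q120 * 0.85, 0.40, 1.10),
    center_hi = c(q200 * 1.15, q120 * 1.15, 1.10, 2.30),
    fwhm = c(0.40, 0.18, 1.00, 1.00),
    fwhm_lo = c(0.05, 0.05, 0.60, 0.60),
    fwhm_hi = c(0.65, 0.65, 2.50, 2.50),
    area = total_area * c(0.10, 0.10, 0.40, 0.40)
  )
  if (axis == "meridian") {
    tab <- rbind(tab, data.frame(
      label = "mer002", center = 1.30, center_lo = 0.70, center_hi = 2.00,
      fwhm = 0.20, fwhm_lo = 0.05, fwhm_hi = 0.65,
      area = total_area * 0.05))
    tab$label[1:2] <- c("mer200", "mer120")
  }
  tab
}

#' Deconvolve a radial diffraction profile into Gaussian components
#'
#' Fits the equatorial model (200) + (120) + two amorphous halos (the
#' meridian model adds a free-center (002) reflection) by bounded nonlinear
#' least squares. Crystalline centers are initialized at `2 pi / d` for
#' d = 1.08 and 0.46 nm and constrained within 15 percent; amorphous widths
#' are constrained broader than the crystalline width bound so that a
#' crystalline/amorphous swap cannot occur. A fit in which a crystalline
#' component still ends up broader than an amorphous one is refit from a
#' perturbed start and rejected if the inversion persists.
#'
#' @param profile a `radial_profile` (or data frame with `q`, `intensity`)
#' @param axis `"equator"` or `"meridian"`; default taken from the profile
#' @return object of class `radial_fit`: list with `components` (label,
#'   center, fwhm, area, height), `offset`, `relative_residual`, `fitted`
#' @export
fit_radial <- function(profile, axis = NULL) {
  if (is.null(axis)) axis <- attr(profile, "axis")
  if (is.null(axis)) axis <- "equator"
  axis <- match.arg(axis, c("equator", "meridian"))
  x <- profile$q
  y <- profile$intensity
  total_area <- max(trapz_area(x, pmax(y, 0)), max(y) * 0.1)

  comp <- radial_component_table(axis, total_area)
  fit <- fit_gaussian_mixture(x, y, comp)

  crystalline <- grepl("^(eq|mer)[0-9]", fit$components$label)
  inversion <- function(f) {
    significant <- f$components$area > 1e-6 * sum(f$components$area)
    cr <- f$components$fwhm[crystalline & significant]
    am <- f$components$fwhm[!crystalline & significant]
    length(cr) > 0 && length(am) > 0 && max(cr) > min(am)
  }
  if (inversion(fit)) {
    comp2 <- comp
    comp2$fwhm <- comp$fwhm * c(0.6, 0.6, 1.4, 1.4, 0.6)[seq_len(nrow(comp))]
    fit2 <- fit_gaussian_mixture(x, y, comp2)
    if (inversion(fit2))
      stop_invalid(paste0("radial fit rejected: crystalline component ",
                          "broader than an amorphous component after refit"))
    fit <- fit2
  }
  structure(c(fit, list(axis = axis)), class = "radial_fit")
}

#' @export
print.radial_fit <- function(x, ...) {
  cat(sprintf("radial fit (%s), relative residual %.2e\n",
              x$axis, x$relative_residual))
  print(x$components, row.names = FALSE)
  invisible(x)
}

#' Crystallinity from equatorial component areas
#'
#' Ratio of the summed integrated areas of the (200) and (120) equatorial
#' crystalline peaks to the total area of crystalline plus the two
#' amorphous components.
#'
#' @param fit a `radial_fit` from an equatorial profile, or its
#'   `components` data frame
#' @return crystalline fraction in `[0, 1]`
#' @export
crystallinity <- function(fit) {
  comp <- if (is.data.frame(fit)) fit else fit$components
  need <- c("eq200", "eq120", "amorphous1", "amorphous2")
  if (!all(need %in% comp$label))
    stop_invalid("missing components: %s",
                 paste(setdiff(need, comp$label), collapse = ", "))
  a <- function(lbl) comp$area[comp$label == lbl][1L]
  cryst <- a("eq200") + a("eq120")
  cryst / (cryst + a("amorphous1") + a("amorphous2"))
}

#' d-spacing and Scherrer crystallite size of a fitted reflection
#'
#' From a peak center PC and width FWHM (both in A-1), computes the lattice
#' spacing `d = 2 pi / PC`, the Bragg angle
#' `theta = arcsin(lambda PC / 4 pi)`, the width in radians
#' `beta = 2 arcsin(lambda FWHM / 4 pi)`, and the Scherrer size
#' `D = K lambda / (beta cos theta)`.
#'
#' @param fit one row of a radial fit's `components` (or any list with
#'   `center` and `fwhm` in A-1)
#' @param wavelength_A X-ray wavelength in Angstrom (default 0.886)
#' @param K Scherrer shape factor (default 0.9)
#' @return list with `d_nm`, `D_nm`, `theta_deg`, `beta_rad`
#' @export
analyze_peak <- function(fit, wavelength_A = 0.886, K = 0.9) {
  pc <- fit$center[1L]
  fwhm <- fit$fwhm[1L]
  check_scalar(pc, "center", lower = 0, strict_lower = TRUE)
  if (!is.finite(fwhm) || fwhm <= 0)
    stop_invalid("FWHM = %g implies an unresolvable (infinite) crystallite",
                 fwhm)
  if (wavelength_A * fwhm / (4 * pi) > 1 || wavelength_A * pc / (4 * pi) > 1)
    stop_invalid("wavelength %g A and q values exceed the arcsin domain",
                 wavelength_A)
  theta <- asin(wavelength_A * pc / (4 * pi))
  beta <- 2 * asin(wavelength_A * fwhm / (4 * pi))
  list(d_nm = 2 * pi / pc / 10,
       D_nm = K * wavelength_A / (beta * cos(theta)) / 10,
       theta_deg = theta * 180 / pi,
       beta_rad = beta)
}

# Two-lobe azimuthal model used by fit_azimuthal
azimuthal_pair <- function(chi, center, fwhm) {
  exp(-4 * log(2) * (angle_diff(chi, center) / fwhm)^2) +
    exp(-4 * log(2) * (angle_diff(chi, center + 180) / fwhm)^2)
}

#' Deconvolve an azimuthal profile into crystalline and amorphous parts
#'
#' Fits, over the full 0-360 degrees, an equator-centered narrow
#' crystalline Gaussian pair plus a broad amorphous Gaussian pair and a
#' constant term. With `include_subsidiary = TRUE`, a symmetric pair of
#' satellite Gaussians (residual intensity from the (201) reflections) is
#' added at `center +/- delta`.
#'
#' @param profile an `azimuthal_profile` (or data frame with `chi`,
#'   `intensity`) spanning at least 180 degrees
#' @param include_subsidiary add symmetric (201) satellite components
#' @return object of class `azimuthal_fit`: list with `components`
#'   (label, center, fwhm in degrees, amplitude, area), `offset`,
#'   `relative_residual`, `fitted`
#' @export
fit_azimuthal <- function(profile, include_subsidiary = FALSE) {
  chi <- profile$chi
  y <- profile$intensity
  if (diff(range(chi)) < 180)
    stop_invalid("azimuthal profile must span at least 180 degrees")
  scale <- max(y)
  if (scale <= 0) stop_invalid("azimuthal profile has no signal")
  ys <- y / scale

  # par: center, narrow fwhm, narrow amp, broad fwhm, broad amp, offset
  #      [, delta, sat fwhm, sat amp]
  model <- function(p) {
    out <- p[3] * azimuthal_pair(chi, p[1], p[2]) +
      p[5] * azimuthal_pair(chi, p[1], p[4]) + p[6]
    if (include_subsidiary)
      out <- out + p[9] * (azimuthal_pair(chi, p[1] + p[7], p[8]) +
                             azimuthal_pair(chi, p[1] - p[7], p[8]))
    out
  }
  objective <- function(p) sum((model(p) - ys)^2)

  init <- c(0, 40, 0.8, 180, 0.1, min(ys))
  lower <- c(-20, 5, 0, 90, 0, 0)
  upper <- c(20, 89, Inf, 400, Inf, 1)
  if (include_subsidiary) {
    init <- c(init, 35, 20, 0.1)
    lower <- c(lower, 15, 5, 0)
    upper <- c(upper, 80, 60, Inf)
  }
  opt <- stats::optim(init, objective, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 1000, factr = 1e4))
  p <- opt$par
  if (p[2] >= p[4])
    stop_invalid("azimuthal fit rejected: narrow/broad width inversion")

  # both lobes; one height-amp Gaussian has area amp * fwhm * 1.0645
  lobe_area <- function(amp, fwhm) 2 * amp * fwhm * FWHM_TO_SD * sqrt(2 * pi)
  comp <- data.frame(
    label = c("crystalline-azimuthal", "amorphous-azimuthal"),
    center = c(p[1], p[1]),
    fwhm = c(p[2], p[4]),
    amplitude = c(p[3], p[5]) * scale,
    area = c(lobe_area(p[3], p[2]), lobe_area(p[5], p[4])) * scale)
  if (include_subsidiary)
    comp <- rbind(comp, data.frame(
      label = "subsidiary-201", center = p[7], fwhm = p[8],
      amplitude = p[9] * scale, area = 2 * lobe_area(p[9], p[8]) * scale))

  structure(list(components = comp, offset = p[6] * scale,
                 relative_residual = sqrt(opt$value / sum(ys^2)),
                 fitted = model(p) * scale),
            class = "azimuthal_fit")
}

#' @export
print.azimuthal_fit <- function(x, ...) {
  cat(sprintf("azimuthal fit, relative residual %.2e\n",
              x$relative_residual))
  print(x$components, row.names = FALSE)
  invisible(x)
}

#' Herman's orientation parameter from azimuthal crystalline widths
#'
#' Evaluates `<cos^2 phi> = 1 - 0.8 sin^2(0.4 FWHM_200)
#' - 1.2 sin^2(0.4 FWHM_120)` with the `0.4 x FWHM` arguments in degrees,
#' then `f = (3 <cos^2 phi> - 1) / 2`. `f` is 1 for perfect axial
#' alignment and 0 for an isotropic distribution.
#'
#' @param fwhm_200 azimuthal FWHM of the (200) crystalline component,
#'   degrees
#' @param fwhm_120 azimuthal FWHM of the (120) crystalline component,
#'   degrees
#' @return list with `f` and `cos2_phi`
#' @export
herman_orientation <- function(fwhm_200, fwhm_120) {
  check_scalar(fwhm_200, "fwhm_200", lower = 0)
  check_scalar(fwhm_120, "fwhm_120", lower = 0)
  s <- function(w) sin(0.4 * w * pi / 180)^2
  cos2 <- 1 - 0.8 * s(fwhm_200) - 1.2 * s(fwhm_120)
  f <- (3 * cos2 - 1) / 2
  if (f < -0.5 || f > 1)
    stop_invalid(paste0("f = %g is outside [-0.5, 1]; check that the ",
                        "azimuthal FWHMs are in degrees"), f)
  list(f = f, cos2_phi = cos2)
}

#' End-to-end analysis of a fiber diffraction image
#'
#' Runs the full reduction chain: equatorial sector integration, radial
#' Gaussian deconvolution, crystallinity, per-reflection d-spacing and
#' Scherrer size, azimuthal profiles over each crystalline reflection's
#' radial band, azimuthal deconvolution, and Herman's orientation
#' parameter.
#'
#' @param image a `waxd_image`
#' @param sector_width equatorial sector width in degrees (default 25)
#' @param q_step radial bin width in A-1 (default 0.005)
#' @param chi_step azimuthal bin width in degrees (default 2)
#' @param K Scherrer shape factor (default 0.9)
#' @param include_subsidiary add (201) satellites to the (120) azimuthal
#'   fit
#' @param band_half_width half-width of each reflection's azimuthal q band
#'   as a fraction of its fitted radial FWHM (default 0.25)
#' @return object of class `crystal_analysis`: list with `crystallinity`,
#'   `d200_nm`, `d120_nm`, `Da_nm`, `Db_nm`, `f_crystal`, `cos2_phi`,
#'   azimuthal crystalline FWHMs, and the intermediate profiles and fits
#' @export
waxd_analyze <- function(image, sector_width = 25, q_step = 0.005,
                         chi_step = 2, K = 0.9,
                         include_subsidiary = FALSE,
                         band_half_width = 0.25) {
  prof_eq <- sector_integrate(image, "equator", sector_width, q_step)
  fit_eq <- fit_radial(prof_eq, "equator")
  comp <- fit_eq$components
  row200 <- comp[comp$label == "eq200", ]
  row120 <- comp[comp$label == "eq120", ]
  lambda <- image$geometry$wavelength_A

  pk200 <- analyze_peak(row200, lambda, K)
  pk120 <- analyze_peak(row120, lambda, K)

  band <- function(row) row$center +
    c(-1, 1) * max(band_half_width * row$fwhm, 3 * q_step)
  az200 <- azimuthal_profile(image, band(row200), chi_step)
  az120 <- azimuthal_profile(image, band(row120), chi_step)
  fit_az200 <- fit_azimuthal(az200)
  fit_az120 <- fit_azimuthal(az120, include_subsidiary = include_subsidiary)
  w200 <- fit_az200$components$fwhm[
    fit_az200$components$label == "crystalline-azimuthal"]
  w120 <- fit_az120$components$fwhm[
    fit_az120$components$label == "crystalline-azimuthal"]
  orient <- herman_orientation(w200, w120)

  structure(list(
    crystallinity = crystallinity(fit_eq),
    d200_nm = pk200$d_nm, d120_nm = pk120$d_nm,
    Da_nm = pk200$D_nm, Db_nm = pk120$D_nm,
    f_crystal = orient$f, cos2_phi = orient$cos2_phi,
    azimuthal_fwhm_200 = w200, azimuthal_fwhm_120 = w120,
    scherrer_K = K,
    radial_profile = prof_eq, radial_fit = fit_eq,
    azimuthal_profiles = list(eq200 = az200, eq120 = az120),
    azimuthal_fits = list(eq200 = fit_az200, eq120 = fit_az120)
  ), class = "crystal_analysis")
}

#' @export
print.crystal_analysis <- function(x, ...) {
  cat(sprintf(paste0(
    "WAXD analysis:\n",
    "  crystallinity  %.1f %%\n",
    "  d200 = %.3f nm, d120 = %.3f nm\n",
    "  Da   = %.2f nm, Db   = %.2f nm (Scherrer, K = %.2g)\n",
    "  f_crystal = %.3f (azimuthal FWHM %.1f / %.1f deg)\n"),
    100 * x$crystallinity, x$d200_nm, x$d120_nm, x$Da_nm, x$Db_nm,
    x$scherrer_K, x$f_crystal, x$azimuthal_fwhm_200, x$azimuthal_fwhm_120))
  invisible(x)
}
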