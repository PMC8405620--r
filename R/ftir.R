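## FTIR amide-I band deconvolution. The amide-I envelope (1600-1700 cm-1)
## is modeled as a sum of eleven Lorentzian components at fixed,
## literature-assigned centers; component areas give the secondary-structure
## fractions. Fitting uses variable projection: widths are optimized by
## box-constrained quasi-Newton steps while the non-negative component areas
## are solved exactly by NNLS at every step.

#' Fixed amide-I component centers (cm-1)
#'
#' The eleven component positions used for amide-I deconvolution.
#' @return numeric vector of 11 centers
#' @export
amide_centers <- function() {
  c(1610, 1618.5, 1624.5, 1632.5, 1642, 1651, 1659, 1666.5, 1678,
    1690.5, 1700)
}

#' Default center-to-structure assignment for amide-I components
#'
#' Maps each fixed component center to one of the four secondary-structure
#' classes, following standard amide-I correlation ranges: low- and
#' high-wavenumber components to beta-sheet, 1642 to random coil, 1651/1659
#' to alpha-helix, 1666.5/1678 to beta-turn. The assignment can be replaced
#' by any named vector `center -> class`.
#'
#' @return named character vector; names are centers, values are classes
#'   (`"beta_sheet"`, `"random_coil"`, `"alpha_helix"`, `"beta_turn"`)
#' @export
amide_assignment <- function() {
  stats::setNames(
    c("beta_sheet", "beta_sheet", "beta_sheet", "beta_sheet",
      "random_coil", "alpha_helix", "alpha_helix", "beta_turn",
      "beta_turn", "beta_sheet", "beta_sheet"),
    as.character(amide_centers()))
}

#' Simulate an FTIR spectrum with known secondary-structure fractions
#'
#' Builds a spectrum as a sum of Lorentzians at the eleven fixed amide-I
#' centers, with the total area of each structure class proportional to
#' `class_fractions` (split evenly among the class's components), plus a
#' convex quadratic baseline and optional Gaussian noise. The generating
#' truth is attached as attribute `truth`.
#'
#' @param class_fractions named fractions over the four structure classes,
#'   summing to 1 (classes with zero weight may be omitted)
#' @param widths component FWHM in cm-1, recycled over the 11 components
#'   (default 16)
#' @param baseline_params numeric `(offset, slope, curvature)` of the convex
#'   baseline `b0 + b1*(x - 1600) + b2*(x - 1600)^2`, curvature >= 0
#' @param noise_sd additive noise sd (intensity units)
#' @param seed integer RNG seed
#' @param wavenumber sampling grid in cm-1 (default 1415-1780 by 1)
#' @param total_area total amide-I area (default 100)
#' @return a `spectrum` with attribute `truth` (list of per-class fractions,
#'   per-component areas and widths)
#' @export
gen_ftir_spectrum <- function(class_fractions, widths = 16,
                              baseline_params = c(0.02, 0, 2e-6),
                              noise_sd = 0, seed = 1,
                              wavenumber = seq(1415, 1780, by = 1),
                              total_area = 100) {
  assign_map <- amide_assignment()
  classes <- unique(unname(assign_map))
  unknown <- setdiff(names(class_fractions), classes)
  if (length(unknown) > 0L)
    stop_invalid("unknown structure class: %s (known: %s)",
                 paste(unknown, collapse = ", "),
                 paste(classes, collapse = ", "))
  fr <- stats::setNames(rep(0, length(classes)), classes)
  fr[names(class_fractions)] <- unlist(class_fractions)
  if (abs(sum(fr) - 1) > 1e-6)
    stop_invalid("class fractions sum to %.8f, not 1", sum(fr))
  if (any(fr < 0)) stop_invalid("class fractions must be non-negative")
  check_scalar(noise_sd, "noise_sd", lower = 0)
  if (length(baseline_params) != 3L || baseline_params[3] < 0)
    stop_invalid("`baseline_params` must be (offset, slope, curvature >= 0)")

  centers <- amide_centers()
  widths <- rep_len(widths, length(centers))
  areas <- vapply(seq_along(centers), function(k) {
    cls <- assign_map[[as.character(centers[k])]]
    total_area * fr[[cls]] / sum(assign_map == cls)
  }, numeric(1))

  y <- rep(0, length(wavenumber))
  for (k in seq_along(centers))
    y <- y + lorentzian_peak(wavenumber, centers[k], widths[k], areas[k])
  dx <- wavenumber - 1600
  y <- y + baseline_params[1] + baseline_params[2] * dx +
    baseline_params[3] * dx^2

  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    y <- y + stats::rnorm(length(y), 0, noise_sd)
  }

  out <- new_spectrum(wavenumber, y, modality = "ftir")
  attr(out, "truth") <- list(class_fractions = fr, areas = areas,
                             widths = widths, centers = centers)
  out
}

# Unit-area Lorentzian design matrix for the current width vector
amide_design <- function(x, centers, widths) {
  vapply(seq_along(centers),
         function(k) lorentzian_peak(x, centers[k], widths[k], 1),
         numeric(length(x)))
}

#' Deconvolve the amide-I band into secondary-structure fractions
#'
#' Fits eleven Lorentzians with fixed centers over 1600-1700 cm-1 to a
#' baseline-subtracted spectrum. Component FWHMs are bounded in
#' `fwhm_bounds`; areas are constrained non-negative and solved by NNLS at
#' every width iterate (variable projection). Fractions are analytic
#' component areas summed per structure class and normalized.
#'
#' @param spec a baseline-subtracted `spectrum` covering 1600-1700 cm-1
#' @param assignment named vector mapping component center to structure
#'   class; default [amide_assignment()]
#' @param fwhm_bounds length-2 FWHM bounds in cm-1 (default `c(5, 40)`)
#' @param band fitted wavenumber interval (default `c(1600, 1700)`)
#' @param starts vector of initial FWHM guesses tried in turn; the best
#'   converged fit is kept
#' @return object of class `amide_fit`: list with `components` (data frame:
#'   center, fwhm, area, class), `fractions` (named, sums to 1),
#'   `beta_sheet_pct`, `residual_norm` and `relative_residual`
#' @export
deconvolve_amide_I <- function(spec, assignment = amide_assignment(),
                               fwhm_bounds = c(5, 40),
                               band = c(1600, 1700),
                               starts = c(20, 12, 30)) {
  x <- spec$wavenumber
  y <- spec$intensity
  if (min(x) > band[1] || max(x) < band[2])
    stop_invalid("spectrum must cover %g-%g cm-1", band[1], band[2])
  keep <- x >= band[1] & x <= band[2]
  x <- x[keep]; y <- y[keep]
  y_scale <- max(abs(y))
  if (y_scale > 0) y <- y / y_scale   # scale-free optimization path
  centers <- as.numeric(names(assignment))
  if (any(is.na(centers)))
    stop_invalid("`assignment` names must be numeric component centers")

  nnls_areas <- function(widths) {
    A <- amide_design(x, centers, widths)
    sol <- pracma::lsqnonneg(A, y)
    list(areas = sol$x, rss = sum((A %*% sol$x - y)^2))
  }
  objective <- function(widths) nnls_areas(widths)$rss

  best <- NULL
  for (w0 in starts) {
    opt <- stats::optim(rep(w0, length(centers)), objective,
                        method = "L-BFGS-B",
                        lower = fwhm_bounds[1], upper = fwhm_bounds[2],
                        control = list(maxit = 400, factr = 1e4))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  total_sq <- sum(y^2)
  if (!is.finite(best$value) || total_sq <= 0)
    stop_invalid("amide-I fit failed: degenerate band (total signal %g)",
                 total_sq)

  sol <- nnls_areas(best$par)
  areas <- sol$areas
  if (sum(areas) <= 0)
    stop_invalid("amide-I fit failed: all component areas are zero")

  cls <- unname(assignment)
  fractions <- vapply(unique(cls), function(cl)
    sum(areas[cls == cl]) / sum(areas), numeric(1))
  names(fractions) <- unique(cls)

  structure(list(
    components = data.frame(center = centers, fwhm = best$par,
                            area = areas * y_scale, class = cls),
    fractions = fractions,
    beta_sheet_pct = 100 * sum(fractions[names(fractions) == "beta_sheet"]),
    residual_norm = sqrt(sol$rss) * y_scale,
    relative_residual = sqrt(sol$rss / total_sq)
  ), class = "amide_fit")
}

#' @export
print.amide_fit <- function(x, ...) {
  cat("Amide-I deconvolution (11 Lorentzians):\n")
  for (cl in names(x$fractions))
    cat(sprintf("  %-12s %5.1f %%\n", cl, 100 * x$fractions[[cl]]))
  cat(sprintf("  relative residual %.2e\n", x$relative_residual))
  invisible(x)
}
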