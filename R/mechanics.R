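## Fiber tensile and cyclic mechanics. Force-displacement traces from a
## constant-crosshead-speed pull test are converted to engineering stress
## and strain; the summary extracts modulus (least-squares slope over the
## initial elastic window), ultimate strength, breaking strain (first 90 %
## drop from peak stress), and toughness (area under the curve to the
## break, in MJ/m3 -- numerically identical to MPa times strain). Cyclic
## loops yield damping capacity (hysteresis area over loading area) and
## damping energy (hysteresis area per initial volume).

#' Elastic-plastic forward-model parameters for synthetic pull tests
#'
#' The loading path is linear elastic to the yield strain, then power-law
#' hardening: `sigma = E eps` for `eps <= eps_y`, and
#' `sigma = sigma_y + h (eps - eps_y)^m` above. Unloading is linear with
#' modulus `E_u`, leaving a permanent set. Defaults mimic a stiff,
#' extensible semi-crystalline protein fiber: 4.2 GPa modulus, elastic to
#' 1.6 % strain, breaking at 47 % strain with ~378 MPa strength, and an
#' unload modulus of 5.12 GPa, which puts the damping capacity of a purely
#' elastic cycle at `1 - E/E_u`, about 18 percent. An unload modulus below
#' `E` would place the unload path above the elastic load path; that is
#' rejected.
#'
#' @param E elastic modulus in GPa
#' @param eps_y yield strain (fraction)
#' @param h hardening coefficient in MPa; `NULL` picks h so that the
#'   loading path reaches `uts` at `eps_b`
#' @param m hardening exponent (0 < m <= 1)
#' @param E_u unload modulus in GPa
#' @param eps_b breaking strain (fraction), > `eps_y`
#' @param uts ultimate tensile strength in MPa used to derive `h`
#' @param noise_sd force noise sd as a fraction of peak force
#' @param seed integer RNG seed
#' @return object of class `mech_params`
#' @export
mech_params <- function(E = 4.2, eps_y = 0.016, h = NULL, m = 0.5,
                        E_u = 5.12, eps_b = 0.47, uts = 378,
                        noise_sd = 0, seed = 1) {
  check_scalar(E, "E", lower = 0, strict_lower = TRUE)
  if (E_u < E)
    stop_invalid(paste0("unload modulus E_u = %g GPa is below E = %g GPa: ",
                        "the unload path would exceed the load path"),
                 E_u, E)
  check_scalar(eps_y, "eps_y", lower = 0, strict_lower = TRUE)
  check_scalar(eps_b, "eps_b", lower = eps_y, strict_lower = TRUE)
  check_scalar(m, "m", lower = 0, upper = 1, strict_lower = TRUE)
  check_scalar(E_u, "E_u", lower = 0, strict_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  sigma_y <- E * 1000 * eps_y
  if (is.null(h)) {
    if (uts <= sigma_y)
      stop_invalid("uts = %g MPa is below the yield stress %g MPa",
                   uts, sigma_y)
    h <- (uts - sigma_y) / (eps_b - eps_y)^m
  }
  check_scalar(h, "h", lower = 0)
  structure(list(E = E, eps_y = eps_y, h = h, m = m, E_u = E_u,
                 eps_b = eps_b, noise_sd = noise_sd, seed = seed),
            class = "mech_params")
}

# Loading-path stress (MPa) at strain eps for given mech_params
load_path_stress <- function(params, eps) {
  E_mpa <- params$E * 1000
  sigma_y <- E_mpa * params$eps_y
  ifelse(eps <= params$eps_y, E_mpa * eps,
         sigma_y + params$h * pmax(eps - params$eps_y, 0)^params$m)
}

# Closed-form area under the loading path from 0 to eps (MPa = MJ/m3)
load_path_area <- function(params, eps) {
  E_mpa <- params$E * 1000
  sigma_y <- E_mpa * params$eps_y
  if (eps <= params$eps_y) return(0.5 * E_mpa * eps^2)
  d <- eps - params$eps_y
  0.5 * E_mpa * params$eps_y^2 + sigma_y * d +
    params$h / (params$m + 1) * d^(params$m + 1)
}

#' Simulate a monotonic tensile trace to failure
#'
#' Loads along the elastic-plastic model path at constant crosshead speed
#' to the breaking strain, then appends an instantaneous >90 percent stress
#' drop. Stress is converted to force through the fiber cross-section and
#' strain to displacement through the gauge length.
#'
#' @param params a `mech_params`
#' @param diameter_um fiber diameter in micrometers
#' @param gauge_mm gauge length in mm (default 5)
#' @param speed_mm_min crosshead speed in mm/min (default 10)
#' @param rate_hz sampling rate in Hz (default 50)
#' @return object of class `mech_trace`: data frame with `time_s`,
#'   `displacement_mm`, `force_N`, plus attributes `diameter_um`,
#'   `gauge_mm`, and `truth` (modulus, uts, breaking strain, toughness)
#' @export
gen_tensile_trace <- function(params, diameter_um = 10, gauge_mm = 5,
                              speed_mm_min = 10, rate_hz = 50) {
  check_scalar(diameter_um, "diameter_um", lower = 0, strict_lower = TRUE)
  check_scalar(gauge_mm, "gauge_mm", lower = 0, strict_lower = TRUE)
  area_m2 <- pi * (diameter_um * 1e-6 / 2)^2

  speed <- speed_mm_min / 60                      # mm/s
  t_break <- params$eps_b * gauge_mm / speed
  time <- seq(0, t_break, by = 1 / rate_hz)
  eps <- speed * time / gauge_mm
  sigma <- load_path_stress(params, eps)
  peak <- max(sigma)

  # appended failure: stress collapses below 10 % of peak
  dt <- 1 / rate_hz
  time <- c(time, time[length(time)] + dt * (1:2))
  eps <- c(eps, eps[length(eps)] + speed * dt * (1:2) / gauge_mm)
  sigma <- c(sigma, 0.05 * peak, 0.02 * peak)

  if (params$noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(params$seed)
    sigma <- sigma + stats::rnorm(length(sigma),
                                  0, params$noise_sd * peak)
  }

  structure(data.frame(
    time_s = time,
    displacement_mm = eps * gauge_mm,
    force_N = sigma * 1e6 * area_m2),
    diameter_um = diameter_um, gauge_mm = gauge_mm,
    truth = list(modulus_gpa = params$E, uts_mpa = peak,
                 breaking_strain = params$eps_b,
                 toughness = load_path_area(params, params$eps_b)),
    class = c("mech_trace", "data.frame"))
}

#' Simulate a sequence of loading/unloading cycles
#'
#' Each cycle loads from the current residual strain along the model path
#' (origin shifted to the residual) to the cycle's peak strain, then
#' unloads linearly with modulus `E_u` to zero stress, leaving a permanent
#' set. Before the next cycle the set is rescaled by
#' `1 - recovery_fraction` (a phenomenological stand-in for
#' humidity-driven recovery; 1 restores the original length). Closed-form
#' damping capacity and energy are attached per cycle.
#'
#' @param params a `mech_params`
#' @param peak_strains ascending peak strains, each below the breaking
#'   strain
#' @param recovery_fraction fraction of the permanent set recovered
#'   between cycles, in `[0, 1]`
#' @param diameter_um fiber diameter in micrometers
#' @param gauge_mm gauge length in mm
#' @param rate_hz sampling rate in Hz
#' @param speed_mm_min crosshead speed in mm/min
#' @return list of `mech_trace` cycles; each carries attribute `truth`
#'   with `damping_capacity_pct`, `damping_energy`, `permanent_set`
#' @export
gen_cyclic_traces <- function(params, peak_strains, recovery_fraction = 0,
                              diameter_um = 10, gauge_mm = 5,
                              rate_hz = 50, speed_mm_min = 10) {
  if (length(peak_strains) == 0L || any(diff(peak_strains) < 0))
    stop_invalid("`peak_strains` must be ascending")
  if (any(peak_strains >= params$eps_b))
    stop_invalid("peak strains must stay below the breaking strain %g",
                 params$eps_b)
  check_scalar(recovery_fraction, "recovery_fraction", lower = 0, upper = 1)
  area_m2 <- pi * (diameter_um * 1e-6 / 2)^2
  E_u_mpa <- params$E_u * 1000
  speed <- speed_mm_min / 60

  out <- vector("list", length(peak_strains))
  set <- 0
  t0 <- 0
  for (k in seq_along(peak_strains)) {
    ep <- peak_strains[k]
    if (ep <= set)
      stop_invalid("cycle %d peak strain %g does not exceed the residual %g",
                   k, ep, set)
    span <- ep - set
    sigma_p <- load_path_stress(params, span)
    a_load <- load_path_area(params, span)
    a_unload <- sigma_p^2 / (2 * E_u_mpa)
    new_set_rel <- span - sigma_p / E_u_mpa        # relative to cycle start
    if (new_set_rel < 0) new_set_rel <- 0

    eps_up <- seq(set, ep, length.out = max(ceiling(span * gauge_mm /
                                                      speed * rate_hz), 50))
    sig_up <- load_path_stress(params, eps_up - set)
    eps_dn <- seq(ep, set + new_set_rel, length.out = length(eps_up))
    sig_dn <- pmax(sigma_p - E_u_mpa * (ep - eps_dn), 0)
    eps_all <- c(eps_up, eps_dn[-1])
    sig_all <- c(sig_up, sig_dn[-1])
    time <- t0 + seq_along(eps_all) / rate_hz

    if (params$noise_sd > 0) {
      old <- .Random.seed_save()
      set.seed(params$seed + k)
      sig_all <- sig_all + stats::rnorm(length(sig_all),
                                        0, params$noise_sd * sigma_p)
      .Random.seed_restore(old)
    }

    out[[k]] <- structure(data.frame(
      time_s = time,
      displacement_mm = eps_all * gauge_mm,
      force_N = sig_all * 1e6 * area_m2),
      diameter_um = diameter_um, gauge_mm = gauge_mm,
      truth = list(
        peak_strain = ep,
        damping_capacity_pct = 100 * (a_load - a_unload) / a_load,
        damping_energy = a_load - a_unload,
        permanent_set = set + new_set_rel),
      class = c("mech_trace", "data.frame"))

    t0 <- max(time)
    set <- (1 - recovery_fraction) * (set + new_set_rel)
  }
  out
}

#' Convert a force-displacement trace to engineering stress-strain
#'
#' Strain is displacement over gauge length; stress is force over the
#' initial cross-sectional area `A = pi (d/2)^2`, in MPa. Points are kept
#' in recorded order (no resampling).
#'
#' @param trace a `mech_trace`, or a data frame with `displacement_mm` and
#'   `force_N`
#' @param diameter_um fiber diameter in micrometers; may be a vector of
#'   repeat measurements, which are averaged; default taken from the trace
#' @param gauge_mm gauge length in mm; default taken from the trace
#' @return object of class `stress_strain`: data frame with `strain`
#'   (fraction) and `stress` (MPa), attributes `area_m2`, `volume_m3`,
#'   `diameter_um`, `gauge_mm`
#' @export
to_stress_strain <- function(trace, diameter_um = NULL, gauge_mm = NULL) {
  if (is.null(diameter_um)) diameter_um <- attr(trace, "diameter_um")
  if (is.null(gauge_mm)) gauge_mm <- attr(trace, "gauge_mm")
  if (is.null(diameter_um) || is.null(gauge_mm))
    stop_invalid("diameter_um and gauge_mm must be given (or trace attrs)")
  diameter_um <- mean(diameter_um)
  check_scalar(diameter_um, "diameter_um", lower = 0, strict_lower = TRUE)
  check_scalar(gauge_mm, "gauge_mm", lower = 0, strict_lower = TRUE)

  area_m2 <- pi * (diameter_um * 1e-6 / 2)^2
  volume_m3 <- area_m2 * gauge_mm * 1e-3
  structure(data.frame(
    strain = trace$displacement_mm / gauge_mm,
    stress = trace$force_N / area_m2 / 1e6),
    area_m2 = area_m2, volume_m3 = volume_m3,
    diameter_um = diameter_um, gauge_mm = gauge_mm,
    truth = attr(trace, "truth"),
    class = c("stress_strain", "data.frame"))
}

#' Tensile summary: modulus, strength, breaking strain, toughness
#'
#' Modulus is the least-squares slope of stress on strain over the elastic
#' window; ultimate strength is the stress maximum; the breaking strain is
#' the strain of the first point after the peak where stress falls below
#' 10 percent of the peak (the 90 percent-drop rule); toughness is the
#' trapezoidal area under the curve from zero to the break, in MJ/m3.
#' Negative stresses (grip settling transients) are clamped to zero for
#' the area integral.
#'
#' @param curve a `stress_strain`
#' @param elastic_window strain interval for the modulus fit (default
#'   0.2-1.5 percent strain)
#' @param allow_censored if no 90 percent drop is found, treat the last
#'   point as the break and flag the result (default `TRUE`)
#' @return object of class `tensile_result`: list with `modulus_gpa`,
#'   `uts_mpa`, `breaking_strain`, `toughness` (MJ/m3),
#'   `elastic_window`, `censored`
#' @export
tensile_summary <- function(curve, elastic_window = c(0.002, 0.015),
                            allow_censored = TRUE) {
  eps <- curve$strain
  sig <- curve$stress
  in_win <- eps >= elastic_window[1] & eps <= elastic_window[2]
  if (sum(in_win) < 4L)
    stop_invalid("only %d points in the elastic window [%g, %g]",
                 sum(in_win), elastic_window[1], elastic_window[2])
  slope <- unname(stats::coef(stats::lm(sig[in_win] ~ eps[in_win]))[2L])

  i_peak <- which.max(sig)
  peak <- sig[i_peak]
  after <- which(seq_along(sig) > i_peak & sig < 0.10 * peak)
  censored <- length(after) == 0L
  if (censored && !allow_censored)
    stop_invalid("no 90%% stress drop detected and censoring disallowed")
  i_break <- if (censored) length(sig) else after[1L]

  keep <- seq_len(i_break)
  toughness <- trapz_area(eps[keep], pmax(sig[keep], 0))
  structure(list(
    modulus_gpa = slope / 1000,
    uts_mpa = peak,
    breaking_strain = eps[i_break],
    toughness = toughness,
    elastic_window = elastic_window,
    censored = censored
  ), class = "tensile_result")
}

#' @export
print.tensile_result <- function(x, ...) {
  cat(sprintf(paste0(
    "tensile: E = %.3g GPa, UTS = %.4g MPa, breaking strain = %.3g,\n",
    "         toughness = %.4g MJ/m3%s\n"),
    x$modulus_gpa, x$uts_mpa, x$breaking_strain, x$toughness,
    if (x$censored) " (censored: no 90% drop observed)" else ""))
  invisible(x)
}

#' Damping capacity and energy of one loading/unloading cycle
#'
#' Splits the curve at the maximum-strain sample (first occurrence on
#' ties), integrates the loading and unloading branches trapezoidally
#' (negative stresses clamped to zero), and reports damping capacity
#' `DC = 100 (A_load - A_unload) / A_load` (percent) and damping energy
#' `DE = A_load - A_unload` (MJ/m3), plus the permanent set (strain where
#' the unloading stress first reaches zero).
#'
#' @param curve a `stress_strain` containing one load and one unload
#'   segment
#' @return object of class `cycle_result`: list with `peak_strain`,
#'   `damping_capacity_pct`, `damping_energy`, `permanent_set`,
#'   `flagged` (TRUE when the unload branch exceeded the load branch)
#' @export
cycle_damping <- function(curve) {
  eps <- curve$strain
  sig <- pmax(curve$stress, 0)
  i_peak <- which.max(eps)
  if (i_peak < 2L || i_peak >= length(eps))
    stop_invalid("curve does not contain distinct load and unload segments")
  load_idx <- seq_len(i_peak)
  unload_idx <- seq(i_peak, length(eps))

  a_load <- trapz_area(eps[load_idx], sig[load_idx])
  # unload branch traversed with decreasing strain; integrate in
  # increasing-strain orientation
  a_unload <- trapz_area(rev(eps[unload_idx]), rev(sig[unload_idx]))
  if (a_load <= 0)
    stop_invalid("loading branch has non-positive area (%g)", a_load)

  dc <- 100 * (a_load - a_unload) / a_load
  flagged <- dc < 0 || dc > 100
  if (flagged)
    warning(sprintf("damping capacity %.2f%% outside [0, 100]: unload ",
                    dc), "branch exceeds the load branch", call. = FALSE)

  zero <- which(curve$stress[unload_idx] <= 0)
  permanent_set <- if (length(zero)) eps[unload_idx][zero[1L]] else
    eps[length(eps)]

  structure(list(
    peak_strain = eps[i_peak],
    damping_capacity_pct = dc,
    damping_energy = a_load - a_unload,
    permanent_set = permanent_set,
    flagged = flagged
  ), class = "cycle_result")
}

#' @export
print.cycle_result <- function(x, ...) {
  cat(sprintf(paste0(
    "cycle to %.3g strain: DC = %.1f %%, DE = %.3g MJ/m3, ",
    "set = %.3g%s\n"),
    x$peak_strain, x$damping_capacity_pct, x$damping_energy,
    x$permanent_set, if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Aggregate per-fiber results into mean and standard deviation
#'
#' @param results list of homogeneous result objects (e.g.
#'   `tensile_result` or `cycle_result`) or of named numeric lists
#' @return data frame with one row per numeric metric: `metric`, `mean`,
#'   `sd` (NA when n = 1), `n`
#' @export
aggregate_replicates <- function(results) {
  if (length(results) == 0L) stop_invalid("no results to aggregate")
  nums <- lapply(results, function(r) {
    vals <- unclass(r)
    vals <- vals[vapply(vals, function(v)
      is.numeric(v) && length(v) == 1L, logical(1))]
    unlist(vals)
  })
  metrics <- names(nums[[1L]])
  mat <- vapply(nums, function(v) v[metrics], numeric(length(metrics)))
  mat <- matrix(mat, nrow = length(metrics))
  n <- ncol(mat)
  data.frame(
    metric = metrics,
    mean = rowMeans(mat),
    sd = if (n > 1L) apply(mat, 1L, stats::sd) else NA_real_,
    n = n
  )
}
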