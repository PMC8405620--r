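## 1D reduction of 2D diffraction images: radial (sector-integrated) and
## azimuthal profiles of background-subtracted counts.

# Background-subtracted counts. With no recorded background exposure a
# constant offset is estimated from the four image corners.
net_counts <- function(image, subtract_background = TRUE,
                       corner_px = 24L) {
  counts <- image$counts
  if (!subtract_background) return(counts)
  if (!is.null(image$background)) {
    net <- counts - image$background
  } else {
    n <- nrow(counts); m <- ncol(counts)
    i <- seq_len(min(corner_px, n)); j <- seq_len(min(corner_px, m))
    offset <- mean(c(counts[i, j], counts[i, m - j + 1L],
                     counts[n - i + 1L, j], counts[n - i + 1L, m - j + 1L]))
    net <- counts - offset
  }
  n_clamped <- sum(net < 0)
  net[net < 0] <- 0
  attr(net, "n_clamped") <- n_clamped
  net
}

bin_means <- function(values, bin_index, n_bins) {
  sums <- rowsum(values, bin_index, reorder = TRUE)
  counts <- rowsum(rep(1, length(values)), bin_index, reorder = TRUE)
  out <- rep(NA_real_, n_bins)
  idx <- as.integer(rownames(sums))
  out[idx] <- sums / counts
  out
}

fill_empty_bins <- function(x, y, what) {
  empty <- !is.finite(y)
  if (any(empty)) {
    warning(sprintf("%d empty %s bins interpolated", sum(empty), what),
            call. = FALSE)
    y[empty] <- stats::approx(x[!empty], y[!empty], xout = x[empty],
                              rule = 2)$y
  }
  y
}

#' Sector-integrated radial intensity profile
#'
#' Averages background-subtracted counts into q bins over a wedge of
#' azimuths centered on the equator or the meridian (both Friedel-related
#' wedges are combined).
#'
#' @param image a `waxd_image` (counts, optional background, geometry)
#' @param axis `"equator"` or `"meridian"`
#' @param sector_width full angular width of the sector in degrees,
#'   in `[5, 60]` (default 25)
#' @param q_step q bin width in A-1 (default 0.005)
#' @param q_range q range to keep; `NULL` spans the sector's coverage
#' @param subtract_background subtract the recorded background exposure
#'   (or a corner-estimated constant) before binning
#' @return object of class `radial_profile`: data frame with columns `q`
#'   (bin centers, A-1) and `intensity` (mean net counts), with attributes
#'   `axis` and `sector_width`
#' @export
sector_integrate <- function(image, axis = c("equator", "meridian"),
                             sector_width = 25, q_step = 0.005,
                             q_range = NULL, subtract_background = TRUE) {
  axis <- match.arg(axis)
  check_scalar(sector_width, "sector_width", lower = 5, upper = 60)
  check_scalar(q_step, "q_step", lower = 0, strict_lower = TRUE)

  coords <- map_pixels(image$geometry, dim(image$counts))
  net <- net_counts(image, subtract_background)
  centers <- if (axis == "equator") c(0, 180) else c(90, 270)
  in_sector <- (abs(angle_diff(coords$chi, centers[1])) <= sector_width / 2) |
    (abs(angle_diff(coords$chi, centers[2])) <= sector_width / 2)

  q <- coords$q[in_sector]
  v <- net[in_sector]
  if (is.null(q_range)) q_range <- c(0, max(q))
  keep <- q >= q_range[1] & q <= q_range[2]
  q <- q[keep]; v <- v[keep]
  breaks <- seq(q_range[1], q_range[2] + q_step, by = q_step)
  idx <- findInterval(q, breaks, rightmost.closed = TRUE)
  n_bins <- length(breaks) - 1L
  mids <- breaks[-length(breaks)] + q_step / 2
  intensity <- fill_empty_bins(mids, bin_means(v, idx, n_bins), "q")

  structure(data.frame(q = mids, intensity = intensity),
            axis = axis, sector_width = sector_width,
            class = c("radial_profile", "data.frame"))
}

#' Azimuthal intensity profile within a radial band
#'
#' Averages background-subtracted counts into azimuth bins over all pixels
#' whose q lies inside `q_band`, covering the full 0-360 degrees.
#'
#' @param image a `waxd_image`
#' @param q_band length-2 q interval in A-1 (typically the radial range of
#'   one equatorial reflection)
#' @param chi_step azimuth bin width in degrees (default 2)
#' @param subtract_background as in [sector_integrate()]
#' @return object of class `azimuthal_profile`: data frame with columns
#'   `chi` (bin centers, degrees) and `intensity`
#' @export
azimuthal_profile <- function(image, q_band, chi_step = 2,
                              subtract_background = TRUE) {
  if (length(q_band) != 2L || q_band[1] >= q_band[2])
    stop_invalid("`q_band` must be an increasing (lo, hi) pair in A-1")
  coords <- map_pixels(image$geometry, dim(image$counts))
  if (q_band[1] > max(coords$q))
    stop_invalid("q band [%g, %g] is outside detector coverage (max q %g)",
                 q_band[1], q_band[2], max(coords$q))
  net <- net_counts(image, subtract_background)
  in_band <- coords$q >= q_band[1] & coords$q <= q_band[2]
  if (!any(in_band))
    stop_invalid("q band [%g, %g] contains no pixels", q_band[1], q_band[2])

  chi <- coords$chi[in_band]
  v <- net[in_band]
  breaks <- seq(0, 360, by = chi_step)
  idx <- findInterval(chi, breaks, rightmost.closed = TRUE)
  n_bins <- length(breaks) - 1L
  mids <- breaks[-length(breaks)] + chi_step / 2
  intensity <- fill_empty_bins(mids, bin_means(v, idx, n_bins), "chi")

  structure(data.frame(chi = mids, intensity = intensity),
            q_band = q_band,
            class = c("azimuthal_profile", "data.frame"))
}
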