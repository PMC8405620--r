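## Plain-text readers/writers for the formats the analysis stages consume:
## two-column spectra CSV, chromatogram + standards CSV, mechanical trace
## CSV, and diffraction images as whitespace-delimited matrices (or TIFF)
## with a key-value geometry sidecar.

#' Read a two-column spectrum CSV
#'
#' Expects columns `wavenumber_cm-1` (or `wavenumber`) and `intensity`.
#'
#' @param path CSV file path
#' @param modality optional modality label
#' @param orientation optional polarization label
#' @return a `spectrum`
#' @export
read_spectrum_csv <- function(path, modality = NULL, orientation = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  wn_col <- intersect(c("wavenumber_cm-1", "wavenumber"), names(df))
  if (length(wn_col) == 0L || !"intensity" %in% names(df))
    stop_invalid("%s must have columns wavenumber_cm-1 (or wavenumber) %s",
                 path, "and intensity")
  new_spectrum(df[[wn_col[1L]]], df$intensity, modality, orientation)
}

#' Write a spectrum to CSV
#' @param spec a `spectrum`
#' @param path output path
#' @export
write_spectrum_csv <- function(spec, path) {
  df <- data.frame(spec$wavenumber, spec$intensity)
  names(df) <- c("wavenumber_cm-1", "intensity")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a SEC chromatogram CSV (columns `volume_mL`, `absorbance`)
#' @param path CSV file path
#' @return a `sec_chromatogram`
#' @export
read_chromatogram_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("volume_mL", "absorbance") %in% names(df)))
    stop_invalid("%s must have columns volume_mL and absorbance", path)
  structure(list(volume_mL = df$volume_mL, absorbance = df$absorbance),
            class = "sec_chromatogram")
}

#' Write a SEC chromatogram to CSV
#' @param chrom a `sec_chromatogram`
#' @param path output path
#' @export
write_chromatogram_csv <- function(chrom, path) {
  utils::write.csv(data.frame(volume_mL = chrom$volume_mL,
                              absorbance = chrom$absorbance),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a SEC standards table CSV (columns `mass_kDa`, `Vr_mL`)
#' @param path CSV file path
#' @return data frame of standards
#' @export
read_standards_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("mass_kDa", "Vr_mL") %in% names(df)))
    stop_invalid("%s must have columns mass_kDa and Vr_mL", path)
  df
}

#' Read a mechanical trace CSV
#'
#' Expects columns `time_s`, `displacement_mm`, `force_N`.
#'
#' @param path CSV file path
#' @param diameter_um fiber diameter measurement(s) in micrometers
#'   (averaged)
#' @param gauge_mm gauge length in mm (default 5)
#' @return a `mech_trace`
#' @export
read_trace_csv <- function(path, diameter_um, gauge_mm = 5) {
  df <- utils::read.csv(path)
  need <- c("time_s", "displacement_mm", "force_N")
  if (!all(need %in% names(df)))
    stop_invalid("%s must have columns %s", path, paste(need, collapse = ", "))
  structure(df[need], diameter_um = mean(diameter_um), gauge_mm = gauge_mm,
            class = c("mech_trace", "data.frame"))
}

#' Write a mechanical trace to CSV
#' @param trace a `mech_trace`
#' @param path output path
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$time_s,
                              displacement_mm = trace$displacement_mm,
                              force_N = trace$force_N),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a diffraction image with its geometry sidecar
#'
#' The counts matrix is written as a whitespace-delimited text matrix (or a
#' 16-bit TIFF when `path` ends in `.tif`/`.tiff` and the tiff package is
#' installed); the geometry goes to `<path>.geom` as `key value` lines
#' (`wavelength_A`, `distance_mm`, `pixel_mm`, `center_row`, `center_col`,
#' `meridian_deg`).
#'
#' @param image a `waxd_image`
#' @param path output path for the counts matrix
#' @param background_path optional output path for the background matrix
#' @return `path`, invisibly
#' @export
write_waxd_image <- function(image, path, background_path = NULL) {
  write_mat <- function(m, p) {
    if (grepl("\\.tiff?$", p, ignore.case = TRUE)) {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop_invalid("the tiff package is required to write %s", p)
      tiff::writeTIFF(m / max(m, 1), p, bits.per.sample = 16L)
    } else {
      utils::write.table(m, p, row.names = FALSE, col.names = FALSE)
    }
  }
  write_mat(image$counts, path)
  if (!is.null(background_path) && !is.null(image$background))
    write_mat(image$background, background_path)

  g <- image$geometry
  center <- g$center_px
  if (is.null(center)) center <- (dim(image$counts) + 1) / 2
  lines <- c(
    paste("wavelength_A", g$wavelength_A),
    paste("distance_mm", g$distance_mm),
    paste("pixel_mm", g$pixel_mm),
    paste("center_row", center[1]),
    paste("center_col", center[2]),
    paste("meridian_deg", g$meridian_deg))
  writeLines(lines, paste0(path, ".geom"))
  invisible(path)
}

#' Read a diffraction image and its geometry sidecar
#'
#' @param path counts matrix path (text matrix or TIFF)
#' @param geometry_path sidecar path; default `<path>.geom`
#' @param background_path optional background matrix path
#' @return a `waxd_image` (without truth)
#' @export
read_waxd_image <- function(path, geometry_path = paste0(path, ".geom"),
                            background_path = NULL) {
  read_mat <- function(p) {
    if (grepl("\\.tiff?$", p, ignore.case = TRUE)) {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop_invalid("the tiff package is required to read %s", p)
      tiff::readTIFF(p)
    } else {
      as.matrix(utils::read.table(p))
    }
  }
  counts <- unname(read_mat(path))
  kv <- utils::read.table(geometry_path,
                          col.names = c("key", "value"))
  val <- function(k) as.numeric(kv$value[kv$key == k][1L])
  geom <- detector_geometry(
    wavelength_A = val("wavelength_A"),
    distance_mm = val("distance_mm"),
    pixel_mm = val("pixel_mm"),
    center_px = c(val("center_row"), val("center_col")),
    meridian_deg = val("meridian_deg"))
  background <- if (!is.null(background_path))
    unname(read_mat(background_path)) else NULL
  structure(list(counts = counts, background = background,
                 geometry = geom, truth = NULL),
            class = "waxd_image")
}
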