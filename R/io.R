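#' Write channel data to disk
#'
#' Raw little-endian float32 samples (axial-major: all axial samples of
#' element 1, then element 2, ...) in `<path>`, with a JSON sidecar
#' `<path>.json` carrying the geometry, depth, frame index and optional
#' seed.
#'
#' @param frame A [channel_data()] frame.
#' @param path Output file path for the raw samples.
#' @param seed Optional seed to record for provenance.
#' @return `path`, invisibly.
#' @export
write_channel_data <- function(frame, path, seed = NULL) {
  stopifnot(inherits(frame, "pa_channel_data"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(frame$samples), con, size = 4L, endian = "little")
  g <- frame$geometry
  meta <- list(
    format = "slscpa-channel-data-v1",
    dtype = "float32le", order = "axial-major",
    nz = nrow(frame$samples), ni = ncol(frame$samples),
    depth_mm = frame$depth, frame_index = frame$frame_index,
    geometry = list(
      num_elements = g$num_elements, pitch_mm = g$pitch,
      sampling_frequency_mhz = g$sampling_frequency,
      sound_speed_m_s = g$sound_speed,
      center_frequency_mhz = g$center_frequency,
      fractional_bandwidth = g$fractional_bandwidth)
  )
  if (!is.null(seed)) meta$seed <- seed
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read channel data written by [write_channel_data()]
#'
#' @param path Path to the raw sample file (the `<path>.json` sidecar must
#'   exist alongside it).
#' @return A [channel_data()] frame (float32 precision).
#' @export
read_channel_data <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, "slscpa-channel-data-v1")) {
    stop("unrecognized channel-data file format")
  }
  g <- meta$geometry
  geometry <- array_geometry(
    num_elements = g$num_elements, pitch = g$pitch_mm,
    sampling_frequency = g$sampling_frequency_mhz,
    sound_speed = g$sound_speed_m_s,
    center_frequency = g$center_frequency_mhz,
    fractional_bandwidth = g$fractional_bandwidth)
  con <- file(path, "rb")
  on.exit(close(con))
  n <- meta$nz * meta$ni
  vals <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  channel_data(matrix(vals, meta$nz, meta$ni), geometry, meta$depth_mm,
               meta$frame_index)
}

#' Write a beamformed image (and optional display image) to disk
#'
#' Writes the pre-log values as a 32-bit float TIFF `<prefix>.tif`, the
#' display image (when given) as an 8-bit PNG `<prefix>.png` (linear map of
#' `[-DR, 0]` dB to `[0, 255]`), and a JSON sidecar `<prefix>.json` with
#' pixel spacings, method and parameters. Requires the `tiff` (and `png`)
#' packages.
#'
#' @param img A [pa_image()].
#' @param prefix Output path prefix.
#' @param display Optional `pa_display` companion.
#' @param params Optional named list recorded in the sidecar (e.g. M, k).
#' @return `prefix`, invisibly.
#' @export
write_beamformed_image <- function(img, prefix, display = NULL,
                                   params = list()) {
  stopifnot(inherits(img, "pa_image"))
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to write image files")
  }
  mx <- max(img$values)
  tiff::writeTIFF(img$values / max(mx, 1), paste0(prefix, ".tif"),
                  bits.per.sample = 32L, reduce = FALSE)
  meta <- list(format = "slscpa-image-v1", method = img$method,
               nz = nrow(img$values), nx = ncol(img$values),
               dx_mm = img$dx, dz_mm = img$dz, value_scale = max(mx, 1),
               normalized = img$normalized)
  if (length(params)) meta$params <- params
  if (!is.null(display)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("the 'png' package is required to write the display PNG")
    }
    dr <- display$dynamic_range
    u8 <- (display$values + dr) / dr  # [-DR, 0] -> [0, 1]
    png::writePNG(t(u8), paste0(prefix, ".png"))
    meta$dynamic_range_db <- dr
  }
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Write a metric or sweep table as CSV
#'
#' UTF-8 CSV with a header row and `.` as the decimal separator.
#'
#' @param table A data frame (e.g. from [sweep_beamforming_params()] or
#'   [failed_segmentation_experiment()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
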