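#' Rectangular region of interest in physical coordinates
#'
#' @param lateral Lateral center in mm.
#' @param axial Axial (depth) center in mm.
#' @param width Lateral extent in mm (> 0, default 3).
#' @param height Axial extent in mm (> 0, default 3).
#' @return An object of class `pa_roi`.
#' @export
roi_spec <- function(lateral, axial, width = 3, height = 3) {
  stopifnot(is.finite(lateral), is.finite(axial), width > 0, height > 0)
  structure(list(lateral = lateral, axial = axial,
                 width = width, height = height),
            class = "pa_roi")
}

# Extract the pixel values of an image inside a ROI; errors if the ROI
# extends beyond the image.
roi_values <- function(img, roi) {
  stopifnot(inherits(roi, "pa_roi"))
  x <- img$lateral_x
  z <- axial_positions(img)
  if (roi$lateral - roi$width / 2 < min(x) - img$dx / 2 ||
      roi$lateral + roi$width / 2 > max(x) + img$dx / 2 ||
      roi$axial - roi$height / 2 < -img$dz / 2 ||
      roi$axial + roi$height / 2 > max(z) + img$dz / 2) {
    stop("ROI extends outside the image")
  }
  cols <- which(abs(x - roi$lateral) <= roi$width / 2)
  rows <- which(abs(z - roi$axial) <= roi$height / 2)
  if (length(cols) == 0L || length(rows) == 0L) {
    stop("ROI contains no pixels")
  }
  as.vector(img$values[rows, cols])
}

rois_overlap <- function(a, b) {
  abs(a$lateral - b$lateral) < (a$width + b$width) / 2 &&
    abs(a$axial - b$axial) < (a$height + b$height) / 2
}

#' Generalized contrast-to-noise ratio
#'
#' Probability-of-discrimination contrast metric: one minus the overlap of
#' the amplitude histograms inside and outside the target,
#' `gCNR = 1 - sum_bins min(p_in, p_out)`, with both histograms computed
#' over 256 shared equal-width bins spanning the pooled value range of the
#' two ROIs. Operates on normalized pre-log images.
#'
#' @param img A normalized [pa_image()].
#' @param roi_in,roi_out Non-overlapping [roi_spec()] regions inside the
#'   image.
#' @param bins Number of histogram bins (default 256).
#' @return gCNR in `[0, 1]`.
#' @export
gcnr <- function(img, roi_in, roi_out, bins = 256L) {
  stopifnot(inherits(img, "pa_image"), bins >= 2L)
  if (rois_overlap(roi_in, roi_out)) stop("ROIs must not overlap")
  vi <- roi_values(img, roi_in)
  vo <- roi_values(img, roi_out)
  lo <- min(vi, vo)
  hi <- max(vi, vo)
  if (hi <= lo) return(0)  # all values identical: full histogram overlap
  bin_of <- function(v) pmin(bins, 1L + floor((v - lo) / (hi - lo) * bins))
  pi_ <- tabulate(bin_of(vi), bins) / length(vi)
  po <- tabulate(bin_of(vo), bins) / length(vo)
  1 - sum(pmin(pi_, po))
}

#' Locate the photoacoustic target
#'
#' The target center is the brightest pixel of the image; ties are broken
#' toward the smallest axial index, then the smallest lateral index.
#'
#' @param img A [pa_image()].
#' @return List with `lateral` and `axial` (mm) and the pixel indices
#'   `row`, `col`.
#' @export
locate_target <- function(img) {
  stopifnot(inherits(img, "pa_image"))
  mx <- max(img$values)
  if (mx <= 0) stop("all-zero image: no target to locate")
  hits <- which(img$values == mx, arr.ind = TRUE)
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  r <- unname(hits[1L, 1L]); cl <- unname(hits[1L, 2L])
  list(lateral = unname(img$lateral_x[cl]), axial = (r - 1L) * img$dz,
       row = r, col = cl)
}

#' Default gCNR regions of interest
#'
#' The inside ROI is a 3 mm x 3 mm rectangle centered on the target; the
#' outside ROI is the same size, shifted 5 mm to the right of the target's
#' lateral center at the same depth.
#'
#' @param target A [locate_target()] result (or list with `lateral`,
#'   `axial`).
#' @param size ROI edge length in mm (default 3).
#' @param offset Lateral shift of the outside ROI in mm (default 5).
#' @return List with `inside` and `outside` [roi_spec()] objects.
#' @export
default_rois <- function(target, size = 3, offset = 5) {
  list(
    inside = roi_spec(target$lateral, target$axial, size, size),
    outside = roi_spec(target$lateral + offset, target$axial, size, size)
  )
}

#' Lateral full width at half maximum
#'
#' Width of the lateral line profile through the target center at half of
#' the profile maximum, with sub-pixel resolution from linear interpolation
#' across the half-maximum crossings nearest the peak.
#'
#' @param img A [pa_image()].
#' @param target A [locate_target()] result; defaults to the image argmax.
#' @return Width in mm.
#' @export
lateral_fwhm <- function(img, target = locate_target(img)) {
  prof <- img$values[target$row, ]
  x <- img$lateral_x
  p <- target$col
  half <- prof[p] / 2
  if (prof[p] <= 0) stop("profile maximum is not positive")
  cross <- function(idx_from, step) {
    j <- idx_from
    while (j + step >= 1L && j + step <= length(prof)) {
      if (prof[j + step] < half) {
        # interpolate between j and j+step
        f <- (prof[j] - half) / (prof[j] - prof[j + step])
        return(x[j] + f * (x[j + step] - x[j]))
      }
      j <- j + step
    }
    stop("profile never falls below half maximum: width unresolvable")
  }
  right <- cross(p, 1L)
  left <- cross(p, -1L)
  abs(right - left)
}

#' Image signal-to-noise ratio
#'
#' `SNR = mu_in / sigma_out`: the mean of a 2.5 mm x 2.5 mm ROI centered on
#' the target divided by the standard deviation of a background ROI of the
#' same size. Five independent background ROIs placed 10 to 15 mm to the
#' left of the target (same depth) give five SNR values, reported as mean
#' and standard deviation. Operates on normalized pre-log images.
#'
#' @param img A normalized [pa_image()].
#' @param target A [locate_target()] result.
#' @param roi_size Edge length of all ROIs in mm (default 2.5).
#' @param background_offsets Lateral offsets of the background ROI centers
#'   from the target, in mm (default five offsets spanning -10 to -15 mm).
#' @return List with `mean`, `sd`, and the five `values`.
#' @export
image_snr <- function(img, target = locate_target(img), roi_size = 2.5,
                      background_offsets = c(-10, -11.25, -12.5, -13.75, -15)) {
  roi_in <- roi_spec(target$lateral, target$axial, roi_size, roi_size)
  mu <- mean(roi_values(img, roi_in))
  snr <- vapply(background_offsets, function(off) {
    roi_bg <- roi_spec(target$lateral + off, target$axial, roi_size, roi_size)
    s <- stats::sd(roi_values(img, roi_bg))
    if (!is.finite(s) || s == 0) {
      stop("degenerate background: zero standard deviation in background ROI")
    }
    mu / s
  }, numeric(1))
  list(mean = mean(snr), sd = stats::sd(snr), values = snr)
}

rms <- function(x) sqrt(mean(x^2))

#' Channel signal-to-noise ratio in dB
#'
#' `SNRc = 20 log10(rms(signal) / rms(noise))`, with the rms taken over the
#' entire channel-data recording.
#'
#' @param signal A [channel_data()] frame or real matrix (the noiseless
#'   recording).
#' @param noise A real matrix of the same shape (the added noise).
#' @return Channel SNR in dB (`Inf` if the noise is identically zero).
#' @export
channel_snr <- function(signal, noise) {
  s <- if (inherits(signal, "pa_channel_data")) signal$samples else signal
  n <- if (inherits(noise, "pa_channel_data")) noise$samples else noise
  stopifnot(all(dim(s) == dim(n)))
  rn <- rms(n)
  if (rn == 0) return(Inf)
  20 * log10(rms(s) / rn)
}

#' Add calibrated Gaussian noise to channel data
#'
#' Draws i.i.d. zero-mean Gaussian noise and scales it so the realized
#' channel SNR ([channel_snr()]) exactly equals the target: the noise rms is
#' set to `rms(signal) * 10^(-snr_db / 20)`.
#'
#' @param frame A [channel_data()] frame (must not be identically zero).
#' @param snr_db Target channel SNR in dB.
#' @param seed Integer seed for the noise draw.
#' @return List with `frame` (noisy [channel_data()]) and `noise` (the
#'   added matrix).
#' @export
add_channel_noise <- function(frame, snr_db, seed) {
  stopifnot(inherits(frame, "pa_channel_data"), is.finite(snr_db))
  if (missing(seed) || is.null(seed)) stop("a seed is required for the noise draw")
  sig_rms <- rms(frame$samples)
  if (sig_rms == 0) stop("cannot set a channel SNR on an all-zero frame")
  target_rms <- sig_rms * 10^(-snr_db / 20)
  noise <- with_local_seed(seed, {
    matrix(stats::rnorm(length(frame$samples)), nrow(frame$samples))
  })
  noise <- noise * (target_rms / rms(noise))
  list(
    frame = channel_data(frame$samples + noise, frame$geometry, frame$depth,
                         frame$frame_index),
    noise = noise
  )
}

#' Sweep the SLSC compounding parameters
#'
#' Beamforms one frame for every combination of cumulative lag `M` and
#' axial kernel `k` and reports the image-quality metrics per combination.
#' The default grid (M from 5 to 35 in steps of 5; k of 3, 11, 19, 31)
#' gives 28 rows.
#'
#' @param frame A [channel_data()] frame.
#' @param M_values Cumulative lags to evaluate.
#' @param k_values Axial kernel sizes to evaluate (odd).
#' @param num_scanlines Number of scanlines.
#' @param filt DC-removal filter.
#' @return A data frame with columns `M`, `k`, `d_mm`, `gCNR`, `fwhm_mm`,
#'   `snr_mean`, `snr_sd`. SNR columns are `NA` when the background ROIs do
#'   not fit inside the image.
#' @export
sweep_beamforming_params <- function(frame,
                                     M_values = seq(5L, 35L, by = 5L),
                                     k_values = c(3L, 11L, 19L, 31L),
                                     num_scanlines = frame$geometry$num_elements,
                                     filt = design_dc_filter(
                                       sampling_frequency = frame$geometry$sampling_frequency)) {
  cube <- aperture_cube(frame, num_scanlines, filt)
  grid <- expand.grid(k = as.integer(k_values), M = as.integer(M_values))
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    M <- grid$M[g]; k <- grid$k[g]
    img <- normalize_image(slsc_image(cube, M, k))
    tgt <- locate_target(img)
    rois <- default_rois(tgt)
    g_val <- tryCatch(gcnr(img, rois$inside, rois$outside),
                      error = function(e) NA_real_)
    f_val <- tryCatch(lateral_fwhm(img, tgt), error = function(e) NA_real_)
    s_val <- tryCatch(image_snr(img, tgt), error = function(e) NULL)
    data.frame(M = M, k = k, d_mm = frame$depth, gCNR = g_val,
               fwhm_mm = f_val,
               snr_mean = if (is.null(s_val)) NA_real_ else s_val$mean,
               snr_sd = if (is.null(s_val)) NA_real_ else s_val$sd)
  })
  out <- do.call(rbind, rows)
  out[order(out$M, out$k), , drop = FALSE]
}
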