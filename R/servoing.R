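#' Segmentation configuration
#'
#' @param threshold Amplitude threshold as a fraction of the image maximum
#'   (0 < threshold < 1; default 0.50, the midpoint of the 0.35-0.66 sweep
#'   used in the degradation study).
#' @param dilate_radius,erode_radius Disc radii in pixels for the
#'   morphological closing (dilation then erosion; default 2 each; 0
#'   disables the step).
#' @return An object of class `pa_seg_config`.
#' @export
seg_config <- function(threshold = 0.50, dilate_radius = 2L,
                       erode_radius = 2L) {
  stopifnot(threshold > 0, threshold < 1, dilate_radius >= 0,
            erode_radius >= 0)
  structure(list(threshold = threshold,
                 dilate_radius = as.integer(dilate_radius),
                 erode_radius = as.integer(erode_radius)),
            class = "pa_seg_config")
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels that
# touch diagonally are merged afterwards with a union-find pass.
label_components_8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  parent <- seq_len(nlab)
  find <- function(a) {
    while (parent[a] != a) a <- parent[a]
    a
  }
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1]))    # up-right
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) > 0L) {
    pairs <- unique(pairs)
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- remap[lab[lab > 0L]]
  out
}

#' Segment the photoacoustic target
#'
#' Binarizes the image at a fraction of its maximum, labels connected
#' components (8-connectivity), keeps the largest, and regularizes the
#' selected component with a morphological closing (dilation then erosion
#' with disc structuring elements) before computing its intensity-weighted
#' centroid in physical coordinates. The lateral reference `p0` is the
#' image lateral center (0 mm), so the lateral offset is `dp = p - p0`.
#'
#' The closing is applied to the selected component rather than to the raw
#' threshold mask: closing first would bridge scattered speckle in
#' noise-dominated images into one percolated component spanning most of
#' the image, making every frame yield a spurious "detection".
#'
#' An empty post-processing mask is a failure result, not an error.
#'
#' @param img A [pa_image()] (normalized internally).
#' @param cfg A [seg_config()].
#' @return An object of class `pa_segmentation`: list with `success`,
#'   `mask` (logical `Nz x Nx`), `centroid` (`lateral`, `axial` in mm),
#'   `lateral_offset` (mm), `area` (pixels).
#' @export
segment_target <- function(img, cfg = seg_config()) {
  stopifnot(inherits(img, "pa_image"), inherits(cfg, "pa_seg_config"))
  mx <- max(img$values)
  empty <- function() structure(
    list(success = FALSE,
         mask = matrix(FALSE, nrow(img$values), ncol(img$values)),
         centroid = NULL, lateral_offset = NA_real_, area = 0L),
    class = "pa_segmentation")
  if (mx <= 0) return(empty())
  mask <- img$values >= cfg$threshold * mx
  if (!any(mask)) return(empty())
  lab <- label_components_8(mask)
  sizes <- tabulate(lab[lab > 0L])
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie: keep the component with the smallest centroid depth
    depth_of <- vapply(best, function(b) {
      mean((which(lab == b, arr.ind = TRUE)[, 1L] - 1L)) * img$dz
    }, numeric(1))
    best <- best[which.min(depth_of)]
  }
  comp <- lab == best
  if (cfg$dilate_radius > 0L) {
    brush <- EBImage::makeBrush(2L * cfg$dilate_radius + 1L, shape = "disc")
    comp <- EBImage::dilate(comp * 1, brush) > 0
  }
  if (cfg$erode_radius > 0L) {
    brush <- EBImage::makeBrush(2L * cfg$erode_radius + 1L, shape = "disc")
    comp <- EBImage::erode(comp * 1, brush) > 0
  }
  if (!any(comp)) comp <- lab == best  # closing erased a thin component
  w <- img$values
  w[!comp] <- 0
  tot <- sum(w)
  if (tot <= 0) {  # largest component carries no intensity (degenerate)
    w[comp] <- 1
    tot <- sum(w)
  }
  rows <- matrix(seq_len(nrow(w)) - 1L, nrow(w), ncol(w))
  cols <- matrix(img$lateral_x, nrow(w), ncol(w), byrow = TRUE)
  centroid_axial <- sum(rows * w) / tot * img$dz
  centroid_lateral <- sum(cols * w) / tot
  structure(
    list(success = TRUE, mask = comp,
         centroid = list(lateral = centroid_lateral, axial = centroid_axial),
         lateral_offset = centroid_lateral,  # p0 = image lateral center (0)
         area = sum(comp)),
    class = "pa_segmentation")
}

#' Did a segmentation fail against the ground truth?
#'
#' A failed segmentation is either no segmentation result or no overlap of
#' the segmented mask with the ground-truth mask.
#'
#' @param result A [segment_target()] result.
#' @param truth Logical ground-truth mask of the same shape.
#' @return `TRUE` when failed.
#' @export
segmentation_failed <- function(result, truth) {
  stopifnot(inherits(result, "pa_segmentation"), is.matrix(truth))
  !result$success || !any(result$mask & truth)
}

#' Visual-servoing controller configuration
#'
#' Discrete proportional velocity law: on a successful segmentation the
#' probe moves by `gain * lateral_offset * frame_interval`; after
#' `failure_window` seconds of consecutive failures the probe performs an
#' expanding lateral search (offsets +step, -step, +2 step, -2 step, ...
#' around the position where failures began, up to `search_extent`).
#'
#' @param gain Proportional gain in 1/s (> 0). The default 10 combined with
#'   a 10 Hz frame rate gives unit closed-loop gain (one-step centering on
#'   a perfect measurement).
#' @param prf Frame rate (laser pulse repetition frequency) in Hz.
#' @param failure_window Consecutive-failure duration in s that triggers
#'   the search (default 1).
#' @param search_step Lateral search step in mm (default 2).
#' @param search_extent Maximum search offset in mm (default 10).
#' @param tolerance Convergence tolerance in mm (default 0.3), used to
#'   define the first center crossing for reporting.
#' @return An object of class `pa_servo_config`.
#' @export
servo_config <- function(gain = 10, prf = 10, failure_window = 1,
                         search_step = 2, search_extent = 10,
                         tolerance = 0.3) {
  stopifnot(gain > 0, prf > 0, failure_window > 0, search_step > 0,
            search_extent > 0, tolerance > 0)
  structure(list(gain = gain, prf = prf, frame_interval = 1 / prf,
                 failure_window = failure_window, search_step = search_step,
                 search_extent = search_extent, tolerance = tolerance),
            class = "pa_servo_config")
}

#' One proportional servo update
#'
#' @param position Current probe lateral position in mm.
#' @param seg A [segment_target()] result for the current frame.
#' @param cfg A [servo_config()].
#' @return New probe lateral position in mm (unchanged on failure).
#' @export
servo_step <- function(position, seg, cfg) {
  stopifnot(inherits(seg, "pa_segmentation"), inherits(cfg, "pa_servo_config"))
  if (!seg$success) return(position)
  position + cfg$gain * cfg$frame_interval * seg$lateral_offset
}

#' Run a closed-loop visual-servoing experiment
#'
#' Per frame: the source appears in the probe frame at (trajectory position
#' minus probe position); channel data are simulated, beamformed, and
#' segmented; on success the probe moves by the proportional velocity law;
#' after `failure_window` seconds of consecutive failures the probe
#' executes an expanding lateral search until a segmentation succeeds or
#' the search extent is exhausted.
#'
#' The tracking error per frame is probe position minus source position.
#' For centering trajectories the summary window is 12 to 15 s after the
#' first center crossing (falling back to the last third of the run when
#' the run is shorter); for tracking trajectories all frames are
#' summarized.
#'
#' @param geometry A [array_geometry()].
#' @param trajectory A [make_trajectory()] result.
#' @param source_depth Source depth in mm.
#' @param depth Image depth in mm.
#' @param method `"slsc"` or `"das"`.
#' @param M,k SLSC parameters.
#' @param noise_snr_db Channel SNR in dB, or `NULL` for noiseless frames.
#' @param cfg A [servo_config()].
#' @param seg_cfg A [seg_config()].
#' @param seed Base seed for per-frame noise.
#' @param num_scanlines Scanline count for beamforming.
#' @param summary_window Optional two-element vector (s) overriding the
#'   summary window, measured from the first center crossing.
#' @param segment_override Optional function `(img, seg_cfg) ->
#'   pa_segmentation` replacing [segment_target()] (e.g. to study the
#'   failure-search path).
#' @return An object of class `pa_tracking`: list with `frames` (data frame
#'   of `time`, `probe`, `desired`, `error`, `success`, `searching`) and
#'   `summary` (`median_error`, `iqr_error` in mm over the analysis window,
#'   `failure_fraction` over all frames).
#' @export
run_servo_experiment <- function(geometry, trajectory, source_depth, depth,
                                 method = c("slsc", "das"), M = 25L, k = 11L,
                                 noise_snr_db = NULL,
                                 cfg = servo_config(),
                                 seg_cfg = seg_config(),
                                 seed = 1L,
                                 num_scanlines = geometry$num_elements,
                                 summary_window = NULL,
                                 segment_override = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(trajectory, "pa_trajectory"))
  n <- nrow(trajectory)
  if (n == 0L) stop("trajectory is empty")
  if (abs(attr(trajectory, "frame_interval") - cfg$frame_interval) > 1e-9) {
    stop("trajectory frame interval does not match the servo configuration")
  }
  fail_limit <- max(1L, as.integer(round(cfg$failure_window / cfg$frame_interval)))
  half_ap <- max(abs(geometry$element_x))

  probe <- 0
  consec_fail <- 0L
  search_idx <- 0L       # 0 = not searching
  search_origin <- NA_real_
  filt <- design_dc_filter(sampling_frequency = geometry$sampling_frequency)

  rec <- data.frame(time = trajectory$time, probe = NA_real_,
                    desired = trajectory$position, error = NA_real_,
                    success = FALSE, searching = FALSE)
  for (j in seq_len(n)) {
    rec$probe[j] <- probe
    rec$error[j] <- probe - trajectory$position[j]
    src_lat <- trajectory$position[j] - probe
    seg <- NULL
    if (abs(src_lat) <= half_ap + geometry$pitch / 2) {
      src <- source_spec(lateral = src_lat, depth = source_depth)
      frame <- simulate_channel_data(
        geometry, src, depth, noise_snr_db = noise_snr_db,
        seed = if (is.null(noise_snr_db)) NULL else seed + j - 1L,
        frame_index = j - 1L)
      bf <- beamform_frame(frame, method = method, M = M, k = k,
                           num_scanlines = num_scanlines, filt = filt)
      seg <- if (is.null(segment_override)) segment_target(bf$image, seg_cfg)
             else segment_override(bf$image, seg_cfg)
    }
    if (is.null(seg) || !seg$success) {
      consec_fail <- consec_fail + 1L
      rec$success[j] <- FALSE
      if (consec_fail >= fail_limit) {
        # expanding lateral search around where failures began
        if (search_idx == 0L) search_origin <- probe
        search_idx <- search_idx + 1L
        sgn <- if (search_idx %% 2L == 1L) 1 else -1
        mag <- ceiling(search_idx / 2) * cfg$search_step
        if (mag <= cfg$search_extent) {
          probe <- search_origin + sgn * mag
          rec$searching[j] <- TRUE
        }
      }
    } else {
      rec$success[j] <- TRUE
      consec_fail <- 0L
      search_idx <- 0L
      probe <- servo_step(probe, seg, cfg)
    }
  }

  kind <- attr(trajectory, "kind")
  abs_err <- abs(rec$error)
  window_frames <- seq_len(n)
  if (kind == "centering") {
    win <- if (is.null(summary_window)) c(12, 15) else summary_window
    crossed <- which(abs_err < cfg$tolerance)
    t0 <- if (length(crossed) > 0) rec$time[crossed[1]] else rec$time[1]
    sel <- which(rec$time >= t0 + win[1] & rec$time <= t0 + win[2])
    if (length(sel) == 0L) sel <- seq(from = max(1L, floor(2 * n / 3)), to = n)
    window_frames <- sel
  } else if (!is.null(summary_window)) {
    sel <- which(rec$time >= summary_window[1] & rec$time <= summary_window[2])
    if (length(sel) > 0L) window_frames <- sel
  }
  structure(
    list(frames = rec,
         summary = list(
           median_error = stats::median(abs_err[window_frames]),
           iqr_error = stats::IQR(abs_err[window_frames]),
           failure_fraction = mean(!rec$success),
           window_frames = window_frames),
         method = method, kind = kind),
    class = "pa_tracking")
}

#' @export
print.pa_tracking <- function(x, ...) {
  cat(sprintf("<pa_tracking:%s/%s> %d frames; median error %.3g mm, IQR %.3g mm, %.1f%% failed\n",
              x$method, x$kind, nrow(x$frames), x$summary$median_error,
              x$summary$iqr_error, 100 * x$summary$failure_fraction))
  invisible(x)
}

#' Segmentation-failure degradation study
#'
#' Emulates the noise-degradation experiment: ground-truth masks are the
#' segmentations of noiseless beamformed frames (per method, at the default
#' threshold); Gaussian noise is then added to reach each channel SNR, the
#' noisy frames are beamformed and re-segmented at each amplitude threshold
#' in the sweep, and a segmentation counts as failed when it produces no
#' result or does not overlap the ground truth. The percentage of failed
#' segmentations over the frames is aggregated as mean and standard
#' deviation over the threshold sweep.
#'
#' @param geometry A [array_geometry()].
#' @param source A [source_spec()]; the noiseless reference frames use it
#'   as is.
#' @param depth Image depth in mm.
#' @param snr_grid Channel SNRs in dB to evaluate (use `Inf` for the
#'   no-noise control).
#' @param thresholds Amplitude-threshold sweep (default 10 evenly spaced
#'   values in `[0.35, 0.66]`).
#' @param methods Beamformers to compare (default both).
#' @param M,k SLSC parameters.
#' @param n_frames Number of frames per condition (default 10).
#' @param seed Base seed; frame `f` at grid point `g` uses
#'   `seed + (g - 1) * n_frames + f - 1`.
#' @param signal_scale Multiplier on the signal in the noisy frames
#'   (default 1; 0 gives pure noise at the amplitude the unscaled signal
#'   would have implied, the "zeroed signal" control).
#' @param num_scanlines Scanline count.
#' @param seg_cfg Baseline [seg_config()] whose morphology settings are
#'   used for every threshold (ground truth uses its default threshold).
#' @return A data frame with columns `method`, `snr_db`, `mean_pct_failed`,
#'   `sd_pct_failed`.
#' @export
failed_segmentation_experiment <- function(geometry, source, depth,
                                           snr_grid,
                                           thresholds = seq(0.35, 0.66,
                                                            length.out = 10),
                                           methods = c("das", "slsc"),
                                           M = 25L, k = 11L,
                                           n_frames = 10L,
                                           seed = 1L,
                                           signal_scale = 1,
                                           num_scanlines = geometry$num_elements,
                                           seg_cfg = seg_config()) {
  stopifnot(length(snr_grid) >= 1L, all(thresholds > 0 & thresholds < 1),
            n_frames >= 1L, signal_scale >= 0)
  filt <- design_dc_filter(sampling_frequency = geometry$sampling_frequency)
  clean <- simulate_channel_data(geometry, source, depth)
  cube_clean <- aperture_cube(clean, num_scanlines, filt)
  image_of <- function(cube, method) {
    img <- if (method == "das") das_beamform(cube) else slsc_image(cube, M, k)
    normalize_image(img)
  }
  truth <- lapply(methods, function(me) {
    segment_target(image_of(cube_clean, me), seg_cfg)$mask
  })
  names(truth) <- methods

  sig_rms <- rms(clean$samples)
  res <- list()
  for (g in seq_along(snr_grid)) {
    snr <- snr_grid[g]
    failed <- array(FALSE, dim = c(length(methods), length(thresholds), n_frames),
                    dimnames = list(methods, NULL, NULL))
    for (f in seq_len(n_frames)) {
      frame_seed <- seed + (g - 1L) * n_frames + f - 1L
      if (is.finite(snr)) {
        target_rms <- sig_rms * 10^(-snr / 20)
        noise <- with_local_seed(frame_seed, {
          matrix(stats::rnorm(length(clean$samples)), nrow(clean$samples))
        })
        noise <- noise * (target_rms / rms(noise))
        samples <- signal_scale * clean$samples + noise
      } else {
        samples <- signal_scale * clean$samples
      }
      frame <- channel_data(samples, geometry, depth)
      cube <- aperture_cube(frame, num_scanlines, filt)
      for (me in methods) {
        img <- image_of(cube, me)
        for (ti in seq_along(thresholds)) {
          cfg_t <- seg_config(thresholds[ti], seg_cfg$dilate_radius,
                              seg_cfg$erode_radius)
          seg <- segment_target(img, cfg_t)
          failed[me, ti, f] <- segmentation_failed(seg, truth[[me]])
        }
      }
    }
    for (me in methods) {
      pct <- 100 * apply(failed[me, , , drop = FALSE], 2, mean)
      res[[length(res) + 1L]] <- data.frame(
        method = me, snr_db = snr,
        mean_pct_failed = mean(pct), sd_pct_failed = stats::sd(pct))
    }
  }
  do.call(rbind, res)
}
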