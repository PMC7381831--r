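#' Evaluate the shared source pulse
#'
#' Time-domain pulse emitted by the point source and received (delayed) by
#' every element. The Gaussian-modulated sinusoid has its -6 dB amplitude
#' bandwidth equal to `fractional_bandwidth * f0`; the N-shaped pulse is the
#' classic thermoelastic bipolar ramp with half-duration `1/(2 f0)`.
#'
#' @param tau Time in microseconds relative to the arrival time.
#' @param f0 Center frequency in MHz.
#' @param bw Fractional bandwidth (Gaussian pulse only).
#' @param model `"gaussian"` or `"nshape"`.
#' @return Pulse amplitude, peak 1.
#' @keywords internal
pulse_waveform <- function(tau, f0, bw, model = c("gaussian", "nshape")) {
  model <- match.arg(model)
  if (model == "gaussian") {
    sigma <- sqrt(2 * log(2)) / (pi * bw * f0)
    out <- exp(-tau^2 / (2 * sigma^2)) * cos(2 * pi * f0 * tau)
    out[abs(tau) > 4 * sigma] <- 0
    out
  } else {
    half <- 1 / (2 * f0)
    out <- ifelse(abs(tau) <= half, -tau / half, 0)
    out
  }
}

# Run expr with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards (keeps simulations reproducible without
# clobbering the session RNG).
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate one frame of photoacoustic channel data
#'
#' Generates the channel data a linear array would record from a single
#' coherent point source (e.g. an optical fiber tip): element `i` receives a
#' copy of the shared pulse delayed by its one-way time of flight
#' `t_i = sqrt((x_s - x_i)^2 + s^2) / c`. Optionally adds i.i.d. zero-mean
#' Gaussian noise scaled so the channel SNR (rms signal over rms noise, in
#' dB, measured over the entire frame) exactly equals `noise_snr_db`.
#'
#' @param geometry A [array_geometry()] object.
#' @param source A [source_spec()] object; its depth must be smaller than
#'   `depth` and its lateral position inside the aperture.
#' @param depth Image depth `d` in mm; sets `Nz = round(d / (c/fs))`.
#' @param noise_snr_db Target channel SNR in dB, or `NULL` for noiseless
#'   data. Requires `seed`.
#' @param seed Integer seed for the noise draw (required when
#'   `noise_snr_db` is given).
#' @param spherical_decay If `TRUE`, scale each element's copy by
#'   `s / r_i` (1/r spherical spreading referenced to the source depth).
#'   Default `FALSE`, which keeps the received waveforms identical across
#'   elements up to the delay.
#' @param frame_index Frame counter stored in the result.
#'
#' @return A [channel_data()] object. When noise was added, the noiseless
#'   signal and the noise matrix are attached as attributes `"signal"` and
#'   `"noise"`.
#' @examples
#' geom <- array_geometry(num_elements = 32)
#' frame <- simulate_channel_data(geom, source_spec(depth = 20), depth = 30)
#' @export
simulate_channel_data <- function(geometry, source, depth,
                                  noise_snr_db = NULL, seed = NULL,
                                  spherical_decay = FALSE,
                                  frame_index = 0L) {
  stopifnot(inherits(geometry, "pa_geometry"), inherits(source, "pa_source"))
  if (source$depth >= depth) {
    stop("source depth (", source$depth, " mm) must be smaller than the image depth (",
         depth, " mm)")
  }
  half_ap <- max(abs(geometry$element_x)) + geometry$pitch / 2
  if (abs(source$lateral) > half_ap) {
    stop("source lateral position ", source$lateral,
         " mm is outside the field of view (half-aperture ",
         signif(half_ap, 4), " mm)")
  }
  if (!is.null(noise_snr_db) && is.null(seed)) {
    stop("a seed is required when noise_snr_db is given")
  }

  c_mm <- sound_speed_mm_us(geometry)
  fs <- geometry$sampling_frequency
  nz <- depth_to_samples(geometry, depth)
  ni <- geometry$num_elements

  r <- sqrt((source$lateral - geometry$element_x)^2 + source$depth^2)  # mm
  t_arrival <- r / c_mm                                                # us
  tau <- matrix(seq_len(nz) - 1, nz, ni) / fs -
    matrix(t_arrival, nz, ni, byrow = TRUE)
  samples <- source$amplitude *
    pulse_waveform(tau, geometry$center_frequency,
                   geometry$fractional_bandwidth, source$pulse)
  if (spherical_decay) {
    samples <- samples * matrix(source$depth / r, nz, ni, byrow = TRUE)
  }

  frame <- channel_data(samples, geometry, depth, frame_index)
  if (!is.null(noise_snr_db) && is.finite(noise_snr_db)) {
    noisy <- add_channel_noise(frame, noise_snr_db, seed)
    frame <- noisy$frame
    attr(frame, "signal") <- samples
    attr(frame, "noise") <- noisy$noise
  }
  frame
}

#' Source trajectory for visual-servoing experiments
#'
#' Builds the lateral motion of the photoacoustic source over time, sampled
#' at the laser pulse repetition frequency (one frame per laser pulse).
#' Two kinds are supported: `"centering"`, a static source laterally offset
#' from the image center (probe-centering experiment), and `"tracking"`, a
#' linear lateral ramp (fiber-tracking experiment).
#'
#' @param kind `"centering"` or `"tracking"`.
#' @param prf Pulse repetition frequency in Hz (> 0); the frame interval is
#'   `1/prf` seconds.
#' @param offset Centering: constant lateral source position in mm
#'   (default 6).
#' @param distance Tracking: total lateral travel in mm (default 10); 0
#'   gives a constant trajectory.
#' @param duration Total duration in seconds (default 20 for centering,
#'   40 for tracking).
#' @param start Tracking: initial lateral position in mm (default 0).
#'
#' @return An object of class `pa_trajectory`: a data frame with columns
#'   `time` (s) and `position` (mm), with attributes `kind` and
#'   `frame_interval`.
#' @examples
#' tr <- make_trajectory("tracking", prf = 10, distance = 10, duration = 40)
#' nrow(tr)  # 400 frames
#' @export
make_trajectory <- function(kind = c("centering", "tracking"), prf = 10,
                            offset = 6, distance = 10, duration = NULL,
                            start = 0) {
  kind <- match.arg(kind)
  stopifnot(prf > 0)
  if (is.null(duration)) duration <- if (kind == "centering") 20 else 40
  stopifnot(duration > 0)
  n <- as.integer(round(duration * prf))
  stopifnot(n >= 1L)
  time <- (seq_len(n) - 1L) / prf
  position <- if (kind == "centering") {
    rep(offset, n)
  } else if (n == 1L) {
    rep(start, n)
  } else {
    start + distance * (time - time[1]) / (time[n] - time[1])
  }
  structure(
    data.frame(time = time, position = position),
    kind = kind,
    frame_interval = 1 / prf,
    class = c("pa_trajectory", "data.frame")
  )
}

#' Simulate a sequence of frames along a trajectory
#'
#' One channel-data frame per trajectory point, with independent per-frame
#' noise draws from a seeded stream (frame `j` uses seed `seed + j - 1`).
#'
#' @param geometry A [array_geometry()].
#' @param trajectory A [make_trajectory()] result (non-empty).
#' @param source_depth Source depth `s` in mm.
#' @param depth Image depth `d` in mm.
#' @param noise_snr_db Channel SNR in dB or `NULL` for noiseless frames.
#' @param seed Base integer seed (required when noise is requested).
#' @param amplitude Source amplitude.
#' @return A list of [channel_data()] frames.
#' @export
simulate_sequence <- function(geometry, trajectory, source_depth, depth,
                              noise_snr_db = NULL, seed = NULL,
                              amplitude = 1) {
  stopifnot(inherits(trajectory, "pa_trajectory"))
  if (nrow(trajectory) == 0L) stop("trajectory is empty")
  lapply(seq_len(nrow(trajectory)), function(j) {
    src <- source_spec(lateral = trajectory$position[j], depth = source_depth,
                       amplitude = amplitude)
    simulate_channel_data(
      geometry, src, depth,
      noise_snr_db = noise_snr_db,
      seed = if (is.null(seed)) NULL else seed + j - 1L,
      frame_index = j - 1L
    )
  })
}
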