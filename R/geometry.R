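#' Linear-array acquisition geometry
#'
#' Describes the receive geometry and sampling of a linear ultrasound array
#' used for photoacoustic acquisition. Element lateral positions are centered
#' on lateral 0, i.e. `x_i = (i - (Ni - 1)/2) * pitch` for `i = 0..Ni-1`.
#'
#' The default values describe a 128-element array with 0.3 mm pitch sampled
#' at 40 MHz in soft tissue (1540 m/s), receiving a 5 MHz pulse with 60%
#' fractional bandwidth.
#'
#' @param num_elements Number of receive elements `Ni` (>= 2).
#' @param pitch Element pitch in mm.
#' @param sampling_frequency Sampling frequency `fs` in MHz.
#' @param sound_speed Speed of sound `c` in m/s.
#' @param center_frequency Pulse center frequency `f0` in MHz.
#' @param fractional_bandwidth Pulse fractional bandwidth (dimensionless,
#'   e.g. 0.6 for 60%).
#'
#' @return An object of class `pa_geometry`: a list with fields
#'   `num_elements`, `pitch`, `element_x` (element lateral positions, mm),
#'   `sampling_frequency`, `sound_speed`, `center_frequency`,
#'   `fractional_bandwidth`.
#' @examples
#' geom <- array_geometry(num_elements = 64)
#' range(geom$element_x)
#' @export
array_geometry <- function(num_elements = 128L,
                           pitch = 0.3,
                           sampling_frequency = 40,
                           sound_speed = 1540,
                           center_frequency = 5,
                           fractional_bandwidth = 0.6) {
  num_elements <- as.integer(num_elements)
  stopifnot(num_elements >= 2L, pitch > 0, sampling_frequency > 0,
            sound_speed > 0, center_frequency > 0,
            fractional_bandwidth > 0)
  # Nyquist for the upper band edge of the simulated pulse
  f_hi <- center_frequency * (1 + fractional_bandwidth / 2)
  if (sampling_frequency <= 2 * f_hi) {
    stop("sampling_frequency must exceed twice the pulse's upper band edge (",
         signif(2 * f_hi, 4), " MHz)")
  }
  i <- seq_len(num_elements) - 1L
  structure(
    list(
      num_elements = num_elements,
      pitch = pitch,
      element_x = (i - (num_elements - 1) / 2) * pitch,
      sampling_frequency = sampling_frequency,
      sound_speed = sound_speed,
      center_frequency = center_frequency,
      fractional_bandwidth = fractional_bandwidth
    ),
    class = "pa_geometry"
  )
}

#' @export
print.pa_geometry <- function(x, ...) {
  cat(sprintf(
    "<pa_geometry> %d elements, pitch %.3g mm, fs %.3g MHz, c %.4g m/s, f0 %.3g MHz (%.0f%% bw)\n",
    x$num_elements, x$pitch, x$sampling_frequency, x$sound_speed,
    x$center_frequency, 100 * x$fractional_bandwidth))
  invisible(x)
}

#' Sound speed in mm per microsecond
#' @param geometry A `pa_geometry`.
#' @return Sound speed in mm/us.
#' @keywords internal
#' @noRd
sound_speed_mm_us <- function(geometry) geometry$sound_speed / 1000

#' Axial sample spacing in mm
#'
#' One-way photoacoustic depth mapping: the depth of axial sample `t`
#' (0-based) is `z = c * t / fs`, so samples are `c / fs` apart.
#'
#' @param geometry A `pa_geometry`.
#' @return Axial spacing in mm per sample.
#' @export
axial_spacing <- function(geometry) {
  sound_speed_mm_us(geometry) / geometry$sampling_frequency
}

#' Photoacoustic point-source specification
#'
#' A single isotropic point source (e.g. an optical fiber tip) emitting one
#' shared bandlimited pulse received by all array elements.
#'
#' @param lateral Lateral position `x_s` in mm (0 = array center).
#' @param depth Source depth `s` in mm (> 0).
#' @param amplitude Peak amplitude, arbitrary linear units (>= 0).
#' @param pulse Pulse model: `"gaussian"` (Gaussian-modulated sinusoid,
#'   default) or `"nshape"` (N-shaped thermoelastic pulse).
#'
#' @return An object of class `pa_source`.
#' @examples
#' src <- source_spec(lateral = 6, depth = 40)
#' @export
source_spec <- function(lateral = 0, depth = 40, amplitude = 1,
                        pulse = c("gaussian", "nshape")) {
  pulse <- match.arg(pulse)
  stopifnot(is.finite(lateral), depth > 0, amplitude >= 0)
  structure(
    list(lateral = lateral, depth = depth, amplitude = amplitude,
         pulse = pulse),
    class = "pa_source"
  )
}

#' Construct a channel-data frame
#'
#' Wraps a real `Nz x Ni` matrix of radio-frequency samples (axial samples in
#' rows, receive elements in columns) together with its acquisition geometry.
#'
#' @param samples Real matrix, `Nz` axial samples by `Ni` elements.
#' @param geometry The `pa_geometry` the data were acquired with.
#' @param depth Image depth `d` in mm; `Nz` must equal
#'   `round(d / axial_spacing(geometry))`.
#' @param frame_index Optional frame counter (default 0).
#' @return An object of class `pa_channel_data`.
#' @export
channel_data <- function(samples, geometry, depth,
                         frame_index = 0L) {
  stopifnot(is.matrix(samples), is.numeric(samples),
            inherits(geometry, "pa_geometry"), depth > 0)
  if (!all(is.finite(samples))) stop("channel data samples must be finite")
  if (ncol(samples) != geometry$num_elements) {
    stop("samples must have one column per element (", geometry$num_elements,
         "), got ", ncol(samples))
  }
  nz_expected <- depth_to_samples(geometry, depth)
  if (nrow(samples) != nz_expected) {
    stop("samples must have ", nz_expected, " rows for depth ", depth,
         " mm, got ", nrow(samples))
  }
  structure(
    list(samples = samples, geometry = geometry, depth = depth,
         frame_index = as.integer(frame_index)),
    class = "pa_channel_data"
  )
}

#' Number of axial samples for a given image depth
#' @param geometry A `pa_geometry`.
#' @param depth Image depth in mm.
#' @return Integer sample count `Nz = round(d / (c/fs))`.
#' @export
depth_to_samples <- function(geometry, depth) {
  as.integer(round(depth / axial_spacing(geometry)))
}

#' @export
print.pa_channel_data <- function(x, ...) {
  cat(sprintf("<pa_channel_data> %d axial samples x %d elements, depth %.3g mm, frame %d\n",
              nrow(x$samples), ncol(x$samples), x$depth, x$frame_index))
  invisible(x)
}
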