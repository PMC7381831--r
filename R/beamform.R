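#' Beamformed image container
#'
#' Nonnegative pre-log image values on the scanline grid, with physical
#' pixel spacings. Rows are axial samples (depth increasing downward),
#' columns are scanlines.
#'
#' @param values Real `Nz x Nx` matrix, values >= 0.
#' @param lateral_x Scanline lateral positions in mm (length `Nx`).
#' @param dz Axial pixel spacing in mm (one-way, `c/fs`).
#' @param method Beamformer tag, e.g. `"das"` or `"slsc"`.
#' @param normalized Logical: `TRUE` once the maximum has been scaled to 1.
#' @return An object of class `pa_image`.
#' @export
pa_image <- function(values, lateral_x, dz, method = "unknown",
                     normalized = FALSE) {
  stopifnot(is.matrix(values), length(lateral_x) == ncol(values), dz > 0)
  if (any(values < 0)) stop("pa_image values must be nonnegative")
  structure(
    list(values = values, lateral_x = lateral_x,
         dx = if (length(lateral_x) > 1) diff(lateral_x[1:2]) else NA_real_,
         dz = dz, method = method, normalized = isTRUE(normalized)),
    class = "pa_image"
  )
}

#' @export
print.pa_image <- function(x, ...) {
  cat(sprintf("<pa_image:%s> %d axial x %d lateral (dz %.4g mm, dx %.4g mm)%s\n",
              x$method, nrow(x$values), ncol(x$values), x$dz, x$dx,
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Axial pixel depths of an image (mm)
#' @param img A `pa_image` or `pa_display`.
#' @return Numeric vector of axial positions, `z_t = t * dz` (0-based).
#' @export
axial_positions <- function(img) (seq_len(nrow(img$values)) - 1) * img$dz

#' Regroup channel acquisitions into one full-aperture frame
#'
#' Systems with fewer receive channels `Nc` than array elements `Ni` record
#' a frame in `NA = Ni / Nc` successive acquisitions; this concatenates the
#' acquisition blocks along the element axis in acquisition order.
#'
#' @param blocks List of `Nz x Nc` matrices, in acquisition order; the list
#'   length must equal `Ni / Nc`, which must be an integer.
#' @param geometry A [array_geometry()] with `Ni` elements.
#' @param depth Image depth in mm.
#' @param frame_index Frame counter.
#' @return A [channel_data()] frame with `Ni` columns.
#' @export
regroup_channels <- function(blocks, geometry, depth, frame_index = 0L) {
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  ni <- geometry$num_elements
  nc <- ncol(blocks[[1]])
  if (ni %% nc != 0L) {
    stop("number of elements (", ni, ") is not divisible by the channel count (",
         nc, ")")
  }
  n_acq <- ni %/% nc
  if (length(blocks) != n_acq) {
    stop("expected ", n_acq, " acquisition blocks (Ni/Nc), got ", length(blocks))
  }
  if (!all(vapply(blocks, ncol, 1L) == nc)) {
    stop("all acquisition blocks must have the same channel count")
  }
  channel_data(do.call(cbind, blocks), geometry, depth, frame_index)
}

#' Design the DC-removal high-pass filter
#'
#' Odd-length linear-phase windowed-sinc high-pass filter applied along the
#' axial (time) dimension of each channel to remove the DC and very-low-
#' frequency content of the raw recording. The design is adjusted so the DC
#' gain is exactly zero (a constant offset is removed completely) while the
#' passband is left within the design ripple.
#'
#' @param cutoff Cutoff frequency in MHz (default 0.5).
#' @param taps Number of coefficients (odd; default 33).
#' @param sampling_frequency Sampling frequency in MHz (default 40).
#' @return An object of class `pa_filter` with fields `coef`, `cutoff`,
#'   `taps`, `sampling_frequency`.
#' @export
design_dc_filter <- function(cutoff = 0.5, taps = 33L,
                             sampling_frequency = 40) {
  taps <- as.integer(taps)
  stopifnot(taps >= 3L, taps %% 2L == 1L, cutoff > 0,
            cutoff < sampling_frequency / 2)
  h <- as.numeric(signal::fir1(taps - 1L, cutoff / (sampling_frequency / 2),
                               type = "high"))
  h <- h - sum(h) / length(h)  # null the DC gain exactly; keeps symmetry
  structure(
    list(coef = h, cutoff = cutoff, taps = taps,
         sampling_frequency = sampling_frequency),
    class = "pa_filter"
  )
}

# Same-length zero-padded convolution of a vector with an odd-length kernel.
conv_same <- function(x, h) {
  n <- length(x)
  half <- (length(h) - 1L) %/% 2L
  y <- stats::convolve(c(rep(0, half), x, rep(0, half)), rev(h),
                       type = "filter")
  y[seq_len(n)]
}

#' Remove the DC component of each channel
#'
#' Convolves every element's axial recording with the high-pass kernel
#' (same-length output, zero-padded edges), executed independently along the
#' axial dimension.
#'
#' @param frame A [channel_data()] frame.
#' @param filt A [design_dc_filter()] object (odd length, shorter than the
#'   recording).
#' @return A [channel_data()] frame of identical shape.
#' @export
remove_dc <- function(frame, filt = design_dc_filter(
                        sampling_frequency = frame$geometry$sampling_frequency)) {
  stopifnot(inherits(frame, "pa_channel_data"), inherits(filt, "pa_filter"))
  h <- filt$coef
  if (length(h) %% 2L == 0L) {
    stop("DC-removal filter must have odd length to preserve group-delay alignment")
  }
  if (length(h) >= nrow(frame$samples)) {
    stop("filter length must be smaller than the number of axial samples")
  }
  out <- apply(frame$samples, 2L, conv_same, h = h)
  channel_data(out, frame$geometry, frame$depth, frame$frame_index)
}

#' Analytic signal along the axial dimension
#'
#' Computes the discrete analytic signal of every channel with the FFT
#' (one-sided spectrum doubling), so the complex magnitude is the envelope
#' and the real part equals the input.
#'
#' @param frame A [channel_data()] frame (or a real matrix with axial
#'   samples in rows).
#' @return Complex `Nz x Ni` matrix.
#' @export
analytic_signal <- function(frame) {
  x <- if (inherits(frame, "pa_channel_data")) frame$samples else frame
  stopifnot(is.matrix(x), nrow(x) >= 2L)
  nz <- nrow(x)
  w <- numeric(nz)
  if (nz %% 2L == 0L) {
    w[1L] <- 1
    w[nz / 2L + 1L] <- 1
    w[2L:(nz / 2L)] <- 2
  } else {
    w[1L] <- 1
    w[2L:((nz + 1L) / 2L)] <- 2
  }
  xf <- stats::mvfft(x) * w
  stats::mvfft(xf, inverse = TRUE) / nz
}

#' Synthetic receive-aperture delay table
#'
#' One-way photoacoustic receive delays, in fractional sample units, from
#' each image pixel to each element: for scanline `l` at lateral `x_l`,
#' element `i` at `x_i`, and axial sample `t` (0-based, depth
#' `z_t = c t / fs`),
#' `delay(i, l, t) = sqrt(z_t^2 + (x_l - x_i)^2) / c * fs
#'                 = sqrt(t^2 + b_il^2)`
#' with `b_il = (x_l - x_i) * fs / c` the lateral offset in samples. The
#' hypotenuse is never shorter than the axial leg, so `delay >= t`.
#'
#' Scanline lateral positions span the aperture uniformly; at line density 1
#' (`num_scanlines = Ni`, the default) they coincide with the element
#' positions.
#'
#' @param geometry A [array_geometry()].
#' @param depth Image depth in mm (> 0); sets `Nz`.
#' @param num_scanlines Number of scanlines `Nx` (default `Ni`).
#' @return An object of class `pa_delay_table` with fields
#'   `lateral_offset_samples` (`Ni x Nx` matrix of `b_il`), `scanline_x`
#'   (mm), `nz`, and `geometry`.
#' @export
receive_delay_table <- function(geometry, depth,
                                num_scanlines = geometry$num_elements) {
  if (depth <= 0) stop("depth must be positive")
  num_scanlines <- as.integer(num_scanlines)
  stopifnot(num_scanlines >= 1L)
  xe <- geometry$element_x
  xl <- if (num_scanlines == 1L) 0
    else if (num_scanlines == geometry$num_elements) xe  # density 1: exact
    else seq(min(xe), max(xe), length.out = num_scanlines)
  samples_per_mm <- geometry$sampling_frequency / sound_speed_mm_us(geometry)
  b <- outer(xe, xl, function(a, b) (b - a) * samples_per_mm)
  structure(
    list(lateral_offset_samples = b, scanline_x = xl,
         nz = depth_to_samples(geometry, depth), geometry = geometry),
    class = "pa_delay_table"
  )
}

#' Look up a single receive delay
#' @param delays A [receive_delay_table()].
#' @param element Element index (1-based).
#' @param scanline Scanline index (1-based).
#' @param t Axial sample index (0-based), may be a vector.
#' @return Delay in fractional samples.
#' @export
delay_at <- function(delays, element, scanline, t) {
  b <- delays$lateral_offset_samples[element, scanline]
  sqrt(t^2 + b^2)
}

#' Delay channel data onto the scanline grid
#'
#' Builds the aperture data cube `s_i(z, x)`: for every pixel, each
#' element's analytic signal is sampled at its fractional receive delay by
#' linear interpolation. Delays that need data beyond the recording yield 0.
#'
#' @param analytic Complex `Nz x Ni` matrix from [analytic_signal()].
#' @param delays A [receive_delay_table()].
#' @return An object of class `pa_cube`: a complex array of dimension
#'   `(Nz, Ni, Nx)` (axial fastest) plus grid metadata.
#' @export
apply_delays <- function(analytic, delays) {
  stopifnot(inherits(delays, "pa_delay_table"))
  nz <- nrow(analytic)
  ni <- ncol(analytic)
  if (nz != delays$nz) {
    stop("analytic data has ", nz, " axial samples but the delay table expects ",
         delays$nz)
  }
  if (ni != nrow(delays$lateral_offset_samples)) {
    stop("analytic data has ", ni, " elements but the delay table expects ",
         nrow(delays$lateral_offset_samples))
  }
  nx <- ncol(delays$lateral_offset_samples)
  t2 <- matrix((seq_len(nz) - 1)^2, nz, ni)
  col_off <- rep((seq_len(ni) - 1L) * nz, each = nz)
  cube <- array(complex(real = 0, imaginary = 0), dim = c(nz, ni, nx))
  for (l in seq_len(nx)) {
    d <- sqrt(t2 + matrix(delays$lateral_offset_samples[, l]^2, nz, ni,
                          byrow = TRUE))
    i0 <- floor(d)
    frac <- d - i0
    valid <- i0 <= nz - 2L  # need samples i0 and i0+1
    i0[!valid] <- 0
    flat <- as.integer(i0) + 1L + col_off
    s <- analytic[flat] * (1 - frac) + analytic[flat + 1L] * frac
    s[!valid] <- 0
    cube[, , l] <- s
  }
  structure(
    list(data = cube,
         scanline_x = delays$scanline_x,
         dz = axial_spacing(delays$geometry),
         geometry = delays$geometry),
    class = "pa_cube"
  )
}

#' @export
print.pa_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<pa_cube> %d elements x %d scanlines x %d axial samples\n",
              d[2], d[3], d[1]))
  invisible(x)
}

#' Delay-and-sum beamforming
#'
#' Conventional DAS baseline: the delayed analytic signals are summed
#' coherently across elements and envelope-detected (complex magnitude of
#' the sum).
#'
#' @param cube A [apply_delays()] result.
#' @return A [pa_image()] (not normalized).
#' @export
das_beamform <- function(cube) {
  stopifnot(inherits(cube, "pa_cube"))
  d <- dim(cube$data)
  vals <- vapply(seq_len(d[3]),
                 function(l) Mod(rowSums(cube$data[, , l, drop = FALSE], dims = 1L)),
                 numeric(d[1]))
  pa_image(matrix(vals, d[1], d[3]), cube$scanline_x, cube$dz, method = "das")
}

#' Ensemble coherence factors at one lag
#'
#' For lag `m`, the ensemble sums over the first `Ni - m` element pairs:
#' `Cij(z,x,m) = sum_i s_i(z,x) * Conj(s_(i+m)(z,x))`,
#' `Cii(z,x,m) = sum_i |s_i(z,x)|^2`,
#' `Cjj(z,x,m) = sum_i |s_(i+m)(z,x)|^2`.
#'
#' @param cube A [apply_delays()] result.
#' @param m Lag, `1 <= m <= Ni - 1`.
#' @return List with complex matrix `Cij` and real matrices `Cii`, `Cjj`,
#'   each `Nz x Nx`, plus the lag `m`.
#' @export
slsc_coherence <- function(cube, m) {
  stopifnot(inherits(cube, "pa_cube"))
  d <- dim(cube$data)
  ni <- d[2]
  m <- as.integer(m)
  if (m < 1L || m > ni - 1L) {
    stop("lag m must satisfy 1 <= m <= Ni - 1 (Ni = ", ni, ")")
  }
  nz <- d[1]; nx <- d[3]
  cij <- matrix(complex(real = 0, imaginary = 0), nz, nx)
  cii <- matrix(0, nz, nx)
  cjj <- matrix(0, nz, nx)
  lo <- seq_len(ni - m)
  hi <- lo + m
  for (l in seq_len(nx)) {
    a <- cube$data[, lo, l, drop = FALSE]
    b <- cube$data[, hi, l, drop = FALSE]
    cij[, l] <- rowSums(a * Conj(b), dims = 1L)
    cii[, l] <- rowSums(Mod(a)^2, dims = 1L)
    cjj[, l] <- rowSums(Mod(b)^2, dims = 1L)
  }
  list(Cij = cij, Cii = cii, Cjj = cjj, m = m)
}

# Truncated axial running sum: column-wise moving sum over a window of k
# samples centered on each row, truncated (not zero-padded) at the edges.
axial_running_sum <- function(x, k) {
  if (k == 1L) return(x)
  nz <- nrow(x)
  half <- (k - 1L) %/% 2L
  cs <- apply(x, 2L, cumsum)
  if (!is.matrix(cs)) cs <- matrix(cs, nrow = nz)
  lo <- pmax(0L, seq_len(nz) - 1L - half)       # 0-based window start
  hi <- pmin(nz - 1L, seq_len(nz) - 1L + half)  # 0-based window end
  up <- cs[hi + 1L, , drop = FALSE]
  down <- rbind(0, cs)[lo + 1L, , drop = FALSE]
  up - down
}

#' Short-lag spatial coherence image
#'
#' Compounds the ensemble coherence factors across an axial kernel of `k`
#' samples and the first `M` lags: per pixel,
#' `SLSC(z,x) = sum_(m=1..M) Re(sum_k Cij) / sqrt(sum_k Cii * sum_k Cjj)`,
#' where `sum_k` is the axial window of `k` samples centered on `z`
#' (truncated at the image edges). Pixels with a vanishing denominator give
#' 0, and negative compounded values are clipped to zero, so the result
#' lies in `[0, M]`.
#'
#' The denominator guard is relative as well as absolute: a pixel yields 0
#' when its compounded energy product falls below
#' `max(1e-30, (1e-6 * scanline energy)^2)`. Pixels that faint carry no
#' physical information, and the relative floor keeps the roundoff noise
#' of the lag sums (which scales with the total scanline energy) from
#' masquerading as coherence in empty regions of noiseless data.
#'
#' @param cube A [apply_delays()] result.
#' @param M Cumulative lag (default 25), `1 <= M <= Ni - 1`.
#' @param k Axial kernel size in samples (odd, default 11).
#' @return A [pa_image()] (not normalized); values in `[0, M]`.
#' @export
slsc_image <- function(cube, M = 25L, k = 11L) {
  stopifnot(inherits(cube, "pa_cube"))
  d <- dim(cube$data)
  M <- as.integer(M); k <- as.integer(k)
  if (M < 1L || M > d[2] - 1L) {
    stop("cumulative lag M must satisfy 1 <= M <= Ni - 1 (Ni = ", d[2], ")")
  }
  if (k < 1L || k %% 2L == 0L) stop("axial kernel k must be odd and >= 1")
  nz <- d[1]; ni <- d[2]; nx <- d[3]
  acc <- matrix(0, nz, nx)
  # Cii/Cjj for every lag are prefix sums of |s_i|^2 over the element axis;
  # Cij for all lags at once is the element-axis autocorrelation, computed
  # with a zero-padded FFT. Numerically equivalent to the per-lag sums of
  # slsc_coherence() up to roundoff.
  ut <- upper.tri(matrix(0, ni, ni), diag = TRUE) * 1
  len <- 2L * ni
  for (l in seq_len(nx)) {
    s <- cube$data[, , l]
    p <- Re(s * Conj(s))
    cum_p <- p %*% ut                      # cum_p[, j] = sum_{i<=j} |s_i|^2
    tot <- cum_p[, ni]
    xp <- rbind(t(s), matrix(0, len - ni, nz))
    f <- stats::mvfft(xp)
    r <- stats::mvfft(f * Conj(f), inverse = TRUE) / len  # r[m+1,z] = sum_i s_(i+m) s_i*
    ms <- seq_len(M)
    num <- axial_running_sum(t(Re(r[ms + 1L, , drop = FALSE])), k)   # nz x M
    den <- axial_running_sum(cum_p[, ni - ms, drop = FALSE], k) *
      axial_running_sum(tot - cum_p[, ms, drop = FALSE], k)
    term <- matrix(0, nz, M)
    ok <- den >= max(1e-30, (1e-6 * sum(tot))^2)
    term[ok] <- num[ok] / sqrt(den[ok])
    acc[, l] <- rowSums(term)
  }
  acc[acc < 0] <- 0
  pa_image(acc, cube$scanline_x, cube$dz, method = "slsc")
}

#' Normalize a beamformed image to unit maximum
#' @param img A [pa_image()].
#' @return The image scaled so its maximum is 1 (all-zero images are left
#'   unchanged), with `normalized = TRUE`.
#' @export
normalize_image <- function(img) {
  stopifnot(inherits(img, "pa_image"))
  mx <- max(img$values)
  vals <- if (mx > 0) img$values / mx else img$values
  pa_image(vals, img$lateral_x, img$dz, img$method, normalized = TRUE)
}

#' Normalize and log-compress for display
#'
#' Scales by the global image maximum and maps to decibels,
#' `20 log10(value / max)`, floored at `-dynamic_range`. An all-zero image
#' maps to a uniform `-dynamic_range` display.
#'
#' @param img A [pa_image()].
#' @param dynamic_range Display dynamic range DR in dB (> 0, default 15).
#' @return An object of class `pa_display`: like `pa_image` but with dB
#'   values in `[-DR, 0]` and a `dynamic_range` field.
#' @export
normalize_log_compress <- function(img, dynamic_range = 15) {
  stopifnot(inherits(img, "pa_image"), dynamic_range > 0)
  mx <- max(img$values)
  if (mx > 0) {
    db <- suppressWarnings(20 * log10(img$values / mx))
    db <- pmax(db, -dynamic_range)
  } else {
    db <- matrix(-dynamic_range, nrow(img$values), ncol(img$values))
  }
  structure(
    list(values = db, lateral_x = img$lateral_x, dx = img$dx, dz = img$dz,
         method = img$method, dynamic_range = dynamic_range),
    class = "pa_display"
  )
}

#' @export
print.pa_display <- function(x, ...) {
  cat(sprintf("<pa_display:%s> %d axial x %d lateral, %g dB dynamic range\n",
              x$method, nrow(x$values), ncol(x$values), x$dynamic_range))
  invisible(x)
}

#' Delay channel data into an aperture cube
#'
#' Convenience composition of the front half of the pipeline:
#' DC removal, analytic-signal transform, and receive delaying.
#'
#' @param frame A [channel_data()] frame.
#' @param num_scanlines Number of scanlines (default one per element).
#' @param filt DC-removal filter (default designed for the frame's sampling
#'   frequency).
#' @return A `pa_cube`.
#' @export
aperture_cube <- function(frame,
                          num_scanlines = frame$geometry$num_elements,
                          filt = design_dc_filter(
                            sampling_frequency = frame$geometry$sampling_frequency)) {
  filtered <- remove_dc(frame, filt)
  analytic <- analytic_signal(filtered)
  delays <- receive_delay_table(frame$geometry, frame$depth, num_scanlines)
  apply_delays(analytic, delays)
}

#' Beamform one frame end to end
#'
#' Full pipeline: DC removal, analytic signal, receive delays, beamforming
#' (DAS or SLSC), normalization, and log compression.
#'
#' @param frame A [channel_data()] frame.
#' @param method `"slsc"` (default) or `"das"`.
#' @param M,k SLSC compounding parameters (ignored for DAS).
#' @param num_scanlines Number of scanlines (default one per element).
#' @param dynamic_range Display dynamic range in dB.
#' @param filt DC-removal filter.
#' @return A list with `image` (normalized pre-log [pa_image()]) and
#'   `display` (log-compressed `pa_display`).
#' @examples
#' geom <- array_geometry(num_elements = 16, sampling_frequency = 20)
#' frame <- simulate_channel_data(geom, source_spec(depth = 10), depth = 15)
#' bf <- beamform_frame(frame, method = "slsc", M = 5, k = 3)
#' @export
beamform_frame <- function(frame, method = c("slsc", "das"), M = 25L, k = 11L,
                           num_scanlines = frame$geometry$num_elements,
                           dynamic_range = 15,
                           filt = design_dc_filter(
                             sampling_frequency = frame$geometry$sampling_frequency)) {
  method <- match.arg(method)
  cube <- aperture_cube(frame, num_scanlines, filt)
  img <- if (method == "das") das_beamform(cube) else slsc_image(cube, M, k)
  list(image = normalize_image(img),
       display = normalize_log_compress(img, dynamic_range))
}
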