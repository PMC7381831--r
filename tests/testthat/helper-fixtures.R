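# Shared fixtures: small geometries, hand-built cubes, and literal
# reference implementations of the coherence equations used as oracles.

small_geometry <- function(ni = 16L, fs = 40) {
  array_geometry(num_elements = ni, pitch = 0.3, sampling_frequency = fs,
                 sound_speed = 1540, center_frequency = 5,
                 fractional_bandwidth = 0.6)
}

# Study-scale geometry for the servoing / degradation experiments:
# 64 elements, 20 MHz sampling, 25 mm image depth, source at 20 mm.
study_geometry <- function() {
  array_geometry(num_elements = 64L, pitch = 0.3, sampling_frequency = 20,
                 sound_speed = 1540, center_frequency = 5,
                 fractional_bandwidth = 0.6)
}

# Wrap a raw complex array (Nz x Ni x Nx) as an aperture data cube.
make_cube <- function(arr, dx = 0.3, dz = 0.0385) {
  stopifnot(length(dim(arr)) == 3L)
  nx <- dim(arr)[3]
  structure(
    list(data = arr,
         scanline_x = (seq_len(nx) - (nx + 1) / 2) * dx,
         dz = dz, geometry = NULL),
    class = "pa_cube")
}

random_cube <- function(nz = 64L, ni = 8L, nx = 4L, seed = 1L) {
  set.seed(seed)
  n <- nz * ni * nx
  make_cube(array(complex(real = rnorm(n), imaginary = rnorm(n)),
                  c(nz, ni, nx)))
}

# A perfectly coherent cube: one waveform replicated across all elements.
coherent_cube <- function(waveform, ni = 8L, nx = 2L) {
  nz <- length(waveform)
  make_cube(array(rep(as.complex(waveform), times = ni * nx),
                  c(nz, ni, nx)))
}

# Literal reference for the per-lag ensemble coherence sums.
naive_coherence <- function(arr, m) {
  d <- dim(arr)
  cij <- matrix(complex(real = 0, imaginary = 0), d[1], d[3])
  cii <- matrix(0, d[1], d[3])
  cjj <- matrix(0, d[1], d[3])
  for (x in seq_len(d[3])) for (z in seq_len(d[1])) {
    for (i in seq_len(d[2] - m)) {
      cij[z, x] <- cij[z, x] + arr[z, i, x] * Conj(arr[z, i + m, x])
      cii[z, x] <- cii[z, x] + Mod(arr[z, i, x])^2
      cjj[z, x] <- cjj[z, x] + Mod(arr[z, i + m, x])^2
    }
  }
  list(Cij = cij, Cii = cii, Cjj = cjj)
}

# Literal triple-loop reference for the compounded coherence image:
# per pixel, lags summed after axial compounding over a truncated window
# of k samples, with the negative values clipped to zero at the end.
naive_slsc <- function(arr, M, k) {
  d <- dim(arr)
  out <- matrix(0, d[1], d[3])
  h <- (k - 1L) %/% 2L
  for (x in seq_len(d[3])) for (z in seq_len(d[1])) {
    zs <- max(1L, z - h):min(d[1], z + h)
    val <- 0
    for (m in seq_len(M)) {
      cij <- 0; cii <- 0; cjj <- 0
      for (zz in zs) for (i in seq_len(d[2] - m)) {
        cij <- cij + arr[zz, i, x] * Conj(arr[zz, i + m, x])
        cii <- cii + Mod(arr[zz, i, x])^2
        cjj <- cjj + Mod(arr[zz, i + m, x])^2
      }
      den <- cii * cjj
      if (den >= 1e-30) val <- val + Re(cij) / sqrt(den)
    }
    out[z, x] <- max(val, 0)
  }
  out
}

# Build a Gaussian-blob image for segmentation/metric tests.
gaussian_blob_image <- function(nz = 80L, nx = 40L, dz = 0.1, dx = 0.3,
                                center_lat = 0, center_ax = 4,
                                sigma = 0.8, normalized = TRUE) {
  x <- (seq_len(nx) - (nx + 1) / 2) * dx
  z <- (seq_len(nz) - 1) * dz
  vals <- outer(z, x, function(zz, xx) {
    exp(-((xx - center_lat)^2 + (zz - center_ax)^2) / (2 * sigma^2))
  })
  img <- pa_image(vals, x, dz, method = "test", normalized = FALSE)
  if (normalized) normalize_image(img) else img
}
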