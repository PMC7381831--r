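test_that("channel regrouping concatenates acquisition blocks in order", {
  geom <- small_geometry(ni = 8L)
  nz <- depth_to_samples(geom, 10)
  blocks <- list(matrix(1, nz, 4), matrix(2, nz, 4))
  frame <- regroup_channels(blocks, geom, depth = 10)
  expect_equal(unname(frame$samples[1, ]), c(rep(1, 4), rep(2, 4)))

  # Ni = Nc: identity pass-through
  one <- matrix(rnorm(nz * 8), nz, 8)
  expect_equal(regroup_channels(list(one), geom, 10)$samples, one)

  # Ni not divisible by Nc, and wrong block counts, are rejected
  expect_error(regroup_channels(list(matrix(0, nz, 3)), geom, 10),
               "not divisible")
  expect_error(regroup_channels(list(matrix(0, nz, 4)), geom, 10),
               "expected 2")
})

test_that("DC-removal filter kills DC, passes the pulse band, and is linear phase", {
  filt <- design_dc_filter(cutoff = 0.5, taps = 33L, sampling_frequency = 40)
  h <- filt$coef
  expect_equal(h, rev(h))                      # symmetric -> linear phase
  expect_lt(abs(sum(h)), 1e-3)                 # DC gain

  geom <- small_geometry(ni = 4L)
  nz <- depth_to_samples(geom, 10)
  # constant column -> output ~ 0 away from the zero-padded edges
  const <- channel_data(matrix(1, nz, 4), geom, 10)
  out <- remove_dc(const, filt)
  interior <- out$samples[33:(nz - 33), ]
  expect_lt(max(abs(interior)), 1e-3)

  # unit impulse column -> the filter coefficients, centered
  imp <- matrix(0, nz, 4); imp[101, ] <- 1
  out2 <- remove_dc(channel_data(imp, geom, 10), filt)
  expect_equal(unname(out2$samples[85:117, 1]), h, tolerance = 1e-12)

  # passband sinusoid preserved within the filter's own response at 5 MHz
  gain5 <- abs(sum(h * exp(-2i * pi * (5 / 40) * (seq_along(h) - 1))))
  t <- (seq_len(nz) - 1) / 40
  sine <- channel_data(matrix(sin(2 * pi * 5 * t), nz, 4), geom, 10)
  out3 <- remove_dc(sine, filt)
  amp <- max(abs(out3$samples[60:(nz - 60), 1]))
  expect_equal(amp, gain5, tolerance = 0.01)

  expect_error(remove_dc(const, structure(list(coef = rep(1, 4)),
                                          class = "pa_filter")), "odd")
})

test_that("analytic signal has the defining one-sided-spectrum properties", {
  nz <- 256L
  x <- matrix(cos(2 * pi * (32 / nz) * (0:(nz - 1))), nz, 2)  # 5 MHz at 40 MHz
  a <- analytic_signal(x)

  expect_equal(Re(a), x, tolerance = 1e-9)
  env <- Mod(a[, 1])
  expect_true(all(abs(env - 1) < 0.01))

  # negative-frequency bins vanish
  sp <- stats::fft(a[, 1])
  neg <- sp[(floor(nz / 2) + 2):nz]
  expect_lt(max(Mod(neg)), 1e-9 * max(Mod(sp)))
})

test_that("receive delays equal the one-way time of flight in samples", {
  geom <- small_geometry(ni = 12L)
  dt <- receive_delay_table(geom, depth = 20, num_scanlines = 12L)
  c_mm_us <- geom$sound_speed / 1000

  # element beneath its own scanline: delay = t exactly
  expect_equal(delay_at(dt, 3L, 3L, 0:99), 0:99)

  # symmetry: elements equidistant from a scanline share delays
  expect_equal(delay_at(dt, 4L, 6L, 17L), delay_at(dt, 8L, 6L, 17L))

  # random triples against an independent scalar computation
  set.seed(9)
  for (r in 1:100) {
    i <- sample(12L, 1); l <- sample(12L, 1); t <- sample(0:400, 1)
    z_mm <- c_mm_us * t / geom$sampling_frequency
    tof_samples <- sqrt(z_mm^2 + (dt$scanline_x[l] - geom$element_x[i])^2) /
      c_mm_us * geom$sampling_frequency
    expect_equal(delay_at(dt, i, l, t), tof_samples, tolerance = 1e-12)
    expect_gte(delay_at(dt, i, l, t), t)  # hypotenuse >= axial leg
  }

  expect_error(receive_delay_table(geom, depth = -1), "positive")
})

test_that("delay application is exact linear interpolation with zero padding", {
  geom <- small_geometry(ni = 4L)
  nz <- depth_to_samples(geom, 5)
  vals <- matrix(complex(real = rnorm(nz * 4), imaginary = rnorm(nz * 4)),
                 nz, 4)
  dt <- receive_delay_table(geom, depth = 5, num_scanlines = 4L)
  cube <- apply_delays(vals, dt)
  for (l in 1:4) for (i in 1:4) {
    d <- delay_at(dt, i, l, 0:(nz - 1))
    i0 <- floor(d); frac <- d - i0
    expected <- ifelse(i0 <= nz - 2,
                       vals[pmin(i0 + 1, nz), i] * (1 - frac) +
                         vals[pmin(i0 + 2, nz), i] * frac,
                       0)
    expect_equal(cube$data[, i, l], expected, tolerance = 1e-12)
  }
  # the on-axis element is an exact sample pick-off (the final sample falls
  # outside the interpolation window and is zeroed)
  expect_identical(cube$data[seq_len(nz - 1), 2, 2], vals[seq_len(nz - 1), 2])
  expect_identical(cube$data[nz, 2, 2], 0 + 0i)
})

test_that("DAS is the envelope of the coherent sum", {
  ni <- 8L
  arr <- array(complex(real = 1, imaginary = 0), c(4, ni, 2))
  img <- das_beamform(make_cube(arr))
  expect_true(all(img$values == ni))

  alt <- array(rep(rep(c(1 + 0i, -1 + 0i), each = 4, times = ni / 2), times = 2),
               c(4, ni, 2))
  expect_true(all(das_beamform(make_cube(alt))$values == 0))

  # noiseless simulated point source: argmax within one pixel of truth
  geom <- small_geometry(ni = 16L)
  src <- source_spec(lateral = 0.75, depth = 15)
  frame <- simulate_channel_data(geom, src, depth = 20)
  img2 <- das_beamform(aperture_cube(frame))
  tgt <- locate_target(img2)
  expect_lte(abs(tgt$lateral - src$lateral), img2$dx)
  expect_lte(abs(tgt$axial - src$depth), img2$dz)
})

test_that("coherence factors match their literal ensemble-sum definition", {
  ni <- 8L
  a <- complex(real = 2, imaginary = 1)
  same <- make_cube(array(a, c(4, ni, 2)))
  for (m in c(1L, 3L)) {
    cf <- slsc_coherence(same, m)
    expect_equal(cf$Cij, matrix((ni - m) * Mod(a)^2 + 0i, 4, 2))
    expect_equal(cf$Cii, matrix((ni - m) * Mod(a)^2, 4, 2))
    expect_equal(cf$Cjj, cf$Cii)
    expect_equal(Re(cf$Cij) / sqrt(cf$Cii * cf$Cjj), matrix(1, 4, 2))
  }

  alt <- make_cube(array(rep(rep(c(1 + 0i, -1 + 0i), each = 4, times = ni / 2),
                             times = 2), c(4, ni, 2)))
  cf1 <- slsc_coherence(alt, 1L)
  expect_equal(Re(cf1$Cij) / sqrt(cf1$Cii * cf1$Cjj), matrix(-1, 4, 2))

  cube <- random_cube(nz = 16L, ni = 8L, nx = 3L, seed = 2L)
  for (m in c(1L, 4L, 7L)) {
    got <- slsc_coherence(cube, m)
    ref <- naive_coherence(cube$data, m)
    expect_equal(got$Cij, ref$Cij, tolerance = 1e-9)
    expect_equal(got$Cii, ref$Cii, tolerance = 1e-9)
    expect_equal(got$Cjj, ref$Cjj, tolerance = 1e-9)
  }
  expect_error(slsc_coherence(cube, 0L), "lag")
  expect_error(slsc_coherence(cube, 8L), "lag")
})

test_that("SLSC image equals the naive triple-loop reference", {
  cube <- random_cube(nz = 64L, ni = 8L, nx = 4L, seed = 3L)
  for (M in c(1L, 5L, 7L)) for (k in c(1L, 3L, 11L)) {
    got <- slsc_image(cube, M, k)$values
    ref <- naive_slsc(cube$data, M, k)
    expect_lt(max(abs(got - ref) / pmax(abs(ref), 1e-12)), 1e-9)
  }
})

test_that("SLSC handles the coherent and degenerate limits", {
  wf <- sin(2 * pi * 0.1 * (0:63)) * exp(-((0:63) - 32)^2 / 100)
  cube <- coherent_cube(wf, ni = 8L, nx = 2L)
  for (M in c(1L, 4L, 7L)) for (k in c(1L, 5L)) {
    img <- slsc_image(cube, M, k)
    # pixels above the relative denominator floor carry full coherence
    sig <- which(abs(wf) > 1e-2 * max(abs(wf)))
    expect_true(all(abs(img$values[sig, ] - M) < 1e-6))
  }

  zero <- make_cube(array(0 + 0i, c(16, 8, 2)))
  expect_true(all(slsc_image(zero, 5L, 3L)$values == 0))

  expect_error(slsc_image(cube, M = 8L), "cumulative lag")
  expect_error(slsc_image(cube, M = 4L, k = 2L), "odd")
})

test_that("per-lag coherence respects the Cauchy-Schwarz bound everywhere", {
  for (seed in 1:3) {
    cube <- random_cube(nz = 32L, ni = 8L, nx = 3L, seed = seed)
    for (m in c(1L, 3L, 6L)) {
      cf <- slsc_coherence(cube, m)
      rho <- Re(cf$Cij) / sqrt(cf$Cii * cf$Cjj)
      expect_true(all(rho >= -1 - 1e-12 & rho <= 1 + 1e-12))
      expect_true(all(Mod(cf$Cij) <= sqrt(cf$Cii * cf$Cjj) * (1 + 1e-12)))
    }
    img <- slsc_image(cube, 6L, 3L)
    expect_true(all(img$values >= 0 & img$values <= 6 + 1e-9))
  }
})

test_that("SLSC is amplitude invariant and DAS is linear in the channel data", {
  cube <- random_cube(nz = 32L, ni = 8L, nx = 3L, seed = 4L)
  scaled <- make_cube(cube$data * 2)  # power-of-two scale: exact in floats
  expect_identical(slsc_image(scaled, 5L, 3L)$values,
                   slsc_image(cube, 5L, 3L)$values)
  expect_identical(das_beamform(scaled)$values, 2 * das_beamform(cube)$values)

  # non-dyadic scales agree to roundoff
  scaled2 <- make_cube(cube$data * 3.7)
  expect_equal(slsc_image(scaled2, 5L, 3L)$values,
               slsc_image(cube, 5L, 3L)$values, tolerance = 1e-12)
})

test_that("normalization and log compression map to [-DR, 0] as stated", {
  vals <- matrix(c(4, 2, 0.04, 0), 2, 2)
  img <- pa_image(vals, c(0, 0.3), dz = 0.1)
  disp <- normalize_log_compress(img, dynamic_range = 15)
  expect_equal(disp$values[1, 1], 0)
  expect_equal(disp$values[2, 1], 20 * log10(0.5), tolerance = 1e-12)
  expect_equal(disp$values[1, 2], -15)  # max/100 clipped to the floor
  expect_equal(disp$values[2, 2], -15)  # zero pixel at the floor
  expect_true(all(disp$values >= -15 & disp$values <= 0))

  zero <- pa_image(matrix(0, 3, 2), c(0, 0.3), dz = 0.1)
  expect_true(all(normalize_log_compress(zero, 15)$values == -15))
})

test_that("the end-to-end pipeline localizes the source for both methods", {
  geom <- small_geometry(ni = 16L)
  src <- source_spec(lateral = -0.9, depth = 15)
  frame <- simulate_channel_data(geom, src, depth = 20)
  slsc <- beamform_frame(frame, method = "slsc", M = 10L, k = 11L)
  das <- beamform_frame(frame, method = "das")

  tgt <- locate_target(slsc$image)
  expect_lte(abs(tgt$lateral - src$lateral), slsc$image$dx)
  # the axial kernel compounds coherence over the pulse extent, so the
  # axial peak is only defined to within the pulse length plus k samples
  sigma_us <- sqrt(2 * log(2)) / (pi * 0.6 * 5)
  ax_tol <- (4 * sigma_us * geom$sampling_frequency + 11) * slsc$image$dz
  expect_lte(abs(tgt$axial - src$depth), ax_tol)

  expect_identical(dim(slsc$image$values), dim(das$image$values))
  expect_equal(slsc$image$dx, das$image$dx)
  expect_equal(max(slsc$image$values), 1)

  zero <- channel_data(matrix(0, depth_to_samples(geom, 20), 16), geom, 20)
  flat <- beamform_frame(zero, method = "slsc", M = 5L, k = 3L)
  expect_true(all(flat$display$values == -15))
})
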