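test_that("the transmit pulse peaks at unit amplitude with its spectrum at the carrier", {
  g <- tiny_grid(n_fast = 1024)
  p <- generate_pulse(g, amplitude = 1)
  expect_equal(max(as.numeric(p)), 1)
  expect_equal(which.max(as.numeric(p)), 1L)   # zero-phase layout

  spec <- Mod(stats::fft(as.numeric(p)))
  half <- seq_len(g$n_fast / 2)
  peak_freq <- (which.max(spec[half]) - 1) / (g$n_fast * g$fast_dt)
  expect_lt(abs(peak_freq - 400e6), 1 / (g$n_fast * g$fast_dt))  # within one bin

  expect_equal(as.numeric(generate_pulse(g, amplitude = 0)), rep(0, g$n_fast))
})

test_that("pulses at or above the fast-time Nyquist are rejected", {
  g <- tiny_grid(n_fast = 128)
  nyq <- 1 / (2 * g$fast_dt)
  expect_error(generate_pulse(g, center_freq = nyq), "Nyquist")
  expect_error(generate_pulse(g, center_freq = 2 * nyq), "Nyquist")
})

test_that("frames are bitwise reproducible under a fixed seed", {
  g <- tiny_grid()
  p <- generate_pulse(g)
  mo <- motion_params(d0 = 0.4, Ar = 0.002, fr = 0.3)
  cl <- clutter_params(noise_sigma = 0.3, unknown_amp = 0.1, seed = 11)
  f1 <- generate_frame(g, mo, cl, p)
  f2 <- generate_frame(g, mo, cl, p)
  expect_identical(f1$data, f2$data)
})

test_that("a motionless, clutter-free subject gives identical columns", {
  g <- tiny_grid()
  p <- generate_pulse(g)
  mo <- motion_params(d0 = 0.4, Ar = 0, fr = 0.3)
  fr <- generate_frame(g, mo, clutter_params(), p)
  expect_lt(max(abs(fr$data - fr$data[, 1])), 1e-12)
})

test_that("pure-noise frames have the configured variance", {
  g <- tiny_grid(n_fast = 256, n_slow = 128)
  p <- generate_pulse(g)
  mo <- motion_params(d0 = 0.4, Ar = 0.002, fr = 0.3, echo_amp = 0)
  fr <- generate_frame(g, mo, clutter_params(noise_sigma = 1, seed = 2), p)
  expect_lt(abs(stats::var(as.numeric(fr$data)) - 1), 0.02)
})

test_that("the echo peak lands at the delay's fast-time sample", {
  g <- grid_params(n_fast = 4096, n_slow = 4, fast_window = 124e-9)
  p <- generate_pulse(g)
  mo <- motion_params(d0 = 9, Ar = 0, fr = 0.3)
  fr <- generate_frame(g, mo, clutter_params(), p)
  expect_equal(which.max(fr$data[, 1]),
               round(2 * 9 / g$v / g$fast_dt) + 1L)
})

test_that("subject delays leaving the record are rejected with the slow-time index", {
  g <- tiny_grid()
  p <- generate_pulse(g)
  mo <- motion_params(d0 = g$v * g$fast_window / 2 * 0.999, Ar = 0.01, fr = 0.3)
  expect_error(generate_frame(g, mo, clutter_params(), p), "slow-time index")
})

test_that("the frame model is additive (superposition of subject and clutter)", {
  g <- tiny_grid()
  p <- generate_pulse(g)
  mo <- motion_params(d0 = 0.4, Ar = 0.002, fr = 0.3)
  no_subject <- motion_params(d0 = 0.4, Ar = 0.002, fr = 0.3, echo_amp = 0)
  cl <- clutter_params(static_reflectors = cbind(delay = 1.5e-9, amp = 0.6),
                       trend_slope = 1e-3, nonstatic_amp = 0.2,
                       nonstatic_delay = 2e-9, nonstatic_drift = 2 * g$fast_dt,
                       unknown_amp = 0.1, noise_sigma = 0.2, seed = 9)
  both <- generate_frame(g, mo, cl, p)
  subject_only <- generate_frame(g, mo, clutter_params(), p)
  clutter_only <- generate_frame(g, no_subject, cl, p)
  expect_equal(both$data, subject_only$data + clutter_only$data,
               tolerance = 1e-12)
})

test_that("a noiseless modulated echo has spectral lines only at respiration harmonics", {
  g <- grid_params(n_fast = 1024, n_slow = 512, fast_window = 31e-9)
  p <- generate_pulse(g)
  k_bin <- 8L   # respiration frequency exactly on an FFT bin
  fr0 <- k_bin * g$slow_rate / g$n_slow
  d0 <- g$v * (600 * g$fast_dt) / 2
  mo <- motion_params(d0 = d0, Ar = 0.02, fr = fr0)
  fr <- generate_frame(g, mo, clutter_params(), p)
  x <- fr$data[601, ]
  X <- Mod(stats::fft(x))
  on_lines <- seq(1, g$n_slow, by = k_bin)
  expect_lt(sum(X[-on_lines]^2) / sum(X^2), 1e-10)
})
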