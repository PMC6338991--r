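test_that("band-pass cascade magnitude is 1/sqrt(2) at each cutoff", {
  bank <- design_bandpass()
  expect_equal(abs(filter_response(bank, bank$lp_cutoff)), 1 / sqrt(2),
               tolerance = 1e-6)
  expect_equal(abs(filter_response(bank, bank$hp_cutoff)), 1 / sqrt(2),
               tolerance = 1e-6)
})

test_that("cascade kills DC and passes the band centre", {
  bank <- design_bandpass()
  expect_lt(abs(filter_response(bank, 1e-9)), 1e-6)
  centre <- sqrt(bank$lp_cutoff * bank$hp_cutoff)
  expect_gte(abs(filter_response(bank, centre)), 0.95)
})

test_that("realized cascade matches the analytic (prewarped) Butterworth product", {
  bank <- design_bandpass()
  w <- seq(0.001, 0.999, length.out = 1024)
  got <- abs(filter_response(bank, w))
  # bilinear-transform Butterworth: analog prototype evaluated at tan(pi*w/2)
  Om <- tan(pi * w / 2)
  Ol <- tan(pi * bank$lp_cutoff / 2)
  Oh <- tan(pi * bank$hp_cutoff / 2)
  ana <- 1 / sqrt(1 + (Om / Ol)^10) * (Om / Oh)^5 / sqrt(1 + (Om / Oh)^10)
  expect_lt(max(abs(got - ana)), 1e-6)
})

test_that("cutoff ordering is validated", {
  expect_error(design_bandpass(lp_cutoff = 0.02, hp_cutoff = 0.1), "cutoffs")
  expect_error(design_bandpass(lp_cutoff = 1.2, hp_cutoff = 0.1), "cutoffs")
})

test_that("fast-time filtering is causal, linear, and matches per-column recursion", {
  bank <- design_bandpass()
  M <- 256; N <- 4
  set.seed(4)
  A <- matrix(rnorm(M * N), M, N)
  B <- matrix(rnorm(M * N), M, N)
  filt <- function(m) apply_fasttime_filter(as_clean(m), bank)$data
  # zero in, zero out; linearity
  expect_equal(filt(matrix(0, M, N)), matrix(0, M, N))
  expect_equal(filt(2 * A - 5 * B), 2 * filt(A) - 5 * filt(B), tolerance = 1e-10)
  # dual route: the vectorized implementation equals signal::filter per column
  ref <- apply(A, 2, function(col)
    as.numeric(signal::filter(bank$hp, signal::filter(bank$lp, col))))
  expect_equal(filt(A), ref, tolerance = 1e-12)
})

test_that("DC columns are suppressed and in-band tones preserved", {
  bank <- design_bandpass()
  M <- 2048
  dc <- matrix(1, M, 1)
  out_dc <- apply_fasttime_filter(as_clean(dc), bank)$data
  expect_lt(max(abs(out_dc[500:M, 1])), 1e-3)
  w0 <- sqrt(bank$lp_cutoff * bank$hp_cutoff)   # band centre, fraction of Nyquist
  tone <- matrix(sin(pi * w0 * (0:(M - 1))), M, 1)
  out <- apply_fasttime_filter(as_clean(tone), bank)$data
  keep <- 500:M   # discard the startup transient
  expect_gte(sqrt(mean(out[keep, 1]^2)) / sqrt(mean(tone[keep, 1]^2)), 0.9)
})

test_that("filtering rejects records shorter than the filter memory", {
  expect_error(apply_fasttime_filter(as_clean(matrix(1, 20, 3))), "filter memory")
})

test_that("block smoothing averages groups of 7 and drops the remainder", {
  m <- matrix(rep(3.5, 14 * 2), 14, 2)
  out <- smooth_fasttime(as_clean(m))
  expect_equal(out$data, matrix(3.5, 2, 2))

  m2 <- matrix(rep(1:14, 3), 14, 3)
  expect_equal(smooth_fasttime(as_clean(m2))$data, matrix(rep(c(4, 11), 3), 2, 3))

  m3 <- matrix(0, 4096, 2)
  expect_equal(nrow(smooth_fasttime(as_clean(m3))$data), 585)  # floor(4096/7)

  # trailing M mod 7 rows must not influence the result
  m4 <- rbind(m2, matrix(999, 3, 3))
  expect_equal(smooth_fasttime(as_clean(m4))$data,
               smooth_fasttime(as_clean(m2))$data)

  expect_error(smooth_fasttime(as_clean(matrix(1, 13, 2))), "M >= 14")
})

test_that("block smoothing scales the grid and reduces white-noise variance ~7x", {
  g <- tiny_grid(n_fast = 700, n_slow = 2)
  sm <- smooth_fasttime(as_clean(matrix(0, 700, 2), grid = g))
  expect_equal(sm$grid$fast_dt, 7 * g$fast_dt)
  expect_equal(sm$grid$fast_dr, 7 * g$fast_dr)
  expect_equal(sm$grid$n_fast, 100L)

  set.seed(5)
  noise <- matrix(rnorm(7000 * 40), 7000, 40)
  out <- smooth_fasttime(as_clean(noise))$data
  ratio <- stats::var(as.numeric(noise)) / stats::var(as.numeric(out))
  expect_lt(abs(ratio - 7) / 7, 0.1)
})
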