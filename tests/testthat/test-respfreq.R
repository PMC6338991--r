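test_that("the ROI is 21 slow-time signals centred on the subject block", {
  m <- matrix(seq_len(30 * 16), 30, 16)
  roi <- roi_extract(as_smoothed(m), center = 15)
  expect_equal(roi$blocks, 5:25)
  expect_equal(nrow(roi$signals), 21L)
  expect_equal(roi$signals, m[5:25, ])   # rows pass through untransformed

  expect_message(roi_edge <- roi_extract(as_smoothed(m), center = 3), "shifted")
  expect_equal(roi_edge$blocks, 1:21)
  expect_message(roi_hi <- roi_extract(as_smoothed(m), center = 28), "shifted")
  expect_equal(roi_hi$blocks, 10:30)

  expect_error(roi_extract(as_smoothed(m[1:15, ]), center = 8), "at least 21")
})

test_that("window segmentation reproduces the fixed-window counts", {
  expect_length(window_segment(numeric(1024)), 3)   # offsets 0, 256, 512
  w <- window_segment(seq_len(1024))
  expect_equal(sapply(w, `[`, 1), c(1, 257, 513))
  expect_length(window_segment(numeric(512)), 1)
  expect_length(window_segment(numeric(768)), 2)
  expect_error(window_segment(numeric(100)), "zero-pad")
  expect_error(window_segment(numeric(600), wi = 512, G = 512), "G < wi")
})

test_that("an exact-bin tone is recovered exactly", {
  fs <- 25.6                      # wi = 512 gives 0.05 Hz bins
  x <- sin(2 * pi * 0.25 * (0:511) / fs)
  est <- accumulate_spectrum(x, fs = fs)
  expect_equal(est$fr_hat, 0.25)
  expect_equal(est$delta_f, 0.05)
  expect_equal(est$q, 1L)
})

test_that("spectrum accumulation is positively homogeneous with a stable peak", {
  fs <- 512 / 17.6
  set.seed(14)
  comps <- lapply(1:5, function(i)
    sin(2 * pi * 0.3 * (0:1023) / fs + i) + 0.3 * rnorm(1024))
  e1 <- accumulate_spectrum(comps, fs = fs)
  e3 <- accumulate_spectrum(lapply(comps, `*`, 3), fs = fs)
  expect_equal(e3$spectrum, 3 * e1$spectrum, tolerance = 1e-12)
  expect_equal(e3$peak_index, e1$peak_index)
  expect_equal(e1$q, 3L)
})

test_that("degenerate spectra are rejected", {
  expect_error(accumulate_spectrum(numeric(512), fs = 29), "zero")
  x <- sin(2 * pi * 0.3 * (0:511) / 29)
  expect_error(accumulate_spectrum(x, fs = 29, guard_band = c(20, 25)),
               "guard band")
})

test_that("the spectral SNR metric matches hand-computed cases", {
  expect_equal(snr_metric(c(0, 1, 1, 1, 0), 3), 20 * log10(1 / 2))
  expect_equal(snr_metric(c(0, 0.5, 10, 0.5, 0), 3), 20 * log10(10 / 1))
  H <- c(0.3, 1.2, 4, 0.5, 0.2)
  expect_equal(snr_metric(H, 3), 20 * log10(4 / (0.3 + 1.2 + 0.5 + 0.2)))
  expect_equal(snr_metric(c(0, 0, 1, 0, 0), 3), Inf)
  expect_error(snr_metric(H, 1), "strictly between")
  expect_error(snr_metric(H, 5), "strictly between")
})

test_that("Welch spectra are flat for white noise and silent for silence", {
  set.seed(15)
  W <- welch_psd(rnorm(2e4), fs = 29.09, seg_len = 256)
  keep <- 4:(nrow(W) - 1)   # away from the demeaned DC bin and Nyquist
  spread <- max(W$psd[keep]) / min(W$psd[keep])
  expect_lt(10 * log10(spread), 6)   # within +/-3 dB of each other

  z <- welch_band_check(numeric(128), fs = 29.09)
  expect_equal(z$band_power_frac, 0)
  expect_true(all(z$psd$psd == 0))
})

test_that("the kept detail band of a respiration tone covers the respiration band", {
  fs <- 512 / 17.6
  x <- sin(2 * pi * 0.3 * (0:1023) / fs)
  d6 <- band_decompose(x, fs = fs)$kept
  rep <- welch_band_check(d6, fs = fs)
  expect_gte(rep$band[2], 0.1)
  expect_lte(rep$band[1], 0.5)
  expect_lt(abs(rep$peak_freq - 0.3), 0.12)  # within one Welch bin (fs/256)
  expect_gte(rep$band_power_frac, 0.5)
})

test_that("accumulated spectra keep the fundamental above its harmonic", {
  run <- reduced_subject_run()
  est <- run$rep$freq
  mu <- est$peak_index
  second <- 2L * (mu - 1L) + 1L
  expect_lt(est$spectrum[second], est$spectrum[mu])
})

test_that("frequency error does not worsen as the noise level falls", {
  meds <- vapply(c(-10, -5, 0, 5), function(snr) {
    errs <- vapply(1:5, function(s) {
      sc <- scenario_subject(snr_db = snr, seed = s, reduced = TRUE)
      est <- suppressMessages(run_pipeline(sc$frame))$freq
      abs(est$fr_hat - sc$motion$fr)
    }, numeric(1))
    stats::median(errs)
  }, numeric(1))
  # ladder runs from noisiest to cleanest: medians must not increase
  expect_true(all(diff(meds) <= 1e-12))
})

test_that("the full chain recovers the simulated respiration frequency", {
  run <- reduced_subject_run()
  expect_lt(abs(run$rep$freq$fr_hat - run$sc$motion$fr), run$rep$freq$delta_f)
  expect_equal(run$rep$freq$q, 3L)
  expect_equal(run$rep$freq$n_signals, 21L)
})
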