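test_that("sample kurtosis hits the closed-form anchors", {
  # sine over full periods: E[s^2] = 1/2, E[s^4] = 3/8 -> K = 1.5
  s <- sin(2 * pi * 7 * (0:999) / 1000)
  expect_equal(sample_kurtosis(s), 1.5, tolerance = 1e-10)
  # uniform[-1, 1]: m4/m2^2 = (1/5)/(1/9) = 1.8
  set.seed(8)
  expect_equal(sample_kurtosis(stats::runif(2e5, -1, 1)), 1.8, tolerance = 0.03)
  # Gaussian: K = 3
  set.seed(9)
  expect_equal(sample_kurtosis(stats::rnorm(2e5)), 3, tolerance = 0.1)
  expect_true(is.na(sample_kurtosis(rep(2, 10))))
})

test_that("the KSD profile is computed per block with safe degenerate handling", {
  set.seed(10)
  m <- rbind(sin(2 * pi * (0:511) * 5 / 512),   # sinusoid: K = 1.5
             matrix(rnorm(3 * 512), 3),
             rep(0, 512))                        # zero variance
  expect_warning(pr <- ksd_profile(as_smoothed(m)), "zero variance")
  expect_equal(nrow(pr), 5L)
  expect_equal(pr$kurtosis[1], 1.5, tolerance = 1e-10)
  expect_equal(pr$excess[1], -1.5, tolerance = 1e-10)
  expect_equal(pr$sd[1], sqrt(sum(m[1, ]^2) / 511), tolerance = 1e-12)
  expect_equal(pr$ksd[5], 0)
  expect_error(ksd_profile(as_smoothed(m[, 1:4])), "N >= 8")
})

test_that("kurtosis is scale invariant and KSD scales as 1/c", {
  set.seed(11)
  m <- matrix(rnorm(6 * 256), 6, 256) + 2 * sin(2 * pi * (0:255) / 32)
  p1 <- ksd_profile(as_smoothed(m))
  p3 <- ksd_profile(as_smoothed(3 * m))
  expect_equal(p3$kurtosis, p1$kurtosis, tolerance = 1e-12)
  expect_equal(p3$ksd, p1$ksd / 3, tolerance = 1e-12)
})

test_that("the Morlet wavelet has its textbook values and symmetry", {
  expect_equal(morlet(0), 1)
  expect_lt(abs(morlet(pi / 10)), 1e-15)        # cosine zero
  t <- seq(-4, 4, by = 0.37)
  expect_equal(morlet(t), morlet(-t))
})

test_that("the scalogram matches direct summation and is linear", {
  set.seed(12)
  z <- rnorm(40)
  scales <- c(2, 5, 11)
  D <- scalogram(z, scales = scales)
  # independent oracle: literal double loop over (scale, position)
  ref <- matrix(0, length(scales), length(z))
  for (i in seq_along(scales)) for (b in seq_along(z))
    ref[i, b] <- sum(z * morlet((seq_along(z) - b) / scales[i])) / sqrt(scales[i])
  expect_equal(D, ref, ignore_attr = TRUE, tolerance = 1e-10)

  y <- rnorm(40)
  expect_equal(scalogram(z + 2 * y, scales = scales),
               scalogram(z, scales = scales) + 2 * scalogram(y, scales = scales),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(scalogram(rep(0, 40), scales = scales),
               matrix(0, 3, 40), ignore_attr = TRUE)
})

test_that("an impulse is localized at its own position at every scale", {
  z <- rep(0, 64); z[23] <- 1
  D <- abs(scalogram(z, scales = c(2, 4, 8, 16)))
  expect_equal(unname(apply(D, 1, which.max)), rep(23L, 4))
})

test_that("scalogram input validation", {
  expect_error(scalogram(rnorm(4)), "at least 8")
  expect_error(scalogram(rnorm(20), scales = numeric(0)), "scales")
  expect_error(scalogram(rnorm(20), scales = c(2, -1)), "scales")
})

test_that("printed 1/a normalization changes amplitudes but not the argmax", {
  set.seed(13)
  z <- rnorm(64) + 3 * morlet(((1:64) - 40) / 5)
  D1 <- abs(scalogram(z, prefactor = "sqrt"))
  D2 <- abs(scalogram(z, prefactor = "printed"))
  expect_equal(which(D1 == max(D1), arr.ind = TRUE)[1, "col"],
               which(D2 == max(D2), arr.ind = TRUE)[1, "col"])
})

test_that("a degenerate all-zero frame yields no detection", {
  g <- tiny_grid(n_fast = 700, n_slow = 64)
  sm <- smooth_fasttime(as_clean(matrix(0, 700, 64), grid = g))
  toa <- estimate_toa(sm)
  expect_false(toa$present)
  expect_true(is.na(toa$tau_hat))
})

test_that("the pipeline locates a reduced-scale subject within one carrier lobe", {
  run <- reduced_subject_run()
  toa <- run$rep$toa
  expect_true(toa$present)
  # range = v * tau / 2 by construction
  expect_equal(toa$range_hat, run$sc$grid$v * toa$tau_hat / 2)
  # one carrier lobe ~ 6 smoothed blocks ~ 0.19 m at the default grid
  block_m <- 7 * run$sc$grid$fast_dr
  expect_lt(abs(toa$range_hat - run$sc$motion$d0), 6 * block_m)
})
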