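#' Simulate a UWB impulse-radar frame
#'
#' Builds an M x N fast-time by slow-time amplitude matrix containing the
#' subject's respiration-modulated echo plus the configured disturbances.
#' Column n holds the transmit pulse delayed by
#' `tau(n) = tau0 + taur*sin(2*pi*fr*n/fs) [+ tauh*sin(2*pi*fh*n/fs)]`,
#' realized by a band-limited (frequency-domain, i.e. periodic sinc)
#' fractional delay so that sub-sample thorax motion (tens of picoseconds,
#' below the fast-time sampling interval) is not quantized away. Static
#' reflector echoes, a drifting-delay clutter reflector, a linear trend, a
#' seeded low-pass random field, and white Gaussian noise are added per the
#' clutter configuration. Output is bitwise reproducible for a fixed seed.
#'
#' @param grid [grid_params()] object.
#' @param motion [motion_params()] object.
#' @param clutter [clutter_params()] object.
#' @param pulse sampled transmit pulse from [generate_pulse()] (its grid must
#'   match `grid`).
#' @return Object of class `uwb_radar_frame`: list with `data` (M x N
#'   matrix), `grid`, and `provenance` (free text).
#' @examples
#' g <- grid_params(n_fast = 512, n_slow = 64, fast_window = 15.5e-9)
#' mo <- motion_params(d0 = 1.5, Ar = 0.005, fr = 0.3)
#' fr <- generate_frame(g, mo, clutter_params(noise_sigma = 0.05, seed = 1),
#'                      generate_pulse(g))
#' dim(fr$data)
#' @export
generate_frame <- function(grid, motion, clutter, pulse) {
  stopifnot(inherits(grid, "uwb_grid"), inherits(motion, "uwb_motion"),
            inherits(clutter, "uwb_clutter"), inherits(pulse, "uwb_pulse"))
  pg <- attr(pulse, "grid")
  if (pg$n_fast != grid$n_fast || abs(pg$fast_dt - grid$fast_dt) > 1e-18)
    stop("pulse was sampled on a different grid")
  M <- grid$n_fast; N <- grid$n_slow
  fs <- grid$slow_rate
  tn <- (seq_len(N) - 1L) / fs

  tau_n <- motion$tau0 + motion$taur * sin(2 * pi * motion$fr * tn)
  if (motion$Ah > 0)
    tau_n <- tau_n + motion$tauh * sin(2 * pi * motion$fh * tn)
  bad <- which(tau_n < 0 | tau_n >= grid$fast_window)
  if (motion$echo_amp > 0 && length(bad))
    stop(sprintf("subject delay leaves the fast-time record at slow-time index %d (tau = %.3g ns)",
                 bad[1], tau_n[bad[1]] * 1e9))

  f <- fft_freqs(M, grid$fast_dt)
  U <- stats::fft(as.numeric(pulse))
  # phase ramps only matter where the pulse spectrum has energy
  inband <- which(Mod(U) > 1e-12 * max(Mod(U)))
  fb <- f[inband]

  # Complex slow-time-dependent delay field (subject + drifting reflector),
  # applied as phase ramps on the pulse spectrum.
  phase <- matrix(0 + 0i, length(inband), N)
  if (motion$echo_amp > 0)
    phase <- phase + motion$echo_amp * exp(-2i * pi * outer(fb, tau_n))
  if (clutter$nonstatic_amp > 0) {
    tau_q <- clutter$nonstatic_delay +
      clutter$nonstatic_drift * (seq_len(N) - 1L) / max(N - 1L, 1L)
    if (any(tau_q < 0 | tau_q >= grid$fast_window))
      stop("nonstatic clutter delay leaves the fast-time record")
    phase <- phase + clutter$nonstatic_amp * exp(-2i * pi * outer(fb, tau_q))
  }
  # Static reflectors: one column-independent phase vector.
  if (!is.null(clutter$static_reflectors) && nrow(clutter$static_reflectors)) {
    sr <- clutter$static_reflectors
    if (any(sr[, "delay"] >= grid$fast_window))
      stop("static reflector delay outside the fast-time record")
    svec <- rowSums(vapply(seq_len(nrow(sr)), function(p)
      sr[p, "amp"] * exp(-2i * pi * fb * sr[p, "delay"]),
      complex(length(inband))))
    phase <- phase + svec
  }
  UP <- matrix(0 + 0i, M, N)
  UP[inband, ] <- U[inband] * phase
  data <- Re(stats::mvfft(UP, inverse = TRUE)) / M

  if (clutter$trend_slope != 0)
    data <- data + matrix(clutter$trend_slope * (seq_len(N) - 1L),
                          M, N, byrow = TRUE)

  if (clutter$unknown_amp > 0 || clutter$noise_sigma > 0) {
    with_local_seed(clutter$seed, {
      if (clutter$unknown_amp > 0)
        data <- data + clutter$unknown_amp * lowpass_field(grid)
      if (clutter$noise_sigma > 0)
        data <- data + matrix(stats::rnorm(M * N, sd = clutter$noise_sigma), M, N)
    })
  }

  structure(list(data = data, grid = grid,
                 provenance = sprintf(
                   "simulated: d0=%.3g m, Ar=%.3g m, fr=%.3g Hz, echo=%.3g, noise sd=%.3g, seed=%d",
                   motion$d0, motion$Ar, motion$fr, motion$echo_amp,
                   clutter$noise_sigma, clutter$seed)),
            class = "uwb_radar_frame")
}

# Smooth random field with unit variance: coarse iid-normal grid bilinearly
# upsampled to M x N (low-pass by construction). Correlation lengths are
# physical: ~2 ns in fast time (below the band-pass) and ~2 s in slow time.
lowpass_field <- function(grid) {
  M <- grid$n_fast; N <- grid$n_slow
  mf <- max(2L, min(as.integer(ceiling(grid$fast_window / 2e-9)), M))
  ms <- max(2L, min(as.integer(ceiling(N / grid$slow_rate / 2)), N))
  cg <- matrix(stats::rnorm(mf * ms), mf, ms)
  xf <- seq(1, mf, length.out = M)
  xs <- seq(1, ms, length.out = N)
  # interpolate along fast then slow
  up_f <- apply(cg, 2, function(col) stats::approx(seq_len(mf), col, xout = xf)$y)
  up <- t(apply(up_f, 1, function(row) stats::approx(seq_len(ms), row, xout = xs)$y))
  up / stats::sd(up)
}

#' Noise level for a target vital-sign SNR
#'
#' Returns the AWGN standard deviation giving the requested signal-to-noise
#' ratio. The "signal" is the vital-sign component: the slow-time-varying
#' part of the subject's echo (the static part of the echo is
#' indistinguishable from static clutter and is removed by the trend
#' subtraction, so it carries no respiration information). Signal power is
#' the mean power of `h[m,n] - mean_n h[m,n]` over the fast-time rows where
#' the echo has appreciable energy (row RMS above `support_frac` of the
#' maximum), computed from a short noiseless, clutter-free simulation:
#' `snr_db = 10*log10(P_vs / sigma^2)`.
#'
#' @param grid [grid_params()] object.
#' @param motion [motion_params()] object (with the subject's `Ar`, `fr`,
#'   `echo_amp` of interest); `Ar > 0` is required.
#' @param pulse the transmit pulse ([generate_pulse()]).
#' @param snr_db target SNR in dB.
#' @param support_frac support threshold as a fraction of the peak row RMS.
#' @param n_ref slow-time samples of the reference simulation (the
#'   modulation power converges within a respiration period; default 256).
#' @return noise standard deviation.
#' @export
noise_sigma_for_snr <- function(grid, motion, pulse, snr_db,
                                support_frac = 0.01, n_ref = 256L) {
  stopifnot(inherits(grid, "uwb_grid"), inherits(motion, "uwb_motion"),
            inherits(pulse, "uwb_pulse"))
  if (!(motion$Ar > 0 && motion$echo_amp > 0))
    stop("vital-sign SNR needs a moving subject (Ar > 0, echo_amp > 0)")
  gref <- grid
  gref$n_slow <- as.integer(min(grid$n_slow, n_ref))
  ref <- generate_frame(gref, motion, clutter_params(), pulse)
  h <- ref$data
  m <- h - rowMeans(h)
  rms <- sqrt(rowMeans(h^2))
  support <- rms > support_frac * max(rms)
  p_vs <- mean(m[support, , drop = FALSE]^2)
  sqrt(p_vs / 10^(snr_db / 10))
}

#' @export
print.uwb_radar_frame <- function(x, ...) {
  cat(sprintf("UWB radar frame: %d x %d (fast x slow)\n",
              nrow(x$data), ncol(x$data)))
  cat(" ", x$provenance, "\n")
  invisible(x)
}
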