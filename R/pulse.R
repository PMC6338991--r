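#' Generate a sampled UWB transmit pulse
#'
#' Returns a Gaussian-envelope cosine burst (Gaussian-modulated sinusoid)
#' sampled on the fast-time grid, the standard surrogate for a UWB monocycle.
#' The envelope width is set so that the two-sided -6 dB fractional bandwidth
#' of the spectral peak equals `rel_bandwidth`.
#'
#' The pulse is returned in zero-phase (wrapped) layout: its peak sits at the
#' first sample and the negative-time half of the burst is wrapped to the end
#' of the vector. This is the natural layout for the frequency-domain
#' fractional delays used by [generate_frame()]; `unwrap_pulse()` re-centres
#' it for plotting.
#'
#' @param grid a [grid_params()] object.
#' @param center_freq spectral peak frequency in Hz (default 400 MHz); must
#'   be below the fast-time Nyquist frequency `1/(2*grid$fast_dt)`.
#' @param rel_bandwidth two-sided -6 dB fractional bandwidth (default 0.5).
#' @param amplitude peak amplitude (default 1).
#' @return Numeric vector of length `grid$n_fast`, class `uwb_pulse`, with
#'   attributes `grid`, `center_freq`, `rel_bandwidth`, `sigma_t` (envelope
#'   standard deviation, s).
#' @examples
#' g <- grid_params(n_fast = 1024, n_slow = 2, fast_window = 31e-9)
#' p <- generate_pulse(g)
#' max(p)  # 1 at the envelope peak
#' @export
generate_pulse <- function(grid, center_freq = 400e6, rel_bandwidth = 0.5,
                           amplitude = 1) {
  stopifnot(inherits(grid, "uwb_grid"))
  nyq <- 1 / (2 * grid$fast_dt)
  if (!(center_freq > 0) || center_freq >= nyq)
    stop(sprintf("center_freq must lie in (0, %.4g Hz), the fast-time Nyquist band", nyq))
  if (!(rel_bandwidth > 0)) stop("rel_bandwidth must be > 0")
  # -6 dB (half-magnitude) points of the Gaussian spectral envelope at
  # fc * (1 +/- rel_bandwidth/2):  exp(-(2*pi*df*sigma_t)^2/2) = 1/2
  sigma_t <- sqrt(2 * log(2)) / (pi * rel_bandwidth * center_freq)
  m <- seq_len(grid$n_fast) - 1L
  # wrapped time axis: 0, dt, ..., then negative times at the tail
  t_wrap <- ifelse(m <= grid$n_fast / 2, m, m - grid$n_fast) * grid$fast_dt
  u <- amplitude * exp(-t_wrap^2 / (2 * sigma_t^2)) * cos(2 * pi * center_freq * t_wrap)
  structure(u, class = "uwb_pulse", grid = grid, center_freq = center_freq,
            rel_bandwidth = rel_bandwidth, sigma_t = sigma_t)
}

#' @rdname generate_pulse
#' @param pulse a `uwb_pulse` vector in wrapped layout.
#' @return `unwrap_pulse()`: a list with `t` (seconds, centred on 0) and `u`.
#' @export
unwrap_pulse <- function(pulse) {
  stopifnot(inherits(pulse, "uwb_pulse"))
  g <- attr(pulse, "grid")
  m <- seq_len(g$n_fast) - 1L
  t_wrap <- ifelse(m <= g$n_fast / 2, m, m - g$n_fast) * g$fast_dt
  o <- order(t_wrap)
  list(t = t_wrap[o], u = as.numeric(pulse)[o])
}

#' @export
print.uwb_pulse <- function(x, ...) {
  cat(sprintf("UWB pulse: Gaussian-modulated cosine, fc = %.4g MHz, -6 dB fractional bandwidth %.2f, sigma_t = %.3g ns, peak %.3g\n",
              attr(x, "center_freq") / 1e6, attr(x, "rel_bandwidth"),
              attr(x, "sigma_t") * 1e9, max(abs(as.numeric(x)))))
  invisible(x)
}

# Two-sided spectrum of a sampled pulse on the fast-frequency FFT grid.
# Returns list(freq, U) with U = fft(u) * dt (approximates the continuous FT).
pulse_spectrum <- function(pulse) {
  stopifnot(inherits(pulse, "uwb_pulse"))
  g <- attr(pulse, "grid")
  list(freq = fft_freqs(g$n_fast, g$fast_dt),
       U = stats::fft(as.numeric(pulse)) * g$fast_dt)
}

# FFT frequency grid in the standard wrapped order (0, +, ..., -, -dt^-1/n).
fft_freqs <- function(n, dt) {
  k <- seq_len(n) - 1L
  ifelse(k <= n / 2, k, k - n) / (n * dt)
}
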