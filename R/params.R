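#' Sampling-grid parameters of a radar record
#'
#' Describes the fast-time / slow-time sampling grid of a UWB impulse radar
#' record. Fast time samples the received waveform within one pulse
#' repetition interval and maps to range; slow time indexes successive
#' pulses.
#'
#' @param n_fast number of fast-time samples M (>= 14; the 7-point block
#'   smoother needs at least two blocks).
#' @param n_slow number of slow-time pulses N (>= 2).
#' @param fast_window fast-time record length in seconds (default 124 ns).
#' @param slow_rate slow-time sampling frequency fs in Hz. The default,
#'   512/17.6 ~= 29.09 Hz, corresponds to 512 pulses acquired in 17.6 s.
#' @param v propagation speed in m/s (default the vacuum speed of light).
#'
#' @return An object of class `uwb_grid`: a list with the arguments plus the
#'   derived fast-time sampling interval `fast_dt` = fast_window / n_fast (s)
#'   and range resolution `fast_dr` = v * fast_dt / 2 (m).
#' @examples
#' g <- grid_params(n_fast = 1024, n_slow = 256, fast_window = 31e-9)
#' g$fast_dr   # range per fast-time sample, ~4.5 mm
#' @export
grid_params <- function(n_fast = 4096, n_slow = 512,
                        fast_window = 124e-9,
                        slow_rate = 512 / 17.6,
                        v = 299792458) {
  stopifnot(is.numeric(n_fast), length(n_fast) == 1,
            is.numeric(n_slow), length(n_slow) == 1)
  n_fast <- as.integer(n_fast); n_slow <- as.integer(n_slow)
  if (n_fast < 14L) stop("n_fast must be >= 14 (block smoothing needs >= 2 blocks of 7)")
  if (n_slow < 2L) stop("n_slow must be >= 2")
  if (!(fast_window > 0)) stop("fast_window must be > 0")
  if (!(slow_rate > 0)) stop("slow_rate must be > 0")
  if (!(v > 0)) stop("v must be > 0")
  fast_dt <- fast_window / n_fast
  structure(list(n_fast = n_fast, n_slow = n_slow,
                 fast_window = fast_window, slow_rate = slow_rate, v = v,
                 fast_dt = fast_dt, fast_dr = v * fast_dt / 2),
            class = "uwb_grid")
}

#' @export
print.uwb_grid <- function(x, ...) {
  cat(sprintf("UWB sampling grid: M = %d fast-time samples over %.3g ns (dT = %.3g ps, dR = %.3g mm)\n",
              x$n_fast, x$fast_window * 1e9, x$fast_dt * 1e12, x$fast_dr * 1e3))
  cat(sprintf("                   N = %d slow-time pulses at fs = %.4f Hz (%.1f s)\n",
              x$n_slow, x$slow_rate, x$n_slow / x$slow_rate))
  invisible(x)
}

#' Thorax-motion parameters of the simulated subject
#'
#' The subject's echo delay is modulated as
#' `tau(t) = tau0 + taur * sin(2*pi*fr*t) [+ tauh * sin(2*pi*fh*t)]`
#' where `tau0 = 2*d0/v` is the two-way delay of the nominal thorax position
#' and `taur = 2*Ar/v` the delay excursion of the respiration movement.
#' A heartbeat term may be added with `Ah > 0` (no estimator is provided for
#' it; it exists so its spectral signature can be simulated).
#'
#' @param d0 nominal radar-to-thorax distance (m).
#' @param Ar respiration amplitude (m); physiological values are 0.005-0.015.
#' @param fr respiration frequency (Hz); physiological values are 0.2-0.4.
#' @param Ah heartbeat amplitude (m), default 0 (off).
#' @param fh heartbeat frequency (Hz), ignored when `Ah = 0`.
#' @param echo_amp amplitude of the subject's echo (unitless, default 1).
#' @return Object of class `uwb_motion` with the arguments plus derived
#'   two-way delays `tau0`, `taur`, `tauh` (seconds).
#' @examples
#' motion_params(d0 = 9, Ar = 0.01, fr = 0.3)
#' @export
motion_params <- function(d0, Ar = 0.01, fr = 0.3, Ah = 0, fh = 1.2,
                          echo_amp = 1) {
  if (!(d0 > 0)) stop("d0 must be > 0")
  if (Ar < 0) stop("Ar must be >= 0")
  if (Ah < 0) stop("Ah must be >= 0")
  if (Ar > 0 && !(fr > 0)) stop("fr must be > 0 when Ar > 0")
  if (echo_amp < 0) stop("echo_amp must be >= 0")
  v <- 299792458
  structure(list(d0 = d0, Ar = Ar, fr = fr, Ah = Ah, fh = fh,
                 echo_amp = echo_amp,
                 tau0 = 2 * d0 / v, taur = 2 * Ar / v, tauh = 2 * Ah / v),
            class = "uwb_motion")
}

#' @export
print.uwb_motion <- function(x, ...) {
  cat(sprintf("Subject motion: d0 = %.2f m (tau0 = %.3g ns), Ar = %.1f mm at fr = %.3f Hz",
              x$d0, x$tau0 * 1e9, x$Ar * 1e3, x$fr))
  if (x$Ah > 0) cat(sprintf(", Ah = %.1f mm at fh = %.2f Hz", x$Ah * 1e3, x$fh))
  cat(sprintf(", echo amplitude %.3g\n", x$echo_amp))
  invisible(x)
}

#' Clutter and noise parameters of a simulated environment
#'
#' The received frame is the subject's echo plus additive disturbances:
#' echoes from static reflectors, a linear trend over slow time, a
#' "nonstatic" reflector whose delay drifts linearly across the record, an
#' "unknown" broadband residual modelled as a seeded low-pass random field,
#' and white Gaussian noise.
#'
#' @param static_reflectors two-column matrix or data.frame `(delay, amp)`:
#'   two-way delay (s, within the fast-time window) and unitless amplitude of
#'   each static reflector. `NULL` for none.
#' @param trend_slope linear-trend increment per slow-time sample (amplitude
#'   units); the trend adds `trend_slope * (n-1)` to every entry of column n.
#' @param nonstatic_amp amplitude of the drifting-delay clutter reflector.
#' @param nonstatic_delay its starting two-way delay (s).
#' @param nonstatic_drift total delay drift over the whole record (s).
#' @param unknown_amp standard deviation of the low-pass "unknown clutter"
#'   random field.
#' @param noise_sigma standard deviation of the additive white Gaussian noise.
#' @param seed integer RNG seed; a fixed seed makes [generate_frame()]
#'   bitwise reproducible.
#' @return Object of class `uwb_clutter`.
#' @examples
#' clutter_params(static_reflectors = cbind(delay = 2 * 4 / 3e8, amp = 0.8),
#'                noise_sigma = 0.1, seed = 1)
#' @export
clutter_params <- function(static_reflectors = NULL, trend_slope = 0,
                           nonstatic_amp = 0, nonstatic_delay = 40e-9,
                           nonstatic_drift = 0.1e-9,
                           unknown_amp = 0, noise_sigma = 0, seed = 1L) {
  if (!is.null(static_reflectors)) {
    static_reflectors <- as.matrix(static_reflectors)
    if (ncol(static_reflectors) != 2)
      stop("static_reflectors must have two columns: delay (s) and amplitude")
    colnames(static_reflectors) <- c("delay", "amp")
    if (any(static_reflectors[, "amp"] < 0)) stop("reflector amplitudes must be >= 0")
    if (any(static_reflectors[, "delay"] < 0)) stop("reflector delays must be >= 0")
  }
  if (nonstatic_amp < 0 || unknown_amp < 0 || noise_sigma < 0)
    stop("clutter amplitudes must be >= 0")
  structure(list(static_reflectors = static_reflectors,
                 trend_slope = trend_slope,
                 nonstatic_amp = nonstatic_amp,
                 nonstatic_delay = nonstatic_delay,
                 nonstatic_drift = nonstatic_drift,
                 unknown_amp = unknown_amp,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "uwb_clutter")
}

#' @export
print.uwb_clutter <- function(x, ...) {
  ns <- if (is.null(x$static_reflectors)) 0L else nrow(x$static_reflectors)
  cat(sprintf("Clutter: %d static reflector(s), trend slope %.3g/sample, nonstatic amp %.3g,\n",
              ns, x$trend_slope, x$nonstatic_amp))
  cat(sprintf("         unknown-field sd %.3g, AWGN sd %.3g, seed %d\n",
              x$unknown_amp, x$noise_sigma, x$seed))
  invisible(x)
}

# Run code with a locally-set RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
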