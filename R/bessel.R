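#' Analytic harmonic amplitudes of the modulated echo spectrum
#'
#' A sinusoidally delay-modulated echo has a slow-time spectrum consisting of
#' lines at `k*fr + l*fh` (Jacobi-Anger expansion of the phase modulation).
#' At the subject's range bin the line amplitudes are
#' \deqn{C_{kl} = \int U(\nu) J_k(\beta_r \nu) J_l(\beta_h \nu) d\nu}
#' with `U` the transmit-pulse spectrum and `J_k` Bessel functions of the
#' first kind. This function evaluates the integral by quadrature on the
#' sampled two-sided pulse spectrum and serves as an independent oracle for
#' the simulator's spectral content.
#'
#' The modulation indices are `beta_r = 2*pi*taur` and `beta_h = 2*pi*tauh`
#' (the delay excursions, so that `beta * nu` is the phase swing at fast
#' frequency `nu`). With `printed_beta = TRUE` the dimensionally inconsistent
#' variant `beta_r = 2*pi*Ar`, `beta_h = 2*pi*Ah` (displacements instead of
#' delays) is used instead; it is provided for comparison only.
#'
#' @param motion [motion_params()] object.
#' @param pulse either a `uwb_pulse` (its spectrum is computed internally) or
#'   a list with elements `freq` (Hz, two-sided) and `U` (complex spectrum).
#' @param k_max,l_max largest respiration / heartbeat harmonic order.
#' @param tau_offset fast-time offset `tau - tau0` (s) of the observed range
#'   bin from the echo centre; the integrand gains a phase factor
#'   `exp(2*pi*i*nu*tau_offset)`. At the centre (`0`, default) the odd-k
#'   amplitudes vanish identically for a symmetric pulse (odd integrand) —
#'   the odd harmonics live on the flanks of the echo.
#' @param printed_beta use displacement-based modulation indices (see above).
#' @return data.frame with columns `k`, `l`, and `C` (complex amplitude).
#'   With `Ah = 0` all rows with `l != 0` are exactly zero.
#' @examples
#' g <- grid_params(n_fast = 1024, n_slow = 2, fast_window = 31e-9)
#' p <- generate_pulse(g)
#' mo <- motion_params(d0 = 2, Ar = 0.05, fr = 0.3)
#' ck <- bessel_harmonic_amplitudes(mo, p, k_max = 3)
#' Mod(ck$C) / Mod(ck$C[1])   # harmonic line ratios
#' @export
bessel_harmonic_amplitudes <- function(motion, pulse, k_max = 3, l_max = 0,
                                       tau_offset = 0, printed_beta = FALSE) {
  stopifnot(inherits(motion, "uwb_motion"), k_max >= 0, l_max >= 0)
  sp <- if (inherits(pulse, "uwb_pulse")) pulse_spectrum(pulse) else pulse
  if (!is.list(sp) || is.null(sp$freq) || is.null(sp$U))
    stop("pulse must be a uwb_pulse or a list(freq, U)")
  if (!length(sp$U)) stop("empty pulse spectrum")
  freq <- sp$freq; U <- sp$U
  df <- if (length(freq) > 1) abs(freq[2] - freq[1]) else 1
  beta_r <- if (printed_beta) 2 * pi * motion$Ar else 2 * pi * motion$taur
  beta_h <- if (printed_beta) 2 * pi * motion$Ah else 2 * pi * motion$tauh
  grid_kl <- expand.grid(k = 0:k_max, l = 0:l_max)
  ph <- exp(2i * pi * freq * tau_offset)
  C <- mapply(function(k, l) {
    sum(U * ph * besselJ_signed(beta_r * freq, k) *
          besselJ_signed(beta_h * freq, l)) * df
  }, grid_kl$k, grid_kl$l)
  data.frame(k = grid_kl$k, l = grid_kl$l, C = C)
}

# J_nu at possibly negative argument: J_nu(-x) = (-1)^nu J_nu(x); J_0(0)=1.
besselJ_signed <- function(x, nu) {
  out <- numeric(length(x))
  pos <- x >= 0
  if (any(pos)) out[pos] <- besselJ(x[pos], nu)
  if (any(!pos)) out[!pos] <- (-1)^nu * besselJ(-x[!pos], nu)
  out
}
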