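#' Design the fast-time Butterworth band-pass cascade
#'
#' The band-pass is realized as a cascade of a fifth-order Butterworth
#' low-pass and a fifth-order Butterworth high-pass. The default normalized
#' cutoffs (fractions of the fast-time Nyquist frequency) are 0.1037 and
#' 0.0222; on the default grid (fast-time Nyquist ~16.5 GHz) this passes
#' roughly 0.37-1.7 GHz, bracketing the 400 MHz transmit pulse.
#'
#' @param lp_cutoff normalized low-pass cutoff (fraction of Nyquist).
#' @param hp_cutoff normalized high-pass cutoff; must be below `lp_cutoff`.
#' @param order filter order of each section (default 5).
#' @return Object of class `uwb_filter_bank`: list with the two `signal::Arma`
#'   coefficient sets (`lp`, `hp`), the cutoffs, and the order.
#' @examples
#' bank <- design_bandpass()
#' abs(filter_response(bank, bank$lp_cutoff))  # combined response at lp cutoff
#' @export
design_bandpass <- function(lp_cutoff = 0.1037, hp_cutoff = 0.0222, order = 5) {
  if (!(hp_cutoff > 0 && hp_cutoff < lp_cutoff && lp_cutoff < 1))
    stop("cutoffs must satisfy 0 < hp_cutoff < lp_cutoff < 1 (fractions of Nyquist)")
  structure(list(lp = signal::butter(order, lp_cutoff, type = "low"),
                 hp = signal::butter(order, hp_cutoff, type = "high"),
                 lp_cutoff = lp_cutoff, hp_cutoff = hp_cutoff, order = order),
            class = "uwb_filter_bank")
}

#' @rdname design_bandpass
#' @param bank a `uwb_filter_bank`.
#' @param w normalized frequencies (fraction of Nyquist) at which to
#'   evaluate the realized cascade transfer function.
#' @return `filter_response()`: complex response `H_lp(w) * H_hp(w)`.
#' @export
filter_response <- function(bank, w) {
  stopifnot(inherits(bank, "uwb_filter_bank"))
  z <- exp(-1i * pi * w)
  hpoly <- function(coef, z) {
    # polynomial in z^-1 evaluated at z = e^{j pi w}; coef[1] + coef[2] z^-1 + ...
    sapply(z, function(zz) sum(coef * zz^(seq_along(coef) - 1)))
  }
  (hpoly(bank$lp$b, z) / hpoly(bank$lp$a, z)) *
    (hpoly(bank$hp$b, z) / hpoly(bank$hp$a, z))
}

# Direct-form IIR y = (b/a) x down every column, zero initial conditions.
# Equivalent to signal::filter() per column but in two vectorized C passes.
iir_columns <- function(b, a, X) {
  X <- as.matrix(X)
  nb <- length(b)
  Xp <- rbind(matrix(0, nb - 1, ncol(X)), X)
  ma <- stats::filter(Xp, b, method = "convolution", sides = 1)
  ma <- ma[-seq_len(nb - 1), , drop = FALSE]
  out <- stats::filter(ma, -a[-1], method = "recursive")
  matrix(as.numeric(out), nrow(X), ncol(X))
}

#' @rdname design_bandpass
#' @details `group_delay()` gives the cascade's group delay in samples at
#'   normalized frequency `w`. A causal recursive filter delays the echo in
#'   fast time by this amount (frequency dependent; ~72 samples at 400 MHz
#'   on the default grid), which would bias the range estimate; the TOA
#'   stage subtracts it as a known system delay.
#' @export
group_delay <- function(bank, w) {
  d <- 1e-7
  vapply(w, function(wi)
    -(Arg(filter_response(bank, wi + d)) - Arg(filter_response(bank, wi))) / (d * pi),
    numeric(1))
}

#' Apply the band-pass cascade along fast time
#'
#' Each slow-time column is filtered along the fast-time axis by the low-pass
#' then the high-pass section, as causal recursive difference equations with
#' zero initial conditions (no forward-backward filtering).
#'
#' @param frame a `uwb_clean_frame` (or any frame object).
#' @param bank a [design_bandpass()] filter bank.
#' @return `uwb_clean_frame` of the same shape.
#' @export
apply_fasttime_filter <- function(frame, bank = design_bandpass()) {
  stopifnot(inherits(bank, "uwb_filter_bank"))
  d <- frame_data(frame)
  if (nrow(d) <= 6 * bank$order)
    stop(sprintf("frame has %d fast-time samples, shorter than the filter memory (need > %d)",
                 nrow(d), 6 * bank$order))
  out <- iir_columns(bank$hp$b, bank$hp$a, iir_columns(bank$lp$b, bank$lp$a, d))
  structure(list(data = out, grid = frame$grid,
                 stage_tag = c(stage_tags(frame), "bandpass_fasttime")),
            class = "uwb_clean_frame")
}

#' Block-average the fast-time axis in groups of 7
#'
#' Averages non-overlapping blocks of 7 consecutive fast-time rows (trailing
#' `M mod 7` rows are dropped), reducing white-noise variance by a factor of
#' ~7. The grid's fast-time sampling interval is scaled accordingly.
#'
#' @param frame a `uwb_clean_frame` (or any frame object) with M >= 14.
#' @param block block length (default 7).
#' @return Object of class `uwb_smoothed_frame`: list with `data`
#'   (`floor(M/block)` x N), `grid` (block-scaled), `block`, `stage_tag`.
#' @examples
#' f <- structure(list(data = matrix(rep(1:14, 2), 14), grid = NULL,
#'                     stage_tag = character()), class = "uwb_clean_frame")
#' smooth_fasttime(f)$data   # block means 4 and 11 in each column
#' @export
smooth_fasttime <- function(frame, block = 7L) {
  d <- frame_data(frame)
  M <- nrow(d)
  if (M < 2 * block)
    stop(sprintf("fast-time smoothing needs M >= %d rows", 2 * block))
  K <- M %/% block
  sm <- matrix(colMeans(matrix(d[seq_len(K * block), , drop = FALSE], nrow = block)),
               K, ncol(d))
  g <- frame$grid
  if (!is.null(g)) {
    g$n_fast <- K
    g$fast_dt <- g$fast_dt * block
    g$fast_dr <- g$fast_dr * block
    g$fast_window <- g$fast_dt * K
  }
  structure(list(data = sm, grid = g, block = as.integer(block),
                 stage_tag = c(stage_tags(frame), sprintf("smoothed_x%d", block))),
            class = "uwb_smoothed_frame")
}

#' @export
print.uwb_smoothed_frame <- function(x, ...) {
  cat(sprintf("Smoothed radar frame: %d block(s) x %d pulses (block = %d fast-time samples)\n",
              nrow(x$data), ncol(x$data), x$block))
  invisible(x)
}
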