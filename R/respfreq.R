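#' Extract the region of interest around the subject's range bin
#'
#' Returns the `2*half_width + 1` slow-time signals centred on the estimated
#' subject block. If the centre is within `half_width` of an edge the window
#' is shifted to fit so the count is preserved (a message notes the shift).
#'
#' @param frame a [smooth_fasttime()] output.
#' @param center 1-based block index of the subject (e.g.
#'   `estimate_toa(frame)$roi_center_index`).
#' @param half_width ROI half width in blocks (default 10, i.e. 21 signals).
#' @return Object of class `uwb_roi`: list with `signals` (matrix, one row
#'   per ROI block), `blocks` (their indices), `center`, `slow_rate`.
#' @export
roi_extract <- function(frame, center, half_width = 10L) {
  d <- frame_data(frame)
  K <- nrow(d)
  width <- 2L * as.integer(half_width) + 1L
  if (K < width)
    stop(sprintf("frame has %d fast-time blocks; ROI needs at least %d", K, width))
  if (is.na(center)) stop("ROI centre is NA (no subject located)")
  lo <- center - as.integer(half_width)
  if (lo < 1L || lo + width - 1L > K) {
    lo <- min(max(lo, 1L), K - width + 1L)
    message(sprintf("ROI shifted to blocks %d..%d to fit the record", lo, lo + width - 1L))
  }
  blocks <- lo:(lo + width - 1L)
  structure(list(signals = d[blocks, , drop = FALSE], blocks = blocks,
                 center = as.integer(center),
                 slow_rate = if (!is.null(frame$grid)) frame$grid$slow_rate else NA_real_),
            class = "uwb_roi")
}

#' Wavelet-band decomposition of a slow-time signal
#'
#' Multilevel discrete wavelet decomposition ([dwt_mra()]) of one slow-time
#' signal, returning every reconstructed band plus the band kept as the
#' denoised respiration component. At sampling rate `fs`, detail level j
#' covers roughly `fs/2^(j+1)` to `fs/2^j` Hz; at the default
#' fs ~= 29.09 Hz level 6 covers ~0.23-0.45 Hz, the respiration band.
#' With `keep = "auto"` the level whose band covers the 0.2-0.4 Hz
#' physiological range at the given `fs` is selected.
#'
#' @param x numeric slow-time signal (length divisible by `2^levels`).
#' @param levels decomposition depth (default 8).
#' @param keep detail level to keep (default 6), or `"auto"`.
#' @param fs slow-time sampling rate in Hz (needed for `"auto"` and for the
#'   reported band edges).
#' @param family wavelet family for [dwt_multilevel()].
#' @return Object of class `uwb_bands`: list with `components` (matrix
#'   d1..dL, aL), `kept` (the kept component), `keep` (its level), `band`
#'   (its nominal frequency range, Hz), `levels`, `family`.
#' @examples
#' fs <- 512 / 17.6
#' x <- sin(2 * pi * 0.3 * (0:1023) / fs)
#' b <- band_decompose(x, fs = fs)
#' sum(b$kept^2) / sum(x^2)   # most energy lands in d6
#' @export
band_decompose <- function(x, levels = 8L, keep = 6L, fs = 512 / 17.6,
                           family = "db4") {
  x <- as.numeric(x)
  if (length(x) < 2^levels) {
    feasible <- floor(log2(length(x)))
    stop(sprintf("signal of length %d too short for %d levels (max feasible depth %d)",
                 length(x), levels, feasible))
  }
  if (identical(keep, "auto")) {
    # level whose dyadic band [fs/2^(j+1), fs/2^j] covers the 0.2-0.4 Hz range
    centers <- fs / 2^(seq_len(levels) + 1) * 1.5   # geometric-ish band centre
    keep <- which.min(abs(log(centers / 0.3)))
  }
  keep <- as.integer(keep)
  if (keep < 1L || keep > levels) stop("keep must be in 1..levels")
  comps <- dwt_mra(x, levels = levels, family = family)
  structure(list(components = comps, kept = comps[keep, ],
                 keep = keep, band = c(fs / 2^(keep + 1), fs / 2^keep),
                 levels = levels, family = family),
            class = "uwb_bands")
}

#' Welch power spectral density (averaged periodogram)
#'
#' Hann-windowed, mean-removed, 50%-overlapping segment-averaged
#' periodogram; one-sided.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param seg_len segment length (default `min(256, length(x))`).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return data.frame with columns `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, seg_len = min(256L, length(x)), overlap = 0.5) {
  n <- length(x)
  if (n < 8) stop("welch_psd needs at least 8 samples")
  seg_len <- min(as.integer(seg_len), n)
  step <- max(1L, as.integer(round(seg_len * (1 - overlap))))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  win <- as.numeric(signal::hanning(seg_len))
  wnorm <- sum(win^2)
  nspec <- seg_len %/% 2 + 1L
  acc <- numeric(nspec)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * win
    P <- Mod(stats::fft(seg))^2 / (wnorm * fs)
    half <- P[seq_len(nspec)]
    # fold two-sided power into the one-sided spectrum (not DC/Nyquist)
    if (seg_len %% 2 == 0) half[2:(nspec - 1L)] <- 2 * half[2:(nspec - 1L)]
    else half[2:nspec] <- 2 * half[2:nspec]
    acc <- acc + half
  }
  data.frame(freq = (seq_len(nspec) - 1L) * fs / seg_len,
             psd = acc / length(starts))
}

#' Dominant-band report of a signal component
#'
#' Welch PSD of a component with the frequency axis in Hz and in normalized
#' units, plus the contiguous band around the spectral peak containing at
#' least half the total power. Used to verify that a kept wavelet band is
#' concentrated where the respiration signal lives.
#'
#' @param component numeric signal (length >= 64).
#' @param fs sampling rate (Hz).
#' @param norm_axis normalized-frequency convention: `"nyquist"` (f/(fs/2),
#'   default) or `"printed"` (f/(pi*fs)).
#' @param ... passed to [welch_psd()].
#' @return list with `psd` (data.frame freq, fn, psd), `peak_freq`,
#'   `band` (c(lo, hi) Hz containing >= 50% of power), `band_power_frac`.
#' @export
welch_band_check <- function(component, fs, norm_axis = c("nyquist", "printed"),
                             ...) {
  norm_axis <- match.arg(norm_axis)
  if (length(component) < 64) stop("welch_band_check needs at least 64 samples")
  W <- welch_psd(component, fs, ...)
  W$fn <- if (norm_axis == "nyquist") W$freq / (fs / 2) else W$freq / (pi * fs)
  tot <- sum(W$psd)
  if (tot == 0) {
    return(list(psd = W, peak_freq = NA_real_, band = c(NA_real_, NA_real_),
                band_power_frac = 0))
  }
  pk <- which.max(W$psd)
  lo <- hi <- pk
  frac <- W$psd[pk] / tot
  while (frac < 0.5 && (lo > 1L || hi < nrow(W))) {
    # greedily grow the contiguous band toward the larger neighbour
    left <- if (lo > 1L) W$psd[lo - 1L] else -Inf
    right <- if (hi < nrow(W)) W$psd[hi + 1L] else -Inf
    if (left >= right) lo <- lo - 1L else hi <- hi + 1L
    frac <- sum(W$psd[lo:hi]) / tot
  }
  list(psd = W, peak_freq = W$freq[pk], band = c(W$freq[lo], W$freq[hi]),
       band_power_frac = frac)
}

#' Segment a slow-time signal into overlapping fixed-length windows
#'
#' Windows of `wi` samples starting at multiples of `wi - G` (overlap `G`):
#' a 1024-sample record with `wi = 512`, `G = 256` yields 3 windows.
#'
#' @param x numeric signal of length N >= `wi`.
#' @param wi window length in samples (default 512).
#' @param G overlap in samples (default 256; must be < `wi`).
#' @return list of numeric windows; `length = 1 + floor((N - wi)/(wi - G))`.
#' @export
window_segment <- function(x, wi = 512L, G = 256L) {
  n <- length(x)
  wi <- as.integer(wi); G <- as.integer(G)
  if (!(G >= 0 && G < wi)) stop("need 0 <= G < wi")
  if (n < wi)
    stop(sprintf("signal length %d < window length %d; zero-pad or use a smaller wi", n, wi))
  step <- wi - G
  starts <- seq(1L, n - wi + 1L, by = step)
  lapply(starts, function(s) x[s:(s + wi - 1L)])
}

#' Accumulate windowed FFT magnitude spectra and estimate the respiration frequency
#'
#' For every region-of-interest signal's denoised component, splits the
#' record into overlapping fixed-length windows, computes each window's FFT
#' magnitude spectrum (after mean removal), and sums all spectra into a
#' single accumulated spectrum H. The respiration-frequency estimate is the
#' frequency of the largest accumulated magnitude, optionally restricted to
#' a physiological guard band; ties break toward the lower frequency.
#'
#' @param components list of numeric vectors (one denoised slow-time signal
#'   per ROI block, e.g. the `kept` component of [band_decompose()]), or a
#'   single numeric vector.
#' @param fs slow-time sampling rate (Hz).
#' @param wi,G window length and overlap in samples, see [window_segment()].
#' @param guard_band numeric `c(lo, hi)` in Hz restricting the peak search
#'   (default `c(0.1, 0.8)`), or `NULL` to search the whole open band
#'   between DC and Nyquist.
#' @param demean remove each window's mean before the FFT (default TRUE).
#' @return Object of class `uwb_freq_estimate`: list with `spectrum` (H over
#'   one-sided bins), `freq` (Hz axis), `peak_index` (1-based bin of the
#'   peak), `fr_hat` (Hz), `delta_f` (Hz resolution fs/wi), `snr_db`
#'   (accumulated-spectrum SNR), `q` (windows per signal), `wi`, `G`,
#'   `n_signals`.
#' @export
accumulate_spectrum <- function(components, fs, wi = 512L, G = 256L,
                                guard_band = c(0.1, 0.8), demean = TRUE) {
  if (is.numeric(components)) components <- list(components)
  if (!length(components)) stop("no input signals")
  wi <- as.integer(wi)
  nspec <- wi %/% 2 + 1L
  H <- numeric(nspec)
  q <- NULL
  for (x in components) {
    wins <- window_segment(as.numeric(x), wi = wi, G = G)
    if (is.null(q)) q <- length(wins)
    for (w in wins) {
      if (demean) w <- w - mean(w)
      H <- H + Mod(stats::fft(w))[seq_len(nspec)]
    }
  }
  if (all(H == 0)) stop("accumulated spectrum is identically zero: no peak")
  freq <- (seq_len(nspec) - 1L) * fs / wi
  # peak search strictly inside (DC, Nyquist), intersected with the guard band
  cand <- seq(2L, nspec - 1L)
  if (!is.null(guard_band))
    cand <- cand[freq[cand] >= guard_band[1] & freq[cand] <= guard_band[2]]
  if (!length(cand)) stop("guard band excludes every FFT bin")
  mu <- cand[which.max(H[cand])]       # which.max: first max -> lower frequency
  structure(list(spectrum = H, freq = freq, peak_index = mu,
                 fr_hat = freq[mu], delta_f = fs / wi,
                 snr_db = snr_metric(H, mu),
                 q = q, wi = wi, G = as.integer(G),
                 n_signals = length(components)),
            class = "uwb_freq_estimate")
}

#' Accumulated-spectrum SNR in dB
#'
#' `20*log10(|H[mu]| / sum of all other magnitudes)` over the one-sided band
#' from DC (`nu1`) to Nyquist (`nu2`) inclusive, excluding the peak bin.
#'
#' @param H one-sided magnitude spectrum.
#' @param peak_index 1-based peak bin; must lie strictly between `nu1` and
#'   `nu2`.
#' @param nu1,nu2 1-based indices of the DC and Nyquist bins (defaults: the
#'   first and last element of `H`).
#' @return SNR in dB; `+Inf` if all other magnitudes are zero.
#' @examples
#' snr_metric(c(0, 1, 10, 1, 0), 3)   # 20*log10(10/2) ~= 14 dB
#' @export
snr_metric <- function(H, peak_index, nu1 = 1L, nu2 = length(H)) {
  if (!(peak_index > nu1 && peak_index < nu2))
    stop("peak index must lie strictly between the DC and Nyquist indices")
  others <- sum(abs(H[nu1:nu2])) - abs(H[peak_index])
  if (others == 0) return(Inf)
  20 * log10(abs(H[peak_index]) / others)
}

#' @export
print.uwb_freq_estimate <- function(x, ...) {
  cat(sprintf("Respiration frequency estimate: %.4f Hz (bin %d, resolution %.4f Hz)\n",
              x$fr_hat, x$peak_index, x$delta_f))
  cat(sprintf("  accumulated over %d signal(s) x %d window(s) of %d samples (overlap %d); SNR = %.2f dB\n",
              x$n_signals, x$q, x$wi, x$G, x$snr_db))
  invisible(x)
}
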