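#' Pipeline configuration
#'
#' Collects every tunable of the processing chain with its default. Unknown
#' keys are rejected so configuration typos fail loudly.
#'
#' @param ... named overrides of the defaults listed below.
#' @return Object of class `uwb_config` (a named list).
#'
#' @section Parameters and defaults:
#' \describe{
#'   \item{lp_cutoff (0.1037), hp_cutoff (0.0222), filter_order (5)}{fast-time
#'     Butterworth band-pass cascade, cutoffs as fractions of the fast-time
#'     Nyquist frequency.}
#'   \item{center_freq (400e6), rel_bandwidth (0.5)}{nominal transmit pulse:
#'     centre frequency (Hz) and -6 dB fractional bandwidth; used to
#'     evaluate the cascade's group delay for the TOA range correction.}
#'   \item{smooth_block (7)}{fast-time block-average length.}
#'   \item{scales (32 log-spaced, 4..64)}{Morlet scalogram scales in blocks.}
#'   \item{presence_ratio (7)}{scalogram peak-to-median presence threshold.}
#'   \item{scalogram_prefactor ("sqrt")}{`"sqrt"` (1/sqrt(a)) or `"printed"` (1/a).}
#'   \item{roi_half_width (10)}{ROI half width in blocks (21 signals).}
#'   \item{dwt_levels (8), dwt_keep (6), wavelet ("db4")}{slow-time denoising:
#'     decomposition depth, kept detail level (or `"auto"`), family.}
#'   \item{wi (512), G (256)}{spectral window length and overlap, samples.}
#'   \item{guard_band (c(0.1, 0.8))}{peak-search band, Hz; `NULL` disables.}
#' }
#' @examples
#' cfg <- pipeline_config(wi = 256, G = 128)
#' cfg$wi
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    lp_cutoff = 0.1037, hp_cutoff = 0.0222, filter_order = 5,
    center_freq = 400e6,
    rel_bandwidth = 0.5,
    smooth_block = 7L,
    scales = default_scales(),
    presence_ratio = 7,
    scalogram_prefactor = "sqrt",
    roi_half_width = 10L,
    dwt_levels = 8L, dwt_keep = 6L, wavelet = "db4",
    wi = 512L, G = 256L,
    guard_band = c(0.1, 0.8)
  )
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over, keep.null = TRUE)
  structure(cfg, class = "uwb_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @return `load_config()`: a `uwb_config`; `save_config()`: `path`,
#'   invisibly. `dump(load(x))` round-trips.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.null(raw$guard_band)) raw$guard_band <- as.numeric(raw$guard_band)
  if (!is.null(raw$scales)) raw$scales <- as.numeric(raw$scales)
  pipeline_config(raw)
}

#' @rdname pipeline_config
#' @param config a `uwb_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "uwb_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.uwb_config <- function(x, ...) {
  cat("Pipeline configuration:\n")
  for (k in names(x)) {
    v <- x[[k]]
    vs <- if (is.numeric(v) && length(v) > 4)
      sprintf("[%d values: %.3g .. %.3g]", length(v), min(v), max(v))
    else paste(format(v, digits = 5), collapse = ", ")
    cat(sprintf("  %-20s %s\n", k, vs))
  }
  invisible(x)
}
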