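#' Remove static clutter by grand-mean subtraction
#'
#' Static clutter produces an additive offset common to the whole record; it
#' is estimated as the grand mean `J` over all M x N entries and subtracted.
#'
#' @param frame a `uwb_radar_frame` or `uwb_clean_frame`.
#' @return Object of class `uwb_clean_frame`: list with `data`, `grid`, and
#'   `stage_tag` recording which operations have been applied. The output's
#'   grand mean is zero (to floating-point tolerance).
#' @examples
#' f <- structure(list(data = matrix(1:4, 2), grid = NULL, provenance = ""),
#'                class = "uwb_radar_frame")
#' remove_static_clutter(f)$data   # grand mean 2.5 removed
#' @export
remove_static_clutter <- function(frame) {
  d <- frame_data(frame)
  if (!length(d)) stop("empty frame")
  if (!all(is.finite(d))) stop("frame contains non-finite entries")
  structure(list(data = d - mean(d), grid = frame$grid,
                 stage_tag = c(stage_tags(frame), "static_clutter_removed")),
            class = "uwb_clean_frame")
}

#' Remove the linear trend from each range bin (LTS)
#'
#' Linear trend subtraction: each fast-time row's slow-time signal is
#' replaced by its least-squares residual against an affine function of the
#' slow-time index (design columns `x1 = 0:(N-1)` and `x2 = 1`). Every
#' output row is orthogonal to both design columns, and the operation is a
#' projection (idempotent).
#'
#' @param frame a `uwb_radar_frame` or `uwb_clean_frame` with N >= 3.
#' @return `uwb_clean_frame` of the same shape.
#' @examples
#' f <- structure(list(data = rbind(0:3, rep(1, 4)), grid = NULL,
#'                     stage_tag = character()), class = "uwb_clean_frame")
#' remove_linear_trend(f)$data    # both rows are exactly affine -> zeros
#' @export
remove_linear_trend <- function(frame) {
  d <- frame_data(frame)
  N <- ncol(d)
  if (N < 3) stop("linear trend removal needs N >= 3 slow-time samples")
  if (!all(is.finite(d))) stop("frame contains non-finite entries")
  X <- cbind(x1 = seq_len(N) - 1, x2 = 1)
  # residual of each row regressed on X: D - D X (X'X)^-1 X'
  W <- d - (d %*% X) %*% solve(crossprod(X), t(X))
  structure(list(data = W, grid = frame$grid,
                 stage_tag = c(stage_tags(frame), "linear_trend_removed")),
            class = "uwb_clean_frame")
}

frame_data <- function(frame) {
  if (!is.list(frame) || is.null(frame$data))
    stop("expected a radar frame object with a $data matrix")
  as.matrix(frame$data)
}

stage_tags <- function(frame) {
  if (!is.null(frame$stage_tag)) frame$stage_tag else character()
}

#' @export
print.uwb_clean_frame <- function(x, ...) {
  cat(sprintf("Cleaned radar frame: %d x %d (fast x slow); stages: %s\n",
              nrow(x$data), ncol(x$data), paste(x$stage_tag, collapse = " -> ")))
  invisible(x)
}
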