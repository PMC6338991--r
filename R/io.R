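#' Read and write radar frames
#'
#' Two on-disk formats are supported. `"text"` is a tab-separated matrix
#' (one fast-time row per line) preceded by `# key=value` header comments
#' carrying the grid metadata — portable and diffable. `"rds"` is R's native
#' serialization of the frame object, which round-trips bit-exactly. The
#' format is inferred from the file extension (`.rds` vs anything else)
#' unless given explicitly.
#'
#' @param frame a `uwb_radar_frame` (or clean/smoothed frame).
#' @param path file path.
#' @param format `"text"`, `"rds"`, or `"auto"` (default, by extension).
#' @return `write_frame()`: `path`, invisibly. `read_frame()`: the frame.
#' @export
write_frame <- function(frame, path, format = c("auto", "text", "rds")) {
  format <- resolve_format(match.arg(format), path)
  if (format == "rds") {
    saveRDS(frame, path)
    return(invisible(path))
  }
  d <- frame_data(frame)
  g <- frame$grid
  if (is.null(g)) stop("frame has no grid metadata")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# n_fast=%d", g$n_fast),
    sprintf("# n_slow=%d", g$n_slow),
    sprintf("# fast_window=%.17g", g$fast_window),
    sprintf("# slow_rate=%.17g", g$slow_rate),
    sprintf("# v=%.17g", g$v),
    sprintf("# provenance=%s", if (!is.null(frame$provenance)) frame$provenance else "")
  ), con)
  utils::write.table(format(d, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_frame
#' @export
read_frame <- function(path, format = c("auto", "text", "rds")) {
  format <- resolve_format(match.arg(format), path)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "rds") {
    obj <- readRDS(path)
    if (!is.list(obj) || is.null(obj$data)) stop("not a radar frame: ", path)
    return(obj)
  }
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#\\s*", "", hdr), "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  need <- c("n_fast", "n_slow", "fast_window", "slow_rate", "v")
  missing_keys <- setdiff(need, keys)
  if (length(missing_keys))
    stop("frame header is missing metadata: ", paste(missing_keys, collapse = ", "))
  num <- function(k) as.numeric(vals[match(k, keys)])
  grid <- grid_params(n_fast = num("n_fast"), n_slow = num("n_slow"),
                      fast_window = num("fast_window"),
                      slow_rate = num("slow_rate"), v = num("v"))
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) != grid$n_fast)
    stop(sprintf("truncated or corrupt frame: expected %d data rows, found %d",
                 grid$n_fast, length(body)))
  cells <- strsplit(body, "\t", fixed = TRUE)
  nc <- lengths(cells)
  if (any(nc != grid$n_slow))
    stop(sprintf("truncated or corrupt frame: row %d has %d columns, expected %d",
                 which(nc != grid$n_slow)[1], nc[nc != grid$n_slow][1], grid$n_slow))
  d <- t(vapply(cells, function(r) as.numeric(r), numeric(grid$n_slow)))
  if (anyNA(d)) stop("frame contains NA entries after parsing")
  prov <- if ("provenance" %in% keys) vals[match("provenance", keys)] else ""
  structure(list(data = d, grid = grid, provenance = prov),
            class = "uwb_radar_frame")
}

resolve_format <- function(format, path) {
  if (format != "auto") return(format)
  if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "text"
}
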