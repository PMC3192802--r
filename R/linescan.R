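#' Line-scan record: time x position signal matrix
#'
#' The shared currency between the 1D solvers, the Brownian simulator and
#' the diffusion-constant fitter. Mirrors a confocal line-scan
#' acquisition: a matrix of (normalized) concentration values sampled at
#' fixed spatial locations with a fixed temporal period.
#'
#' @param time_s Numeric vector of sample times, s (strictly increasing).
#' @param position_um Numeric vector of sample positions, um.
#' @param values Matrix `length(time_s) x length(position_um)`.
#' @param meta Named list of acquisition metadata (e.g. `dt`, `dx`,
#'   `normalization`, `raw_counts`).
#' @return An object of class `linescan_record`.
#' @export
linescan_record <- function(time_s, position_um, values, meta = list()) {
  values <- as.matrix(values)
  stopifnot(is.numeric(time_s), is.numeric(position_um),
            nrow(values) == length(time_s),
            ncol(values) == length(position_um))
  if (length(time_s) > 1 && any(diff(time_s) <= 0))
    stop("time_s must be strictly increasing", call. = FALSE)
  meta$dt <- meta$dt %||% (if (length(time_s) > 1) stats::median(diff(time_s)) else NA_real_)
  meta$dx <- meta$dx %||% (if (length(position_um) > 1) stats::median(diff(position_um)) else NA_real_)
  meta$normalization <- meta$normalization %||% "none"
  structure(list(time_s = time_s, position_um = position_um,
                 values = values, meta = meta),
            class = "linescan_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.linescan_record <- function(x, ...) {
  cat(sprintf("Line-scan record: %d time points x %d positions\n",
              length(x$time_s), length(x$position_um)))
  cat(sprintf("  t in [%.4g, %.4g] s (dt = %.4g s)\n",
              min(x$time_s), max(x$time_s), x$meta$dt))
  cat(sprintf("  x in [%.4g, %.4g] um (dx = %.4g um)\n",
              min(x$position_um), max(x$position_um), x$meta$dx))
  cat(sprintf("  normalization: %s\n", x$meta$normalization))
  invisible(x)
}

#' @export
as.data.frame.linescan_record <- function(x, ...) {
  data.frame(
    time_s = rep(x$time_s, times = length(x$position_um)),
    position_um = rep(x$position_um, each = length(x$time_s)),
    value = as.vector(x$values))
}

#' Write a line-scan record to tidy CSV (or a binary container)
#'
#' The default CSV has columns `time_s, position_um, value` preceded by
#' `#`-prefixed metadata lines (`dt`, `dx`, normalization convention).
#' For large runs `format = "rds"` writes the full object (including
#' raw counts) as a compressed binary container.
#'
#' @param record A [linescan_record()].
#' @param path Output file path.
#' @param format `"csv"` (default, portable) or `"rds"` (binary,
#'   lossless, compact).
#' @return `path`, invisibly.
#' @export
write_linescan <- function(record, path, format = c("csv", "rds")) {
  stopifnot(inherits(record, "linescan_record"))
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(record, path)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  scal <- Filter(function(v) is.atomic(v) && length(v) == 1L, record$meta)
  for (nm in names(scal))
    writeLines(sprintf("# %s: %s", nm, format(scal[[nm]], digits = 15)), con)
  utils::write.csv(as.data.frame(record), con, row.names = FALSE)
  invisible(path)
}

#' Read a line-scan record written by [write_linescan()]
#'
#' @param path CSV (or `.rds`) file path.
#' @return A [linescan_record()].
#' @export
read_linescan <- function(path) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    rec <- readRDS(path)
    stopifnot(inherits(rec, "linescan_record"))
    return(rec)
  }
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", lines[h])
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (!is.na(num)) num else val
  }
  df <- utils::read.csv(text = lines[setdiff(seq_along(lines), hdr)])
  ts <- sort(unique(df$time_s))
  xs <- sort(unique(df$position_um))
  vals <- matrix(NA_real_, length(ts), length(xs))
  vals[cbind(match(df$time_s, ts), match(df$position_um, xs))] <- df$value
  linescan_record(ts, xs, vals, meta)
}
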