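#' Read one or more signal channels from delimited text
#'
#' Expects comma-separated text with a header row naming the channels (a
#' `time` column, if present, is used to infer the sampling rate). The
#' sampling rate may instead be given via `fs` or a JSON sidecar
#' `<path>.json` containing `{"fs": <Hz>}`.
#'
#' @param path Path to the CSV file.
#' @param fs Sampling rate in Hz; overrides the sidecar and the time column.
#' @return A named list of [phs_signal] tibbles (columns `time`, `value`,
#'   `clean` = `value`), one per channel column.
#' @export
read_timeseries <- function(path, fs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, header = TRUE)
  if (is.null(fs)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      fs <- meta$fs
    } else if ("time" %in% names(df) && nrow(df) >= 2) {
      fs <- 1 / diff(df$time[1:2])
    }
  }
  if (is.null(fs) || !is.finite(fs) || fs <= 0) {
    stop("sampling rate unknown: pass `fs`, provide a `<path>.json` sidecar, ",
         "or include a `time` column", call. = FALSE)
  }
  channels <- setdiff(names(df), "time")
  if (length(channels) == 0) stop("no channel columns found", call. = FALSE)
  bad <- which(!stats::complete.cases(df[channels]) |
                 !apply(as.matrix(df[channels]), 1L, function(r) all(is.finite(r))))
  if (length(bad)) {
    stop("non-finite values in row(s) ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  t <- (seq_len(nrow(df)) - 1) / fs
  out <- lapply(channels, function(ch) new_phs_signal(t, df[[ch]], df[[ch]], fs))
  stats::setNames(out, channels)
}

#' Write a signal or phase decomposition as delimited text
#'
#' Writes comma-separated text with a header row and, for signals, a JSON
#' sidecar `<path>.json` recording the sampling rate, seed metadata and true
#' change-point indices so a round trip is lossless.
#'
#' @param x A [phs_signal] tibble, a decomposition from [decompose_phase()],
#'   or any data frame.
#' @param path Output CSV path.
#' @param meta Optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path, meta = list()) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  side <- c(list(fs = attr(x, "fs"),
                 change_points = attr(x, "change_points")), meta)
  side <- side[!vapply(side, is.null, logical(1))]
  if (length(side)) {
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Write an analysis report as JSON or delimited text
#'
#' Change-point reports, noise-variance estimates and smoothing diagnostics
#' are written as JSON with a fixed key order; benchmark tables are written
#' as tidy CSV. All embedded numbers are written at full precision so the
#' reports round-trip.
#'
#' @param x A `change_point_report`, `sigma_estimate`, `phase_smooth` or
#'   `benchmark_result` object.
#' @param path Output path (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  UseMethod("write_report")
}

#' @export
write_report.change_point_report <- function(x, path) {
  payload <- list(
    detected = as.integer(attr(x, "detected")),
    truth = as.integer(attr(x, "truth")),
    tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn, mcc = x$mcc
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
write_report.sigma_estimate <- function(x, path) {
  jsonlite::write_json(as.list(glance(x)), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @export
write_report.phase_smooth <- function(x, path) {
  jsonlite::write_json(as.list(glance(x)), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @export
write_report.benchmark_result <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read reports written by [write_report()]
#'
#' @param path Path written by [write_report()].
#' @return For a change-point report JSON, a `change_point_report` tibble
#'   (reconstructed via [score_change_points()] counts); for a benchmark CSV,
#'   a `benchmark_result` tibble.
#' @export
read_change_point_report <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- tibble::tibble(tp = as.integer(p$tp), fp = as.integer(p$fp),
                        fn = as.integer(p$fn), tn = as.integer(p$tn),
                        mcc = as.numeric(p$mcc))
  attr(out, "detected") <- as.integer(p$detected)
  attr(out, "truth") <- as.integer(p$truth)
  class(out) <- c("change_point_report", class(out))
  out
}

#' @rdname read_change_point_report
#' @export
read_benchmark_result <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, header = TRUE))
  class(df) <- c("benchmark_result", class(df))
  df
}
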