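#' Read a voltage trace from disk
#'
#' Two plain-text layouts are supported:
#' \describe{
#'   \item{`"tv_csv"`}{Two-column CSV `t, value` (header optional). The time
#'     column must be uniformly spaced within a relative tolerance of 1e-9;
#'     the rate is inferred from the spacing.}
#'   \item{`"native"`}{The package's own headered CSV written by
#'     [write_timeseries()]: `#` comment lines carrying `rate`, `t0` and
#'     `channel` metadata followed by a single `value` column. A missing
#'     `rate` line is an error.}
#' }
#'
#' @param path File to read.
#' @param format `"auto"` (default; sniffs the header), `"tv_csv"` or
#'   `"native"`.
#' @return A [time_series()].
#' @export
read_timeseries <- function(path, format = c("auto", "tv_csv", "native")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_timeseries: no such file: ", path)
  first <- readLines(path, n = 1L)
  if (format == "auto")
    format <- if (startsWith(first, "#")) "native" else "tv_csv"
  if (format == "native") {
    hdr <- character()
    con <- file(path, "r"); on.exit(close(con))
    repeat {
      ln <- readLines(con, n = 1L)
      if (!length(ln) || !startsWith(ln, "#")) break
      hdr <- c(hdr, ln)
    }
    meta <- list()
    for (h in hdr) {
      kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1]]
      if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
    }
    if (is.null(meta$rate))
      stop("read_timeseries: native file lacks required 'rate' metadata")
    vals <- utils::read.csv(path, comment.char = "#")[[1]]
    time_series(vals, rate = as.numeric(meta$rate),
                t0 = if (is.null(meta$t0)) 0 else as.numeric(meta$t0),
                channel = if (is.null(meta$channel)) "" else meta$channel)
  } else {
    df <- utils::read.csv(path, header = grepl("[A-Za-z]", first))
    if (ncol(df) < 2) stop("read_timeseries: expected two columns (t, value)")
    t <- as.numeric(df[[1]]); v <- as.numeric(df[[2]])
    if (length(t) < 2) stop("read_timeseries: need at least two samples")
    dt <- diff(t)
    rel <- abs(dt - dt[1]) / dt[1]
    bad <- which(rel > 1e-9)
    if (length(bad))
      stop(sprintf("read_timeseries: non-uniform sampling at row %d (dt %g vs %g)",
                   bad[1] + 1L, dt[bad[1]], dt[1]))
    time_series(v, rate = 1 / dt[1], t0 = t[1])
  }
}

#' Write a voltage trace in the package's native headered-CSV layout
#'
#' @param ts A [time_series()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "time_series"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# rate = %.17g", ts$rate),
               sprintf("# t0 = %.17g", ts$t0),
               sprintf("# channel = %s", ts$channel),
               "value"), con)
  writeLines(sprintf("%.17g", ts$samples), con)
  invisible(path)
}

#' Read / write spike-time lists (CSV, one time per row, header `time_s`)
#'
#' @param train A [spike_train()].
#' @param path CSV file.
#' @param source,duration Metadata for [read_spikes()]; `duration` defaults
#'   to just past the last spike if not given.
#' @return `write_spikes`: `path`, invisibly. `read_spikes`: a
#'   [spike_train()].
#' @export
write_spikes <- function(train, path) {
  stopifnot(inherits(train, "spike_train"))
  utils::write.csv(data.frame(time_s = train$times), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path, source = "OTHER", duration = NULL) {
  df <- utils::read.csv(path)
  if (!"time_s" %in% names(df))
    stop("read_spikes: expected a 'time_s' column")
  t <- as.numeric(df$time_s)
  if (is.null(duration))
    duration <- if (length(t)) max(t) + 1e-6 else 0
  spike_train(t, source = source, duration = duration)
}

#' Write / read a state segmentation as TSV
#'
#' Columns `start_s`, `end_s`, `label`. Round-trips exactly to the printed
#' precision (microseconds).
#'
#' @param seg A [state_segmentation()].
#' @param path TSV file.
#' @param rate Working rate restored on read (Hz).
#' @return `write_segmentation`: `path`, invisibly; `read_segmentation`: a
#'   [state_segmentation()].
#' @export
write_segmentation <- function(seg, path) {
  stopifnot(inherits(seg, "state_segmentation"))
  if (nrow(seg) > 1 && any(seg$start[-1] < seg$end[-nrow(seg)] - 1e-12))
    stop("write_segmentation: refusing to write overlapping intervals")
  df <- data.frame(start_s = sprintf("%.6f", seg$start),
                   end_s = sprintf("%.6f", seg$end),
                   label = seg$label)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segmentation
#' @export
read_segmentation <- function(path, rate = 1000) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  state_segmentation(df$start_s, df$end_s, df$label, rate = rate)
}

#' Write / read a stimulation table (TSV: onset_s, duration_s)
#'
#' @param protocol A [stimulation_protocol()].
#' @param path TSV file.
#' @return `write_stimulation`: `path` invisibly; `read_stimulation`: a
#'   [stimulation_protocol()].
#' @export
write_stimulation <- function(protocol, path) {
  stopifnot(inherits(protocol, "stimulation_protocol"))
  utils::write.table(
    data.frame(onset_s = sprintf("%.6f", protocol$onsets),
               duration_s = sprintf("%.6f", rep(protocol$duration,
                                                length(protocol$onsets)))),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stimulation
#' @export
read_stimulation <- function(path) {
  df <- utils::read.delim(path)
  stimulation_protocol(as.numeric(df$onset_s),
                       duration = if (nrow(df)) as.numeric(df$duration_s[1]) else 0.5)
}
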