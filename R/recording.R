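#' Multichannel recording
#'
#' Container for a uniformly sampled multichannel trace: a channels-by-samples
#' numeric matrix plus sampling rate, ordered channel labels, the time of the
#' first sample, and free-form metadata. All channels share one length and one
#' rate. Time is in seconds, samples are 0-based internally, and every
#' windowed operation in the package uses half-open `[start, stop)` windows so
#' that adjacent windows partition a trace without double counting.
#'
#' @param samples numeric matrix (channels x samples) or numeric vector for a
#'   single channel. Values in volts or arbitrary acquisition units.
#' @param rate_hz sampling rate in Hz (ventral-root recordings are typically
#'   acquired at 10 kHz, EMG at 13.5 kHz).
#' @param channel_ids character vector of unique channel labels, one per row,
#'   e.g. `"VR-L5-left"`, `"EMG-triceps"`.
#' @param t0_s time of the first sample in seconds (stimulus-aligned sweeps
#'   use negative `t0_s` so that the stimulus sits at time 0).
#' @param meta named list of free-form annotations.
#' @return an object of class `recording`.
#' @export
recording <- function(samples, rate_hz, channel_ids = NULL, t0_s = 0,
                      meta = list()) {
  if (is.vector(samples) && is.numeric(samples)) {
    samples <- matrix(samples, nrow = 1L)
  }
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("`samples` must be a numeric matrix (channels x samples) or vector")
  }
  if (nrow(samples) < 1L) stop("a recording needs at least one channel")
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(nrow(samples)))
  channel_ids <- as.character(channel_ids)
  rec <- structure(
    list(samples = samples, rate_hz = as.numeric(rate_hz),
         channel_ids = channel_ids, t0_s = as.numeric(t0_s), meta = meta),
    class = "recording")
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  if (!is.finite(rec$rate_hz) || rec$rate_hz <= 0) {
    stop("rate_hz must be a positive number")
  }
  if (length(rec$channel_ids) != nrow(rec$samples)) {
    stop("channel_ids must have one label per channel")
  }
  if (anyDuplicated(rec$channel_ids)) stop("channel_ids must be unique")
  invisible(rec)
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s) x %d samples @ %g Hz, t0 = %g s (%.4g s)\n",
              n_channels(x), n_samples(x), x$rate_hz, x$t0_s, duration_s(x)))
  cat("  channels:", paste(x$channel_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Recording accessors
#'
#' @param rec a [recording()].
#' @return `n_samples()`/`n_channels()` return integer counts; `duration_s()`
#'   the trace duration `n_samples / rate_hz` in seconds; `get_channel()` one
#'   channel's samples as a numeric vector; `time_axis()` the per-sample time
#'   stamps in seconds.
#' @name recording-accessors
NULL

#' @rdname recording-accessors
#' @export
n_samples <- function(rec) ncol(rec$samples)

#' @rdname recording-accessors
#' @export
n_channels <- function(rec) nrow(rec$samples)

#' @rdname recording-accessors
#' @export
duration_s <- function(rec) ncol(rec$samples) / rec$rate_hz

#' @rdname recording-accessors
#' @param channel channel label or index; `NULL` selects the only channel of a
#'   single-channel recording.
#' @export
get_channel <- function(rec, channel = NULL) {
  idx <- channel_index(rec, channel)
  rec$samples[idx, ]
}

#' @rdname recording-accessors
#' @export
time_axis <- function(rec) {
  rec$t0_s + (seq_len(n_samples(rec)) - 1L) / rec$rate_hz
}

channel_index <- function(rec, channel = NULL) {
  if (is.null(channel)) {
    if (n_channels(rec) != 1L) {
      stop("recording has several channels; name the one to use")
    }
    return(1L)
  }
  if (is.numeric(channel)) {
    if (channel < 1 || channel > n_channels(rec)) stop("channel index out of range")
    return(as.integer(channel))
  }
  idx <- match(channel, rec$channel_ids)
  if (is.na(idx)) stop(sprintf("unknown channel '%s'", channel))
  idx
}

#' Extract a time window from a recording
#'
#' Returns the half-open window `[start_s, stop_s)` as a new recording whose
#' `t0_s` is `start_s`. Sample count is `round((stop - start) * rate)`, so a
#' 30 ms window of a 10 kHz trace holds exactly 300 samples, and slices over a
#' partition of the full span concatenate back to the original sample
#' sequence.
#'
#' @param rec a [recording()].
#' @param start_s,stop_s window bounds in seconds;
#'   `t0_s <= start_s < stop_s <= t0_s + duration`.
#' @return a [recording()] covering the window.
#' @export
slice_window <- function(rec, start_s, stop_s) {
  validate_recording(rec)
  if (!(start_s < stop_s)) stop("inverted window: need start_s < stop_s")
  t0 <- rec$t0_s
  n <- n_samples(rec)
  i0 <- round((start_s - t0) * rec$rate_hz)
  i1 <- round((stop_s - t0) * rec$rate_hz)
  if (i0 < 0 || i1 > n) stop("window out of recording bounds")
  recording(rec$samples[, (i0 + 1L):i1, drop = FALSE], rec$rate_hz,
            rec$channel_ids, t0_s = start_s, meta = rec$meta)
}

# number of significant digits written to text formats; doubles round-trip
# exactly at 17
.csv_digits <- 17L

#' Read and write recordings
#'
#' Two on-disk representations are supported. `"csv"` is a grep-able text
#' dialect: `#`-prefixed `key=value` metadata lines (required keys `rate_hz`,
#' `channel_ids` as a semicolon-separated list, `t0_s`), then a
#' `time_s,<ch1>,...` column header, then comma-delimited data rows with `.`
#' as decimal point. `"container"` is a binary serialization of the same
#' layout (channels x samples matrix plus the three attributes) that
#' round-trips bit-identically; use it for long traces.
#'
#' @param path file path.
#' @param format `"csv"` or `"container"`.
#' @param rec a [recording()].
#' @return `read_recording()` a [recording()]; `write_recording()` `path`,
#'   invisibly.
#' @export
read_recording <- function(path, format = c("csv", "container")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (format == "container") {
    obj <- readRDS(path)
    if (!inherits(obj, "recording")) stop("container does not hold a recording")
    validate_recording(obj)
    return(obj)
  }
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- sub("^#\\s*", "", meta_lines)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  names(vals) <- keys
  if (!"rate_hz" %in% keys) stop("format error: missing '# rate_hz=' header")
  if (!"channel_ids" %in% keys) stop("format error: missing '# channel_ids=' header")
  rate_hz <- as.numeric(vals[["rate_hz"]])
  channel_ids <- strsplit(vals[["channel_ids"]], ";", fixed = TRUE)[[1]]
  t0_s <- if ("t0_s" %in% keys) as.numeric(vals[["t0_s"]]) else 0
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) < 1L) stop("format error: no column header row")
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  if (header[1] != "time_s") stop("format error: first column must be time_s")
  data_rows <- body[-1]
  n_col <- length(header)
  if (length(data_rows) == 0L) stop("format error: no data rows")
  fields <- strsplit(data_rows, ",", fixed = TRUE)
  widths <- lengths(fields)
  if (any(widths != n_col)) {
    stop(sprintf("format error: ragged row %d (expected %d fields, got %d)",
                 which(widths != n_col)[1], n_col, widths[widths != n_col][1]))
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                nrow = n_col)  # columns of mat are rows of the file
  if (anyNA(mat)) {
    bad <- which(apply(mat, 2L, anyNA))[1]
    stop(sprintf("format error: non-numeric sample in data row %d", bad))
  }
  samples <- mat[-1L, , drop = FALSE]
  if (length(channel_ids) != nrow(samples)) {
    stop("format error: channel_ids count does not match value columns")
  }
  extra <- setdiff(keys, c("rate_hz", "channel_ids", "t0_s"))
  meta <- as.list(vals[extra])
  recording(samples, rate_hz, channel_ids, t0_s = t0_s, meta = meta)
}

#' @rdname read_recording
#' @export
write_recording <- function(rec, path, format = c("csv", "container")) {
  format <- match.arg(format)
  validate_recording(rec)
  if (format == "container") {
    saveRDS(rec, path)
    return(invisible(path))
  }
  fmt <- function(x) formatC(x, digits = .csv_digits, format = "g")
  head_lines <- c(
    sprintf("# rate_hz=%s", fmt(rec$rate_hz)),
    sprintf("# channel_ids=%s", paste(rec$channel_ids, collapse = ";")),
    sprintf("# t0_s=%s", fmt(rec$t0_s)))
  extra <- rec$meta[vapply(rec$meta, function(v)
    is.atomic(v) && length(v) == 1L, logical(1))]
  if (length(extra)) {
    head_lines <- c(head_lines,
                    sprintf("# %s=%s", names(extra), vapply(extra, as.character,
                                                            character(1))))
  }
  header <- paste(c("time_s", rec$channel_ids), collapse = ",")
  tt <- fmt(time_axis(rec))
  cols <- apply(rec$samples, 1L, fmt)           # samples x channels
  if (is.null(dim(cols))) cols <- matrix(cols, ncol = n_channels(rec))
  rows <- do.call(paste, c(list(tt), split(cols, col(cols)), sep = ","))
  writeLines(c(head_lines, header, rows), path)
  invisible(path)
}

#' Event tables
#'
#' An event table carries discrete time-stamped annotations — detected spikes,
#' ground-truth simulation labels, scored behavioral twitches — as rows of
#' `(time_s, channel_id, label, value)`, sorted by non-decreasing time. The
#' reserved channel id `"behavior"` marks events not tied to a recorded
#' channel.
#'
#' @param time_s event times in seconds.
#' @param channel_id channel each event belongs to.
#' @param label free-form event class (e.g. `"burst"`, `"slr"`, `"twitch"`).
#' @param value numeric payload (amplitude, sweep index, ...).
#' @return a `data.frame` of class `event_table`, sorted by time.
#' @export
event_table <- function(time_s = numeric(0), channel_id = character(0),
                        label = character(0), value = numeric(0)) {
  n <- length(time_s)
  recycle <- function(x, fill) {
    if (n == 0L) return(x[0])
    if (length(x) == 0L) rep(fill, n) else x
  }
  df <- data.frame(time_s = as.numeric(time_s),
                   channel_id = as.character(recycle(channel_id, "behavior")),
                   label = as.character(recycle(label, "event")),
                   value = as.numeric(recycle(value, NA_real_)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$time_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("event_table", "data.frame")
  df
}

#' @rdname event_table
#' @param path file path of a CSV with columns `time_s,channel_id,label,value`.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "channel_id", "label", "value")
  if (!all(need %in% names(df))) {
    stop("event CSV must have columns time_s,channel_id,label,value")
  }
  event_table(df$time_s, df$channel_id, df$label, df$value)
}

#' @rdname event_table
#' @param events an `event_table`.
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Stimulus event
#'
#' One electrical or mechanical stimulus: onset time, magnitude in device
#' units (uA for dorsal-root shocks, grams for tail pressure), and pulse
#' width. The default width is the 0.2 ms supramaximal pulse used for
#' dorsal-root stimulation.
#'
#' @param time_s stimulus onset in seconds.
#' @param intensity non-negative stimulus magnitude.
#' @param duration_s pulse width in seconds.
#' @return an object of class `stimulus_event`.
#' @export
stimulus_event <- function(time_s, intensity = NA_real_, duration_s = 2e-4) {
  if (!is.na(intensity) && intensity < 0) stop("intensity must be >= 0")
  structure(list(time_s = as.numeric(time_s),
                 intensity = as.numeric(intensity),
                 duration_s = as.numeric(duration_s)),
            class = "stimulus_event")
}
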