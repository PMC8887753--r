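#' Construct an RR-interval series
#'
#' The universal currency of the pipeline: one row per beat, holding the beat
#' onset time (seconds from recording start), the RR interval that ends at
#' that beat (milliseconds), and a flag marking intervals that were replaced
#' during artifact correction. Onset times and intervals are kept consistent:
#' `time_s[k+1] - time_s[k] == rr_ms[k+1]/1000`.
#'
#' @param rr_ms numeric vector of RR intervals in milliseconds (all > 0).
#' @param onset_time_s optional beat onset times in seconds; when omitted they
#'   are rebuilt as `cumsum(rr_ms)/1000`.
#' @param corrected logical vector marking replaced intervals (default all
#'   `FALSE`).
#' @param ga_weeks gestational age in decimal weeks (metadata).
#' @param recording_id recording identifier (metadata).
#' @return a `data.frame` of class `rr_series` with columns `time_s`, `rr_ms`,
#'   `corrected` and attributes `ga_weeks`, `recording_id`.
#' @export
rr_series <- function(rr_ms, onset_time_s = NULL, corrected = NULL,
                      ga_weeks = NA_real_, recording_id = "recording") {
  rr_ms <- as.numeric(rr_ms)
  n <- length(rr_ms)
  if (n < 1L) stop_fhrv("an RR series needs at least one interval")
  bad <- which(!is.finite(rr_ms) | rr_ms <= 0)
  if (length(bad)) {
    stop_fhrv("nonpositive or non-finite RR intervals at rows: ",
              paste(bad, collapse = ", "))
  }
  if (is.null(onset_time_s)) {
    onset_time_s <- cumsum(rr_ms) / 1000
  } else {
    onset_time_s <- as.numeric(onset_time_s)
    if (length(onset_time_s) != n) stop_fhrv("onset_time_s and rr_ms lengths differ")
    if (any(diff(onset_time_s) <= 0)) {
      stop_fhrv("onset times must be strictly increasing (rows: ",
                paste(which(diff(onset_time_s) <= 0) + 1L, collapse = ", "), ")")
    }
    gap <- abs(diff(onset_time_s) - rr_ms[-1L] / 1000)
    if (any(gap > 1e-9)) {
      stop_fhrv("onset times inconsistent with RR intervals (first offending row: ",
                which(gap > 1e-9)[1L] + 1L, ")")
    }
  }
  corrected <- if (is.null(corrected)) rep(FALSE, n) else as.logical(corrected)
  if (length(corrected) != n) stop_fhrv("corrected mask and rr_ms lengths differ")
  out <- data.frame(time_s = onset_time_s, rr_ms = rr_ms, corrected = corrected)
  class(out) <- c("rr_series", "data.frame")
  attr(out, "ga_weeks") <- ga_weeks
  attr(out, "recording_id") <- recording_id
  out
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %s: %d beats, %.1f s, GA %.1f weeks, %d corrected\n",
              attr(x, "recording_id") %||% "?", nrow(x),
              x$time_s[nrow(x)] - x$time_s[1L] + x$rr_ms[1L] / 1000,
              attr(x, "ga_weeks") %||% NA_real_, sum(x$corrected)))
  invisible(x)
}

#' Extract a time window of an RR series, keeping metadata
#'
#' Keeps beats whose onset falls in `[start_s, end_s)`.
#' @param series an [rr_series()].
#' @param start_s,end_s window bounds in seconds.
#' @return an `rr_series` (possibly with zero rows).
#' @export
series_window <- function(series, start_s, end_s) {
  keep <- series$time_s >= start_s & series$time_s < end_s
  out <- series[keep, , drop = FALSE]
  class(out) <- c("rr_series", "data.frame")
  attr(out, "ga_weeks") <- attr(series, "ga_weeks")
  attr(out, "recording_id") <- attr(series, "recording_id")
  out
}

#' Read an RR-interval CSV
#'
#' Expects a header `time_s,rr_ms` with an optional `corrected` (0/1) column.
#' Onset/RR consistency is checked; if onset times disagree with the
#' intervals by more than 1e-6 s they are rebuilt from the intervals with a
#' warning.
#'
#' @param path file path.
#' @param ga_weeks,recording_id metadata attached to the returned series.
#' @return an [rr_series()].
#' @export
read_rr_csv <- function(path, ga_weeks = NA_real_, recording_id = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "rr_ms")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_fhrv("missing columns in ", path, ": ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$rr_ms) | df$rr_ms <= 0)
  if (length(bad)) stop_fhrv("nonpositive RR intervals in ", path, " at rows: ",
                             paste(bad, collapse = ", "))
  if (any(diff(df$time_s) <= 0)) {
    stop_fhrv("non-monotone onset times in ", path, " at rows: ",
              paste(which(diff(df$time_s) <= 0) + 1L, collapse = ", "))
  }
  corrected <- if ("corrected" %in% names(df)) df$corrected != 0 else NULL
  t <- df$time_s
  if (max(abs(diff(t) - df$rr_ms[-1L] / 1000)) > 1e-6) {
    warning("onset times inconsistent with RR intervals; rebuilding onsets from rr_ms")
    t <- df$time_s[1L] - df$rr_ms[1L] / 1000 + cumsum(df$rr_ms) / 1000
  } else {
    # snap to exact consistency so the strict constructor invariant holds
    t <- df$time_s[1L] - df$rr_ms[1L] / 1000 + cumsum(df$rr_ms) / 1000
  }
  rr_series(df$rr_ms, onset_time_s = t, corrected = corrected,
            ga_weeks = ga_weeks,
            recording_id = recording_id %||% sub("\\.csv$", "", basename(path)))
}

#' Write an RR-interval CSV (`time_s,rr_ms,corrected`)
#' @param series an [rr_series()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_rr_csv <- function(series, path) {
  df <- data.frame(time_s = series$time_s, rr_ms = series$rr_ms,
                   corrected = as.integer(series$corrected))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
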