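#' Enumerate candidate analysis windows with per-window quality
#'
#' Sliding windows of `length_s` seconds at `step_s` steps spanning the
#' recording. Each window carries the corrected fraction and longest
#' corrected run computed from the intervals whose onset falls inside it.
#'
#' @param series a corrected [rr_series()].
#' @param length_s window length, seconds (64 or 120 in the standard
#'   pipeline).
#' @param step_s step between window starts, seconds (default 1).
#' @param max_fraction,max_consecutive quality-gate thresholds (strict
#'   inequalities, see [quality_report()]).
#' @return data.frame with columns `start_s`, `end_s`, `n_beats`,
#'   `fraction_corrected`, `max_consecutive_corrected`, `quality_pass`;
#'   zero rows when the recording is shorter than `length_s`.
#' @export
enumerate_windows <- function(series, length_s, step_s = 1,
                              max_fraction = 0.05, max_consecutive = 5L) {
  t <- series$time_s
  # recording span includes the lead-in of the first interval
  t_start <- t[1L] - series$rr_ms[1L] / 1000
  span <- t[length(t)] - t_start
  if (span < length_s) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_beats = integer(0), fraction_corrected = numeric(0),
                      max_consecutive_corrected = integer(0),
                      quality_pass = logical(0)))
  }
  starts <- t_start + seq(0, span - length_s + 1e-9, by = step_s)
  rows <- lapply(starts, function(s) {
    inw <- t >= s & t < s + length_s
    frac <- mean(series$corrected[inw])
    run <- max_run(series$corrected[inw])
    data.frame(start_s = s, end_s = s + length_s, n_beats = sum(inw),
               fraction_corrected = frac,
               max_consecutive_corrected = as.integer(run),
               quality_pass = frac < max_fraction && run < max_consecutive)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify every candidate window of a recording
#'
#' Combines [enumerate_windows()] with [classify_window()] on the
#' recording's bpm trace.
#'
#' @param series a corrected [rr_series()].
#' @param length_s window length, seconds.
#' @param step_s window step, seconds.
#' @param criteria a [classification_criteria()].
#' @param ga_weeks gestational age; defaults to the series attribute.
#' @param trace optional precomputed `bpm_trace` (with baseline).
#' @param max_fraction,max_consecutive quality-gate thresholds.
#' @return data.frame: one row per candidate window with quality fields,
#'   logical label columns `shrp`, `hrp_i`, `hrp_ii`, `hrp_iii`,
#'   `stationarity_score`, `drift_bpm`, `bandwidth_bpm`, `n_accels`,
#'   `mean_bpm`.
#' @export
classify_windows <- function(series, length_s, step_s = 1,
                             criteria = classification_criteria(),
                             ga_weeks = attr(series, "ga_weeks"),
                             trace = NULL,
                             max_fraction = 0.05, max_consecutive = 5L) {
  wins <- enumerate_windows(series, length_s, step_s, max_fraction, max_consecutive)
  if (!nrow(wins)) return(cbind(wins, shrp = logical(0), hrp_i = logical(0),
                                hrp_ii = logical(0), hrp_iii = logical(0),
                                stationarity_score = numeric(0),
                                drift_bpm = numeric(0), bandwidth_bpm = numeric(0),
                                n_accels = integer(0), mean_bpm = numeric(0)))
  if (is.null(trace)) trace <- to_bpm_trace(series)
  exc <- detect_excursions(trace, criteria$excursion_amp_bpm,
                           criteria$excursion_dur_s)
  cls <- lapply(wins$start_s, function(s) {
    classify_window(trace, s, length_s, ga_weeks, criteria, exc)
  })
  wins$shrp <- vapply(cls, function(w) "SHRP" %in% w$labels, logical(1))
  wins$hrp_i <- vapply(cls, function(w) "HRP_I" %in% w$labels, logical(1))
  wins$hrp_ii <- vapply(cls, function(w) "HRP_II" %in% w$labels, logical(1))
  wins$hrp_iii <- vapply(cls, function(w) "HRP_III" %in% w$labels, logical(1))
  wins$stationarity_score <- vapply(cls, function(w) w$stationarity_score, numeric(1))
  wins$drift_bpm <- vapply(cls, function(w) w$evaluation$drift_shrp_bpm, numeric(1))
  wins$bandwidth_bpm <- vapply(cls, function(w) w$evaluation$bandwidth_bpm, numeric(1))
  wins$n_accels <- vapply(cls, function(w) w$evaluation$n_qualifying_accels_ctx, integer(1))
  wins$mean_bpm <- vapply(cls, function(w) w$evaluation$mean_bpm, numeric(1))
  wins
}

label_column <- function(class_label) {
  switch(class_label,
         SHRP = "shrp", HRP_I = "hrp_i", HRP_II = "hrp_ii", HRP_III = "hrp_iii",
         stop_fhrv("unknown class label: ", class_label))
}

#' Select the pair of time series compared in the reliability analysis
#'
#' Two qualifying, non-overlapping windows of the same class are selected
#' per recording. Policy `first_last` takes the chronologically first and
#' last qualifying windows (the default for patterns I-III, minimizing
#' information bias); `top_stationarity` (the default for SHRP) takes the
#' two non-overlapping qualifying windows with the highest stationarity
#' score, ties broken chronologically, the final pair ordered by time.
#' Selection never sees HRV values, so it is blinded to the outcome by
#' construction.
#'
#' @param windows a window table from [classify_windows()].
#' @param class_label one of `"SHRP"`, `"HRP_I"`, `"HRP_II"`, `"HRP_III"`.
#' @param policy `"first_last"` or `"top_stationarity"`.
#' @return list of class `segment_pair`: `selected` (logical), `class_label`,
#'   `policy`, `first`, `second` (window rows) or `reason` when excluded.
#' @export
select_pair <- function(windows, class_label,
                        policy = c("first_last", "top_stationarity")) {
  policy <- match.arg(policy)
  col <- label_column(class_label)
  cand <- windows[windows$quality_pass & windows[[col]], , drop = FALSE]
  excluded <- function(reason) {
    structure(list(selected = FALSE, class_label = class_label,
                   policy = policy, reason = reason), class = "segment_pair")
  }
  if (nrow(cand) < 2L)
    return(excluded("fewer than 2 qualifying windows"))
  pair <- NULL
  if (policy == "first_last") {
    first <- cand[1L, ]
    last <- cand[nrow(cand), ]
    if (last$start_s >= first$end_s) pair <- list(first, last)
  } else {
    ord <- order(-cand$stationarity_score, cand$start_s)
    for (i in seq_along(ord)) {
      a <- cand[ord[i], ]
      for (j in seq_along(ord)[-seq_len(i)]) {
        b <- cand[ord[j], ]
        if (b$start_s >= a$end_s || a$start_s >= b$end_s) {
          pair <- if (a$start_s < b$start_s) list(a, b) else list(b, a)
          break
        }
      }
      if (!is.null(pair)) break
    }
  }
  if (is.null(pair))
    return(excluded("no two non-overlapping qualifying windows"))
  structure(list(selected = TRUE, class_label = class_label, policy = policy,
                 first = pair[[1L]], second = pair[[2L]], reason = NULL),
            class = "segment_pair")
}
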