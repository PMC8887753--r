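#' Classification criteria for heart rate patterns
#'
#' Thresholds follow the CTG conventions used in fetal heart rate pattern
#' assessment: qualifying accelerations/decelerations are +/-15 bpm from
#' baseline sustained for at least 15 s; the stationary pattern (SHRP)
#' additionally requires baseline drift below 10 bpm per 2 minutes; pattern I
#' requires drift below 10 bpm per 3 minutes, oscillation bandwidth below
#' +/-5 bpm and heart rate below 160 bpm; pattern II has bandwidth above
#' +/-5 bpm; pattern III above +/-10 bpm with frequent long-lasting
#' accelerations. Patterns I-III are gestational-age gated (I: 24+1 to 32+0
#' weeks; II: 24+1 to 41+6; III: above 32+0 up to 41+6).
#'
#' "Isolated" versus "frequent" accelerations are quantified as at most 1
#' versus at least 2 qualifying events per surrounding 10 minutes; this
#' operationalization is a documented package choice.
#'
#' @param excursion_amp_bpm,excursion_dur_s qualifying excursion definition.
#' @param shrp_drift_bpm,shrp_drift_span_s SHRP baseline-drift rule.
#' @param hrp1_drift_bpm,hrp1_drift_span_s pattern I drift rule.
#' @param bandwidth_low_bpm,bandwidth_high_bpm oscillation-bandwidth
#'   cut-offs (+/-5 and +/-10 bpm).
#' @param tachy_bpm heart-rate ceiling for patterns I/II.
#' @param hrp1_ga,hrp2_ga,hrp3_ga applicability ranges in decimal weeks.
#' @param isolated_max_per_10min,frequent_min_per_10min acceleration-count
#'   quantification.
#' @param long_accel_s minimum duration of a "long-lasting" acceleration.
#' @return a list of class `classification_criteria`.
#' @export
classification_criteria <- function(excursion_amp_bpm = 15, excursion_dur_s = 15,
                                    shrp_drift_bpm = 10, shrp_drift_span_s = 120,
                                    hrp1_drift_bpm = 10, hrp1_drift_span_s = 180,
                                    bandwidth_low_bpm = 5, bandwidth_high_bpm = 10,
                                    tachy_bpm = 160,
                                    hrp1_ga = c(24 + 1 / 7, 32),
                                    hrp2_ga = c(24 + 1 / 7, 41 + 6 / 7),
                                    hrp3_ga = c(32, 41 + 6 / 7),
                                    isolated_max_per_10min = 1L,
                                    frequent_min_per_10min = 2L,
                                    long_accel_s = 30) {
  structure(as.list(environment()), class = "classification_criteria")
}

#' Convert an RR series to a uniformly sampled bpm trace with baseline
#'
#' `bpm = 60000 / rr_ms` is spline-interpolated onto a uniform grid and a
#' baseline is attached via [estimate_baseline()].
#'
#' @param series a corrected [rr_series()].
#' @param fs grid rate, Hz (default 4).
#' @return a `data.frame` of class `bpm_trace` with columns `time_s`, `bpm`,
#'   `baseline_bpm`.
#' @export
to_bpm_trace <- function(series, fs = 4) {
  t <- series$time_s
  if (length(t) < 3L) stop_fhrv("need at least 3 beats")
  if (t[length(t)] - t[1L] < 120)
    warning("series shorter than 120 s; drift evaluation spans will be clipped")
  bpm <- 60000 / series$rr_ms
  n_grid <- floor((t[length(t)] - t[1L]) * fs) + 1L
  grid <- t[1L] + (seq_len(n_grid) - 1L) / fs
  sf <- splinefun(t, bpm, method = "natural")
  trace <- data.frame(time_s = grid, bpm = sf(grid), baseline_bpm = NA_real_)
  class(trace) <- c("bpm_trace", "data.frame")
  estimate_baseline(trace)
}

#' Estimate the heart-rate baseline of a bpm trace
#'
#' Two-pass robust estimate: (1) running median over a centered 60-s window
#' (shrinking at the edges); (2) samples deviating from the first pass by
#' 15 bpm or more (i.e. candidate accelerations/decelerations) are excluded
#' and the running median is recomputed from the remainder, then smoothed by
#' a centered 15-s moving average. The result is defined at every grid
#' point.
#'
#' @param trace a `bpm_trace`.
#' @param median_window_s width of the running-median window, seconds.
#' @param excl_threshold_bpm deviation excluding a sample from pass 2.
#' @param smooth_window_s width of the final moving-average smoother.
#' @return the trace with `baseline_bpm` filled in.
#' @export
estimate_baseline <- function(trace, median_window_s = 60,
                              excl_threshold_bpm = 15, smooth_window_s = 15) {
  b <- trace$bpm
  n <- length(b)
  dt <- trace$time_s[2L] - trace$time_s[1L]
  half <- max(1L, round(median_window_s / 2 / dt))
  run_median <- function(vals, keep) {
    vapply(seq_len(n), function(i) {
      lo <- max(1L, i - half)
      hi <- min(n, i + half)
      v <- vals[lo:hi][keep[lo:hi]]
      if (length(v)) median(v) else NA_real_
    }, numeric(1))
  }
  p1 <- run_median(b, rep(TRUE, n))
  keep <- abs(b - p1) < excl_threshold_bpm
  p2 <- run_median(b, keep)
  p2[is.na(p2)] <- p1[is.na(p2)]
  trace$baseline_bpm <- moving_average_partial(p2, max(1L, round(smooth_window_s / 2 / dt)))
  trace
}

#' Detect accelerations and decelerations
#'
#' Maximal contiguous runs where `|bpm - baseline| >= min_amp_bpm`; a run
#' qualifies when it lasts at least `min_dur_s`. The excursion kind is taken
#' from the sign of the peak deviation.
#'
#' @param trace a `bpm_trace` with baseline estimated.
#' @param min_amp_bpm amplitude threshold (default 15 bpm).
#' @param min_dur_s duration threshold (default 15 s).
#' @return data.frame with columns `start_s`, `end_s`, `duration_s`,
#'   `peak_deviation_bpm`, `kind`, `qualifies` (zero rows when no excursion).
#' @export
detect_excursions <- function(trace, min_amp_bpm = 15, min_dur_s = 15) {
  dev <- trace$bpm - trace$baseline_bpm
  dt <- trace$time_s[2L] - trace$time_s[1L]
  r <- rle(abs(dev) >= min_amp_bpm)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0), peak_deviation_bpm = numeric(0),
                      kind = character(0), qualifies = logical(0)))
  }
  out <- do.call(rbind, lapply(keep, function(j) {
    idx <- starts[j]:ends[j]
    peak <- dev[idx][which.max(abs(dev[idx]))]
    dur <- r$lengths[j] * dt
    data.frame(start_s = trace$time_s[starts[j]],
               end_s = trace$time_s[ends[j]] + dt,
               duration_s = dur,
               peak_deviation_bpm = peak,
               kind = if (peak > 0) "acceleration" else "deceleration",
               qualifies = dur >= min_dur_s)
  }))
  rownames(out) <- NULL
  out
}

#' Oscillation bandwidth of a window
#'
#' Half of the 2.5th-97.5th percentile span of `bpm - baseline` within the
#' window, with samples inside qualifying excursions excluded; the
#' percentile span resists single-sample noise better than min/max.
#'
#' @param trace a `bpm_trace` with baseline.
#' @param start_s,end_s window bounds, seconds.
#' @param excursions optional excursion table from [detect_excursions()].
#' @return bandwidth in bpm, or `NA` when the window is fully covered by
#'   qualifying excursions.
#' @export
oscillation_bandwidth <- function(trace, start_s, end_s, excursions = NULL) {
  if (is.null(excursions)) excursions <- detect_excursions(trace)
  inw <- trace$time_s >= start_s & trace$time_s < end_s
  excl <- rep(FALSE, nrow(trace))
  q <- excursions[excursions$qualifies, , drop = FALSE]
  for (j in seq_len(nrow(q))) {
    excl <- excl | (trace$time_s >= q$start_s[j] & trace$time_s < q$end_s[j])
  }
  dev <- (trace$bpm - trace$baseline_bpm)[inw & !excl]
  if (!length(dev)) return(NA_real_)
  qs <- quantile(dev, c(0.025, 0.975), names = FALSE, type = 7)
  (qs[2L] - qs[1L]) / 2
}

baseline_drift <- function(trace, center_s, span_s) {
  lo <- center_s - span_s / 2
  hi <- center_s + span_s / 2
  idx <- trace$time_s >= lo & trace$time_s <= hi
  b <- trace$baseline_bpm[idx]
  if (!length(b)) return(NA_real_)
  max(b) - min(b)
}

ga_in <- function(ga, range) !is.na(ga) && ga >= range[1L] && ga <= range[2L]

#' Classify a candidate time-series window into heart rate patterns
#'
#' Labels are non-exclusive: a window may be SHRP and pattern I at once.
#' SHRP requires no qualifying excursion overlapping the window and baseline
#' drift (max - min of the estimated baseline over a 120-s span centered on
#' the window, clipped to the recording) below 10 bpm. Pattern I (GA-gated)
#' requires mean heart rate < 160 bpm, drift over a 180-s span < 10 bpm,
#' bandwidth < 5 bpm and only isolated accelerations, none overlapping the
#' window. Pattern II requires bandwidth > 5 bpm with heart rate < 160 bpm
#' outside qualifying accelerations. Pattern III (GA-gated) requires
#' bandwidth > 10 bpm and at least 2 qualifying accelerations lasting 30 s
#' or more in the surrounding 10 minutes. The stationarity score is minus
#' the SHRP-span drift, so higher is more stationary.
#'
#' @param trace a `bpm_trace` with baseline.
#' @param start_s window start, seconds.
#' @param length_s window length (64 or 120 in the standard pipeline).
#' @param ga_weeks gestational age in decimal weeks (gates patterns I-III).
#' @param criteria a [classification_criteria()].
#' @param excursions optional precomputed excursion table.
#' @return list of class `pattern_window`: `start_s`, `end_s`, `labels`
#'   (character vector, possibly empty), `stationarity_score`, `evaluation`
#'   (drift/bandwidth/acceleration-count/max-bpm record).
#' @export
classify_window <- function(trace, start_s, length_s, ga_weeks,
                            criteria = classification_criteria(),
                            excursions = NULL) {
  cr <- criteria
  if (is.null(excursions))
    excursions <- detect_excursions(trace, cr$excursion_amp_bpm, cr$excursion_dur_s)
  end_s <- start_s + length_s
  center <- (start_s + end_s) / 2
  inw <- trace$time_s >= start_s & trace$time_s < end_s
  if (!any(inw)) stop_fhrv("window outside trace")

  q <- excursions[excursions$qualifies, , drop = FALSE]
  overlap_win <- q$start_s < end_s & q$end_s > start_s
  qa <- q[q$kind == "acceleration", , drop = FALSE]
  ctx_lo <- center - 300
  ctx_hi <- center + 300
  in_ctx <- qa$start_s < ctx_hi & qa$end_s > ctx_lo
  n_accel_ctx <- sum(in_ctx)
  n_long_accel_ctx <- sum(in_ctx & qa$duration_s >= cr$long_accel_s)

  drift_shrp <- baseline_drift(trace, center, cr$shrp_drift_span_s)
  drift_hrp1 <- baseline_drift(trace, center, cr$hrp1_drift_span_s)
  bw <- oscillation_bandwidth(trace, start_s, end_s, excursions)
  mean_bpm <- mean(trace$bpm[inw])

  # max heart rate outside qualifying accelerations (pattern II tachycardia rule)
  in_accel <- rep(FALSE, nrow(trace))
  for (j in seq_len(nrow(qa))) {
    in_accel <- in_accel | (trace$time_s >= qa$start_s[j] & trace$time_s < qa$end_s[j])
  }
  non_accel_bpm <- trace$bpm[inw & !in_accel]
  max_bpm_non_accel <- if (length(non_accel_bpm)) max(non_accel_bpm) else NA_real_

  labels <- character(0)
  if (!any(overlap_win) && is.finite(drift_shrp) && drift_shrp < cr$shrp_drift_bpm)
    labels <- c(labels, "SHRP")
  if (ga_in(ga_weeks, cr$hrp1_ga) &&
      is.finite(bw) && bw < cr$bandwidth_low_bpm &&
      mean_bpm < cr$tachy_bpm &&
      is.finite(drift_hrp1) && drift_hrp1 < cr$hrp1_drift_bpm &&
      n_accel_ctx <= cr$isolated_max_per_10min &&
      !any(overlap_win & q$kind == "acceleration"))
    labels <- c(labels, "HRP_I")
  if (ga_in(ga_weeks, cr$hrp2_ga) &&
      is.finite(bw) && bw > cr$bandwidth_low_bpm &&
      is.finite(max_bpm_non_accel) && max_bpm_non_accel < cr$tachy_bpm)
    labels <- c(labels, "HRP_II")
  if (!is.na(ga_weeks) && ga_weeks > cr$hrp3_ga[1L] && ga_weeks <= cr$hrp3_ga[2L] &&
      is.finite(bw) && bw > cr$bandwidth_high_bpm &&
      n_long_accel_ctx >= cr$frequent_min_per_10min)
    labels <- c(labels, "HRP_III")

  structure(list(start_s = start_s, end_s = end_s, labels = labels,
                 stationarity_score = -drift_shrp,
                 evaluation = list(drift_shrp_bpm = drift_shrp,
                                   drift_hrp1_bpm = drift_hrp1,
                                   bandwidth_bpm = bw,
                                   n_qualifying_accels_ctx = n_accel_ctx,
                                   mean_bpm = mean_bpm,
                                   max_bpm_non_accel = max_bpm_non_accel)),
            class = "pattern_window")
}
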