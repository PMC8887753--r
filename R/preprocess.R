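#' Detect artifactual RR intervals by deviation from the running reference
#'
#' Forward single pass: interval k is flagged when it deviates from the most
#' recent accepted interval by more than `threshold_ms`. The reference is the
#' last unflagged value (cascade-safe): a single spike does not cause its
#' normal successor to be flagged. The first interval is never flagged.
#'
#' Typical thresholds are 40 ms, escalated to 100 ms for recordings whose
#' true beat-to-beat changes exceed 40 ms.
#'
#' @param series an [rr_series()].
#' @param threshold_ms positive deviation threshold in milliseconds.
#' @return logical vector, one element per interval.
#' @export
detect_artifacts <- function(series, threshold_ms = 40) {
  stopifnot(threshold_ms > 0)
  rr <- series$rr_ms
  n <- length(rr)
  mask <- logical(n)
  if (n < 2L) return(mask)
  ref <- rr[1L]
  for (k in 2:n) {
    if (abs(rr[k] - ref) > threshold_ms) {
      mask[k] <- TRUE
    } else {
      ref <- rr[k]
    }
  }
  mask
}

#' Replace flagged RR intervals by cubic-spline interpolation
#'
#' A natural cubic spline is fit to the accepted intervals as a function of
#' beat onset time (seconds, robust when runs of beats are flagged) and
#' evaluated at the flagged beats' original onset times. Onset times are then
#' recomputed from the corrected RR sequence so the onset/RR consistency
#' invariant holds. Flagged runs at a series boundary that would require
#' extrapolation are replaced by the nearest accepted value, with a warning.
#'
#' @param series an [rr_series()].
#' @param mask logical artifact mask aligned to intervals (e.g. from
#'   [detect_artifacts()]).
#' @return corrected [rr_series()] with `corrected` set at replaced positions.
#' @export
correct_artifacts <- function(series, mask) {
  stopifnot(length(mask) == nrow(series))
  if (!any(mask)) return(series)
  good <- !mask
  if (sum(good) < 4L) stop_fhrv("too few accepted intervals to fit a spline")
  t <- series$time_s
  rr <- series$rr_ms
  sf <- splinefun(t[good], rr[good], method = "natural")
  new_rr <- rr
  flagged <- which(mask)
  inside <- t[flagged] >= min(t[good]) & t[flagged] <= max(t[good])
  new_rr[flagged[inside]] <- sf(t[flagged[inside]])
  if (any(!inside)) {
    warning("flagged run at series boundary; replaced by nearest accepted value")
    for (i in flagged[!inside]) {
      nearest <- which(good)[which.min(abs(t[good] - t[i]))]
      new_rr[i] <- rr[nearest]
    }
  }
  t0 <- t[1L] - rr[1L] / 1000
  rr_series(new_rr, onset_time_s = t0 + cumsum(new_rr) / 1000,
            corrected = series$corrected | mask,
            ga_weeks = attr(series, "ga_weeks"),
            recording_id = attr(series, "recording_id"))
}

#' Segment quality report
#'
#' A segment passes when strictly less than `max_fraction` of its intervals
#' were corrected and the longest run of consecutive corrections is strictly
#' shorter than `max_consecutive`.
#'
#' @param series an [rr_series()] with its `corrected` mask populated.
#' @param max_fraction allowed corrected fraction (default 0.05).
#' @param max_consecutive allowed consecutive corrections (default 5).
#' @return list with `fraction_corrected`, `max_consecutive_corrected`,
#'   `passes`.
#' @export
quality_report <- function(series, max_fraction = 0.05, max_consecutive = 5L) {
  frac <- mean(series$corrected)
  run <- max_run(series$corrected)
  list(fraction_corrected = frac,
       max_consecutive_corrected = as.integer(run),
       passes = frac < max_fraction && run < max_consecutive)
}

second_diff_matrix <- function(n) {
  Matrix::sparseMatrix(i = rep(seq_len(n - 2L), 3L),
                       j = c(seq_len(n - 2L), seq_len(n - 2L) + 1L,
                             seq_len(n - 2L) + 2L),
                       x = rep(c(1, -2, 1), each = n - 2L),
                       dims = c(n - 2L, n))
}

sp_trend_solve <- function(z, lambda) {
  n <- length(z)
  D2 <- second_diff_matrix(n)
  A <- Matrix::Diagonal(n) + lambda^2 * Matrix::crossprod(D2)
  as.numeric(Matrix::solve(A, z))
}

#' Smoothness-priors detrending
#'
#' Removes the regularized trend `(I + lambda^2 * t(D2) %*% D2)^{-1} z`
#' (D2 the second-difference operator), acting as a time-varying high-pass
#' filter. The full sparse positive-definite system is solved exactly, so
#' boundary samples are handled without approximation. With `lambda = 0`
#' the trend equals the signal and the detrended output is identically zero.
#'
#' @param x uniformly sampled numeric series (length >= 3).
#' @param lambda dimensionless smoothing parameter (default 500, which at a
#'   4 Hz sampling rate corresponds to a ~0.035 Hz half-power cutoff, see
#'   [cutoff_frequency()]).
#' @return detrended numeric vector with the removed trend in
#'   `attr(, "trend")`.
#' @export
detrend_smoothness_priors <- function(x, lambda = 500) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L) stop_fhrv("smoothness-priors detrending needs at least 3 samples")
  if (lambda < 0) stop_fhrv("lambda must be >= 0")
  if (lambda == 0) {
    out <- rep(0, n)
    attr(out, "trend") <- x
    return(out)
  }
  trend <- sp_trend_solve(x, lambda)
  out <- x - trend
  attr(out, "trend") <- trend
  out
}

#' Half-power cutoff frequency of the smoothness-priors high-pass filter
#'
#' Builds the detrending operator on a uniform grid, extracts its interior
#' (time-invariant) row as an impulse response, evaluates the frequency
#' response numerically, and locates the frequency where the squared
#' magnitude equals 0.5. For `lambda = 500` at 4 Hz this is ~0.035 Hz.
#'
#' @param lambda smoothing parameter (> 0).
#' @param sampling_hz sampling rate of the series the filter acts on.
#' @param n grid length used to build the operator; the interior row decays
#'   well inside the default 1201 samples for any practical lambda.
#' @return cutoff frequency in Hz.
#' @export
cutoff_frequency <- function(lambda, sampling_hz, n = 1201L) {
  stopifnot(lambda > 0, sampling_hz > 0)
  mid <- (n + 1L) %/% 2L
  e <- numeric(n)
  e[mid] <- 1
  h <- e - sp_trend_solve(e, lambda)  # interior row of the high-pass operator
  lags <- seq_len(n) - mid
  mag2 <- function(f) {
    w <- 2 * pi * f / sampling_hz
    Mod(sum(h * exp(-1i * w * lags)))^2
  }
  uniroot(function(f) mag2(f) - 0.5,
          lower = sampling_hz * 1e-7, upper = sampling_hz / 2,
          tol = .Machine$double.eps^0.5)$root
}

#' Resample an RR series to a uniform tachogram
#'
#' Natural cubic-spline interpolation of RR (ms) as a function of beat onset
#' time, evaluated on a uniform grid at `resample_hz`. Resampling is used by
#' the spectral path only; time-domain parameters operate on the beat-domain
#' series.
#'
#' @param series an [rr_series()] (>= 3 beats inside the requested span).
#' @param resample_hz grid rate, Hz (default 4).
#' @param start_s,end_s span to cover; defaults to the full series. The grid
#'   is `start_s + k/resample_hz` for `k = 0, 1, ...` up to (excluding)
#'   `end_s`.
#' @return a `data.frame` of class `tachogram` with columns `time_s`,
#'   `rr_ms`.
#' @export
resample_tachogram <- function(series, resample_hz = 4, start_s = NULL,
                               end_s = NULL) {
  stopifnot(resample_hz > 0)
  t <- series$time_s
  rr <- series$rr_ms
  start_s <- start_s %||% t[1L]
  end_s <- end_s %||% t[length(t)]
  inside <- sum(t >= start_s & t <= end_s)
  if (inside < 3L) stop_fhrv("segment shorter than 3 beats")
  n_grid <- floor((end_s - start_s) * resample_hz - 1e-9) + 1L
  grid <- start_s + (seq_len(n_grid) - 1L) / resample_hz
  sf <- splinefun(t, rr, method = "natural")
  out <- data.frame(time_s = grid, rr_ms = sf(grid))
  class(out) <- c("tachogram", "data.frame")
  attr(out, "resample_hz") <- resample_hz
  out
}
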