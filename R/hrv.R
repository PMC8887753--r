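#' Spectral analysis configuration
#'
#' Fetal frequency bands reflect the higher fetal respiratory rate:
#' LF 0.04-0.4 Hz, HF 0.4-1.5 Hz (band powers in ms^2). The band lower edge
#' is inclusive and the upper edge exclusive, so 0.4 Hz belongs to HF only.
#'
#' @param resample_hz tachogram rate, Hz (default 4; the HF upper edge must
#'   not exceed `resample_hz/2`).
#' @param ar_order autoregressive model order (default 24).
#' @param lf_band,hf_band frequency bands, Hz.
#' @param window taper for the FFT path (only `"hann"` is implemented).
#' @return list of class `spectral_config`.
#' @export
spectral_config <- function(resample_hz = 4, ar_order = 24,
                            lf_band = c(0.04, 0.4), hf_band = c(0.4, 1.5),
                            window = "hann") {
  if (lf_band[2L] > hf_band[1L]) stop_fhrv("LF and HF bands must not overlap")
  if (hf_band[2L] > resample_hz / 2)
    stop_fhrv("HF upper edge must be <= resample_hz/2")
  if (ar_order < 1L) stop_fhrv("ar_order must be >= 1")
  structure(as.list(environment()), class = "spectral_config")
}

#' Time-domain HRV parameters
#'
#' Mean RR is the arithmetic mean, SDNN the sample standard deviation
#' (N-1 denominator), RMSSD the root mean square of successive differences.
#' In the standard pipeline the mean is computed from the un-detrended
#' corrected series while SDNN/RMSSD are computed from the detrended series;
#' this function computes all three on the values it is given, and
#' [segment_hrv()] wires the two sources together.
#'
#' @param rr_ms numeric vector of RR intervals, ms (>= 3 values).
#' @return list with `mean_rr_ms`, `sdnn_ms`, `rmssd_ms`.
#' @export
time_domain <- function(rr_ms) {
  rr_ms <- as.numeric(rr_ms)
  if (length(rr_ms) < 3L) stop_fhrv("time-domain parameters need >= 3 intervals")
  d <- diff(rr_ms)
  list(mean_rr_ms = mean(rr_ms),
       sdnn_ms = sd(rr_ms),
       rmssd_ms = sqrt(mean(d^2)))
}

new_psd <- function(freq_hz, psd, fs) {
  out <- data.frame(freq_hz = freq_hz, psd = psd)
  class(out) <- c("fhrv_psd", "data.frame")
  attr(out, "fs") <- fs
  out
}

#' FFT periodogram power spectral density
#'
#' Single Hann-tapered periodogram of the full segment (one window, zero
#' overlap), zero-padded to at least `pad_factor` times the segment length
#' rounded up to a power of two. The normalization divides by the window
#' energy, so the Riemann integral of the one-sided PSD over (0, fs/2]
#' equals the taper-compensated sample variance; for a sinusoid of
#' amplitude a the integrated peak power is a^2/2.
#'
#' @param x detrended, uniformly sampled tachogram values (ms); a
#'   `tachogram` data.frame is also accepted.
#' @param fs sampling rate, Hz.
#' @param pad_factor zero-padding factor (default 4).
#' @return a `data.frame` of class `fhrv_psd` with columns `freq_hz`, `psd`
#'   (ms^2/Hz, one-sided).
#' @export
psd_fft <- function(x, fs = 4, pad_factor = 4) {
  if (inherits(x, "tachogram")) {
    fs <- attr(x, "resample_hz") %||% fs
    x <- x$rr_ms
  }
  x <- as.numeric(x)
  n <- length(x)
  if (n < 16L) stop_fhrv("segment too short for spectral analysis (< 16 samples)")
  x <- x - mean(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)
  xw <- x * w
  nfft <- 2^ceiling(log2(pad_factor * n))
  X <- fft(c(xw, rep(0, nfft - n)))
  k <- 0:(nfft %/% 2L)
  p <- Mod(X[k + 1L])^2 / (fs * sum(w^2))
  one_sided <- rep(2, length(k))
  one_sided[c(1L, length(k))] <- 1
  new_psd(k * fs / nfft, p * one_sided, fs)
}

#' Burg autoregressive power spectral density
#'
#' AR coefficients by Burg's method at a fixed order (default 24, matching
#' the pipeline's spectral configuration), PSD evaluated as
#' `sigma^2 / (fs |A(e^{i 2 pi f / fs})|^2)` on a dense one-sided grid and
#' rescaled so its trapezoidal integral over (0, fs/2] equals the sample
#' variance of the segment.
#'
#' The returned frequency grid is non-uniform: around each near-unit-circle
#' pole of the fitted AR polynomial the grid is refined logarithmically down
#' to well inside the peak width, so the trapezoidal mass of very sharp
#' spectral lines (strong sinusoidal components) is captured accurately
#' instead of being aliased by a coarse uniform grid.
#'
#' @param x detrended tachogram values (ms) or a `tachogram` data.frame.
#' @param fs sampling rate, Hz.
#' @param order AR model order; must satisfy `2 * order < length(x)`.
#' @param n_freq number of base (uniform) frequency intervals.
#' @return a `data.frame` of class `fhrv_psd`.
#' @export
psd_ar <- function(x, fs = 4, order = 24L, n_freq = 2048L) {
  if (inherits(x, "tachogram")) {
    fs <- attr(x, "resample_hz") %||% fs
    x <- x$rr_ms
  }
  x <- as.numeric(x)
  n <- length(x)
  if (order >= n / 2) stop_fhrv("AR order must be < half the segment length")
  f <- seq(0, fs / 2, length.out = n_freq + 1L)
  v <- var(x)
  if (v < .Machine$double.eps) return(new_psd(f, rep(0, length(f)), fs))
  fit <- ar.burg(x, aic = FALSE, order.max = order, demean = TRUE)
  a <- fit$ar
  # refine the grid around sharp poles (peak half-width ~ (1-r) fs / 2pi)
  z <- 1 / polyroot(c(1, -a))
  r <- Mod(z)
  fp <- Arg(z) / (2 * pi) * fs
  sharp <- which(r > 0.9 & r < 1 & fp > 0 & fp < fs / 2)
  if (length(sharp)) {
    extra <- unlist(lapply(sharp, function(k) {
      w <- max((1 - r[k]) * fs / (2 * pi), 1e-15)
      off <- 10^seq(log10(w) - 3, log10(fs / 2), length.out = 60L)
      fp[k] + c(-off, off)
    }))
    extra <- extra[extra > 0 & extra < fs / 2]
    f <- sort(unique(c(f, extra)))
  }
  e <- exp(-2i * pi * outer(f, seq_len(length(a))) / fs)
  denom <- Mod(1 - as.vector(e %*% a))^2
  denom <- pmax(denom, .Machine$double.xmin)
  p <- 2 * fit$var.pred / (fs * denom)
  total <- trapz(f, p)
  new_psd(f, p * (v / total), fs)
}

#' Integrate a PSD over a frequency band
#'
#' Trapezoidal integral over `[band[1], band[2])` with the PSD linearly
#' interpolated at the band edges, so adjacent bands tile the axis exactly:
#' LF + HF + residual equals the total integrated power to rounding error.
#'
#' @param psd an `fhrv_psd`.
#' @param band numeric length-2 band, Hz.
#' @return band power in ms^2.
#' @export
band_power <- function(psd, band) {
  f <- psd$freq_hz
  p <- psd$psd
  lo <- band[1L]
  hi <- band[2L]
  if (lo < f[1L] - 1e-12 || hi > f[length(f)] + 1e-12)
    stop_fhrv("band outside PSD support")
  inner <- f[f > lo & f < hi]
  xs <- c(lo, inner, hi)
  ys <- approx(f, p, xout = xs, rule = 2)$y
  trapz(xs, ys)
}

#' All nine HRV parameters for one selected time-series window
#'
#' Mean RR comes from the un-detrended corrected beat series inside the
#' window; SDNN/RMSSD from the beat series after smoothness-priors
#' detrending (set `detrend_time_domain = FALSE` for raw values); LF/HF
#' powers and their ratio from the 4 Hz detrended tachogram under both the
#' FFT periodogram and the Burg AR estimator. The LF/HF ratio is `NA` when
#' the HF power integrates to zero.
#'
#' @param series a corrected [rr_series()].
#' @param start_s,end_s window bounds, seconds.
#' @param config a [spectral_config()].
#' @param lambda smoothness-priors parameter (default 500).
#' @param detrend_time_domain detrend the beat series before SDNN/RMSSD
#'   (default `TRUE`, mirroring the Kubios workflow).
#' @return one-row data.frame: `mean_rr_ms`, `sdnn_ms`, `rmssd_ms`,
#'   `lf_fft_ms2`, `hf_fft_ms2`, `lfhf_fft`, `lf_ar_ms2`, `hf_ar_ms2`,
#'   `lfhf_ar`.
#' @export
segment_hrv <- function(series, start_s, end_s, config = spectral_config(),
                        lambda = 500, detrend_time_domain = TRUE) {
  seg <- series_window(series, start_s, end_s)
  if (nrow(seg) < 3L) stop_fhrv("segment has fewer than 3 beats")
  rr <- seg$rr_ms
  td_input <- if (detrend_time_domain && length(rr) >= 3L) {
    as.numeric(detrend_smoothness_priors(rr, lambda))
  } else rr
  td <- time_domain(td_input)
  tach <- resample_tachogram(series, config$resample_hz, start_s, end_s)
  det <- as.numeric(detrend_smoothness_priors(tach$rr_ms, lambda))
  pf <- psd_fft(det, config$resample_hz)
  pa <- psd_ar(det, config$resample_hz, config$ar_order)
  lf_f <- band_power(pf, config$lf_band)
  hf_f <- band_power(pf, config$hf_band)
  lf_a <- band_power(pa, config$lf_band)
  hf_a <- band_power(pa, config$hf_band)
  data.frame(mean_rr_ms = mean(rr),
             sdnn_ms = td$sdnn_ms,
             rmssd_ms = td$rmssd_ms,
             lf_fft_ms2 = lf_f,
             hf_fft_ms2 = hf_f,
             lfhf_fft = if (hf_f > 0) lf_f / hf_f else NA_real_,
             lf_ar_ms2 = lf_a,
             hf_ar_ms2 = hf_a,
             lfhf_ar = if (hf_a > 0) lf_a / hf_a else NA_real_)
}
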