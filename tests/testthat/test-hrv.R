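test_that("time-domain parameters match hand calculations and brute force", {
  td <- time_domain(c(400, 400, 400))
  expect_equal(td$mean_rr_ms, 400)
  expect_equal(td$sdnn_ms, 0)
  expect_equal(td$rmssd_ms, 0)
  td2 <- time_domain(c(400, 410, 400, 410))
  expect_equal(td2$mean_rr_ms, 405)
  expect_equal(td2$rmssd_ms, 10)
  expect_equal(td2$sdnn_ms, sqrt(100 / 3))
  expect_error(time_domain(c(400, 410)), ">= 3")
  # oracle equivalence on random inputs
  withr::with_seed(1, {
    for (i in 1:200) {
      x <- runif(sample(3:50, 1), 300, 600)
      td <- time_domain(x)
      expect_equal(td$sdnn_ms, oracle_sdnn(x), tolerance = 1e-12)
      expect_equal(td$rmssd_ms, oracle_rmssd(x), tolerance = 1e-12)
    }
  })
})

test_that("FFT periodogram recovers sinusoid power and conserves variance", {
  t <- (0:479) / 4
  x <- 10 * sin(2 * pi * 1.0 * t + 0.3)
  p <- psd_fft(x, 4)
  expect_equal(band_power(p, c(0.4, 1.5)), 50, tolerance = 0.05)
  expect_lt(band_power(p, c(0.04, 0.4)), 2.5)
  # LF sinusoid lands in LF
  xl <- 10 * sin(2 * pi * 0.1 * t + 0.3)
  pl <- psd_fft(xl, 4)
  expect_equal(band_power(pl, c(0.04, 0.4)), 50, tolerance = 0.05)
  expect_lt(band_power(pl, c(0.4, 1.5)), 2.5)
  # white noise: integrated PSD ~ variance
  withr::with_seed(2, w <- rnorm(480, sd = 3))
  pw <- psd_fft(w, 4)
  expect_equal(band_power(pw, c(0, 2)), var(w), tolerance = 0.1)
  # zero input: zero PSD
  expect_true(all(psd_fft(rep(0, 480), 4)$psd == 0))
  expect_error(psd_fft(rnorm(8), 4), "16 samples")
})

test_that("band integration tiles the frequency axis exactly", {
  withr::with_seed(3, x <- rnorm(480))
  p <- psd_fft(x, 4)
  total <- band_power(p, c(0, 2))
  parts <- band_power(p, c(0, 0.04)) + band_power(p, c(0.04, 0.4)) +
    band_power(p, c(0.4, 1.5)) + band_power(p, c(1.5, 2))
  expect_equal(parts, total, tolerance = 1e-9)
  expect_error(band_power(p, c(1, 3)), "support")
})

test_that("Burg AR spectrum is flat for white noise and peaks correctly", {
  withr::with_seed(4, w <- rnorm(480, sd = 2))
  pa <- psd_ar(w, 4, 24)
  # integrated AR PSD equals the series variance by construction
  expect_equal(band_power(pa, c(0, 2)), var(w), tolerance = 0.05)
  # flat within a factor 2 over the analysis bands
  sel <- pa$freq_hz > 0.04 & pa$freq_hz < 1.5
  expect_lt(max(pa$psd[sel]) / min(pa$psd[sel]), 4)  # max/min <= 2 each way
  # AR(2) process with a known 0.9 Hz spectral peak
  withr::with_seed(5, {
    n <- 1500
    e <- rnorm(n)
    x <- numeric(n)
    for (k in 3:n) x[k] <- 0.2971 * x[k - 1] - 0.9025 * x[k - 2] + e[k]
    x <- x[501:n]
  })
  pk <- psd_ar(x[1:480], 4, 24)
  expect_equal(pk$freq_hz[which.max(pk$psd)], 0.9, tolerance = 0.05 / 0.9)
  expect_error(psd_ar(rnorm(40), 4, 24), "order")
})

test_that("FFT and AR band powers agree on smooth two-sinusoid input", {
  withr::with_seed(6, {
    t <- (0:479) / 4
    x <- 8 * sin(2 * pi * 0.15 * t + 1) + 6 * sin(2 * pi * 0.9 * t + 2) +
      rnorm(480, sd = 1)
  })
  pf <- psd_fft(x, 4)
  pa <- psd_ar(x, 4, 24)
  lf <- c(0.04, 0.4)
  hf <- c(0.4, 1.5)
  expect_equal(band_power(pa, lf), band_power(pf, lf), tolerance = 0.15)
  expect_equal(band_power(pa, hf), band_power(pf, hf), tolerance = 0.15)
})

test_that("generator ground truth propagates through the spectral chain", {
  # SDNN^2 ~ a_lf^2/2 + a_hf^2/2 + noise^2, averaged over seeds to tame the
  # chi-square sampling error of the realized noise variance
  v <- vapply(1:5, function(s) {
    sd(generate_rr_recording(synth_config(duration_s = 130, lf_amp_ms = 6,
                                          lf_freq_hz = 0.1, hf_amp_ms = 4,
                                          hf_freq_hz = 0.8, noise_sd_ms = 2,
                                          seed = s))$series$rr_ms)^2
  }, numeric(1))
  expect_equal(mean(v), 18 + 8 + 4, tolerance = 0.1)
  # noiseless modulation: band powers carry the analytic a^2/2 each
  rec <- generate_rr_recording(synth_config(duration_s = 130, lf_amp_ms = 6,
                                            lf_freq_hz = 0.1, hf_amp_ms = 4,
                                            hf_freq_hz = 0.8, seed = 8))
  seg <- segment_hrv(rec$series, 0, 120)
  expect_equal(seg$lf_fft_ms2, 18, tolerance = 0.2)
  expect_equal(seg$hf_fft_ms2, 8, tolerance = 0.25)
  expect_equal(seg$lf_ar_ms2, 18, tolerance = 0.25)
  expect_equal(seg$hf_ar_ms2, 8, tolerance = 0.3)
})

test_that("segment HRV returns the nine-parameter contract", {
  rec <- generate_rr_recording(synth_config(duration_s = 130, hf_amp_ms = 5,
                                            noise_sd_ms = 1, seed = 2))
  seg <- segment_hrv(rec$series, 0, 120)
  expect_named(seg, c("mean_rr_ms", "sdnn_ms", "rmssd_ms",
                      "lf_fft_ms2", "hf_fft_ms2", "lfhf_fft",
                      "lf_ar_ms2", "hf_ar_ms2", "lfhf_ar"))
  expect_true(all(seg[, c("lf_fft_ms2", "hf_fft_ms2", "lf_ar_ms2",
                          "hf_ar_ms2")] >= 0))
  expect_equal(seg$lfhf_fft, seg$lf_fft_ms2 / seg$hf_fft_ms2)
  # mean RR comes from the raw corrected series, not the detrended one
  expect_equal(seg$mean_rr_ms,
               mean(series_window(rec$series, 0, 120)$rr_ms))
})
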