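test_that("artifact detection flags deviations beyond the threshold", {
  s <- rr_series(c(400, 400, 460, 400))
  expect_identical(detect_artifacts(s, 40), c(FALSE, FALSE, TRUE, FALSE))
  s2 <- rr_series(c(400, 430, 400))
  expect_identical(detect_artifacts(s2, 40), rep(FALSE, 3))
  # the reference does not advance over a flagged spike
  s3 <- rr_series(c(400, 800, 405, 403))
  expect_identical(detect_artifacts(s3, 40), c(FALSE, TRUE, FALSE, FALSE))
  # an injected missed beat is always caught
  inj <- inject_artifacts(const_series(400, 200), 1 / 200, kinds = "missed",
                          seed = 4)
  mask <- detect_artifacts(inj$series, 40)
  expect_true(mask[inj$truth$artifact_positions])
  expect_length(detect_artifacts(rr_series(400), 40), 1L)
})

test_that("cubic-spline correction restores flat data and the time invariant", {
  s <- rr_series(c(400, 400, 800, 400, 400, 400))
  mask <- c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  out <- correct_artifacts(s, mask)
  expect_true(abs(out$rr_ms[3] - 400) < 20)
  expect_true(out$corrected[3])
  expect_true(all(abs(diff(out$time_s) - out$rr_ms[-1] / 1000) < 1e-9))
  # no flags: identity
  expect_identical(correct_artifacts(s, rep(FALSE, 6)), s)
  # boundary run falls back to nearest neighbour with a warning
  sb <- rr_series(c(900, 400, 400, 400, 400))
  expect_warning(outb <- correct_artifacts(sb, c(TRUE, FALSE, FALSE, FALSE, FALSE)),
                 "boundary")
  expect_equal(outb$rr_ms[1], 400)
})

test_that("detect+correct is idempotent on corrected flat data", {
  inj <- inject_artifacts(const_series(420, 400), 0.03, kinds = "spike", seed = 9)
  fixed <- correct_artifacts(inj$series, detect_artifacts(inj$series, 40))
  expect_false(any(detect_artifacts(fixed, 40)))
})

test_that("correction moves SDNN toward the clean value", {
  wins <- 0L
  for (seed in 1:20) {
    cfg <- synth_config(duration_s = 120, lf_amp_ms = 5, hf_amp_ms = 3,
                        noise_sd_ms = 2, seed = seed)
    clean <- generate_rr_recording(cfg)$series
    inj <- inject_artifacts(clean, 0.03, seed = seed + 100)
    fixed <- correct_artifacts(inj$series, detect_artifacts(inj$series, 40))
    ref <- sd(clean$rr_ms)
    if (abs(sd(fixed$rr_ms) - ref) < abs(sd(inj$series$rr_ms) - ref))
      wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("quality gate applies strict 5% / 5-run rules", {
  mk <- function(n, idx) {
    s <- const_series(400, n)
    s$corrected[idx] <- TRUE
    s
  }
  q <- quality_report(mk(100, c(10, 30, 50, 70)))
  expect_equal(q$fraction_corrected, 0.04)
  expect_equal(q$max_consecutive_corrected, 1L)
  expect_true(q$passes)
  expect_false(quality_report(mk(100, seq(10, 60, by = 10)))$passes)  # 6%
  expect_false(quality_report(mk(100, c(10, 20, 30, 40, 50)))$passes) # 5%
  expect_false(quality_report(mk(200, 50:54))$passes)                 # run of 5
  expect_true(quality_report(mk(200, c(50:53, 90:93)))$passes)        # runs of 4
})

test_that("smoothness-priors detrending removes constants and is linear", {
  z <- rep(3.7, 50)
  expect_true(all(abs(detrend_smoothness_priors(z, 500)) < 1e-6))
  # lambda = 0: trend is the identity solution
  x <- rnorm(40)
  expect_identical(as.numeric(detrend_smoothness_priors(x, 0)), rep(0, 40))
  # linearity
  withr::with_seed(5, y <- rnorm(200))
  d1 <- as.numeric(detrend_smoothness_priors(y, 500))
  d3 <- as.numeric(detrend_smoothness_priors(3 * y, 500))
  expect_equal(d3, 3 * d1, tolerance = 1e-10)
  # DC rejection after adding an offset
  expect_equal(as.numeric(detrend_smoothness_priors(y + 100, 500)), d1,
               tolerance = 1e-6)
  expect_error(detrend_smoothness_priors(c(1, 2), 500), "3 samples")
})

test_that("detrending passes high frequencies and suppresses low ones", {
  withr::with_seed(11, x <- rnorm(4800))
  d <- as.numeric(detrend_smoothness_priors(x, 500))
  p_raw <- psd_fft(x, 4)
  p_det <- psd_fft(d, 4)
  hi_ratio <- band_power(p_det, c(0.07, 2)) / band_power(p_raw, c(0.07, 2))
  lo_ratio <- band_power(p_det, c(1e-4, 0.02)) / band_power(p_raw, c(1e-4, 0.02))
  expect_equal(hi_ratio, 1, tolerance = 0.05)
  expect_lte(lo_ratio, 0.25)
})

test_that("half-power cutoff matches the analytic interior-row response", {
  f0 <- cutoff_frequency(500, 4)
  expect_equal(f0, 0.035, tolerance = 0.005 / 0.035)
  # analytic symbol of the interior row: H = x/(1+x), x = 16 lambda^2 sin^4(w/2)
  analytic <- function(lambda, fs) {
    g <- function(f) {
      x <- 16 * lambda^2 * sin(pi * f / fs)^4
      (x / (1 + x))^2 - 0.5
    }
    uniroot(g, c(1e-6, fs / 2), tol = 1e-12)$root
  }
  expect_equal(f0, analytic(500, 4), tolerance = 1e-4)
  # monotone in lambda; proportional to the sampling rate
  expect_lt(cutoff_frequency(2000, 4), f0)
  expect_equal(cutoff_frequency(500, 8) / f0, 2, tolerance = 1e-6)
})

test_that("tachogram resampling preserves constants, grid and frequency content", {
  s <- const_series(400, 500)
  tach <- resample_tachogram(s, 4)
  expect_true(all(abs(diff(tach$time_s) - 0.25) < 1e-12))
  expect_equal(tach$rr_ms, rep(400, nrow(tach)), tolerance = 1e-9)
  # 0.2 Hz / 10 ms modulation dominates the periodogram at 0.2 Hz
  rec <- generate_rr_recording(synth_config(duration_s = 300, lf_amp_ms = 10,
                                            lf_freq_hz = 0.2))
  tg <- resample_tachogram(rec$series, 4)
  p <- psd_fft(tg$rr_ms - mean(tg$rr_ms), 4)
  peak <- p$freq_hz[which.max(p$psd)]
  expect_equal(peak, 0.2, tolerance = 0.01 / 0.2)
  expect_error(resample_tachogram(rr_series(c(400, 400)), 4), "3 beats")
})
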