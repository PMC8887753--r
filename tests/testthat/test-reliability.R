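test_that("closed-form variance components match hand calculation", {
  f <- fit_variance_components(exp(c(1.0, 2.0)), exp(c(1.2, 1.8)))
  expect_equal(f$sigma_e2, 0.02)
  expect_equal(f$sigma_b2, 0.31)
  expect_equal(f$mu_log, 1.5)
  # identical replicates: zero within variance
  f0 <- fit_variance_components(c(3, 5, 9), c(3, 5, 9))
  expect_equal(f0$sigma_e2, 0)
  expect_error(fit_variance_components(c(1, -2, 3), c(1, 2, 3)), "subjects")
  expect_error(fit_variance_components(1, numeric(0)), "equal length")
})

test_that("closed form equals iterative REML on random balanced data", {
  withr::with_seed(10, {
    for (i in 1:30) {
      m <- sample(20:50, 1)
      sb <- runif(1, 0.4, 1)
      se <- runif(1, 0.2, 0.5)
      b <- rnorm(m, 0, sb)
      y1 <- 2 + b + rnorm(m, 0, se)
      y2 <- 2 + b + rnorm(m, 0, se)
      f <- fit_variance_components(exp(y1), exp(y2))
      o <- reml_oracle(y1, y2)
      expect_equal(f$sigma_b2, o$sigma_b2, tolerance = 1e-8)
      expect_equal(f$sigma_e2, o$sigma_e2, tolerance = 1e-8)
    }
  })
})

test_that("closed form agrees with lme4 REML", {
  skip_if_not_installed("lme4")
  withr::with_seed(21, {
    m <- 40
    b <- rnorm(m, 0, 0.6)
    y <- 2 + rep(b, each = 2) + rnorm(2 * m, 0, 0.3)
  })
  df <- data.frame(subject = factor(rep(1:40, each = 2)), y = y)
  fit <- lme4::lmer(y ~ 1 + (1 | subject), data = df, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  f <- fit_variance_components(exp(y[seq(1, 79, 2)]), exp(y[seq(2, 80, 2)]))
  expect_equal(f$sigma_b2, vc$vcov[1], tolerance = 1e-4)
  expect_equal(f$sigma_e2, vc$vcov[2], tolerance = 1e-4)
})

test_that("within-subject CV follows the log-normal formula", {
  expect_equal(within_cv(0), 0)
  expect_equal(within_cv(0.04), 0.2020168, tolerance = 1e-6)
  expect_equal(within_cv(log(1.0676)), 0.26, tolerance = 1e-6)
  ci <- within_cv_ci(0.04, 46)
  expect_lt(ci[["lower"]], ci[["cv"]])
  expect_gt(ci[["upper"]], ci[["cv"]])
})

test_that("ICC is the between share of total variance", {
  expect_equal(icc(0.3, 0.1), 0.75)
  expect_equal(icc(0.25, 0.04), 0.8620690, tolerance = 1e-6)
  expect_equal(icc(0, 0.2), 0)
  expect_equal(icc(0.2, 0), 1)
  expect_warning(expect_true(is.na(icc(0, 0))), "undefined")
  expect_error(icc(-0.1, 0.2), ">= 0")
})

test_that("Bland-Altman agreement is exact on degenerate and biased pairs", {
  ba0 <- bland_altman(c(3, 5, 9), c(3, 5, 9))
  expect_equal(ba0$median_ratio, 1)
  expect_equal(ba0$loa_ratio, c(1, 1))
  v2 <- c(4.1, 5.3, 7.7, 9.2)
  ba <- bland_altman(1.1 * v2, v2)
  expect_equal(ba$mean_log_diff, log(1.1), tolerance = 1e-12)
  # ratio LoA geometry: half-width exp(1.96 sqrt(2) sigma_e)
  withr::with_seed(3, {
    b <- rnorm(200, 0, 0.5)
    y1 <- exp(2 + b + rnorm(200, 0, 0.198))
    y2 <- exp(2 + b + rnorm(200, 0, 0.198))
  })
  bb <- bland_altman(y1, y2)
  f <- fit_variance_components(y1, y2)
  expect_equal(log(bb$loa_ratio[2] / bb$loa_ratio[1]) / 2,
               qnorm(0.975) * sqrt(2 * f$sigma_e2), tolerance = 1e-6)
  expect_equal(exp(qnorm(0.975) * sqrt(2) * 0.198), 1.73, tolerance = 0.01)
})

test_that("averaging-of-n extrapolation reduces to base values and is monotone", {
  ex <- extrapolate_average_of_n(0.25, 0.04, 1:6)
  expect_equal(ex$cv_n[1], within_cv(0.04))
  expect_equal(ex$icc_n[1], icc(0.25, 0.04))
  expect_equal(ex$icc_n[2], 0.9259259, tolerance = 1e-6)
  expect_true(all(diff(ex$icc_n) > 0))
  expect_true(all(diff(ex$cv_n) < 0))
  expect_true(all(ex$pi_lower < 1 & ex$pi_upper > 1))
  expect_error(extrapolate_average_of_n(0.2, 0.1, 0), ">= 1")
})

mk_segments <- function(v1, v2, parameter = "sdnn_ms", class = "SHRP",
                        length_s = 120, ga = 30) {
  m <- length(v1)
  data.frame(recording_id = rep(sprintf("r%03d", seq_len(m)), 2),
             ga_weeks = ga, class = class, length_s = length_s,
             replicate = rep(1:2, each = m), parameter = parameter,
             value = c(v1, v2))
}

test_that("reliability report flags acceptability and insufficiency", {
  # sigma_e for CV = 0.13, sigma_b for ICC = 0.93
  se2 <- log(1 + 0.13^2)
  sb2 <- 0.93 / 0.07 * se2
  withr::with_seed(9, {
    b <- rnorm(60, 0, sqrt(sb2))
    v1 <- exp(2 + b + rnorm(60, 0, sqrt(se2)))
    v2 <- exp(2 + b + rnorm(60, 0, sqrt(se2)))
  })
  rep1 <- reliability_report(mk_segments(v1, v2))
  expect_true(rep1$table$acceptable[1])
  expect_named(rep1$table,
               c("parameter", "class", "length_s", "n", "median", "range_lo",
                 "range_hi", "cv", "cv_lo", "cv_hi", "loa_lo", "loa_hi",
                 "icc", "acceptable", "note"))
  expect_equal(nrow(rep1$per_n), 6L)
  # two pairs only: insufficient
  rep2 <- reliability_report(mk_segments(c(3, 5), c(3.1, 5.2)))
  expect_match(rep2$table$note[1], "insufficient")
  expect_true(is.na(rep2$table$cv[1]))
})

test_that("outlier sensitivity rerun drops extreme pairs", {
  v1 <- c(2, 3, 4, 5, 80)  # last value > 10x the median
  v2 <- c(2.2, 2.9, 4.1, 5.2, 70)
  base <- reliability_report(mk_segments(v1, v2))
  sens <- reliability_report(mk_segments(v1, v2), exclude_outliers = TRUE)
  expect_equal(base$table$n, 5L)
  expect_equal(sens$table$n, 4L)
  expect_match(sens$table$note, "outlier")
})

test_that("GA-grouped report stratifies into the three printed groups", {
  seg <- rbind(mk_segments(c(3, 4, 5, 6), c(3.1, 4.2, 4.9, 6.3), ga = 23),
               mk_segments(c(3, 4, 5, 6), c(3.1, 4.2, 4.9, 6.3), ga = 30),
               mk_segments(c(3, 4, 5, 6), c(3.1, 4.2, 4.9, 6.3), ga = 38))
  seg$recording_id <- paste0(seg$recording_id, "-", seg$ga_weeks)
  rep3 <- reliability_report(seg, by_ga_group = TRUE)
  expect_setequal(rep3$table$ga_group, c("A", "B", "C"))
})
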