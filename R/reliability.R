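#' Closed-form variance components for paired log-normal measurements
#'
#' On the natural-log scale the model is a balanced random-intercept model,
#' `y_ij = mu + b_i + e_ij` with two replicates per subject. The estimators
#' are `sigma_e2 = sum(d_i^2) / (2m)` (d_i the within-pair difference, m the
#' number of pairs), `sigma_b2 = max(0, var(pair means) - sigma_e2 / 2)`,
#' and `mu` the grand mean. For the balanced two-replicate design with no
#' fixed order effect these equal the REML estimates (the between component
#' truncated at the zero boundary).
#'
#' @param value_first,value_second positive measurement values, one pair per
#'   subject (chronologically first and second time series).
#' @param subject optional subject identifiers used in error messages.
#' @return list with `n_pairs`, `mu_log`, `sigma_b2`, `sigma_e2`.
#' @export
fit_variance_components <- function(value_first, value_second, subject = NULL) {
  m <- length(value_first)
  if (length(value_second) != m) stop_fhrv("pair vectors must have equal length")
  if (m < 2L) stop_fhrv("need at least 2 pairs")
  bad <- which(!(value_first > 0) | !(value_second > 0))
  if (length(bad)) {
    who <- if (is.null(subject)) bad else subject[bad]
    stop_fhrv("nonpositive values for subjects: ", paste(who, collapse = ", "))
  }
  y1 <- log(value_first)
  y2 <- log(value_second)
  d <- y1 - y2
  sigma_e2 <- sum(d^2) / (2 * m)
  sigma_b2 <- max(0, var((y1 + y2) / 2) - sigma_e2 / 2)
  list(n_pairs = m, mu_log = mean(c(y1, y2)),
       sigma_b2 = sigma_b2, sigma_e2 = sigma_e2)
}

#' Within-subject coefficient of variation on the log scale
#'
#' Exact log-normal CV, `sqrt(exp(sigma_e2) - 1)`; at the magnitudes typical
#' of HRV reliability this differs from the small-variance approximation
#' `sigma_e` by under 1 percent.
#'
#' @param sigma_e2 within-subject log-scale variance (>= 0).
#' @return CV as a proportion.
#' @export
within_cv <- function(sigma_e2) {
  if (any(sigma_e2 < 0)) stop_fhrv("sigma_e2 must be >= 0")
  sqrt(exp(sigma_e2) - 1)
}

#' Chi-square confidence interval for the within-subject CV
#'
#' `m * sigma_e2 / sigma_e2_true` is chi-square with m degrees of freedom
#' under the paired model (each pair difference contributes one), giving
#' limits on `sigma_e2` that transform monotonically to CV limits.
#'
#' @param sigma_e2 estimated within-subject log-scale variance.
#' @param m number of pairs.
#' @param conf confidence level (default 0.95).
#' @return named vector `cv`, `lower`, `upper`.
#' @export
within_cv_ci <- function(sigma_e2, m, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- m * sigma_e2 / qchisq(1 - a, df = m)
  hi <- m * sigma_e2 / qchisq(a, df = m)
  c(cv = within_cv(sigma_e2), lower = within_cv(lo), upper = within_cv(hi))
}

#' Intraclass correlation coefficient
#'
#' `sigma_b2 / (sigma_b2 + sigma_e2)`: the share of total log-scale variance
#' attributable to true between-subject differences (relative reliability).
#'
#' @param sigma_b2,sigma_e2 log-scale variance components (>= 0, not both 0).
#' @return ICC in [0, 1]; `NA` with a warning when both components are zero.
#' @export
icc <- function(sigma_b2, sigma_e2) {
  if (sigma_b2 < 0 || sigma_e2 < 0) stop_fhrv("variance components must be >= 0")
  if (sigma_b2 == 0 && sigma_e2 == 0) {
    warning("both variance components are zero; ICC undefined")
    return(NA_real_)
  }
  sigma_b2 / (sigma_b2 + sigma_e2)
}

#' Bland-Altman agreement of paired measurements on the log/ratio scale
#'
#' The mean log difference estimates systematic first-versus-second bias;
#' the 95% limits of agreement are `mean(d) +/- 1.96 * sqrt(2) * sigma_e`
#' with `sigma_e` the model within-SD from [fit_variance_components()]
#' (so the limits are exactly consistent with the CV; see the methods
#' vignette). Back-transforming gives the median ratio and LoA on the ratio
#' scale.
#'
#' @param value_first,value_second positive paired values, first minus
#'   second on the log scale.
#' @return list with `n_pairs`, `mean_log_diff`, `loa_log` (length 2),
#'   `median_ratio`, `loa_ratio` (length 2).
#' @export
bland_altman <- function(value_first, value_second) {
  fit <- fit_variance_components(value_first, value_second)
  d <- log(value_first) - log(value_second)
  half <- .qnorm975 * sqrt(2 * fit$sigma_e2)
  loa_log <- c(mean(d) - half, mean(d) + half)
  list(n_pairs = fit$n_pairs,
       mean_log_diff = mean(d),
       loa_log = loa_log,
       median_ratio = exp(mean(d)),
       loa_ratio = exp(loa_log))
}

#' Reliability of the average of n repeated time series
#'
#' Averaging n independent time series from the same fetus divides the
#' within variance by n: `cv_n = sqrt(exp(sigma_e2/n) - 1)`,
#' `icc_n = sigma_b2 / (sigma_b2 + sigma_e2/n)`, and the 95% prediction
#' interval of the n-average around the subject's true median on the ratio
#' scale is `exp(+/- 1.96 * sigma_e / sqrt(n))`. This is analytic
#' extrapolation under the equal-variance assumption, not a new fit.
#'
#' @param sigma_b2,sigma_e2 log-scale variance components.
#' @param n number of averaged time series (vectorized, each >= 1).
#' @return data.frame with columns `n`, `cv_n`, `icc_n`, `pi_lower`,
#'   `pi_upper`.
#' @export
extrapolate_average_of_n <- function(sigma_b2, sigma_e2, n = 1:6) {
  if (any(n < 1)) stop_fhrv("n must be >= 1")
  e_n <- sigma_e2 / n
  data.frame(n = n,
             cv_n = within_cv(e_n),
             icc_n = sigma_b2 / (sigma_b2 + e_n),
             pi_lower = exp(-.qnorm975 * sqrt(e_n)),
             pi_upper = exp(.qnorm975 * sqrt(e_n)))
}

ga_group <- function(ga_weeks) {
  cut(ga_weeks, breaks = c(20, 28, 35, 42), labels = c("A", "B", "C"),
      right = FALSE, include.lowest = TRUE)
}

#' Grouped reliability report for per-segment HRV parameters
#'
#' For each parameter x pattern class x window length (x gestational-age
#' group when `by_ga_group`), the paired values are fitted with the
#' closed-form variance-components model and summarized as n, median, range,
#' within-CV with chi-square CI, ratio-scale limits of agreement, ICC, an
#' acceptability flag (CV <= `cv_max` and ICC >= `icc_min`), plus an
#' averaging-of-n extrapolation block. Groups with fewer than 3 complete
#' pairs are reported as insufficient. Outliers (values above 10x the group
#' median) are retained by default, mirroring the primary analysis; setting
#' `exclude_outliers = TRUE` reruns each group without pairs containing
#' such values (sensitivity analysis).
#'
#' @param segments long-format data.frame with columns `recording_id`,
#'   `ga_weeks`, `class`, `length_s`, `replicate` (1 or 2), `parameter`,
#'   `value`.
#' @param by_ga_group also stratify by gestational-age group
#'   (A: 20+0-27+6, B: 28+0-34+6, C: 35+0-41+0 weeks).
#' @param exclude_outliers drop pairs containing values > 10x group median.
#' @param cv_max,icc_min acceptability thresholds (defaults 0.15 and 0.80).
#' @param n_avg_max largest n in the averaging extrapolation (default 6).
#' @return list with `table` (one row per group) and `per_n` (the
#'   averaging-of-n block, long over n = 1..`n_avg_max`).
#' @export
reliability_report <- function(segments, by_ga_group = FALSE,
                               exclude_outliers = FALSE,
                               cv_max = 0.15, icc_min = 0.80, n_avg_max = 6L) {
  need <- c("recording_id", "ga_weeks", "class", "length_s", "replicate",
            "parameter", "value")
  miss <- setdiff(need, names(segments))
  if (length(miss)) stop_fhrv("segments is missing columns: ",
                              paste(miss, collapse = ", "))
  segments <- segments[is.finite(segments$value), , drop = FALSE]
  keys <- list(parameter = segments$parameter, class = segments$class,
               length_s = segments$length_s)
  if (by_ga_group) keys$ga_group <- as.character(ga_group(segments$ga_weeks))
  groups <- split(segments, keys, drop = TRUE, sep = "\r")
  rows <- list()
  per_n <- list()
  for (g in groups) {
    key <- data.frame(parameter = g$parameter[1L], class = g$class[1L],
                      length_s = g$length_s[1L])
    if (by_ga_group) key$ga_group <- as.character(ga_group(g$ga_weeks[1L]))
    v1 <- g$value[g$replicate == 1L]
    v2 <- g$value[g$replicate == 2L]
    id1 <- g$recording_id[g$replicate == 1L]
    id2 <- g$recording_id[g$replicate == 2L]
    common <- intersect(id1, id2)
    v1 <- v1[match(common, id1)]
    v2 <- v2[match(common, id2)]
    ok <- v1 > 0 & v2 > 0
    v1 <- v1[ok]
    v2 <- v2[ok]
    note <- ""
    if (exclude_outliers && length(v1)) {
      med <- median(c(v1, v2))
      keep <- v1 <= 10 * med & v2 <= 10 * med
      if (any(!keep)) note <- sprintf("%d outlier pair(s) excluded", sum(!keep))
      v1 <- v1[keep]
      v2 <- v2[keep]
    }
    m <- length(v1)
    if (m < 3L) {
      rows[[length(rows) + 1L]] <- cbind(
        key, data.frame(n = m, median = NA_real_, range_lo = NA_real_,
                        range_hi = NA_real_, cv = NA_real_, cv_lo = NA_real_,
                        cv_hi = NA_real_, loa_lo = NA_real_, loa_hi = NA_real_,
                        icc = NA_real_, acceptable = NA,
                        note = "insufficient (< 3 pairs)"))
      next
    }
    fit <- fit_variance_components(v1, v2)
    cvci <- within_cv_ci(fit$sigma_e2, m)
    ba <- bland_altman(v1, v2)
    icc_hat <- icc(fit$sigma_b2, fit$sigma_e2)
    all_v <- c(v1, v2)
    rows[[length(rows) + 1L]] <- cbind(
      key, data.frame(n = m, median = median(all_v),
                      range_lo = min(all_v), range_hi = max(all_v),
                      cv = cvci[["cv"]], cv_lo = cvci[["lower"]],
                      cv_hi = cvci[["upper"]],
                      loa_lo = ba$loa_ratio[1L], loa_hi = ba$loa_ratio[2L],
                      icc = icc_hat,
                      acceptable = cvci[["cv"]] <= cv_max && icc_hat >= icc_min,
                      note = note))
    per_n[[length(per_n) + 1L]] <- cbind(
      key, extrapolate_average_of_n(fit$sigma_b2, fit$sigma_e2,
                                    seq_len(n_avg_max)),
      row.names = NULL)
  }
  table <- if (length(rows)) do.call(rbind, rows) else NULL
  per_n_tab <- if (length(per_n)) do.call(rbind, per_n) else NULL
  if (!is.null(table)) rownames(table) <- NULL
  if (!is.null(per_n_tab)) rownames(per_n_tab) <- NULL
  list(table = table, per_n = per_n_tab)
}
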