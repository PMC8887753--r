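# Independent oracles used to cross-check the package's implementations.

# brute-force single-pass references for the time-domain parameters
oracle_sdnn <- function(x) {
  m <- mean(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}
oracle_rmssd <- function(x) {
  s <- 0
  for (k in 2:length(x)) s <- s + (x[k] - x[k - 1])^2
  sqrt(s / (length(x) - 1))
}

# constant RR series helper
const_series <- function(rr = 400, n = 300, ga = 30) {
  rr_series(rep(rr, n), ga_weeks = ga)
}

# square-pulse bpm trace built directly on a 4 Hz grid (no generator)
square_trace <- function(duration_s = 300, base = 140, pulse_amp = 0,
                         pulse_start = 0, pulse_dur = 0, fs = 4) {
  tt <- seq(0, duration_s, by = 1 / fs)
  bpm <- rep(base, length(tt)) +
    ifelse(tt >= pulse_start & tt < pulse_start + pulse_dur, pulse_amp, 0)
  tr <- data.frame(time_s = tt, bpm = bpm, baseline_bpm = base)
  class(tr) <- c("bpm_trace", "data.frame")
  tr
}

# Numeric REML for the balanced two-replicate random-intercept model,
# independent of the closed form: the REML criterion (restricted
# log-likelihood built from the per-subject 2x2 covariance) is minimized
# numerically by coordinate descent over the within variance u = sigma_e2
# and the pair-sum variance v = sigma_e2 + 2 sigma_b2, each coordinate by
# golden-section search. The unconstrained stationary point is located and
# sigma_b2 truncated at zero afterwards, matching the estimator's stated
# boundary convention.
reml_oracle <- function(y1, y2) {
  m <- length(y1)
  mu <- mean(c(y1, y2))
  r1 <- y1 - mu
  r2 <- y2 - mu
  nll <- function(b2, e2) {
    det <- e2 * (e2 + 2 * b2)
    if (det <= 0 || e2 <= 0) return(1e12)
    w11 <- (b2 + e2) / det
    w12 <- -b2 / det
    quad <- sum(w11 * (r1^2 + r2^2) + 2 * w12 * r1 * r2)
    m * log(det) + quad + log(2 * m * (w11 + w12))
  }
  g <- function(u, v) nll((v - u) / 2, u)
  u <- var(y1 - y2) / 2 + 1e-4   # rough starting scale only
  v <- 2 * var((y1 + y2) / 2) + 1e-4
  for (it in 1:50) {
    u_new <- optimize(function(uu) g(uu, v), c(1e-10, 10), tol = 1e-14)$minimum
    v_new <- optimize(function(vv) g(u_new, vv),
                      c(1e-10, 20), tol = 1e-14)$minimum
    done <- abs(u_new - u) < 1e-13 && abs(v_new - v) < 1e-13
    u <- u_new
    v <- v_new
    if (done) break
  }
  # Newton polish per coordinate (golden section stalls near sqrt(eps))
  polish <- function(f, x) {
    for (i in 1:6) {
      h <- 1e-6 * (1 + abs(x))
      d1 <- (f(x + h) - f(x - h)) / (2 * h)
      d2 <- (f(x + h) - 2 * f(x) + f(x - h)) / h^2
      if (!is.finite(d1) || !is.finite(d2) || d2 <= 0) break
      step <- d1 / d2
      if (x - step <= 0) break
      x <- x - step
      if (abs(step) < 1e-12) break
    }
    x
  }
  u <- polish(function(uu) g(uu, v), u)
  v <- polish(function(vv) g(u, vv), v)
  list(sigma_b2 = max(0, (v - u) / 2), sigma_e2 = u)
}
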