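#' Configuration for the synthetic fetal RR generator
#'
#' Defaults emulate a quiet fetal recording around 430 ms mean RR
#' (roughly 140 bpm, inside the 360-510 ms range typical of healthy
#' fetuses) with optional baseline drift, CTG-style accelerations,
#' sinusoidal LF/HF modulation, white beat-to-beat noise and detector
#' artifacts.
#'
#' @param duration_s recording length in seconds (must fit at least one
#'   64-s analysis window).
#' @param base_rr_ms baseline RR interval, ms.
#' @param drift_bpm_per_2min linear baseline drift rate, bpm per 120 s.
#' @param accel_rate_per_min expected qualifying accelerations per minute.
#' @param accel_amplitude_bpm peak acceleration excursion, bpm.
#' @param accel_duration_s plateau duration of each acceleration, seconds
#'   (trapezoid with 2.5 s ramps).
#' @param lf_freq_hz,lf_amp_ms low-frequency sinusoidal RR modulation
#'   (0.04 <= lf_freq_hz < 0.4), amplitude in ms.
#' @param hf_freq_hz,hf_amp_ms high-frequency modulation
#'   (0.4 <= hf_freq_hz <= 1.5), amplitude in ms.
#' @param noise_sd_ms white beat-to-beat noise SD, ms.
#' @param artifact_rate fraction of beats corrupted by detector artifacts,
#'   in [0, 0.2].
#' @param ga_weeks gestational age, decimal weeks.
#' @param seed integer RNG seed; identical config + seed gives identical
#'   output.
#' @param fixed_phase if `TRUE` the LF/HF sinusoid phases are 0 (exact
#'   regression tests); otherwise they are drawn uniformly per seed.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(duration_s = 300, base_rr_ms = 430,
                         drift_bpm_per_2min = 0,
                         accel_rate_per_min = 0, accel_amplitude_bpm = 20,
                         accel_duration_s = 20,
                         lf_freq_hz = 0.1, lf_amp_ms = 0,
                         hf_freq_hz = 0.8, hf_amp_ms = 0,
                         noise_sd_ms = 0, artifact_rate = 0,
                         ga_weeks = 30, seed = 1L, fixed_phase = FALSE) {
  cfg <- as.list(environment())
  if (duration_s <= 0) stop_fhrv("duration_s must be positive")
  if (base_rr_ms <= 0) stop_fhrv("base_rr_ms must be positive")
  if (!(lf_freq_hz >= 0.04 && lf_freq_hz < 0.4))
    stop_fhrv("lf_freq_hz must lie in [0.04, 0.4)")
  if (!(hf_freq_hz >= 0.4 && hf_freq_hz <= 1.5))
    stop_fhrv("hf_freq_hz must lie in [0.4, 1.5]")
  if (artifact_rate < 0 || artifact_rate > 0.2)
    stop_fhrv("artifact_rate must lie in [0, 0.2]")
  class(cfg) <- "synth_config"
  cfg
}

# trapezoidal bpm excursion: plateau `plateau_s` at `amp`, 2.5 s ramps
accel_pulse <- function(t, center_s, amp, plateau_s, ramp_s = 2.5) {
  u <- abs(t - center_s)
  ifelse(u <= plateau_s / 2, amp,
         ifelse(u <= plateau_s / 2 + ramp_s,
                amp * (1 - (u - plateau_s / 2) / ramp_s), 0))
}

#' Generate a synthetic fetal RR recording with ground truth
#'
#' Beats are emitted iteratively, `t[k+1] = t[k] + rr(t[k])/1000`, where the
#' instantaneous RR is the drifting baseline plus acceleration excursions
#' (specified in bpm, converted via rr = 60000/bpm) plus additive sinusoidal
#' LF/HF modulation in milliseconds plus white noise. Additive-in-ms
#' modulation makes the analytic band power of each sinusoid exactly
#' amplitude^2/2, which downstream spectral estimators are tested against.
#'
#' @param config a [synth_config()].
#' @return a list with `series` (an [rr_series()]) and `truth`, a list with
#'   `artifact_positions`, `artifact_events`, `true_band_power_lf_ms2`,
#'   `true_band_power_hf_ms2`, `true_pattern_label`, `accel_times_s`.
#' @export
generate_rr_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  c_ <- config
  if (c_$duration_s < 64)
    stop_fhrv("duration too short to contain one 64-s window")
  out <- with_seed(c_$seed, {
    phases <- if (c_$fixed_phase) c(0, 0) else runif(2, 0, 2 * pi)
    n_ev <- round(c_$accel_rate_per_min * c_$duration_s / 60)
    margin <- c_$accel_duration_s / 2 + 10
    ev_t <- if (n_ev > 0) {
      sort(runif(n_ev, margin, c_$duration_s - margin))
    } else numeric(0)
    base_bpm0 <- 60000 / c_$base_rr_ms
    n_guess <- ceiling(c_$duration_s * 1000 / c_$base_rr_ms * 1.5) + 16L
    rr <- numeric(n_guess)
    t <- 0
    k <- 0L
    repeat {
      bl_bpm <- base_bpm0 + c_$drift_bpm_per_2min * t / 120
      bl_rr <- if (c_$drift_bpm_per_2min == 0) c_$base_rr_ms else 60000 / bl_bpm
      ab <- if (length(ev_t)) {
        sum(accel_pulse(t, ev_t, c_$accel_amplitude_bpm, c_$accel_duration_s))
      } else 0
      acc_ms <- if (ab != 0) 60000 / (bl_bpm + ab) - bl_rr else 0
      r <- bl_rr + acc_ms +
        c_$lf_amp_ms * sin(2 * pi * c_$lf_freq_hz * t + phases[1L]) +
        c_$hf_amp_ms * sin(2 * pi * c_$hf_freq_hz * t + phases[2L]) +
        rnorm(1L, 0, c_$noise_sd_ms)
      if (r <= 0) stop_fhrv("generator produced a nonpositive RR; parameters too extreme")
      t_next <- t + r / 1000
      if (t_next > c_$duration_s) break
      k <- k + 1L
      if (k > length(rr)) rr <- c(rr, numeric(n_guess))
      rr[k] <- r
      t <- t_next
    }
    list(rr = rr[seq_len(k)], ev_t = ev_t)
  })
  series <- rr_series(out$rr, ga_weeks = c_$ga_weeks,
                      recording_id = sprintf("sim-%d", c_$seed))
  qualifying <- length(out$ev_t) > 0 &&
    c_$accel_amplitude_bpm >= 15 && c_$accel_duration_s >= 15
  truth <- list(
    artifact_positions = integer(0),
    artifact_events = data.frame(kind = character(0), position = integer(0)),
    true_band_power_lf_ms2 = c_$lf_amp_ms^2 / 2,
    true_band_power_hf_ms2 = c_$hf_amp_ms^2 / 2,
    true_pattern_label = if (!qualifying && abs(c_$drift_bpm_per_2min) < 10)
      "SHRP" else "not_SHRP",
    accel_times_s = out$ev_t
  )
  if (c_$artifact_rate > 0) {
    inj <- inject_artifacts(series, c_$artifact_rate,
                            kinds = c("missed", "ectopic", "spike"),
                            seed = c_$seed + 1L)
    series <- inj$series
    truth$artifact_positions <- inj$truth$artifact_positions
    truth$artifact_events <- inj$truth$artifact_events
  }
  list(series = series, truth = truth)
}

#' Inject detector-style artifacts into a clean RR series
#'
#' Three corruption kinds mirror what automatic fetal R-wave detection gets
#' wrong: `missed` merges two adjacent intervals into one (~2x RR),
#' `ectopic` splits one interval into a short/long pair preserving total
#' time, and `spike` perturbs a single interval by a uniform +/-(60-200) ms.
#' Missed and ectopic events preserve the cumulative recording time, so the
#' onset/RR consistency invariant still holds after injection.
#'
#' @param series a clean [rr_series()].
#' @param rate fraction of beats corrupted, in [0, 0.2]; the number of
#'   events is `floor(rate * n_intervals)`.
#' @param kinds subset of `c("missed", "ectopic", "spike")`.
#' @param seed integer RNG seed.
#' @return list with `series` (corrupted) and `truth`: `artifact_positions`
#'   (indices of every modified interval in the output series; an ectopic
#'   split contributes two) and `artifact_events` (one row per event with
#'   its kind and output position).
#' @export
inject_artifacts <- function(series, rate, kinds = c("missed", "ectopic", "spike"),
                             seed = 1L) {
  if (rate < 0 || rate > 0.2) stop_fhrv("artifact rate must lie in [0, 0.2]")
  kinds <- match.arg(kinds, several.ok = TRUE)
  n <- nrow(series)
  n_ev <- floor(rate * n)
  empty <- list(artifact_positions = integer(0),
                artifact_events = data.frame(kind = character(0),
                                             position = integer(0)))
  if (n_ev == 0L) return(list(series = series, truth = empty))
  if (n < 3L * n_ev + 4L) stop_fhrv("series too short for requested artifact rate")
  res <- with_seed(seed, {
    # sample positions with pairwise gap >= 3 so events never interact
    pos <- sort(sample(seq(3L, n - 2L - 2L * (n_ev - 1L)), n_ev)) +
      2L * (seq_len(n_ev) - 1L)
    kind <- sample(kinds, n_ev, replace = TRUE)
    rr <- series$rr_ms
    for (idx in rev(seq_len(n_ev))) {
      i <- pos[idx]
      if (kind[idx] == "spike") {
        rr[i] <- rr[i] + sample(c(-1, 1), 1L) * runif(1L, 60, 200)
        if (rr[i] <= 0) rr[i] <- abs(rr[i]) + 60
      } else if (kind[idx] == "missed") {
        rr[i] <- rr[i] + rr[i + 1L]
        rr <- rr[-(i + 1L)]
      } else { # ectopic: short/long split preserving the interval sum
        s <- rr[i]
        short <- s * runif(1L, 0.30, 0.45)
        rr <- append(rr[-i], c(short, s - short), after = i - 1L)
      }
    }
    list(rr = rr, pos = pos, kind = kind)
  })
  shift <- vapply(seq_len(n_ev), function(idx) {
    before <- res$pos < res$pos[idx]
    sum(res$kind == "ectopic" & before) - sum(res$kind == "missed" & before)
  }, integer(1))
  out_pos <- res$pos + shift
  positions <- sort(unlist(Map(function(p, k) {
    if (k == "ectopic") c(p, p + 1L) else p
  }, out_pos, res$kind)))
  t0 <- series$time_s[1L] - series$rr_ms[1L] / 1000
  corrupted <- rr_series(res$rr, onset_time_s = t0 + cumsum(res$rr) / 1000,
                         ga_weeks = attr(series, "ga_weeks"),
                         recording_id = attr(series, "recording_id"))
  list(series = corrupted,
       truth = list(artifact_positions = as.integer(positions),
                    artifact_events = data.frame(kind = res$kind,
                                                 position = as.integer(out_pos))))
}

#' Configuration for paired log-normal reliability simulations
#'
#' @param n_subjects number of fetuses.
#' @param mu_log grand mean on the natural-log scale.
#' @param sigma_b between-subject SD on the log scale.
#' @param sigma_e within-subject SD on the log scale.
#' @param n_replicates measurements per subject (>= 2).
#' @param seed integer RNG seed.
#' @return a list of class `rel_sim_config`.
#' @export
rel_sim_config <- function(n_subjects = 48L, mu_log = 2, sigma_b = 0.5,
                           sigma_e = 0.2, n_replicates = 2L, seed = 1L) {
  if (sigma_b < 0 || sigma_e < 0) stop_fhrv("sigma_b and sigma_e must be >= 0")
  if (n_replicates < 2L) stop_fhrv("n_replicates must be >= 2")
  structure(as.list(environment()), class = "rel_sim_config")
}

#' Generate paired log-normal measurements with known variance components
#'
#' `ln(value_ij) = mu_log + b_i + e_ij`, `b_i ~ N(0, sigma_b^2)`,
#' `e_ij ~ N(0, sigma_e^2)`. All values are positive by construction.
#'
#' @param config a [rel_sim_config()].
#' @return data.frame with columns `subject`, `replicate`, `value`.
#' @export
generate_paired_measurements <- function(config) {
  stopifnot(inherits(config, "rel_sim_config"))
  c_ <- config
  with_seed(c_$seed, {
    b <- rnorm(c_$n_subjects, 0, c_$sigma_b)
    e <- matrix(rnorm(c_$n_subjects * c_$n_replicates, 0, c_$sigma_e),
                nrow = c_$n_subjects)
    data.frame(
      subject = rep(seq_len(c_$n_subjects), each = c_$n_replicates),
      replicate = rep(seq_len(c_$n_replicates), times = c_$n_subjects),
      value = exp(c_$mu_log + rep(b, each = c_$n_replicates) + as.vector(t(e)))
    )
  })
}

#' Generate a bpm trace with a known intended heart rate pattern
#'
#' Four trace kinds exercise the classifier's decision boundaries:
#' `flat` (SHRP-qualifying), `drifting` (baseline drift disqualifies SHRP),
#' `accelerating` (one qualifying acceleration centered mid-trace
#' disqualifies SHRP), and `oscillating` (sinusoidal bandwidth straddling
#' the +/-5 bpm pattern cut-off: amplitude < 5 bpm is intended pattern I,
#' > 5 bpm intended pattern II).
#'
#' @param kind one of `"flat"`, `"drifting"`, `"accelerating"`,
#'   `"oscillating"`.
#' @param duration_s trace length, seconds.
#' @param base_bpm resting fetal heart rate, bpm.
#' @param noise_sd_bpm white sample noise SD, bpm.
#' @param ga_weeks gestational age, decimal weeks.
#' @param drift_bpm_per_2min drift rate for `"drifting"`.
#' @param accel_amplitude_bpm,accel_duration_s acceleration shape for
#'   `"accelerating"` (trapezoid plateau, 2.5 s ramps).
#' @param osc_amp_bpm,osc_freq_hz oscillation for `"oscillating"`.
#' @param fs sampling rate of the trace grid, Hz.
#' @param seed integer RNG seed.
#' @return list with `trace` (a `bpm_trace` without baseline; run
#'   [estimate_baseline()]), `intended` (one of `"SHRP"`, `"not_SHRP"`,
#'   `"HRP_I"`, `"HRP_II"`) and `ga_weeks`.
#' @export
generate_pattern_trace <- function(kind = c("flat", "drifting", "accelerating",
                                            "oscillating"),
                                   duration_s = 240, base_bpm = 140,
                                   noise_sd_bpm = 0.5, ga_weeks = 28,
                                   drift_bpm_per_2min = 15,
                                   accel_amplitude_bpm = 20, accel_duration_s = 20,
                                   osc_amp_bpm = 8, osc_freq_hz = 0.1,
                                   fs = 4, seed = 1L) {
  kind <- match.arg(kind)
  tt <- seq(0, duration_s, by = 1 / fs)
  bpm <- with_seed(seed, {
    x <- base_bpm + rnorm(length(tt), 0, noise_sd_bpm)
    switch(kind,
      flat = x,
      drifting = x + drift_bpm_per_2min * tt / 120,
      accelerating = x + accel_pulse(tt, duration_s / 2, accel_amplitude_bpm,
                                     accel_duration_s),
      oscillating = x + osc_amp_bpm * sin(2 * pi * osc_freq_hz * tt +
                                            runif(1, 0, 2 * pi)))
  })
  intended <- switch(kind,
    flat = "SHRP",
    drifting = "not_SHRP",
    accelerating = "not_SHRP",
    oscillating = if (osc_amp_bpm > 5) "HRP_II" else "HRP_I")
  trace <- data.frame(time_s = tt, bpm = bpm, baseline_bpm = NA_real_)
  class(trace) <- c("bpm_trace", "data.frame")
  list(trace = trace, intended = intended, ga_weeks = ga_weeks)
}

#' Write generator ground truth as a JSON sidecar
#' @param truth ground-truth list from [generate_rr_recording()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
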