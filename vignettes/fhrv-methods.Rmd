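---
title: "Methods: fetal heart rate variability reliability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fetal heart rate variability reliability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhrv)
```

## The problem

Fetal heart rate variability (FHRV) — the beat-to-beat variation of fetal
RR intervals obtained from non-invasive fetal ECG — is a candidate marker
of fetal autonomic function. Before FHRV parameters can be used for
surveillance, their test–retest reliability must be established: how much
do two short time series from the same recording of the same fetus
disagree purely by chance? This package implements the full measurement
chain from a per-beat RR series to reliability statistics, together with a
synthetic generator that provides ground truth for every stage.

The parameters are the standard nine: mean RR (ms), SDNN (ms), RMSSD (ms),
and LF power, HF power and LF/HF ratio under both an FFT periodogram and a
Burg autoregressive estimator, with fetal bands LF 0.04–0.4 Hz and HF
0.4–1.5 Hz (the fetal HF band sits higher than the adult one because fetal
breathing movements are faster).

## Preprocessing

**Artifact handling.** Automatic fetal R-wave detection produces missed
beats (a merged ~2x interval), ectopic-like splits (a short/long pair) and
spurious detections. `detect_artifacts()` is a forward single pass flagging
any interval deviating more than 40 ms (escalable to 100 ms per recording
when true beat-to-beat changes are large) from the *most recent accepted*
interval. Using the last accepted value rather than the raw predecessor is
deliberate: after a single spike, the next normal interval is compared
against the pre-spike reference and is not dragged into a cascade of
flags. `correct_artifacts()` replaces flagged values with a natural cubic
spline fitted to the accepted intervals as a function of beat onset time —
time, not beat index, so the interpolant stays well-behaved when a run of
beats is removed. Onset times are rebuilt from the corrected intervals, so
the invariant `time_s[k+1] - time_s[k] = rr_ms[k+1]/1000` always holds.
Boundary runs that would need extrapolation fall back to the nearest
accepted value with a warning.

**Quality gate.** A segment is usable when strictly less than 5% of its
intervals were corrected and no run of 5 or more consecutive corrections
occurs. Both inequalities are strict: 5 corrected out of 100, or exactly 5
in a row, fails.

**Detrending.** Slow trends (baseline drift) would otherwise dominate SDNN
and leak into the LF band. The smoothness-priors operator removes the
regularized trend `(I + lambda^2 D2'D2)^{-1} z` with `lambda = 500`. We
solve the full sparse symmetric positive-definite system exactly (Matrix
package), so boundary samples need no approximation. The filter's
time-invariant interior behaviour is characterized numerically by
`cutoff_frequency()`: the operator is built on a long grid, its interior
row taken as an impulse response, and the half-power point of its
frequency response located by root finding. At 4 Hz sampling,
`lambda = 500` gives a cutoff of about 0.035 Hz; the same lambda applied
to the beat-domain series (mean fetal RR ~ 430 ms, i.e. an effective
rate near 2.3 Hz) implies a proportionally lower effective cutoff — this
is documented behaviour, not hidden: the cutoff scales exactly linearly
with the sampling rate.

Time-domain parameters (SDNN/RMSSD) are computed on the detrended
beat-domain series by default (`detrend_time_domain = FALSE` gives raw
values); mean RR always comes from the un-detrended corrected series.
Spectral parameters are computed on the 4 Hz resampled tachogram
(natural cubic spline of RR versus onset time on an exact 0.25 s grid)
after detrending. Resampling is applied only on the spectral path.

## Pattern classification

RR intervals are converted to bpm and assessed CTG-style. Windows receive
non-exclusive labels:

* **SHRP** (stationary heart rate pattern): no qualifying excursion
  (±15 bpm from baseline sustained ≥ 15 s) overlapping the window, and
  baseline drift below 10 bpm over a 120-s span centered on the window.
* **Pattern I** (GA 24+1 to 32+0 weeks): mean rate < 160 bpm, drift
  < 10 bpm per 3 min, oscillation bandwidth < ±5 bpm, accelerations at
  most isolated (≤ 1 per surrounding 10 min, none overlapping the window).
* **Pattern II** (GA 24+1 to 41+6): bandwidth > ±5 bpm, rate < 160 bpm
  outside qualifying accelerations.
* **Pattern III** (GA above 32+0 up to 41+6): bandwidth > ±10 bpm with
  frequent (≥ 2 per 10 min) long-lasting (≥ 30 s) accelerations.

Design choices where the clinical definitions are qualitative:

* **Baseline.** No standard algorithm exists; we use a two-pass robust
  estimate — a 60-s running median (shrinking at the edges), exclusion of
  samples deviating ≥ 15 bpm from it (candidate accelerations/
  decelerations), a second median pass on the remainder, then a 15-s
  moving average. On a flat trace the baseline is exact; one qualifying
  acceleration moves the interior baseline by well under 2 bpm.
* **Drift** is measured on the estimated baseline (max − min over the
  evaluation span), not on raw bpm, and the span is centered on the
  candidate window and clipped at recording edges.
* **Bandwidth** is half the 2.5th–97.5th percentile span of
  `bpm - baseline` (excursion samples excluded) rather than min/max, to
  resist single-sample noise. A ±a bpm sinusoid measures ≈ 0.997 a.
* **Isolated vs frequent** accelerations are quantified as ≤ 1 vs ≥ 2
  qualifying events per surrounding 10 minutes; both constants are
  configurable in `classification_criteria()`.

The stationarity score of a window is minus its 120-s baseline drift, so
larger is more stationary.

## Segment selection

Candidate windows of 64 s and 120 s are enumerated at a 1-s step (the
step is a desk-scale choice; finer steps change candidates only
marginally). Per class, two non-overlapping qualifying windows are
selected: chronologically first and last for patterns I–III (minimizing
information bias), or the two with the highest stationarity score for
SHRP, ties resolved chronologically and the final pair ordered in time.
Selection sees no HRV values, so blinding to the outcome holds by
construction. A recording contributes to a class/length cell only when two
non-overlapping qualifying windows exist; otherwise it is excluded with a
logged reason.

## Spectral estimators

* **FFT path**: one Hann-tapered periodogram of the whole segment (a
  single window, zero overlap — on a 64/120-s segment there is no room
  for meaningful averaging anyway), zero-padded to ≥ 4x length rounded to
  a power of two. The normalization divides by the window energy, so the
  integrated one-sided PSD equals the taper-compensated sample variance
  and a sinusoid of amplitude a integrates to a^2/2 exactly.
* **AR path**: Burg coefficients at fixed order 24 (`stats::ar.burg`),
  PSD `sigma^2 / (fs |A|^2)` rescaled so its integral equals the sample
  variance. Strong sinusoidal components drive poles extremely close to
  the unit circle, producing near-delta peaks that a uniform frequency
  grid integrates arbitrarily badly; the grid is therefore refined
  logarithmically around every sharp pole (down to a thousandth of the
  peak width), after which band powers from the two estimators agree
  within a few percent on smooth inputs.
* **Band powers** integrate the PSD by trapezoid with the band edges
  interpolated, so adjacent bands tile the axis exactly (LF + HF +
  residual = total). The band lower edge is inclusive, the upper edge
  exclusive; 0.4 Hz belongs to HF. The LF/HF ratio is reported missing
  when HF integrates to zero.

## Reliability model

All parameters are analyzed on the natural-log scale, where the paired
values are homoscedastic and approximately normal. The model is a
balanced random-intercept model, `y_ij = mu + b_i + e_ij` with
`b_i ~ N(0, sigma_B^2)` and `e_ij ~ N(0, sigma_E^2)`. With two replicates
per subject the REML estimates have closed forms: `sigma_E^2 =
sum(d_i^2)/(2m)` from the within-pair differences, and `sigma_B^2 =
max(0, var(pair means) - sigma_E^2/2)`. The test suite verifies this
against an independent iterative REML optimizer to 1e-8 on hundreds of
random datasets. At the zero boundary the between component is truncated
and the within component kept at its unconstrained value — a conservative
convention (the within variance, hence the CV, is never understated).

Derived statistics:

* **Within-subject CV** `sqrt(exp(sigma_E^2) - 1)`, the exact log-normal
  form; at the magnitudes seen here it differs from the approximation
  `sigma_E` by under 1%. Its CI uses chi-square limits on `sigma_E^2`
  with m degrees of freedom (one difference per pair).
* **ICC** `sigma_B^2 / (sigma_B^2 + sigma_E^2)`, in [0, 1] by
  construction.
* **Limits of agreement**: the mean log difference (systematic
  first-vs-second bias) ± 1.96·sqrt(2)·sigma_E, back-transformed to a
  ratio scale. Using the model within-SD rather than the empirical SD of
  differences makes the LoA exactly consistent with the CV
  (`log(upper/lower)/2 = 1.96 sqrt(2) sigma_E` to machine precision);
  with no bias the two definitions differ only at order `mean(d)^2`.
* **Averaging of n**: replacing one time series by the mean of n divides
  the within variance by n, giving `cv_n`, `icc_n` and the ratio-scale
  95% prediction interval `exp(±1.96 sigma_E / sqrt(n))` analytically —
  an extrapolation under the equal-variance assumption, not a refit.

Acceptability is flagged at CV ≤ 0.15 and ICC ≥ 0.80. Groups with fewer
than 3 complete pairs are reported as insufficient. Values above 10x the
group median are retained by default (they are treated as true
physiological outliers); `exclude_outliers = TRUE` reruns the group
without such pairs as a sensitivity analysis. Gestational-age
stratification uses groups A 20+0–27+6, B 28+0–34+6 and C 35+0–41+0
weeks.

## The synthetic generator

`generate_rr_recording()` emits beats iteratively,
`t[k+1] = t[k] + rr(t[k])/1000`, with the instantaneous RR equal to a
(possibly drifting) baseline plus acceleration excursions plus additive
sinusoidal LF/HF modulation plus white noise. Two conventions matter:

* LF/HF modulation is additive **in milliseconds**, so the analytic band
  power of each sinusoid is exactly `amplitude^2/2` — the spectral stages
  are tested against these values. Accelerations are specified in bpm
  (the CTG convention) and converted via `rr = 60000/bpm`.
* The "RR at emission time" rule is used rather than an integral
  pulse-frequency-modulation model; at fetal rates (~2.3 beats/s) it
  recovers band power well, and IPFM is out of scope.

Artifacts (`inject_artifacts()`) merge, split or perturb intervals;
missed/ectopic events preserve cumulative time so the onset/RR invariant
survives corruption, and the ground truth lists every modified interval.
`generate_paired_measurements()` draws paired log-normal values with known
variance components for testing the reliability layer, and
`generate_pattern_trace()` produces bpm traces whose intended pattern
label is known by construction (flat, drifting, accelerating, or
oscillating with bandwidth straddling the ±5 bpm cut-off).

Defaults emulate a healthy fetal recording: baseline RR near 430 ms
(Table-style healthy range 360–510 ms), accelerations of +20 bpm lasting
20 s, modulation at 0.1 Hz (LF) and 0.8 Hz (HF), and artifact rates up to
a few percent. What the generator does **not** emulate: coloured
(1/f-like) variability, fetal movement and breathing epochs, maternal
interference, and gestational-age-dependent changes in variability
magnitude. Passing tests therefore demonstrate the correctness of the
measurement chain and the statistics, not clinical performance on real
NI-FECG data.

## Numerical choices and problem sizes

* Sparse Cholesky solves for detrending; natural cubic splines
  (`stats::splinefun`) for all interpolation; `stats::ar.burg` for AR
  fits; exact trapezoid band integration with edge interpolation.
* Tests run the classifier-fidelity study at 200 traces of 240 s per
  trace kind, the variance-recovery study at 200 cohorts of 48 fetuses
  plus one cohort of 1000, and the oracle-equivalence study at 1000
  random series and 500 random balanced datasets; the end-to-end pipeline
  demonstration uses cohorts of 3–8 recordings of 400–600 s at a 2–4 s
  window step. These sizes keep the whole suite under a couple of minutes
  on a laptop while leaving the Monte Carlo error well inside the asserted
  tolerances.
* Seeds: every stochastic component takes an explicit integer seed;
  identical config + seed reproduces output bit for bit.

## Known limitations

* The balanced two-replicate closed form does not cover unbalanced
  designs or more than two replicates per subject (the averaging-of-n
  block is analytic extrapolation, exactly as intended).
* Pattern II/III definitions quantify qualitative clinical language;
  the constants are configurable and documented, but other
  operationalizations are defensible.
* Day-to-day (between-recording) reliability and fetal movement
  detection are out of scope.
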