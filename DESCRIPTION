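Package: fhrv
Title: Reliability of Fetal Heart Rate Variability from RR-Interval Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the test-retest reliability of fetal heart
    rate variability (FHRV) measured from beat-to-beat RR-interval series.
    Implements artifact detection and cubic-spline replacement, quality
    gating, smoothness-priors detrending, 4 Hz tachogram resampling,
    CTG-style heart rate pattern classification (including a stationary
    heart rate pattern class), first/last and highest-stationarity segment
    selection, time-domain (mean RR, SDNN, RMSSD) and spectral-domain
    (FFT periodogram and Burg autoregressive LF/HF band power) parameters,
    and log-scale random-intercept variance-components reliability
    statistics: within-subject coefficient of variation, intraclass
    correlation, Bland-Altman limits of agreement on a ratio scale, and
    extrapolation to the average of n repeated time series. A seeded
    synthetic fetal RR generator with analytic ground truth supports
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
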