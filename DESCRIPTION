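Package: uwbresp
Title: Respiration Monitoring with Ultra-Wideband Impulse Radar
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Noncontact detection of human respiration from ultra-wideband
    (UWB) impulse radar recordings. Provides a synthetic frame simulator
    (pulse train reflected from a sinusoidally moving thorax, static and
    drifting clutter, linear trend, additive white Gaussian noise) with a
    Bessel-harmonic analytic oracle for its slow-time spectrum; static
    clutter removal by grand-mean subtraction and linear trend subtraction;
    signal-to-noise improvement by a fifth-order Butterworth band-pass
    cascade and fast-time block smoothing; subject localization in fast
    time with the kurtosis-to-standard-deviation (KSD) statistic and a
    Morlet wavelet scalogram; and respiration-frequency estimation from a
    region of interest by multilevel wavelet detail-band denoising and
    accumulation of overlapping fixed-window FFT magnitude spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
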