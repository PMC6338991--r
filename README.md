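# uwbresp

Noncontact respiration monitoring with ultra-wideband (UWB) impulse radar.

A UWB impulse radar records an M x N matrix of received amplitudes: fast
time (rows) maps to range, slow time (columns) observes each range bin over
successive pulses. Breathing displaces the thorax by `Ar` = 0.5-1.5 cm at
`fr` = 0.2-0.4 Hz, modulating the two-way delay of the subject's echo by
`2*Ar/v` — tens of picoseconds, buried under clutter and noise. `uwbresp`
implements a complete detection chain for this setting, plus a simulator so
the chain can be exercised and validated without hardware:

* **Simulator** — pulse train delayed by
  `tau(n) = 2*d0/v + (2*Ar/v) sin(2*pi*fr*n/fs)` via frequency-domain
  fractional delay, plus static reflectors, linear trend, drifting and
  diffuse clutter, and AWGN (`generate_frame()`), with a Bessel-harmonic
  quadrature oracle for its line spectrum
  (`bessel_harmonic_amplitudes()`): the k-th respiration harmonic at the
  echo centre has amplitude `C_k = Integral U(nu) J_k(2*pi*taur*nu) dnu`.
* **Clutter suppression** — grand-mean subtraction and linear trend
  subtraction (per-bin least-squares projection on `[n, 1]`).
* **SNR improvement** — fifth-order Butterworth low-pass (0.1037) +
  high-pass (0.0222) cascade along fast time, then 7-sample block averaging.
* **Localization** — per-bin KSD statistic, `(K - 3)/SD` of the slow-time
  samples (kurtosis K = 3 for noise, 1.5 for sinusoidal modulation), and
  the Morlet scalogram (`exp(-t^2/2) cos(5t)`) of the KSD profile; the
  scalogram argmax gives the delay/range, a peak-to-median ratio the
  presence decision.
* **Frequency estimation** — 21 slow-time signals around the subject,
  denoised by keeping detail level 6 of an 8-level Daubechies wavelet
  decomposition (0.23-0.45 Hz at the default fs), cut into 512-sample
  windows with 256 overlap, and all FFT magnitude spectra summed; the peak
  of the accumulated spectrum is `fr_hat`, with a spectral SNR per
  `20*log10(|H[peak]| / sum(|H[others]|))`.

See the methods vignette (`vignettes/uwb-respiration-pipeline.Rmd`) for the
model, parameter conventions, and known accuracy limits.

## Worked example

```r
library(uwbresp)

# a breathing subject 9 m away, 1 cm amplitude at 0.3 Hz, -10 dB noise
sc  <- scenario_subject(d0 = 9, fr = 0.3, Ar = 0.01, snr_db = -10, seed = 1)
rep <- run_pipeline(sc$frame)
rep
#> UWB respiration pipeline report
#> TOA estimate: block 290, tau = 59.49 ns, range = 8.917 m; present = TRUE (peak/median = 9.63)
#> Respiration frequency estimate: 0.2841 Hz (bin 6, resolution 0.0568 Hz)
#>   accumulated over 21 signal(s) x 3 window(s) of 512 samples (overlap 256); SNR = -11.29 dB
```

The subject is detected (scalogram peak 9.6x the median, threshold 7) at
8.92 m — an 8 cm error, i.e. about one smoothed range block after the
filter's group delay is corrected. The frequency estimate is the accumulated
spectrum's peak bin, 0.2841 Hz; the true 0.3 Hz lies within one 0.0568 Hz
bin. The reported spectral SNR of -11.3 dB says the peak magnitude is ~4x
smaller than the summed magnitudes of all other bins, typical for these
noise levels.

The same stages are scriptable from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "uwbresp.R", package = "uwbresp"))')
Rscript $CLI simulate --config scenario.yaml --seed 7 --out frame.rds
Rscript $CLI pipeline --in frame.rds --out report.json
```

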