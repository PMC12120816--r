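---
title: "hipposlice: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hipposlice: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipposlice)
```

# Scope

`hipposlice` quantifies four families of hippocampal-slice measurements:

1. **Spontaneous sharp-wave ripples (SWR)** in CA1 field potentials:
   event detection, sharp-wave area, ripple count/amplitude/frequency.
2. **Carbachol-induced gamma oscillations**: power-spectral metrics over
   20–60 Hz, slice exclusion rules, and an autocorrelation rhythmicity
   index.
3. **Evoked fEPSPs**: initial slope, input–output curves, half-maximal
   stimulation intensity, paired-pulse ratios, and HFS-LTP normalization.
4. **Synapse morphometry**: rule-based spine classification and density,
   polygonal-ROI fluorescence intensity, and two-channel puncta
   colocalization.

Every analysis has a matching synthetic generator with recorded ground
truth, so each stage is verifiable without raw recordings, plus an
end-to-end two-group pipeline with a normality-gated comparison.

# Signal model and filtering

Recordings are uniformly sampled single-channel traces in mV (the
reference acquisition regime is 2-min artifact-free stretches digitized at
10 kHz). All filters realize the magnitude response of a 4th-order
Butterworth applied forward–backward. Because no IIR filtering
infrastructure is assumed, the response is applied in the frequency domain
— which is *exactly* zero-phase — with ~1 s reflect padding against edge
transients. Consequences worth knowing:

* In-band gain errors match `filtfilt` conventions: −6 dB at the band
  edges, e.g. a 10 Hz unit sinusoid passes a 45 Hz lowpass within 1%, and
  a 200 Hz sinusoid leaves <1% residual.
* Gain at 0.8× the cutoff is ≈0.86, an inherent property of this filter
  order; tighter passband flatness would require an unusually high order
  and is not what the SWR literature uses.

The spectral estimator is an averaged modified periodogram (Hann window,
50% overlap, boundary-crossing windows dropped) with window length
`round(fs / 0.8192)` so the grid reproduces the 0.8192 Hz resolution of
the original acquisition software (12 207 samples at 10 kHz). Per-bin
power is scaled so the spectrum sums to the mean squared amplitude
(Parseval within 10% on stationary inputs); integrated 20–60 Hz power is
therefore a plain sum of in-band bins, in mV².

# Sharp-wave ripple detection

Default parameters (all configurable via `swr_params()`):

| parameter | default | meaning |
|---|---|---|
| `sw_lowpass_hz` | 45 | sharp-wave lowpass cutoff |
| `sw_threshold_sd` | 2.5 | detection threshold, SD units of the filtered trace |
| `min_interval_ms` | 80 | minimum interval between events |
| `sw_window_ms` | 125 | analysis window centred on the SW maximum |
| `ripple_band_hz` | 120–300 | ripple bandpass |
| `ripple_threshold_sd` | 3 | ripple threshold, SD of band-passed trace |
| `ripple_window_ms` | 25 | ripple analysis window |
| `polarity` | absolute | deflection sign convention |

Choices where the procedure was genuinely open:

* **SD baseline**: the SD is computed over the *entire* filtered trace,
  not a pre-event baseline; events are sparse, so the inflation is small.
* **Polarity**: deflection sign in stratum pyramidale is not fixed here;
  the default detects deviations of either sign from the mean, with
  explicit `positive`/`negative` options.
* **80 ms rule conflicts** keep the larger-amplitude peak.
* **SW area** is the trapezoidal integral of (signal − window mean)
  between the last mean-crossing before and the first after the peak, in
  mV·ms; windows without a crossing integrate to the edge and are flagged.
* **Ripple amplitude** per ripple is the mean of its rising
  (peak − preceding trough) and falling (peak − following trough)
  components; missing troughs fall back to the window-edge minimum and
  flag the event. **Ripple frequency** is the mean reciprocal inter-peak
  interval over consecutive ripples (absent with fewer than two ripples);
  peak positions are refined by parabolic interpolation before the
  intervals are taken.

# The synthetic LFP world

`simulate_lfp()` implants difference-of-Gaussians sharp waves (FWHM
40 ms, unit-normalized, amplitude 0.3 mV by default) carrying a ripple
burst confined to ±12.5 ms around the peak, on pink (default) or white
noise of SD 0.05 mV. Event times are homogeneous Poisson arrivals thinned
to an 80 ms dead time and kept 100 ms clear of the trace edges, so ground
truth always respects the detector's refractory and full-window contracts.

Two generator choices deserve emphasis:

* **Ripple envelope.** The burst uses a flat-top envelope (flat over
  ±10 ms, cosine-tapered to ±12.5 ms) and a cosine carrier phase-locked to
  the SW peak. A smoothly waxing–waning envelope is more biological, but
  amplitude modulation drags band-passed local maxima toward the burst
  centre and biases the inter-peak-interval frequency estimate by about
  +5 Hz at 200 Hz; with the flat top the residual bias is ≈+2.7 Hz, which
  is inherent to measuring a finite enveloped burst by peak intervals.
  Recovered frequencies are expected slightly *above* the implanted
  carrier for any enveloped burst.
* **Noise model and what a green benchmark means.** The detection
  benchmark (recall/precision ≥ 0.95 at amplitude 6× noise SD) is run on
  white noise. With 1/f noise, a threshold defined *relative to the SD of
  the same trace* is crossed by slow noise excursions at a rate that no
  event amplitude can fix — the threshold scales along with the noise.
  Real recordings sit between these worlds (their low-frequency power is
  real but not Gaussian); a green benchmark certifies the detector logic,
  not performance on arbitrarily 1/f-dominated data.

# Gamma metrics

`gamma_metrics()` restricts the peak search to 20–60 Hz by default
(pass `peak_band` to widen it); the exclusion rule
(`apply_exclusion()`) discards slices with integrated 20–60 Hz power
below 1e-5 mV² or peak frequency below 20 Hz, is strict at the boundary,
idempotent, and never un-excludes.

The rhythmicity statistic `autocorr_second_peak()` low-passes at 100 Hz,
autocorrelates (lag 0 ≡ 1), and returns the value at the *second positive
peak*. Counting conventions differ between labs, so both are implemented:
the default counts the lag-0 maximum as the first positive peak, making
the returned value the one-period peak (the usual rhythmicity index); the
alternative (`"one_period_first"`) returns the two-period peak. Peaks
must exceed `min_r = 0.2`: band-limiting gives even pure noise a
deterministic sidelobe structure of ~0.1 in its correlogram, so a
sqrt(N)-type bound would be wrong by an order of magnitude. Note one
degenerate case: a mathematically noiseless out-of-band tone survives
normalization (the ACF is scale-invariant), so the "out-of-band tones
leave no peak" behaviour holds in the presence of any realistic noise
floor, and is tested that way.

# fEPSP analysis

* **Slope**: magnitude of a straight-line fit over the 20–80% span of the
  initial rising phase of the dominant deflection, after a 1 ms
  post-stimulus blanking window; reported positive, in mV/ms. Cursor
  placement (peak, onset, fraction band) happens on a 5-sample smoothed
  copy while the fit uses raw samples — placing cursors on the noisy trace
  correlates sample selection with the noise and biases LTP ratios by
  several percent.
* **Half-max intensity**: the smallest tested intensity whose mean slope
  is closest to half the maximal mean slope; ties and flat curves resolve
  to the lower intensity (flat curves are flagged degenerate).
* **Paired pulses** (ISIs 10, 20, 50, 100, 200 ms): the second response is
  measured after subtracting a mono-exponential extrapolation of the first
  response's decay, fitted between the first peak and the second stimulus;
  the correction is skipped when the residual tail is negligible.
* **LTP**: slopes are normalized to the mean over a 10 min pre-HFS
  baseline (×100) with HFS at time 0; the experiment endpoint is the mean
  ± SEM over the final 10 min.

The sweep generator uses a raised-cosine rising phase (2 ms) and
mono-exponential decay (8 ms). This is deliberate: the 20–80% chord of a
raised cosine is 93% of its maximal slope, so the fitted slope tracks the
max-dV/dt ground truth within the stated 10%, and the exponential decay
makes the paired-pulse tail correction exact by construction. A pure
alpha-function rise would violate the 10% agreement for any straight-line
fit. Test pulses run at 3/min (one per 20 s), the standard low-frequency
monitoring rate.

# Morphometry

The six spine classes are defined by overlapping inequalities, so a fixed
precedence (first match wins) is applied and test-pinned:

`heads ≥ 2 → branched`; `length > 2 µm → filopodia`;
`width > 0.6 µm → mushroom`; `length/width < 1 → stubby`;
`length < 1 µm → thin`; otherwise `long_thin`.

Without the precedence, e.g. length 0.8 / width 0.7 µm satisfies both the
"thin" and "mushroom" inequalities. The generator samples strictly inside
each class region with margins wider than its jitter, so round-trip
accuracy is exactly 100% by construction — this validates the classifier's
regions, not biological separability. Thorny excrescences are a manual
pass-through label; no geometric rule exists for them here.

Densities are normalized to 50 µm of dendrite; hierarchical aggregation
takes unweighted means segment→neuron→animal (neurons with two vs three
segments count equally), with the per-animal mean as the analysis unit.

ROI intensity is the pixel-sum inside a polygon (even-odd rule on pixel
centres) divided by the ROI area in µm². Puncta detection is a global
threshold, 8-connected labeling and an area band; colocalization is
greedy nearest-neighbour matching within 0.5 µm (configurable — the
original interactive tool's settings are unrecoverable), each punctum
used once, normalized to 50 µm. TIFF I/O is intentionally out of scope in
this build (no TIFF reader in the dependency set); images travel as
in-memory matrices or headerless CSV.

# Statistics and the pipeline

`compare_groups()` Shapiro–Wilk-tests both samples at α = 0.05; if both
pass, a two-sided Student's t-test (equal variances) is used, otherwise a
Mann–Whitney U test. Everything is reported (n, means, SEMs, gate
p-values, chosen test, statistic, p). ROUT outlier removal is *not*
implemented — it is named but not defined in the source methods; a plain
\>3 MAD flagger (`mad_outlier_flags()`, off by default) is provided and
clearly labeled as not ROUT.

`run_pipeline()` simulates two slice cohorts, runs the full SWR/gamma/
spine chain, and compares three endpoints: SWR incidence, integrated
20–60 Hz power, and spine density per 50 µm. Integrated power is used
rather than peak frequency because peak frequency is quantized to the
0.8192 Hz grid and becomes constant across high-SNR slices, which
degenerates rank tests; per-slice spine counts get Poisson sampling
variation for the same reason. Pipeline slices are simulated on white
noise — the calibration world in which detected incidence tracks the
implanted rate (recall/precision ≈ 1) — so implanted rate differences
surface on the incidence endpoint instead of being washed out by
threshold crossings of 1/f noise. The type-I acceptance check runs 200
seeded cohorts at a reduced scale (20 s at 2 kHz, 6 slices/group) purely
for runtime; all analysis thresholds keep their standard values.

# Numerical notes and limitations

* Determinism: every generator expands one integer seed into fixed
  per-component substreams; identical configuration and seed give
  identical output, and adding one generator does not perturb another.
* The ripple-frequency estimator inherits a small positive bias from
  finite enveloped bursts (see above); it stays within ±4 Hz at 200 Hz.
* Recovered LTP plateaus carry a residual noise-induced bias below ~4% at
  noise SD 5% of the response amplitude.
* The generators are stated statistical worlds, not biophysics: no
  conductance models, no network simulation, no pharmacodynamics (peptide
  treatment exists only as a condition label), and spine geometry is
  sampled from decision regions rather than measured morphologies.
* Out of scope: ripple-only detection, phase–amplitude coupling,
  time-frequency analysis, artifact rejection (inputs are declared
  artifact-free), automated spine segmentation from Z-stacks, and
  repeated-measures ANOVA reporting.
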