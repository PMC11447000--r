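---
title: "Methods: EEG and HD-MEA hyperexcitability biomarkers"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`neuromark` implements the quantitative analysis chain used to
characterise cortical hyperexcitability in mouse models of
neurodevelopmental disorders, in particular *Syngap1* haploinsufficiency:
wireless-telemetry EEG/EMG with an accelerometer channel on the in vivo
side, and high-density microelectrode array (HD-MEA) recordings of
cultured cortical neurons on the in vitro side. The animal recordings such
studies rest on are not publicly deposited, so the package pairs every
analysis stage with a seeded synthetic generator that produces inputs with
known ground truth; all quantitative claims about the pipeline are made on
that synthetic ground truth by the test suite and the acceptance script,
never asserted from literature values.

# Spectral analysis

Telemetry EEG (500 Hz, hardware band-passed 0.1–100 Hz) is cut into
contiguous half-open epochs `[t, t + L)`; a trailing partial epoch is
discarded. The power spectral density of an epoch is a single
Hamming-windowed periodogram of the mean-removed samples,

$$\hat S(f_k) \;=\; \frac{c_k\,\lvert \mathrm{FFT}(w \odot x)_k \rvert^2}{f_s \sum_i w_i^2},$$

with one-sided doubling ($c_k = 2$ except at DC and Nyquist). Dividing by
$\sum w_i^2$ (window power correction) makes the rectangle-rule integral
of the density recover the sample variance — the Parseval identity the
test suite checks to 1% on white noise. No sub-segmentation (Welch
averaging inside an epoch) is used: the published analysis operates on
30-s FFT epochs, and between-epoch averaging provides the variance
reduction instead.

Decisions worth recording:

* **Native resolution vs 2-Hz reporting.** The vendor description of PSD
  frequency handling (0.05-Hz increments "early", 2-Hz bins "once a steady
  signal was secured") does not define an algorithm. We compute at native
  30-s resolution (1/30 Hz), integrate *native* spectra for band powers,
  and expose `bin_psd()` (mean density per half-open 2-Hz bin, reported at
  bin centres) purely for reporting and plotting. Binning conserves
  integrated power because the native grid divides the bin width.
* **Band edges.** Delta 0.5–4, theta 4–8, alpha 8–12, beta 12–30, gamma
  30–50 Hz, half-open `[low, high)` so adjacent bands share an edge
  without double counting (4 Hz belongs to theta). The source literature
  is internally inconsistent about theta (4–8 in one place, 5–9 in
  another); we default to the figure-legend edges and leave them
  configurable in `eeg_bands()` and the YAML config.
* **Band powers over a recording** average per-epoch band powers over
  non-artifact 10-s epochs; the epoch count actually averaged is reported
  so downstream statistics can weight recordings honestly.
* **Artifact rule.** An epoch is artifact when the rectified, mean-removed
  signal reaches 0.2 mV on EEG or 1 mV on EMG (inclusive at the limit).
  The channel mean is taken over the whole recording so a DC offset cannot
  trip the rule. Whether the published PSD averaging excluded artifact
  epochs is unstated; we exclude them.

# Spike and spike-train detection

A spike event is a maximal contiguous run of samples whose mean-removed
absolute amplitude is at least 200 µV, kept when the run lasts between
1 and 200 ms. "Absolute threshold" is read as rectified amplitude —
epileptiform discharges are biphasic, and a one-sided reading would halve
sensitivity for negative-going spikes. Runs clipped by the recording edge
are kept if the observed duration already satisfies the minimum.

Trains are formed by greedy left-to-right chaining on peak-to-peak
intervals: a spike joins the open chain iff the interval from the previous
spike lies in [0.05, 0.5] s (inclusive at both ends); the first interval
outside the window closes the chain. A closed chain is a train iff it has
at least 3 spikes *and* spans at least 1 s from first to last peak. The
"spiking time equal to 1 s" rule admits another reading (a merging
window); we implement minimum span, which is the reading under which the
three printed rules jointly define a well-posed object, and validate every
reported train against all rules simultaneously with an independent
checker in the tests. The interval minimum is implemented as a chaining
gate only, not as a detector refractory period.

# Sleep staging

Each 10-s epoch yields four features: the delta ratio (epoch delta power
over the recording-mean delta power), the theta:delta ratio (within
epoch), the EMG ratio (epoch EMG variance over its recording mean), and
mean accelerometer activity. The normalizing means are taken over
non-artifact epochs; self-normalization is our resolution of the undefined
"ratio" denominators — it makes the published anchor values (0.5, 1, 1.3,
3, 1, 2.4) scale-free, matching their dimensionless presentation.

Each feature contributes a membership vector over {active wake, wake,
SWS, paradoxical}: piecewise-linear ramps that are 0 at one printed anchor
and saturate at 1 at the other, with the complementary mass split equally
among the stages the feature does not discriminate (the vendor's exact
curve shape is proprietary; a saturating ramp is the simplest curve
consistent with "maximum probability at X"). The four vectors are averaged
with equal weights — the published description states all four inputs
contribute equally — and an epoch is classified by argmax, except that
activity above 0.1 (strict) or an EMG ratio of at least 1.5 × 2.4 = 3.6
forces active wake outright. Exact probability ties break in the fixed
order wake > SWS > paradoxical > active wake. No temporal smoothing or
minimum-bout rule is applied (none is described), so permuting epochs
permutes the hypnogram identically.

# HD-MEA network bursts

Network (chip-wide) bursting is quantified from the pooled spike times of
the recorded electrodes: a 10-ms histogram convolved with a unit-area
Gaussian kernel (sd 100 ms, truncated at ±4σ; the grid is padded by 4σ so
the rate integral equals the pooled spike count exactly). The published
methods state Gaussian convolution but no numeric parameters ("custom
code"); our defaults — bin 10 ms, σ 100 ms, threshold mean + 3 sd of the
smoothed rate, a 50-spike participation floor, 0.2-s minimum peak
separation, edges at 10% of peak height (or at the threshold, whichever
crossing is nearer the peak) — follow common MEA network-burst practice
and are all exposed in `burst_params()` and the config. Bursts are
network-wide, not per-electrode, matching the raster-plot description of
synchronized vertical bands; detection is therefore invariant to electrode
relabeling. The inter-burst interval is peak-to-peak, undefined (NA)
below two bursts. The activity-scan / network-assay geometry (26,400
electrodes surveyed 30 s each; the 1024 highest-rate electrodes recorded
300 s) is reproduced in `summarize_activity_scan()` /
`select_top_electrodes()`, with cutoff ties broken by ascending electrode
id for determinism.

With the default mean + 3 sd threshold alone, a 300-s smoothed Poisson
rate crosses its own 3-sd level several times by chance — that is why the
spike-count floor exists. The false-positive property suite additionally
uses k = 5, the stringent setting under which a homogeneous Poisson
raster yields zero bursts in ≥95% of runs; planted-burst recovery is
tested at the default k = 3.

# Synthetic generators

`generate_sleep_recording()` emits, per epoch, EEG = delta sinusoid
(1.5 Hz) + theta sinusoid (6.5 Hz) + white noise, EMG = white noise, and
a truncated-jittered activity level, with per-stage amplitudes from
`stage_signatures()` and phases randomized per epoch. The default
signatures were chosen once to be physiologically plausible and cleanly
separated: SWS 100 µV delta with near-silent EMG; paradoxical 100 µV
theta with atonia; wake mixed low-amplitude EEG (25 µV oscillations) with
moderate EMG; active wake high EMG (1.2 × wake) and activity 0.5 ≫ 0.1.
Two constraints shaped the numbers: all EEG amplitudes stay safely under
the 0.2 mV artifact limit, and the wake signature's delta power must stay
below half the recording-mean delta power even when slow-wave sleep is
under-represented in a short Markov sequence — wake oscillation
amplitudes of 40 µV turned out to violate this under skewed stage mixes,
which is why the default is 25 µV. Stage sequences come from an explicit
label list or a first-order Markov chain (default persistence 0.75,
uniform stationary distribution).

`inject_spike_trains()` adds biphasic spikes (half-sine main lobe at full
amplitude, 20% undershoot) at fixed intra-train intervals. The undershoot
is kept at 20% so that, at the default 400 µV amplitude, only the main
lobe crosses the 200 µV threshold — a symmetric biphasic wave would split
each spike into two detected events a few milliseconds apart and break
the chaining by the interval-minimum rule. Random placement spaces trains
by at least 1 s of silence so plants can never chain together.

`generate_raster()` draws per-electrode (in)homogeneous Poisson spikes
with a rate multiplier inside planted burst windows. These generators
emulate the *features the classifiers consume*; they do not model
realistic EEG 1/f background, spindles, state transitions inside an
epoch, electrode noise, or biophysical neuron dynamics. Passing the
recovery suites therefore demonstrates correctness of the analysis rules
under the stated feature model, not field performance on animal data.

# Statistics

Genotype comparisons use the pooled two-tailed Student t-test (a thin
wrapper over `stats::t.test(var.equal = TRUE)`, with the constant-data
degenerate case defined as t = 0, p = 1; Welch by flag), and outlier
screening uses the two-sided Grubbs test with the t-quantile critical
value, removing at most one point per invocation (iterative removal is an
option, off by default — note the classical masking behaviour when two
extremes sit on opposite sides). The cohort power simulation draws
per-subject delta power as lognormal with a 20% between-subject
coefficient of variation — a typical between-animal spread for telemetry
band power in hybrid-background cohorts — with a 1.5× planted genotype
effect at n = 8 per group; under these conditions the pooled t detects
the effect in ≈95% of cohorts.

# Problem sizes and numerics

The test and acceptance workloads are sized for a laptop-class single
core: a 2-h staged recording (720 epochs), a 30-min spike-train recording
with 40 planted trains, 300-s MEA assays at 256–1024 electrodes with 100
seeded replicates per planted burst count, and 10,000 Grubbs replicates.
Parseval is checked on epoch-averaged spectra (30 epochs) because the
single-epoch ratio of windowed to unwindowed sample variance has ≈1.5%
sampling noise at 15,000 samples. Floating-point conventions: half-open
interval membership uses a 1e-12 slack; the burst histogram convolution is
direct (no FFT) so conservation is exact; epoch boundary samples belong to
the later epoch.

# Limitations

* EDF files are not read; the supported inputs are in-memory recordings
  and the plain CSV interchange format (no maintained EDF reader is
  available in the dependency set, and the binary format is out of scope
  to implement here).
* Sleep staging has no circadian decomposition, bout statistics, or
  transition modelling; the four-stage output is the endpoint.
* MEA analysis starts from spike times; raw-voltage spike detection and
  sorting, axon tracking, and per-unit burst statistics are out of scope.
* Repeated-measures ANOVA with post-hoc corrections, used in the source
  literature for time-course figures, is deliberately not re-implemented;
  standard R facilities (`aov`, `emmeans`) apply directly to the tidy
  outputs.
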