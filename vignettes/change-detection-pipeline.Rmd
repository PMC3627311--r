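---
title: "Analysing fNIRS change-detection block designs with nirschange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing fNIRS change-detection block designs with nirschange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirschange)
```

## The problem

In the change-detection (oddball) paradigm for infant near-infrared
spectroscopy, a background non-word (here /abuna/) is repeated during
*baseline* blocks and interleaved with a contrasting non-word (/abna/, a
consonant cluster, or /abuuna/, a long vowel) during fixed-length *target*
blocks.  The contrast between target and baseline blocks is taken to index
discrimination of the two stimulus types.  Because the baseline is the
absence of *change*, not the absence of stimulation, evoked responses are
small, and every analysis stage — hemoglobin conversion, artifact
exclusion, regression, multiple-comparison control, response
reconstruction, lateralization — must be calibrated carefully.  This
package implements that full pipeline together with a ground-truth-known
simulator, so each stage can be validated without access to any recordings.

## Probe geometry

Each temporal area carries a 2 × 4 optode lattice with sources and
detectors in a checkerboard (top-left node a source), 25 mm apart for
infants and 30 mm for adults.  Channels are derived from source–detector
adjacency: 10 short channels per pad, plus 4 long channels between nodes
offset by one row and two columns (25√5 ≈ 55.9 mm) on instruments that
support them.

```{r}
lay <- build_layout(2, 4, 25, include_long = TRUE)
table(lay$channels$kind, lay$channels$hemisphere)
```

Two design choices are deliberately open to the user.  First, published
figure labels for this montage are not algorithmically recoverable, so the
package uses a documented deterministic numbering (row-major node scan,
rightward then downward edges) and exposes the auditory region of interest
as a configuration field (`roi_channels`, default `c(4, 6, 7)`).  Only the
ROI *flags* matter for laterality results, not the labels themselves.
Second, the checkerboard orientation is fixed (top-left = source) because
any alternating assignment yields the same channel set; fixing one makes
outputs reproducible.

## Stimulus schedules

`generate_infant_schedule()` alternates jittered baselines (9–18 s) with
9 s targets, beginning and ending with a baseline, with a stimulus onset
asynchrony (SOA) of 1.5 s and equal counts of the two target conditions in
pseudo-random order.  Baseline durations are drawn uniformly from
*multiples of the SOA* inside the jitter interval (9, 10.5, …, 18 s): only
those lengths hold a whole number of token slots, which is what makes an
18 s baseline carry exactly 12 tokens and a 9 s target exactly 6.

"Pseudo-random" is given concrete, documented content: within target
blocks the target and background words interleave with no run longer than
2 and both words present; in multi-token mode the three exemplars of each
word cycle without immediate repetition.  The expected session length of
the maximal design (30 targets, 31 baselines averaging 13.5 s) is
30·9 + 31·13.5 = 688.5 s ≈ 11.5 min, which the generator reproduces
empirically across seeds.

The adult follow-up crosses target duration (9 s vs. 15 s, the latter
with 15–22 s baselines) with token variability (single vs. multiple
exemplars).  The published block count ("4–5 times") is read as *per
change condition*: with 5 per condition, a short session runs ≈ 4 min and
a long one ≈ 5–6 min, consistent with the reported 4–5 min sessions,
whereas 4–5 targets in total would yield ≈ 2 min sessions.

Word durations are carried as token metadata from the phoneme-level
measurements; the /abna/ total is 458.6 ms, and the longest word
(/abuuna/, 822.5 ms by phoneme sum — 0.1 ms above the rounded per-word
value, a rounding artifact) fits comfortably inside the 1.5 s SOA slot.

## The synthetic recording generator

`simulate_recording()` builds each channel as

  oxy(t) = Σ_condition amplitude × (boxcar ⊛ HRF)(t) + noise(t) + artifacts(t),

with deoxy-Hb built analogously from its own amplitudes (default
−0.3 × oxy, the canonical oxy-up/deoxy-down pattern) and an independent
noise realization.  The canonical HRF is a double-gamma (peak 5.5 s,
undershoot 15 s, peak:undershoot ratio 6), zero at onset and
peak-normalized to 1; because the simulator and the GLM build condition
regressors identically (normalized to peak 1), an injected amplitude is
recovered directly as the condition beta in mM·mm.

The noise model sums white sensor noise, slow sinusoidal drift (periods
≥ 60 s), a cardiac sinusoid (~2.5 Hz in infants, slower defaults for
adults) and a respiratory sinusoid (~0.6 Hz), each with a random phase per
channel.  No published amplitudes exist for these components in this
paradigm; the defaults (white 0.03, drift 0.05, cardiac 0.01, respiratory
0.02 mM·mm) were chosen once as representative of continuous-wave infant
recordings and are not tuned thereafter.  Motion artifacts are injected as
probe-level steps or spikes on the oxy trace.  A 10 Hz default sampling
rate is typical of the instrument class; calibration simulations in the
tests and the acceptance script use 5 Hz and white-only noise where
stationarity matters (see below), with sizes chosen to keep each suite in
the minutes range (e.g. 120–200 null sessions of 16 target blocks, 1,000
Monte-Carlo iterations instead of the 10,000 production default).

What the simulator does *not* emulate — systemic physiology shared across
channels, heteroscedastic infant motion, optical coupling changes, true
anatomical variability — bounds what passing tests mean: they validate the
*estimator machinery* (unbiasedness, calibration, error control) under the
stated noise model, not the field performance of the method on real infant
data.

## Preprocessing

**Conversion.** Dual-wavelength optical density converts to hemoglobin by
inverting the 2 × 2 extinction matrix per sample (modified Beer–Lambert
law).  The differential pathlength is left unresolved, so units are
mM·mm throughout.  Representative extinction matrices for 780/830 nm and
670/850 nm systems ship as overridable constants; the forward/inverse
round trip is exact to machine precision for any invertible matrix, and a
condition number above 10³ triggers a warning.

**Filtering.** The analysis band is 0.02–0.7 Hz, realized as third-order
Butterworth high- and low-pass sections applied forward–backward
(zero-phase).

**Artifact rejection.** A sample is artifacted when band-limited total-Hb
moves more than 1.5 mM·mm within a 100 ms sliding window, assessed at the
level of probes (pads): any channel's flag excludes the whole pad, since
motion moves the pad, not a channel.  One numerical subtlety forced a
documented choice here: a third-order 0.7 Hz low-pass smears a unit step
over more than a second, capping its within-100 ms excursion at ~14% of
its amplitude — on fully band-passed data the criterion could never flag a
2 mM·mm event.  The detector therefore runs on *drift-removed*
(0.02 Hz high-passed) total-Hb by default, which preserves fast
transients; `lowpass_hz` restores full-band behaviour if wanted.  The
windowed max-minus-min excursion is used rather than a rescaled
sample-to-sample derivative (the other defensible reading).

Flagged runs closer than 0.5 s merge into events; events with peak
excursion above 2 × threshold or duration above 1 s are *major*.  Ordinary
events are excluded by zero weights in the GLM (padded by 1 sample);
major events additionally contribute a step ("baseline-shift") regressor
that is 0 before the event and 1 after, absorbing the baseline jump large
movements leave behind.  The merge gap, padding, and major criteria are
unavoidably conventional; all are exposed as arguments.

## The channel GLM

The design matrix holds an intercept, one regressor per condition
(condition boxcar convolved with the canonical HRF), sine/cosine detrend
pairs with periods 2, 3, …, n minutes up to the session duration
(mean-centred so they stay orthogonal to the intercept even over
non-integer period counts; sessions under 2 minutes get none, with a
warning), and the baseline-shift boxcars.  Fits are least squares on the
weight-1 samples; rank deficiency (e.g. a condition with no blocks) is an
error naming the offending columns.  Each channel reports betas, standard
errors, `z = beta/se` (the "Z-score" entering the adult factorial
analysis), and `r`, the correlation between the observed series and the
fitted condition prediction on usable samples.

**Responding channels.** Whether a channel's `r` exceeds chance is decided
by a Monte-Carlo max-statistic (Westfall–Young style) procedure,
N = 10,000 by default: each iteration circularly shifts every channel's
observed series by an independent uniform offset of at least 30 s, refits,
and keeps the maximum |r| across the channel family; the corrected p is
the fraction of null maxima at or above the observed |r|.  The resampling
unit is not fixed by convention, so the package makes circular shifting
the default — it preserves the autocorrelation of the series, which makes
it the conservative choice for coloured noise — and offers a
residual-permutation alternative (`null = "residual"`).  Corrected
p-values are monotone in |r| by construction, and the family-wise error of
the default procedure calibrates to ≈ 5% on null simulations (the
acceptance suite measures this over 200 white-noise sessions; white noise
is used because circular-shift exchangeability is exact for stationary
series, making the calibration target unambiguous).

**Group analyses.** Betas of responding channels and their hemispheric
counterparts enter a two-way within-subject ANOVA (Condition ×
Hemisphere); the adult follow-up enters GLM Z-scores into a duration ×
token-variability ANOVA.  Both use `stats::aov()` with subject error
strata; degenerate strata (zero effect and zero error sums of squares)
report F = 0, p = 1.  The test suite checks both against hand-computed
cell-mean sums of squares.  Conventional repeated-measures degrees of
freedom are reported — (1, n−1) per effect — which for n = 8 subjects are
(1, 7); published F statistics for this design quoting (1, 31) presumably
pooled differently, and are not reproducible from the described inputs.

## FIR reconstruction and laterality

The shape-free response estimate fits, per condition, a bank of 20
one-second boxcars shifted 0–19 s from each target onset (the published
count "20 boxcars shifted by 0, 1, …, 20 s" names 21 shifts; the count
wins, and both bin number and width are configurable).  Oxy and deoxy are
fit separately; total-Hb betas are their bin-wise sum.  The per-hemisphere
ROI response is the maximum *absolute* total-Hb beta over ROI channels and
bins starting within 0–9 s (half-open window), with the signed value
retained for reporting.  The laterality index is (L − R)/(L + R), in
[−1, 1] whenever the inputs are magnitudes (which the absolute-peak
definition guarantees), antisymmetric and scale-invariant; L + R = 0 is
reported as missing.  Group summaries use the mean, type-7
(linear-interpolation) quartiles, and range — the quartile convention is
stated because box-figure conventions vary.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(
  schedule = list(n_target_blocks = 16),
  synth = list(fs = 10, oxy_amp = c(cluster = 0.08, duration = 0.08)),
  glm = list(n_mc = 1000)
)
res <- run_pipeline(cfg, seed = 1)
res$manifest$counts
head(res$fit_report)
res$laterality
```

The run is a pure function of (config, seed): per-stage seeds derive from
the master seed, and writing outputs produces a manifest whose checksums
are identical across repeated runs.

## Known limitations

* The artifact-detector defaults (merge gap, major criteria, detection
  filtering) are conventional where the literature is silent; sensitivity
  to them should be checked on real data.
* Circular-shift nulls assume approximate stationarity; strongly
  non-stationary physiology (e.g. state changes mid-session) would argue
  for the residual alternative.
* The simulator's independence of noise across channels understates the
  spatial correlation of systemic physiology, so multi-channel error
  control on real data may be more conservative than the simulated
  calibration suggests.
* Scalp registration (10–20 alignment) is metadata only; no photon
  transport is modelled.
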