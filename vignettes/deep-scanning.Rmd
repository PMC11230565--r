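---
title: "Deep scanning: two-stage detection of vessel noise in estuarine recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep scanning: two-stage detection of vessel noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepscan)
```

## The problem

Passive acoustic observatories in estuaries record a few minutes of
underwater sound at fixed intervals, accumulating hundreds of thousands of
short WAV files per deployment.  Recreational-vessel noise is an important
anthropogenic component of these soundscapes, but estuaries are loud and
biologically rich: snapping shrimp produce millisecond broadband clicks that
are among the loudest natural sounds in the sea, and fish choruses raise the
broadband level for tens of minutes at a time without any vessel being
present.  A detector that flags "loud" therefore flags fish; a detector
that only looks at spectrogram texture wastes compute on two minutes of
mostly background per file.

`deepscan` implements a two-stage compromise.  Stage 1 is cheap and runs on
everything: the waveform is cut into half-second frames, each frame's
calibrated broadband sound pressure level (SPL) is computed, and frames that
stand above the file-wide median SPL are grouped into candidate segments.
Stage 2 is selective: a fixed-size spectrogram window around each candidate
is classified by a small feed-forward neural network trained on curated
vessel and non-vessel examples.  The target class is the *burst-broadband*
(BB) signature of a vessel passing at speed — a seconds-long burst spanning
the band well above fish chorusing — in its narrow (mean 5.9 s, SD 2.1 s)
and wide (mean 15.9 s, SD 6.6 s) variants.  Slow-vessel signatures
(long variable-broadband passages, low-frequency idling) are deliberately
out of the detection target: the low-frequency class in particular is
nearly indistinguishable from fish chorus, and the simulator provides both only
as confounders.

## Stage 1: calibrated framed SPL and median gating

Each frame `y` of `N` samples is Hann-tapered and its single-sided power
spectrum summed over the analysis band:

    Pss(f) = 2 |DFT(y w) / (N mean(w))|^2      (DC/Nyquist not doubled)
    SPL    = 10 log10( sum_band Pss / B ) - S

`B` is the window's power-bandwidth factor (exactly 1.5 for the periodic
Hann window once the window is amplitude-normalized by its coherent gain,
as done here), so a sine of amplitude `A` measures `10 log10(A^2/2)` and
white noise measures its mean-square — the property the test suite checks
against time-domain oracles.  `S = M_h + G + 20 log10(1/V_ADC)` converts
ADC-normalized units to dB re 1 uPa; sensitivity, gain and converter
voltage live in a single `calibrationSpec()` (default −185.5 dB re V/uPa,
20 dB, 1 V).  Published descriptions of comparable deployments quote the
sensitivity variously between −186 and −185 dB re V/uPa; the value is
deliberately a required, documented parameter rather than a constant.

The median SPL is always computed over the *whole file* — a 2-minute file
is short enough that a vessel passage does not dominate the median, and the
median is what makes the gate adaptive across tides, seasons and stations.
Gating at the literal median would mark roughly half the frames of any
noise-only file, so the gate requires `median + margin` with a default
margin of 3 dB (`margin = 0` reproduces the literal rule for comparison).
Marked frames merge across gaps of up to `mergeGap = 1` s and segments
shorter than `minDuration = 1` s are dropped — both chosen to bridge
within-burst dips without gluing distinct events together.

## Snap cleaning

Snaps are removed before stage 1 so that their full-spectrum energy neither
inflates frame SPL nor paints vertical stripes through the feature windows.
Detection is amplitude-based: a sample whose magnitude exceeds
`spikeFactor = 4` times the local RMS envelope (50 ms window) starts a snap
interval.  Amplitude alone is not enough: in Gaussian-like background a
4-sigma excursion occurs about once per 16 000 samples, which at 80 kHz
would fabricate hundreds of "snaps" per file.  What physically separates a
snap from a tail sample is millisecond-scale energy, so an interval is kept
only when its 1 ms RMS exceeds twice the slow envelope.  Kept intervals are
excised and refilled with the centered moving average of the surrounding
non-snap samples (50 ms window).  Detection and excision iterate to a
fixpoint (a dense snap cluster inflates the envelope and can hide a weaker
neighbour until the cluster is removed), which also makes the operation
idempotent.  Whether one smooths the whole waveform or excises spikes is a
genuine design fork; excision was chosen because global smoothing would
low-pass-destroy exactly the broadband signature the detector needs.

## Stage 2: feature windows and the classifier

A feature window spans `deltaT = 5.5` s around a candidate instant and
800–10 000 Hz in frequency.  The band's lower edge sits above fish
chorusing (roughly 50–800 Hz); the upper edge keeps storage and compute
modest while retaining the burst's texture.  The window duration is an
explicit parameter: working profiles in the 5.0–7.5 s range behave
similarly, and 5.5 s matches the narrow-burst scale.  The log-magnitude
spectrogram patch is bilinearly resampled to a fixed 32 × 32 grid and
standardized to zero mean, unit variance *within the window*.
Standardization is deliberate: stage 2 should judge spectro-temporal shape,
not loudness — loudness was stage 1's criterion — and it makes the score
exactly invariant to the absolute gain of the recording chain.  A window
clipped by a file edge is zero-padded back to shape so the classifier
input never changes size (though the scanner slides windows inward rather
than score padded ones; see below).

The classifier is a small dense network, input 1024 → 10 → 8 → 6 → 1, with
tanh hidden units and a sigmoid output; `{Z_f}` / `{Z_n}` training windows
map to targets 1/0 and the default decision threshold is 0.5.  No deeper
architecture is warranted by a few hundred training windows.  Training uses
full-batch Adam on class-weighted binary cross-entropy with a seeded 80/20
validation split and early stopping (patience 300 epochs, max 1500);
everything about training is reproducible from the seeds recorded in
`trainingMeta`.  Two training choices matter and are worth stating
explicitly.  First, the loss weights classes inversely to their frequency:
at the ~1:15 vessel/non-vessel imbalance of curated feature sets an
unweighted loss lets the majority class drown out the positives.  Second,
early stopping monitors the class-weighted validation *error rate* (loss
as tie-break), not the validation loss: on a separable, imbalanced set the
loss bottoms out within a few tens of epochs — long before the decision
boundary is in place — and stopping there returns a model that is confident
about nothing.  Negative windows are sampled at least one window-length
away from any logged burst, 15 per positive by default — about the class
imbalance of curated vessel feature sets.

During a scan, each candidate segment gets one window centered at its SPL
peak; segments longer than `deltaT` (wide bursts) are additionally tiled
every `deltaT/2` and the maximum score is kept.  Window centers are slid
inward so the window always lies inside the file (zero-padding remains
only for files shorter than one window): a half-empty edge window is not a
pattern the classifier was trained on, and scoring one produces noise, not
evidence.  A positive anywhere flags the file, matching the per-file error
definition used for evaluation: `rho = (N - n_err) / N` over files, with
an error being either a flagged file without a vessel or a missed file
with one.

## SEL metrics

For a detected segment the package reports the Peak Difference (peak SPL
minus the file median), the Mean Difference (mean of the above-median SPL
values in the segment, minus the median; a file-wide variant is available
via `meanScope = "file"` since either reading of "values above the median
line" is defensible), and the Area Size — the trapezoidal area between the
SPL curve and the median line, clamped below at zero, in dB s — as the
sound-exposure-level proxy.  Only the above-median area is integrated
because the metric is meant to capture *added* noise energy.  The dB-scale
area equals an SEL only heuristically, so `selAreaLinear()` provides the
physically additive variant that integrates the linear excess power.
Cumulative vessel SEL per station is the sum of per-detection areas.

## The simulator

`simulateScene()` builds labeled scenes from four ingredients:

* **Background**: Gaussian broadband noise at a configurable RMS
  (default 0.01 in ADC units).
* **Snaps**: Poisson arrivals (default 5 s⁻¹) of ~1 ms damped sinusoids
  with random carrier, peak-normalized to `snapAmplitudeFactor` (default 8)
  times the background RMS.
* **Fish chorus**: band-limited noise in 50–800 Hz with a slow sinusoidal
  amplitude modulation (default depth 0.6, period 30 s), at a level
  (default +6 dB) above the background.  The modulation matters: it makes
  chorus files produce genuine stage-1 candidates, which is precisely the
  case stage 2 exists to reject.
* **Vessel events**: band-limited noise under a Tukey envelope.  Burst
  durations, when not fixed, are drawn from normals with the narrow/wide
  means and SDs above, truncated below at 0.5 s.  The default burst level
  of +12 dB over background is a testing choice — field recordings carry no
  single burst-to-background ratio — and the level is a per-event
  parameter.

`simulateCorpus()` writes WAV files plus `truth.csv`/`labels.csv`, with
exactly `round(nFiles * prevalence)` burst-positive files and a seeded 30%
of files carrying a chorus.

What the simulator does *not* emulate: propagation (spreading loss,
multipath), engine tonals and their Doppler tracks, tide- and
temperature-driven background drift, and the full zoo of biological
transients.  Passing the end-to-end test therefore shows that the pipeline
implements its own contract — gate on energy, classify shape, score files
— not that any particular accuracy carries over to field data.  The
synthetic corpus keeps the negatives "hard" only in the chorus/snap sense.
Variable-broadband and low-frequency confounders exist in the generator for
robustness experiments but are not mixed into the default corpus: at the
reduced study rate used for testing (16 kHz) a variable-broadband signature
occupies the same analysis band as a burst and is not separable by design —
the method's scope is burst-broadband detection.

## Numerical choices and degenerate inputs

* All-zero frames map to an SPL of −Inf with a warning, never an error.
* DC and Nyquist bins are not doubled in the single-sided spectrum; the
  band default (1 Hz lower edge) excludes DC anyway.
* Ties at a segment's SPL peak resolve to the earliest frame.
* A feature band clipped by Nyquist is clamped; fewer than two spectrogram
  rows in the band is an error.
* The trapezoidal SEL area of a segment with no above-median frame is 0,
  as are both differences.
* The classifier guards against single-class training data and shape
  mismatches; an all-zero network scores the sigmoid of its output bias.
* WAV writing clips out-of-range amplitudes with a warning; multi-channel
  reads take channel 1 with a warning.

## Problem sizes used in validation

The test-suite and acceptance computations run at a reduced sample rate of
16 kHz with 120 s files: a 60-file training corpus and a disjoint 100-file
evaluation corpus at prevalence 0.3, 1000-draw duration checks, and
1000-series gating-oracle sweeps.  These sizes exercise every code path at
full statistical resolution for the properties being checked while keeping
a complete validation run to a few minutes of CPU.
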