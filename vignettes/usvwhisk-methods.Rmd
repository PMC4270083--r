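---
title: "Methods: quantifying vocalization-whisking-spiking coordination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying vocalization-whisking-spiking coordination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usvwhisk)
```

This vignette documents the models, parameter choices and numerical
decisions behind the package, in the spirit of a methods section: what each
stage assumes, which tunables matter, what the synthetic-data generator does
and does not emulate, and where design was genuinely open.

## Whisking kinematics

Whisker-angle traces (degrees, protraction positive, sampled at the
high-speed camera rate of 250 Hz) are linearly interpolated to 1000 Hz and
band-passed at 1–25 Hz with a fourth-order Butterworth filter applied
forward and backward (`preprocessTrace()`). Zero-phase filtering was chosen
because cycle *timing* feeds every downstream phase statistic; the cost is
an effective eighth-order roll-off, which is harmless here. The posture
(DC) component is removed before filtering so that the forward–backward
pass has small edge transients.

Whisk cycles run between successive local maxima of the filtered angle
(maximum protraction), detected with a 40 ms minimum peak separation —
deliberately below the 50 ms quality-control floor, so the separation
constraint can suppress noise doublets but never a legitimate cycle. A
cycle is valid iff its duration lies in [50, 250] ms and its peak-to-trough
amplitude is at least 7.5°. The amplitude criterion is applied to the
*filtered* trace; whether it should instead apply pre-filtering is not
decidable from the method description we follow, and the filtered variant
was chosen because the QC exists to protect the phase estimate, which is
also computed post-filtering. Whisking phase is the angle of the analytic
signal (FFT-based Hilbert transform), unwrapped and re-anchored per
detected cycle so that phase is exactly 0° at each maximum protraction,
passes 180° at maximum retraction, and stays below 360° until the next
peak. The per-cycle anchoring uses a linear rescaling of the unwrapped
analytic phase across each cycle; for sinusoidal motion this is the
identity, and for jittered cycles it guarantees the monotonicity invariant
that the raw analytic angle cannot. Samples outside valid cycles are
masked and excluded from every phase statistic.

Whisking rhythmicity is estimated by Welch's method on the filtered trace
with ~2 s Hann segments (≤ 0.5 Hz resolution), restricted to 4–25 Hz. A
peak is only called a dominant rhythm if it exceeds 3× the median in-band
power; on white-noise traces this flags a rhythm in well under a quarter of
runs.

## Vocal analysis

Spectrogram parameters are kept as an explicit object
(`spectrogramSpec()`) whose frequency and time resolutions are always
derived (`fs / nfft` and `nfft (1 − overlap) / fs`), never stored: the
1024-point window at 250 kHz gives 244 Hz and, at 93.75 % overlap,
0.256 ms; the 500-point window at 80 % overlap gives 0.4 ms. (For the
500-point window the naive frequency-resolution formula gives 500 Hz; a
published figure of 58 Hz for that configuration appears to reflect an
effective-bandwidth convention of the original acquisition software, and
this package deliberately reports the naive formula.)

Call-source assignment uses four microphones, two per platform side
(channels 1–2 subject, 3–4 stimulus). Each side's score is the *maximum*
over its two channels — robust to one occluded microphone — and a call is
assigned to the louder side only if the score ratio reaches a margin
threshold. The margin defaults to 1.5 (linear), a value at which the
generator's default directional regime (directionality 2, lognormal
intensity noise with CV 0.5) yields roughly 70 % correct / few % wrong /
the rest unassigned, matching the accuracy regime reported for real
single-emitter control recordings (70–79 % correct). Assignment
percentages are always computed on the full call count and rounded only at
presentation.

Calling rates are onsets per second of scenario time; a call belongs to a
touch iff its onset falls inside the half-open touch interval, so a call at
exactly a touch offset is out of touch. For calling periodicity, the modal
inter-call interval comes from the successive-interval histogram, but the
spectral estimate is computed on the smoothed outline of the *all-order*
interval histogram (intervals from each call to every later call within
6 s): a perfectly periodic call train collapses to a single bin in the
successive-interval histogram, whereas its all-order histogram is a comb
whose PSD carries the calling rhythm. The outline is smoothed with a 5-bin
moving average, transformed by Welch's method (2 s segments, 75 % overlap)
and lightly Daniell-smoothed, which stabilizes the noise floor enough that
a 3×-median dominance criterion rejects Poisson call trains in the large
majority of null runs.

Trigger-locked sound power cumulates short-time spectral power over
frequencies, combines triggers by the geometric mean (intensities span
orders of magnitude), and normalizes by the pre-trigger average, so the
pre-trigger portion of the trace is 1 by construction. Triggers whose
window overlaps any vocalization are excluded, and trigger counts can be
equalized across classes by random subsampling.

## Coordination statistics

The Hodges–Ajne statistic `m` is the minimum number of observations in any
closed half-circle, found by enumerating boundaries at the data points.
For the p-value the package uses the classical formula
`p = (n − 2m) C(n, m) 2^(1−n)` (evaluated in log space) for all `m`,
setting `p = 1` when the expression is non-positive (perfectly balanced
data) and capping at 1. Restricting the formula to `m < n/3` and falling
back to `p = 1` elsewhere would be useless in practice: uniform data at
realistic sample sizes almost always have `m ≥ n/3`, and the test would
lose all type-I behavior. As implemented, simulation at n = 664 gives a
rejection rate of 3–7 % at α = 0.05, i.e. the test is approximately
calibrated and slightly conservative.

The retraction/protraction split counts valid call-onset phases in
(0°, 180°] (retraction; the 180° boundary is closed by the phase-type
definition) against the rest; phase exactly 0° — the protraction peak
itself — counts as protraction. Ties at these boundaries are measure-zero
for real data.

## Unit classification and stability

Waveforms are normalized by peak voltage and widths measured at 25 % of
peak on both flanks with linear interpolation between samples. The 25 %
level is a package choice — the width criterion we follow names the
features but not the threshold — selected because it is robust to baseline
noise while preserving the RS/FS bimodality. Features are scaled to the
widest unit (assigned exactly 1); k-means with two clusters, ten restarts
and a fixed seed labels the wide-mean cluster RS. Since k-means with both
features transformed by one common affine map yields the same partition,
the classification is insensitive to the unknown affine convention of any
particular published feature axis, and this invariance is asserted as a
test.

The stability metric samples, per permutation, control periods outside the
interaction windows — as many and as long as the interactions, placed
uniformly without overlap — and correlates firing rate against period
midpoint. The score is the mean |R| over permutations (drift direction is
irrelevant to exclusion), and units above 0.4 are excluded. With few
interaction windows the null |R| is intrinsically large (|R| of a few
points is biased away from 0), so the metric is meaningful only for
sessions with a reasonable number of interactions, as in the data it was
designed for.

## Response metrics

The default response window is call duration + 25 ms (the four fixed onset
windows, 0–25 … 76–100 ms, are retained as alternatives). Baselines are
matched in length to their events and placed 10 s of *clean* time before
the event onset: walking backwards from the onset, only time outside every
exclusion window (all calls and all interactions) accrues, and the
baseline starts at the point where 10 s have accumulated. If the window
does not fit inside one unbroken clean stretch it slides earlier until it
does; split baselines are disallowed, events with insufficient clean
history are dropped and counted. Baselines never intersect exclusions, and
this is asserted on every run. The touch off-response window is the fixed
200 ms after each touch offset, truncated by the next touch onset or the
session end (duration-corrected).

The response index `(in − out)/(in + out)` is bounded in [−1, 1],
antisymmetric, zero for equal rates and flagged undefined when both rates
are zero. In/out-of-touch call comparisons partition calls by onset and
require a configurable per-condition floor (default 5 calls). Because only
a minority of calls occur during touch, the bootstrap
(`bootstrapEqualizedRi()`) resamples the out-of-touch calls without
replacement at the in-touch sample size, B = 1000 by default; resampling
*without* replacement is the natural choice for a sample-size-matching
control (with `n_in` equal to the full out-of-touch count it degenerates to
the full-sample index, a property used as a test). Group comparisons use
Wilcoxon signed-rank (paired) or Mann–Whitney U (unpaired), plus
Kolmogorov–Smirnov for distribution shape; a D'Agostino–Pearson normality
screen is reported but never gates the nonparametric tests (it is
implemented in-package and verified against an independent reference
implementation).

## Phase locking and the shuffle test

Spike phases are read off the valid-masked phase trace at the nearest
sample. Histograms are occupancy-normalized: each of 16 bins is divided by
the time the phase trace spends in it, giving a rate per phase bin, with
zero-occupancy bins excluded. The Rayleigh vector is computed from
occupancy-weighted spike phases rather than bin centers, avoiding binning
bias; 16 bins are reporting-only. Whether the original procedure weighted
by occupancy before or after the vector step is ambiguous; both are
available (`rayleighVector()` takes optional weights) and
occupancy-weighted is the default.

The shuffle test circularly shifts the spike train against the phase trace
*within the concatenated valid time*, preserving inter-spike structure —
the property that makes the test insensitive to spike count, unlike
Rayleigh or Hodges–Ajne tests applied directly. The observed
occupancy-weighted Rayleigh length is compared with 10,000 shifted
recomputations by default (tests and the calibration script use 1000,
which is ample for a 95 % criterion), and a unit counts as locked iff it
has ≥ 10 spikes in tracked time, Rayleigh length > 0.2 and shuffle
quantile ≥ 0.95. Under the null the quantile is uniform; the package's
calibration (200 uncoupled Poisson units, 1000 shuffles) yields a
rejection rate statistically indistinguishable from the nominal 5 %.
A caveat reproduced by the test suite: a unit that merely responds to
calls which are themselves phase-coupled to whisking will pass the locking
criterion well above chance — locking results must therefore be
cross-referenced against call responsiveness, and the pipeline report does
so.

## The synthetic-session generator

The generator emulates the statistical structure the analysis assumes,
with ground truth retained for recovery tests. Its defaults encode the
study conditions: a 5-minute subject-alone baseline followed by a social
period; whisking as a frequency-jittered oscillator (8 Hz, period CV 0.1,
peak-to-trough amplitude 20°, sampled at 250 Hz) rather than filtered
noise, so cycle markers are exact ground truth for the detector; touch
episodes with lognormal durations matched to 2.86 ± 2.68 s (mean ± SD),
truncated at 0.2 s, at 1.76 events/min; calling as an inhomogeneous point
process at 0.13 Hz (alone), 0.80 Hz (social, out of touch) and 1.50 Hz (in
touch), implemented by thinning at the von Mises-boosted maximum rate —
exact for an inhomogeneous Poisson process; subject calls phase-coupled to
the subject's whisking (von Mises, default κ = 1 about 90°,
mid-retraction), stimulus calls uncoupled, reproducing the
emitter/partner asymmetry. No quantitative coupling strength is published
for the real data; κ = 1 was fixed once as the weakest coupling that
reproduces the qualitative retraction bias reliably at session-scale call
counts, and it makes no claim to match the observed 381:283 split
numerically. Call categories follow the published proportions; durations
are lognormal with the published per-category means and SDs, while mean
frequencies and bandwidths use SDs inferred from the published 20th–80th
quantile spreads (the SEM-derived SD is consistent with the published SD
for durations but not for the skewed frequency distributions). Microphone
intensities give the emitter's side the full per-call loudness and the far
side that divided by the directionality (default 2), all under lognormal
noise (CV 0.5) — the regime that lands the default assignment accuracy
between the reported 70 and 80 %. Absolute calibration is unknown, so
intensities are relative linear amplitudes throughout. Units are
inhomogeneous Poisson with multiplicative gains in call windows
(+ latency), touch windows and 200 ms off-windows; waveforms are
asymmetric bumps (fast fixed rise, class-specific decay) whose 25 %-width
is drawn from RS (0.6 ms) or FS (0.3 ms) Gaussians with 0.05 ms SD, and
default base rates follow the reported class medians (RS 4.4 Hz,
FS 11.1 Hz).

What the generator does **not** emulate: acoustic waveform structure of
USVs (audio, when supplied, is tone bursts sufficient for the power
analysis), bursting or refractory spike-train structure, slow
non-stationarities other than the drift injected deliberately in stability
tests, whisker tracking noise and dropped frames, and cross-animal
whisking-phase coupling (absent in the real data). Passing tests therefore
demonstrate correctness of the estimators under the assumed generative
structure, not robustness to every pathology of real recordings.

## Problem sizes and numerical choices

Test and calibration problem sizes were chosen as the smallest that make
each statistical assertion reliable rather than fragile: rate-ratio
recovery pools counts over ten 2000 s sessions (the per-session Poisson CV
of the in/out ratio is ~8 %, so single-session checks against a 10 % band
would test the draw, not the estimator); the shuffle-test calibration uses
200 units × 1000 shuffles; k-means recovery at 6-SD separation is judged
at the population level because individual draws land midway between
cluster means with ~3σ probability. FFT lengths are padded to highly
composite sizes (mixed-radix FFTs degrade to quadratic cost on awkward
lengths); padding perturbs only the trace ends, which cycle QC already
distrusts. All intervals are half-open `[start, end)`, times are seconds
on one session clock, and CSV round-trips write doubles with `%.17g` so
sessions reload bit-exactly.

## Known limitations

- The analytic-signal phase assumes a reasonably narrow-band whisk; broad
  multi-rhythmic traces will produce non-monotone raw phase that the
  per-cycle anchoring can only partially repair (such cycles typically
  fail QC).
- The stability metric is uninformative for sessions with very few
  interaction windows (the null |R| is large by construction).
- The Hodges–Ajne p-value formula is approximate between `n/3 ≤ m < n/2`;
  it is slightly conservative there, which is the safe direction for a
  coupling claim.
- Source assignment assumes exactly two microphones per side and a
  symmetric geometry; with asymmetric setups the margin threshold needs
  recalibration.
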