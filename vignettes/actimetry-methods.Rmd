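---
title: "Methods: bilateral wrist actimetry of upper-limb use"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bilateral wrist actimetry of upper-limb use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actimetry)
```

# The measurement problem

After a stroke, the hemiparetic upper limb is often under-used at home even
when clinical capacity scores are fair: patients solve daily tasks with the
non-paretic arm. Two wrist-worn tri-axial accelerometers (50 Hz, ±8 g clip)
worn continuously for about a week give an *ecological* record from which
limb-use asymmetry can be quantified. This package computes three families
of per-day variables from such paired recordings and the cohort statistics
built on them. Throughout, the **test** limb is the paretic limb of a
stroke subject or the non-dominant limb of a control, and the **reference**
limb is the contralateral one; all ratios are test/reference, so 1 means
balanced use and values below 1 mean the test limb is used less.

# Signal model and per-day variables

## Preprocessing

Each wrist's signal is assumed to sit on a regular 50 Hz grid; file
timestamps are validated (strict monotonicity, rate within 1% of nominal,
no gaps beyond one sample) but the grid, not the timestamps, drives all
computation, because the finite-difference jerk assumes a constant `dt`.
Gaps are rejected rather than imputed: the protocol assumes continuous
wear, and imputation would manufacture jerk and counts. Recordings are cut
into calendar days at a configurable local time-of-day boundary (default
midnight; nothing in the method depends on where the cut falls, and the
boundary is exposed because deployment conventions differ). When ingesting
from files, day slices shorter than `min_day_s` (default 12 h) are dropped
from the medians — partial first/last days otherwise bias the daily counts
downward; the threshold is configurable, and callers assembling day pairs
in memory are unaffected.

A zero-phase low-pass at 10 Hz precedes all kinematics. The filter is a
4th-order Butterworth run forward and backward: the cutoff is the method's
constant, while family and order are implementation choices — Butterworth
for a maximally flat passband, and zero-phase so that movement onsets are
not delayed relative to the 0.5 s windowing grid. The elevation angle is
computed from the filtered signal for the same reason the low-pass exists
at all (sensor noise would otherwise alias into the per-window range of
motion).

## Jerk ratio and JR50

Per axis, jerk is the centered difference
`J_i(t) = (a_i(t+dt) − a_i(t−dt)) / 2dt`, exact for locally linear
acceleration and second-order accurate otherwise; the two endpoint samples
have no centered difference and are dropped rather than extrapolated, so
paired limbs share one interior grid. The per-sample jerk ratio

`JR(t) = 2 |J_test| / (|J_test| + |J_ref|)  ∈ [0, 2]`

is undefined only when both magnitudes are zero; those samples are
excluded and counted. Samples where exactly one limb is still are kept —
they form the genuine spikes at 0 and 2 that unilateral movement produces.
(The alternative reading, excluding samples where *either* limb's jerk is
zero, would delete those spikes; we keep the both-zero-only rule because
the one-sided spikes are informative and the exclusion's purpose is merely
to avoid 0/0.)

The day's JR histogram over [0, 2] is normalized so that its integral is
2, and JR50 is the area over [1, 2]. Binning is not part of the method's
definition, so the default width is 0.02 (100 bins), fine enough that the
mass a bin can straddle is below 2% of the total. One numerical choice
matters: identical bilateral signals put every sample exactly at JR = 1,
which is a bin edge. Such samples are split half/half between the bins
below and above 1, so balanced use yields JR50 = 1 rather than 0 or 2, and
swapping the limbs maps JR50 to 2 − JR50 exactly in that case (and within
one bin's mass in general).

## Functional use from the elevation angle

The forearm elevation is recovered from the gravity direction:
`α(t) = 90° − arccos(a_y / ‖a‖)`, with `a_y` the axis along the forearm.
The arccos form returns the angle from the gravity vector; we expose the
signed complement so that the horizontal is 0°, hand-up +90°, hand-down
−90°, which makes the functional criterion `|α| ≤ 30°` literal. The arccos
argument is clamped to [−1, 1]; samples with zero norm have no direction
and are flagged invalid, and any 0.5 s window containing one is discarded
from every count. The estimate is exact in quasi-static epochs and degrades
gracefully with movement: with linear acceleration bounded by 0.1 g the
error stays within a few degrees (verified on scripted trajectories in the
test suite).

The day is tiled with non-overlapping 0.5 s windows (trailing remainder
dropped). A window is a functional movement when *every* sample satisfies
`|α| ≤ 30°` — the strictest consistent reading of the band condition; a
mean-based reading would admit windows that dip through the band — and the
in-window range `max α − min α` is at least 30°. FuncUse30 is the daily
count per limb, FuncUseRatio30 their ratio (undefined, and reported as
such, when the reference count is 0; undefined day values are excluded
from the subject median with a warning).

The amplitude profile counts windows per 10° range bin `[0°,10°) …
[80°,90°)`. By default the horizontal band is kept for the profile, which
caps the observable range at 60° and leaves the bins from [60°,70°)
upward structurally empty; the band can be dropped
(`profile_apply_band = FALSE`) to profile the full range. Both modes are
implemented because the band's role in the amplitude analysis is a design
point on which reasonable pipelines differ; the default keeps the profile
consistent with the FuncUse30 definition, so the bins at and above 30°
sum exactly to FuncUse30. Movements spanning two windows are counted per
window, not merged.

## Use hours

The activity-count chain emulates the wrist-actigraphy lineage: resample
to 30 Hz, band-pass 0.25–2.5 Hz, quantize at 0.001664 g per count on 1 s
epochs, and call an epoch active when its count strictly exceeds 2.
UseHours is the active time in hours; UseHoursRatio the test/reference
ratio.

Three choices are worth recording:

* 50→30 Hz is a non-integer factor, so plain decimation does not apply.
  We use rational polyphase resampling (upsample 3, linear-phase FIR
  anti-alias filter with integer group delay, downsample 5), which
  preserves the 30 Hz grid without aliasing; DC passes within 1e-4 and a
  1 Hz tone within 0.1% (asserted in the tests).
* The per-epoch aggregation before quantization is the rectified *mean*
  per axis; mean and sum differ only by the fixed samples-per-epoch
  factor, and the count threshold is documented against the mean
  convention. Axes are combined by vector magnitude
  (`sqrt(c_x² + c_y² + c_z²)`), the convention of the count lineage the
  resolution constant comes from; `axis_combine = "sum"` is available.
* Counts stay real-valued (no flooring), and the threshold is strict
  (`> 2`, not `≥ 2`), as the rule is stated.

## Cohort statistics

Each subject contributes the median of their available days per variable.
Shapiro–Wilk checks motivate the nonparametric tests (constant samples are
rejected as degenerate rather than given a p-value). Group comparisons use
two-sided Mann–Whitney tests; paired ratio-vs-ratio contrasts within the
stroke group use two-sided Wilcoxon signed-rank tests. Exact null
distributions are used whenever the sample permits (n ≤ 25, no ties),
otherwise the normal approximation with continuity and tie corrections;
both paths are checked against exhaustive enumeration oracles for n ≤ 8 in
the test suite. Bonferroni correction multiplies the raw p by the family
size and clips at 1. The family sizes are not derivable from the method
itself, so they are explicit configuration: default 3 for the independent
comparisons of the three ratios and 3 for the three pairwise ratio
contrasts within stroke; raw and adjusted p are always reported side by
side. Each ratio is regressed on FM-UE by ordinary least squares (slope,
intercept, r²) within the stroke group.

# The synthetic-data generator

Real recordings of this kind are identifiable clinical data, so the
package generates its own validation inputs. A script assigns each limb a
sequence of non-overlapping epochs:

* **rest** — static posture (default elevation −70°, a hanging arm) with
  only Gaussian sensor noise (default rms 0.005 g, a realistic MEMS noise
  floor; at that level ≥ 99% of rest epochs stay at or below the activity
  threshold, asserted in the tests);
* **fidget** — static posture plus small band-limited movement power;
* **armswing** — walking-like oscillation around −70° at ~1 Hz: activity
  without functional movement, exercising the band exclusion;
* **functional** — window-aligned triangular elevation sweeps of
  prescribed amplitudes rising from a common baseline and returning
  within one 0.5 s window, with movement-band (0.5–3 Hz) acceleration of
  rms 0.05–0.1 g sustained across the epoch so counts register it as
  active. The epoch's first window absorbs the smoothed posture
  transition into the epoch, so a script of K sweeps is recovered as
  exactly K functional windows.

Gravity is rendered as `a_y = sin α`, `a_x = cos α` (plus movement noise
on x/z), matching the elevation convention above. Determinism is strict:
one seed, one bit-identical recording.

Cohorts are driven by a per-subject latent asymmetry `u ∈ [0, 1]`, the
fraction of bilateral functional events performed by the test limb.
Healthy subjects draw `u` near 0.5; stroke subjects draw low `u`, with
FM-UE mapped linearly from `u` onto [27, 66] (the moderate-to-mild range),
so every ratio should fall with impairment. Two further asymmetries make
the stroke-like cohort structurally realistic: the test limb's sweep
amplitudes shrink as `u` falls below 0.5 (large-amplitude functional use
disappears first, which is what makes the functional-use ratio decline
with amplitude bin), and walking bouts are bilateral (shared arm-swing
keeps use-hours relatively symmetric, which is why UseHoursRatio is less
depressed than FuncUseRatio30).

What the generator does **not** emulate — and what passing recovery tests
therefore cannot certify on real data: biomechanical limb dynamics and
inter-joint coupling, hand-role semantics (reach vs stabilize), non-wear
and donning artifacts, sensor drift or temperature effects, sleep posture,
and movements that are functional without passing through the horizontal
band. Recovery results bound algorithmic correctness, not clinical
validity.

# Numerical choices

* **Zero-phase filtering.** Forward–backward IIR filtering is realized
  with odd-reflection padding before `signal::filtfilt` (which starts
  from zero state); pad lengths are ≥ 100 samples for the 10 Hz low-pass
  and 20 s of samples for the 0.25 Hz band edge, after which a DC input
  passes within 1e-6 and 1e-3 respectively.
* **Resampler.** FIR length is 2·32·max(p,q)+1 taps (odd, so the group
  delay is an integer at the upsampled rate and the output grid aligns
  with t = 0); convolution runs via overlap-add FFT for long days.
* **Degenerate inputs.** Zero-norm samples → invalid elevation (NA),
  never an exception; both-zero jerk → excluded and counted; zero
  reference counts/hours → ratio NA ("undefined is a value, not an
  error"); all-zero paired differences and constant Shapiro samples →
  explicit errors; empty groups → errors; too-small paired samples →
  the comparison is skipped with a warning in the cohort report.
* **Bin edges.** JR bins must divide [0,1] and [1,2] evenly so that 1 is
  an edge and the half-split rule is exact; amplitude bins are
  left-closed `[lo, hi)`.

# Problem sizes in the shipped studies

The simulation studies run at compressed scale chosen so that sampling
noise is small relative to the effects asserted: synthetic days of 2–12
minutes (a day's structure — rest, reaches, a walking bout — without its
dead time), cohorts of up to 20 subjects × 3 days for rank-correlation
recovery of `u`, and 14 subjects × 2 days for the structural stroke-vs-
healthy contrasts. Counts scale linearly with day length, ratios and JR50
are scale-free, so nothing in the method changes with duration; the
day-length parameters are exposed for anyone wanting full-length runs.

# Known limitations

* The elevation angle is gravity-referenced: sustained linear
  acceleration comparable to g corrupts it, and no gyroscope fusion is
  attempted (by design — the method targets accelerometer-only loggers).
* JR50's binning introduces edge effects bounded by one bin's mass; the
  half-split rule removes the worst case (balanced use) exactly.
* The activity-count chain is an emulation of a proprietary lineage, not
  a bit-exact replica; its constants (resolution, band, threshold) are
  configuration, and comparisons across devices should treat UseHours as
  device-convention-bound.
* Bonferroni family sizes are conventions, not derivations; both raw and
  adjusted p-values are reported so other correction choices can be
  applied downstream.
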