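---
title: "Burst-resolved beta analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Burst-resolved beta analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science implemented in `betabursts`: the signal
model behind each stage, the parameters that matter (with units and
defaults), what the synthetic-data generator does and does not emulate, and
the decisions taken where the methodology left genuine freedom. Everything
quantitative stated here is computed by the package's test suite or by
`scripts/acceptance.R`; nothing is asserted about real data.

## The analysis problem

Sensorimotor beta activity (15–30 Hz) around a discrete motor event shows a
characteristic trial-averaged profile: a power decrease during movement
(event-related desynchronization, ERD) and a rebound afterwards
(event-related synchronization, ERS). On single trials this average conceals
a bursty structure: brief (~100–150 ms) high-amplitude envelope excursions
whose probability and timing vary across trials. The pipeline operates on
epoched single-trial time series — trials × samples for one
subject/session/region, sampled at 256 Hz over −2000..+2000 ms, time-locked
so 0 ms is the motor event (the left-hand force peak in the bimanual task
this package was written around) — and quantifies that burst structure.

All windows in the package are half-open, `[start, end)`, in ms relative to
the event. The three analysis windows default to Baseline (−1750..−750),
Movement (−750..250) and Post-movement (250..1250).

## Envelope extraction and thresholding

Each trial is bandpass filtered at the subject's peak beta frequency ±3 Hz
with a 4th-order Butterworth applied forward and backward (`filtfilt`, zero
phase, effective order 8), and the amplitude envelope is the magnitude of
the analytic signal. Envelopes are normalized by the *session-wide mean*
(one scalar per subject–session–region), so the session mean envelope is
exactly 1. A per-trial-mean variant exists behind `normalize = "trial"`, but
the session-wide default is deliberate: the data-driven threshold scan
correlates per-trial burst counts with per-trial mean amplitude, and
per-trial normalization would destroy exactly the across-trial amplitude
differences that correlation needs.

The burst threshold is `median + k * SD` of the envelope, pooled over all
samples of all trials of the set. The pooling level (subject–session–region)
is a design choice: it matches the level at which normalization is defined.
The scan evaluates candidates `k = 0.5..4.0` in steps of 0.1 by default,
computes the Spearman correlation (average ranks on ties) between burst
count and mean amplitude per set, averages the correlation across sets, and
selects the argmax. Sets in which counts (or amplitudes) have zero variance
have no defined correlation; they are excluded from that candidate's average
and counted in the scan output. The reference multiple used throughout the
package's defaults is `k = 1.4`.

Bursts are maximal runs of samples with envelope strictly above threshold.
Offsets are end-exclusive (one sample past the last suprathreshold sample),
so `duration = offset − onset` equals the run length in ms and occupancy
sums exactly over disjoint windows. The burst peak is the maximum envelope
sample within the run, earliest sample on ties. No minimum burst duration is
imposed by default (`min_duration_ms = 0`).

## Burst metrics

*Occupancy (burst probability)* is the mean of the binary suprathreshold
raster over trials and window samples — a fraction in [0, 1], reported as a
percentage at the user's discretion.

*Timing variability*: per trial, the binary raster row is smoothed with a
Gaussian kernel (σ = 50 ms by default; the kernel is truncated at ±4σ and
zero-padded) and the first strict local maximum after 0 ms is taken as the
trial's first post-zero burst-peak time; plateaus resolve to their first
sample, and trials without a post-zero burst are excluded (at least two
retained trials are required). The across-trial sample SD (n−1) of these
times is the timing-variability statistic; their mean is the latency. The σ
of 50 ms is wide enough to merge the sub-burst ripple of a single event and
narrow enough not to merge distinct bursts a gap apart. An alternative
population-level reading of "timing variability" — the dispersion of the
times at which the trial-averaged burst-probability curve peaks — exists in
the literature; the per-trial first-peak definition is implemented as
primary because it yields one value per trial and therefore a well-defined
across-trial SD.

*Amplitude* and *duration* per window average burst peak amplitudes and
durations over the events whose *peak time* falls in the window — bursts may
straddle window boundaries, and assigning by peak is the only choice that
makes every event belong to exactly one window. Empty windows yield `NA`.

## Time–frequency analysis

Morlet wavelets cover 15–30 Hz in 1 Hz steps. The number of cycles grows
nonlinearly with frequency, `cycles(f) = c_min + (c_max − c_min) · ((f −
f_min)/(f_max − f_min))^γ` with defaults `c_min = 4`, `c_max = 8`,
`γ = 0.7`: low beta keeps good temporal resolution while high beta gains
frequency resolution. The exact cycle function is a package choice — only
its qualitative shape (increasing, concave) matters for the analyses the
package performs, and all three constants are configurable.

Power is computed per trial by FFT convolution, squared magnitude, averaged
over trials, and evaluated only on the analysis span (−750..+1500 ms by
default). The epoch must exceed the analysis span by each wavelet's half
support (±3.5 temporal σ); violations raise an error naming the deficit
rather than silently returning edge-contaminated power.

Relative normalization divides each frequency row by its mean over the whole
analysis span and all trials — a whole-epoch relative baseline, which makes
the per-frequency mean exactly 1 and power comparable across sessions. The
session-specific mean is the whole-span mean rather than a pre-stimulus
window because the epochs contain no neutral pre-stimulus segment: the
baseline window itself carries task-related beta.

Peak beta frequency is the argmax over 15–30 Hz of normalized power averaged
over 0..1000 ms (where rebound beta is most prominent), ties broken toward
the lower frequency (deterministic). The estimate from a reference session
is intended to be reused across that subject's sessions. ERD/ERS curves are
band means of relative power; window means use Movement −400..+250 ms and
Post-movement +250..+1000 ms.

## Cluster-based permutation testing

For paired conditions over units (subjects) × features (time samples, or a
frequency × time grid), the per-feature dependent-samples t is thresholded
at the t value with two-tailed tail probability 0.025 at n−1 df; features
with zero-variance differences get t = 0 and a flag. Suprathreshold features
are clustered by adjacency — consecutive samples in 1-D, the 4-neighbourhood
on 2-D grids, or a user-supplied adjacency list (e.g. sensor neighbourhoods
from electrode geometry; the package computes no geometry itself). Each
cluster's statistic is its summed t. The null distribution is the maximum
absolute cluster mass across both signs under within-unit condition
sign-flips (the standard two-tailed max-statistic correction), with
Monte-Carlo p-values using the (b+1)/(m+1) correction so p is never 0; when
the permutation budget reaches 2^n the test switches to exact exhaustive
enumeration. `typeI_harness()` validates the machinery empirically: under
exchangeable null pairs the family-wise rejection rate should sit near α.

## Behavioral scoring

The bimanual task holds a steady right-hand force at 25% MVC (±2%) for a
3-second cursor trajectory while a single ballistic left-hand pulse (also
25% MVC) must hit a target placed at a random angle in [π/4, 2π − π/4]
radians along the circular path. Scoring choices:

- Right-hand validity is the fraction of trajectory samples inside the force
  range; left-hand correctness requires the pulse peak force in range *and*
  the peak within ±125 ms of the target center, boundary inclusive (that is
  the natural reading of "within ±125 ms").
- BPDS combines (1) right-hand stability = RMSE of right force against
  target over `[peak − 226 ms, peak)`, (2) |left peak force − target|, and
  (3) |peak time − target time|, each divided by a scale factor, into a
  Euclidean norm. How newtons and milliseconds are made commensurable is not
  fixed by the method itself; the package takes explicit scale factors
  (recommended: baseline-session across-trial SDs per component) and reports
  them with the result, so absolute BPDS values are meaningful only relative
  to a stated scaling. RMSE (not SD or time-out-of-range) operationalizes
  "stability" because it penalizes both drift and noise around the target.
- The adaptive rule narrows a hand's tolerance once accuracy reaches 80% to
  the smallest interval containing the `ceiling(0.7 n)` responses closest to
  target; below 80% the tolerance is untouched (idempotent). The narrowed
  range is clipped to the current range (narrowing never widens) and a
  degenerate interval (all kept responses identical) is widened to ±0.5% of
  the target magnitude. Left peak = global maximum of the trace, earliest
  sample on ties.

## The synthetic-data generator

No raw EEG accompanies the methodology, so the generator is a first-class
module: it produces epochs whose *measured* burst statistics — under exactly
the reference chain above (bandpass ±3 Hz, Hilbert, session-mean
normalization, threshold median + 1.4 SD) — match programmable targets.

The signal model is a 1/f Gaussian background (power ∝ f^−1 by default,
shaped in the frequency domain) plus Hann-tapered sinusoidal wave packets at
the beta carrier (21 Hz default). Background amplitude is modulated across
the epoch with 100 ms cosine ramps: pre-zero windows carry their own gains,
the post-zero span up to the end of the post-movement window is strongly
suppressed, and the tail beyond it returns to baseline level. The post-zero
suppression is both the synthetic analogue of movement-related beta
desynchronization and a measurement necessity: the first post-zero burst
peak must be governed by the injected packet model, not by background
threshold crossings. Post-zero structure is: one "first" packet whose peak
time follows a truncated-normal timing model, then further packets in a
forward chain with a minimum peak separation that keeps neighbouring
suprathreshold runs from merging under the Hann taper.

Calibration is empirical (simulate–measure–adjust), and several of its
design features come from properties of the chain worth recording:

- *Scale invariance.* Session-mean normalization makes every measured
  statistic invariant to a common scaling of background gains and packet
  amplitudes, so naive independent feedback loops drift along this null
  direction. The post-movement packet amplitude acts as the scale anchor:
  with no explicit amplitude target it is held at a fixed margin above the
  measured threshold (threshold/amplitude = 0.77), which keeps first packets
  reliably detected and detected durations controllable.
- *Channel assignment.* Post-movement occupancy is steered by the packet
  rate (with steps that grow once the chain saturates); pre-zero occupancy
  is rate-primary on top of a background-crossing floor, with background
  gains only ever trimmed downward via the Rayleigh-tail relation
  `log P(crossing) ∝ −(threshold/gain)²`. The timing model is pre-solved
  analytically by inverting truncated-normal moments and then refined by
  feedback.
- *Measurement protocol.* Calibration measures statistics in batches of
  `n_trials` (per-batch normalization and threshold, i.e. exactly one
  simulated subject-session), because thresholds estimated from 55 trials
  are noisy and run lengths are convex in the threshold — calibrating
  against pooled large-n measurements would leave a systematic per-subject
  bias. Convergence requires two consecutive passing full-size iterations so
  a single lucky noisy measurement cannot terminate the servo at the
  tolerance edge.
- *Stated tolerances.* Post-movement occupancy converges to ±0.5 percentage
  points; baseline/movement occupancies to ±1.2 points (these phases are
  scientifically specified only as ranges); duration to ±4 ms; first-peak
  timing SD to ±12 ms and mean to ±30 ms. Default amplitude targets are
  unset: normalized peak amplitude is an emergent property of the mixture
  (it lands near the low-2s under the default conditions), and a servo on it
  (via the packet/background occupancy share) engages only when an explicit
  target is given.
- *Degenerate inputs.* A window with occupancy target 0 is muted outright
  (no packets, zero background gain); with all targets 0 the epochs are
  silent, the threshold is 0, and strict exceedance finds no bursts.
  Occupancy targets that the packet chain cannot reach raise an error naming
  the window.

The default configuration is the early-training study condition:
post-movement occupancy 0.151, duration 134 ms, first-peak timing SD 467 ms
(mean 750 ms, a choice within the post-movement window since the method
itself prescribes no latency), baseline/movement occupancies 0.08/0.06, 55
trials per subject at 256 Hz. The late-training condition used in validation
sets occupancy 0.194, duration 150 ms, timing SD 410 ms.

What the generator does *not* emulate: scalp mixing and volume conduction
(series are "already source-localized"), artifacts (EMG, eye movements),
heavy-tailed or nonstationary background variance beyond the per-window
gains, burst waveform asymmetry or spectral heterogeneity, and cross-region
co-occurrence. Passing parameter-recovery tests therefore demonstrates that
the pipeline measures what it claims to measure on signals with this
statistical structure — not that real EEG satisfies the model. One physical
limit worth noting: with a ±3 Hz band over a 4 s epoch the envelope has only
~24 effective degrees of freedom per trial, so per-trial envelope medians
and SDs fluctuate by roughly 15% even for a stationary background; stability
assertions in the tests use that scale.

## Validation problem sizes

The test suite validates burst detection against an independent run-length
oracle on 1000 random envelopes (exact, event-for-event); the threshold scan
against a naive loop-based reimplementation on a 20-set ensemble (exact);
parameter recovery through the full chain at 27 simulated subjects × 55
trials per condition (tolerances: occupancy ±1.5 percentage points, timing
SD ±35 ms, duration ±10 ms); the ERD/ERS sign property (movement mean < 1 <
post-movement mean of relative beta power) on 20 seeds of a
rebound-enhanced condition; Monte-Carlo versus exhaustive permutation
agreement at n = 6 within 0.05; and the empirical family-wise type-I error
over 500 null repetitions within [0.03, 0.08] at α = 0.05.
`scripts/acceptance.R` reruns the two 27 × 55 recovery conditions end to end
and writes the recovered means as JSON.

## Known limitations

- The calibration servo assumes the default window layout qualitatively
  (a pre-zero baseline, a window spanning 0, a post-zero window named
  `postmove`); exotic window sets may need hand-set internal parameters.
- Timing targets are bounded by the truncated support [30 ms, epoch end −
  50 ms]: first-peak SDs approaching the uniform limit of that interval are
  unreachable, and the calibration will say so rather than approximate.
- The threshold scan's selected multiple on synthetic ensembles depends on
  the injected amplitude mixture; the package never asserts that any
  particular multiple (including the 1.4 reference default) is optimal for
  other data.
- `window_paired_summary()` is a convenience for paired session contrasts;
  full mixed-model inference on the metrics table is out of scope by design
  — the long format feeds `lme4`/`glmmTMB`/`emmeans` directly.
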