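---
title: "From gaze samples to a trait dissociation: the gazedissect pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From gaze samples to a trait dissociation: the gazedissect pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazedissect)
```

## The problem

In visual-search paradigms used in developmental psychiatry, participants
view arrays containing one social target (an image of a human eye region)
among non-social distractors while a remote eye tracker records binocular
gaze at 120 Hz. Two fixation-level measures carry distinct theoretical
loads:

* **latency to first fixation on the eyes** — the time from array onset to
  the start of the first fixation inside the eyes region of interest (ROI),
  indexing bottom-up orienting to social information;
* **first-pass dwell** — the total fixation time inside the eyes ROI from
  first entry until the first exit, indexing maintained engagement (its
  inverse: how quickly the viewer disengages, the "avoidance" half of the
  vigilance–avoidance pattern in social anxiety).

The scientific question the statistics layer serves is a *double
dissociation*: does a dimensional autistic-traits score (SRS raw total)
relate selectively to orienting latency, while a social-anxiety score
(SPAI-C raw total) relates selectively to dwell? Because both trait scores
are measured in the same sample and correlate with each other, comparing
"which trait predicts this measure more strongly" requires a test for
*dependent* correlations — Steiger's Z — rather than an independent-samples
comparison.

`gazedissect` implements the full chain: gaze-log parsing, fixation
detection, trial-level quality control, the two dependent measures, and the
correlation machinery — plus a synthetic-cohort generator that renders
complete 120 Hz recordings with *planted* trait–attention couplings, so
every stage can be validated against known ground truth. The generator is
first-class, tested code: it is the package's substitute for raw participant
recordings, which studies of this kind typically cannot share.

## Fixation detection

Raw samples carry per-eye positions and Tobii-style validity codes (0–1 =
reliably tracked). The pipeline:

1. **Cyclopean combination** (`combine_eyes()`): the mean of the two eye
   positions when both are valid, the single valid eye otherwise, missing
   when neither qualifies.
2. **Gap interpolation** (`interpolate_gaps()`): runs of missing samples
   spanning at most `max_gap_interp_ms` (default 75 ms — roughly a blink's
   leading edge, and long enough to bridge one or two dropped frames) are
   filled linearly and flagged; longer gaps are left missing and always
   terminate a fixation.
3. **Sliding-window mean-difference filter** (`detect_fixations()`): for
   each sample the displacement signal is the Euclidean distance between the
   mean position of the `window_halfwidth_samples` samples before it and the
   mean of those after it (default 5 samples ≈ 42 ms at 120 Hz). Samples
   where this signal exceeds `velocity_threshold_px` (default 35 px) *and*
   is a local maximum are saccade boundaries; on a tied plateau the earliest
   sample wins. Runs of samples between boundaries containing no missing
   span become candidate fixations; adjacent candidates whose centroids lie
   closer than `distance_threshold_px` (default 35 px) are merged, with the
   pooled centroid recomputed until the pass is stable; candidates shorter
   than `min_fixation_ms` (default 60 ms) are then dropped.

Both thresholds are in pixels, not visual degrees or px/s: the "velocity"
threshold applies to the window-mean displacement. This matches the
vendor-style distance/velocity filter family this detector reimplements;
the vendor implementation itself is proprietary and does not document its
window size or gap handling, so both are exposed parameters here rather
than claims about any particular product. Applying the duration floor
*after* merging lets merging legitimately rescue a fixation chopped in two
by a noise spike.

Accuracy of the detector is characterised by its boundary tolerance: on
noise-free step streams the detected boundary falls within
`window_halfwidth_samples` of the true change-point. Down the pipeline this
becomes the tolerance for metric recovery: one sample period (8.33 ms) plus
one window half-width (~42 ms) for latency, and twice the half-width for
dwell, which has an entry *and* an exit boundary.

## Trial quality control and the dependent measures

Each trial is the 500 ms baseline interval before array onset plus the
stimulus window `[onset, offset)`; sample and fixation membership is
half-open at both ends, and a fixation straddling onset or offset is clipped
there for duration accounting. Four inclusion rules apply:

* **anticipatory**: the first fixation on the target starts < 100 ms after
  onset — too fast to be stimulus-driven; the trial is excluded entirely;
* **low_validity**: fewer than 33% of the trial's raw samples have both-eyes
  validity 0–1;
* **baseline_fail**: gaze was at the screen-center rectangle for less than
  50% of the baseline interval (missing samples count against the check —
  the conservative reading of an attention check);
* **no_target_fixation**: no fixation ever lands in the eyes ROI. These
  trials contribute to neither measure, but they *do* count as valid
  recordings in the contrast-eligibility accounting, since the recording
  itself is sound.

ROI membership of a fixation is by centroid (a per-sample-majority variant
is available as `qc_params(roi_membership = "samples")` for sensitivity
analysis). The center rectangle is sized like a stimulus ROI; the paradigm
geometry (1280 × 1024 px screen, four 300 × 224 px stimulus rectangles on
the screen quadrants, eyes position counterbalanced across the 12 arrays)
lives in the ROI config and is a fixture choice, not something any
computation depends on — all thresholds are in pixels.

Participant summaries average each measure over included trials, overall
and by cue condition (silent vs cued), and mark participants with at least
50% valid trials in *both* conditions as eligible for the paired
cued/silent contrast. We equate "valid trial" for this accounting with
passing the three data-quality rules; whether the original accounting also
required a target fixation is not documented, so the pipeline logs the
`no_target_fixation` count separately.

## The statistics layer

For each measure × trait pair the analysis reports the zero-order Pearson
correlation (exact t test, `df = n − 2`) and the first-order partial
correlation controlling the other trait,

$$r_{xy.z} = \frac{r_{xy} - r_{xz} r_{yz}}
  {\sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}, \qquad
  t = r\sqrt{\frac{n-3}{1-r^2}},$$

with pairwise-complete `n` reported alongside every coefficient (a missing
trait score drops a participant from that pair only). Before each pair is
correlated, a Cook's-distance screen on the simple regression of measure on
trait removes bivariate outliers with `D_i > 4/n` (the threshold is
config-exposed; removal is per analysis pair, not global).

Comparing the two traits' correlations with one measure uses Steiger's Z in
the Fisher-transform form with a pooled coefficient:

$$\bar r = \tfrac{1}{2}(r_{12} + r_{13}), \quad
  \bar\psi = r_{23}(1 - 2\bar r^2) - \tfrac{1}{2}\bar r^2
             (1 - 2\bar r^2 - r_{23}^2), \quad
  \bar s = \frac{\bar\psi}{(1-\bar r^2)^2},$$

$$Z = \left(z(r_{12}) - z(r_{13})\right)
      \sqrt{\frac{n-3}{2(1-\bar s)}},$$

with \(z(\cdot)\) the Fisher transform. `Z` is exactly antisymmetric in the
two compared correlations and zero when they are equal; both properties are
enforced by tests. All p values are two-tailed; no multiple-testing
correction is applied; the Shapiro–Wilk screen of every analysis variable is
reported but never gates the pipeline. Rounding matters with these
formulas: evaluated on correlations rounded to two decimals (.57/.35/.36 at
n = 21) they give Z ≈ 0.982 and partial r ≈ 0.508, and the package freezes
those values as formula checkpoints — results computed from unrounded raw
data will generally differ in the second decimal.

## The synthetic cohort

`cohort_params()` encodes the emulated study conditions. Trait scores are
bivariate normal (means 49 and 35.0, SDs 19 and 7.3, correlation 0.36),
truncated at zero and rounded, with SRS subscales generated as noisy
proportional splits. Per-trial latency is lognormal — empirical saccade
latencies are right-skewed — parameterised by mean/SD: 711/268 ms on silent
trials, 611/173 ms on cued trials (the cue conditions differ *only* in this
base latency; no cue-by-trait interaction is planted). First-pass dwell is
lognormal with mean 500 ms. A participant's standardised trait A shifts
their mean latency by `beta_latency` ms per SD (default +60) and trait B
shifts dwell by `beta_dwell` (default −80); standardisation uses the
configured population moments, not sample moments, so the betas keep a
fixed meaning at any cohort size.

Each trial renders as: 1000 ms center animation + 500 ms blank (the last
500 ms forming the baseline interval), then a 5000 ms array — typical
presentation times for this paradigm family; neither duration is stated by
the emulated study, so both are config-exposed. With probability
`p_first_look_target` (0.6) the first look after onset goes straight to the
eyes; otherwise one distractor look precedes it. After the planted dwell
the gaze wanders distractors (200–400 ms hops, never repeating the previous
one) until offset; re-orienting after the dwell is always planted, so
`no_target_fixation` arises only through missingness and ground truth stays
simple. With probability `anticipatory_rate` (0.05) the first target look is
planted before the 100 ms cutoff. Streams are rendered at exactly 120 Hz:
ROI-center positions plus isotropic Gaussian noise (`noise_sd_px`, default
5 px), 2-sample saccade transitions, a constant 20 px binocular disparity
around the cyclopean point, and dropout runs of ~12 samples whose start
rate is solved so the expected missing fraction equals `missingness_rate`
(default 0.10). One master seed derives a per-participant substream, so
cohorts reproduce piecewise and bit-exactly.

**Choosing betas for a target correlation.** A participant's measured mean
over \(n\) trials has between-participant noise SD
\(\sigma_m = \sqrt{\sum_c n_c \sigma_c^2} / n\) under the generator model,
so the trait–measure population correlation is
\(r = \beta / \sqrt{\beta^2 + \sigma_m^2}\) and the beta inducing a target
\(r\) is \(\beta = \sigma_m\, r / \sqrt{1 - r^2}\)
(`beta_for_target_r()`). With the default per-trial SDs this gives
β ≈ +35 ms/SD for latency and ≈ −45 ms/SD for dwell at a target of ±0.5.
Trial exclusions shrink the effective trial count and detector error adds
slightly to \(\sigma_m\), so realised correlations sit a little below the
target — the recovery tests allow ±0.15 for exactly this reason. The
`dwell_sd` default (270 ms) was likewise chosen from this model so the
default dwell coupling produces a moderate correlation at paradigm scale.

## What passing tests do and do not show

The validation suite runs the detector against change-point oracles on
noise-free and noisy step streams, classifies a hand-built 12-trial QC
fixture (one rule violation per trial), recovers planted latencies and
dwells on noise-free cohorts to within the detector's boundary tolerance,
checks the correlation machinery against algebraic identities
(residual-regression equivalence, the leave-one-out form of Cook's
distance, Steiger antisymmetry) and Monte-Carlo calibration (type-I error
within [0.035, 0.065] at α = .05), and recovers the planted double
dissociation across 100 seeded replicates of 100-participant cohorts, with
100 matching null replicates. Under the null the per-replicate correlation
has sampling SD ≈ 0.1 at N = 100, so "centered on zero" is asserted on the
*mean* of the signed estimates (|mean r| < 0.05), not on the mean absolute
value, which no unbiased estimator could keep below its own sampling
dispersion. Problem sizes (120-sample unit streams, 10–100 participants,
100 replicates, 2000-draw calibration runs) were chosen so each property is
tested at the scale where its failure mode would appear.

What this does *not* show: the generator renders clean plateau-and-saccade
gaze with stationary Gaussian noise. Real recordings contain smooth pursuit,
post-saccadic oscillations, drift, blink artefacts with partial-validity
edges, and calibration error that varies across the screen — none of which
are modelled. Passing recovery tests therefore certifies the *pipeline
logic* (segmentation, QC arithmetic, measure definitions, statistics), not
detector performance on pathological real-world signals. Likewise the
planted couplings are linear in the standardised traits; the pipeline would
not detect, and the tests do not probe, nonlinear trait–attention relations.

## Numerical and design choices

* ROI rectangles are half-open on both axes, so a point on a shared edge
  belongs to exactly one rectangle and the stimulus ROIs partition their
  union.
* Timestamps are milliseconds as doubles; trial-relative times are computed
  by subtraction, never stored redundantly. Window membership comparisons
  use a 1 ns slack to keep the 8.33 ms grid stable under floating-point
  arithmetic.
* Displacement-signal ties pick the earlier sample as the boundary, making
  segmentation deterministic.
* Degenerate inputs fail loudly: zero-variance correlation inputs, constant
  regression predictors, identical-difference paired tests, `s̄ ≥ 1`
  Steiger configurations and sub-minimum sample sizes are errors, not
  silent `NA`s.
* Trials excluded by anticipation lose both measures (the rule discards the
  trial, not the measurement); `no_target_fixation` trials lose both
  measures but keep their validity standing.
* The association analysis aborts below 10 complete participants rather
  than returning unstable coefficients.

## Limitations

The detector is a single member of the distance/velocity filter family;
I-VT/I-DT variants with degree-based thresholds are out of scope, as are
saccade kinematics, pupillometry and time-course analyses. The statistics
layer implements exactly the analysis set described above; it applies no
multiple-testing correction and offers no robust-correlation fallback, by
design. Monitor geometry is carried in the config but unused — a study
whose thresholds are specified in visual degrees would need a conversion
layer this package deliberately omits.
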