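---
title: "Measuring articulatory kinematics and coordination variability in repeated sentence productions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring articulatory kinematics and coordination variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(artikin)
```

## The measurement problem

When a speaker repeats a short sentence such as *"Buy Bobby a puppy"*,
the upper lip, lower lip and jaw execute a rapid sequence of oral
opening and closing movements. Optical tracking of lip markers at
250 Hz turns each repetition into displacement trajectories from which
two families of measures are computed:

* **Magnitude measures** — how far and how fast the articulators move:
  per-movement displacement amplitude, peak velocity and duration for
  target syllables, and phrase-level *dynamic ranges* (the central 80%
  span of the displacement and velocity sample distributions over the
  whole utterance, the articulator's operating range).
* **A coordination-consistency measure** — the lip-aperture (LA)
  variability index: how repeatable the time course of oral aperture
  is from one repetition of the sentence to the next.

These measures are used to compare groups of preschool children who
stutter with fluent peers in a 2 (group) x 2 (sex) between-subject
design with repeated measures on within-subject factors (movement
direction, syllable, sentence). `artikin` implements the whole chain —
raw marker tables to group statistics — together with a gestural
simulator that generates data with known ground truth, so that every
stage can be validated quantitatively without access to child
recordings, which are not publicly deposited.

## Pipeline and assumptions

### Head-motion correction

Lip markers are measured in room coordinates, so head motion
contaminates them. With at least three non-collinear head-mounted
reference markers, each frame's head configuration is registered to a
reference frame (the first frame of the trial) by a least-squares
rigid transform — rotation plus translation, no scaling — obtained
from the SVD-based orthogonal Procrustes solution. Applying the
per-frame transform to a lip marker expresses it relative to the
skull; any motion common to all markers cancels exactly (verified to
below 1e-6 mm end to end on simulated trials with programmed head
motion). Assumptions: the head-marker set is rigid (residual RMS per
frame is reported and flagged above 1 mm), and the head-frame axes
inherit the laboratory axes at the reference frame, so
superior-inferior is laboratory +z at that posture. No anatomical
re-axing is attempted.

### Smoothing and differentiation

Displacement is low-pass filtered with a 4th-order Butterworth applied
forward and backward (zero phase; `filter$cutoff_hz`, default 10 Hz —
the convention in orofacial kinematics, since articulatory content in
this task lies below ~8 Hz). The implementation pads the signal with
an odd-symmetric reflection plus constant lead-in blocks long enough
for the slowest filter pole to decay, so a constant input is
reproduced exactly and in-band signals are undistorted at the trial
edges. Velocity is obtained by central differences (exact for linear
signals; truncation error is negligible at 250 Hz for sub-10-Hz
content).

One consequence worth knowing: zero-phase smoothing broadens each
gesture's velocity pulse by roughly the filter kernel width. When
adjacent opening/closing pulses are separated by holds shorter than
about 50 ms — which happens under trial-to-trial timing jitter — the
overlapping tails can shift a velocity extremum by about one frame
(4 ms) and stretch zero-crossing landmarks into the holds. Peak
*counts* are unaffected; movement-cycle boundaries therefore use a
small velocity tolerance (2% of the trial's peak speed) rather than a
strict sign change, and validation against simulator ground truth
allows 1.5 frames under the full variability model.

### Segmentation

With +z superior, oral opening drives the lower lip downward, so each
opening movement produces a negative lower-lip velocity peak. A
five-opening sentence is segmented from its first to its fifth
negative opening peak, found as local velocity minima whose depth
exceeds `segmentation$prominence_frac` (default 0.10) times the
trial's maximum absolute velocity. If more than five qualify, the five
most prominent are used in temporal order; fewer than five is a loud
per-trial error — the original workflow resolved such cases by eye,
and an explicit threshold plus an error path is the scriptable
substitute. Both lips are cut at identical indices; the lower-lip
velocity defines the cut. Opening/closing cycles for target syllables
are extracted around configured cycle ordinals
(`segmentation$cycles`, default Bob = 2, pup = 4 — the published trace
figures mark the cycles graphically but not ordinally, so this is
configuration, not inference).

A repetition set enters analysis only with at least
`analysis$min_trials` (7) valid repetitions, and at most the first
`analysis$max_trials` (10) are used — mirroring the 7–10 fluent
productions retained per child in the emulated study.

### Kinematic measures

* amplitude: |displacement(offset) − displacement(onset)| per cycle
  (cycles are monotone between velocity zero-crossings, so this equals
  the peak-to-trough extent up to noise);
* peak velocity: max |velocity| within the cycle (mm/s);
* duration: (offset − onset) / sample rate;
* dynamic range: percentile(50 + 40) − percentile(50 − 40) with
  linear-interpolation (type-7) percentiles — the central-80%
  interpretation of "80% of points", computed on signed velocity by
  default (`dynamic_range$velocity_signed`); a dense sinusoid of
  amplitude A gives 2A·sin(0.4π) ≈ 1.9021A, the closed form used in
  the tests;
* sentence duration: span between the bounding opening peaks,
  (n_frames − 1)/rate — the off-by-one convention is stated because it
  differs between implementations.

Per-participant values are arithmetic means over trials. A configured
normative screen (`exclusion$normative`, `k_sd` = 3) flags
participants whose dynamic ranges exceed a normative mean by more than
3 SD as measurement artifacts; normative values come from outside this
package and default to off.

### The LA variability index

For each repetition the lip-aperture signal LA(t) = upper(t) −
lower(t) is computed sample-by-sample on the segmented traces, then
projected onto 1000 equally spaced relative-time points with an
interpolating cubic spline, then standardised to mean 0, SD 1
(population SD). The across-trial standard deviation (sample SD,
n − 1) is evaluated at 2% increments of relative time — realised as
every 20th sample of the 1000-point axis, 50 values — and summed.
Higher sums mean less repeatable coordination. Whether the grid should
also include relative time 0 cannot be settled from published
descriptions; both variants are supported (`sti$include_zero`) and
differ negligibly.

The definition has sharp invariances, all tested: the index is 0 for
identical repetitions, invariant to per-trial positive affine
amplitude transforms (amplitude normalisation removes them), to
uniform time dilation of any trial (time normalisation removes it),
and to trial order; it strictly increases with injected timing jitter.
The SD conventions (population within trial, sample across trials) are
fixed so that an independent brute-force implementation matches to
1e-9.

### Group statistics

Levene's test (classic, mean-centred — the variant implied by an
unqualified "Levene's test") screens variance homogeneity before each
ANOVA. The mixed-design ANOVA is computed as a univariate split-plot:
between-subject effects are tested on per-subject means and each
within-subject effect (and its interactions with between factors) on
per-subject difference scores, with Type-III (sum-to-zero) tests so
unbalanced between cells are handled on an unweighted-means basis.
Within factors are restricted to 2 levels — all within factors in this
design (direction, syllable, sentence) are 2-level, which also makes
sphericity corrections moot. On balanced designs the implementation
reproduces `aov`'s error-stratum F values to 1e-9; its interaction
type-I error is calibrated to 0.05 by simulation at the study's
unbalanced cell sizes. Post hocs use the Tukey-Kramer studentised
range with the unequal-n standard error; with two equal-n groups it
collapses to the pooled t test exactly. Pearson correlations among
measures (pairwise deletion) and a pooled-variance t test by therapy
history complete the workflow.

## The simulator

`generate_trial()` builds a lower-lip trace as five minimum-jerk
opening/closing gestures — x(τ) = D(10τ³ − 15τ⁴ + 6τ⁵), chosen for its
closed-form peak velocity 15D/(8T) rather than physiological fidelity;
the shape is a plumbing choice, not a claim about motor control. The
upper lip counter-moves at a configurable gain (default 0.3), so lip
aperture is dominated by the lower lip, qualitatively matching
published traces. Head markers are static in the head frame, with
optional programmed rigid head motion composited onto all markers.

Template defaults are chosen once to sit inside the reported preschool
ranges: openings of 6.2–8.4 mm over 0.14–0.16 s (cycle 2 largest,
"Bob"; cycle 4 smallest, "pup"), closings slightly smaller and faster,
40 ms holds, ~1.23 s from first to fifth opening peak (reported
preschool mean ≈ 1.24 s), peak velocities of 75–190 mm/s.

Trial-to-trial variability has four orthogonal knobs
(`variability_model()`): a per-trial multiplicative amplitude factor
(CV 0.15), per-gesture onset jitter with durations intact (SD 20 ms),
a per-trial tempo factor (CV 0.05), and additive measurement noise
(0.1 mm, low-passed at 30 Hz). The separation is deliberate: amplitude
and tempo scatter are exactly removed by the LA normalisations, so
only jitter (phase variability) and noise raise the LA index — a
testable consequence the suite asserts. Jitter configurations that
would overlap adjacent gestures are resampled (up to 50 attempts), so
realised jitter is mildly truncated at high settings.
`generate_cohort()` draws each participant's gesture scale from their
design cell (default cells 43/14/27/13 with male-stutter scale 0.83,
emulating the observed displacement-dynamic-range contrast) and
threads all randomness from one root seed through per-participant and
per-trial derived seeds.

What the simulator does *not* emulate: articulator-specific dynamics
(the upper lip is a scaled mirror of the lower lip), phonetic
segmental structure, disfluencies, drift or non-rigid facial-tissue
motion, and marker dropout beyond injected NaN runs. Passing tests
therefore demonstrate that the pipeline measures what it claims on
signals with the assumed structure — not that the assumed structure
exhausts real child speech.

## Numerical choices and degenerate inputs

* Percentiles: R type 7 (linear interpolation), stated in results
  metadata.
* Spline: `stats::spline` (Forsythe–Malcolm–Moler end conditions);
  endpoints are knots, hence preserved exactly.
* Zero-variance LA trials (flat aperture) are a normalisation error —
  such a trial is unanalysable and aborts with its trial id.
* All-identical statistical inputs report F = 0, p = 1 rather than
  0/0.
* Dropout: NaN runs of at most 5 frames (20 ms, well under one
  movement cycle) are linearly interpolated and counted; longer runs
  or boundary dropouts invalidate the trial. This is a stated
  convention — the original capture system's handling is undocumented.
* Rotation recovery enforces det = +1 (reflection-corrected SVD);
  collinear head markers are rejected up front.

## Worked example

```{r example}
set.seed(1)
sc <- gesture_score()
trials <- lapply(1:8, function(i)
  generate_trial(sc, variability_model(), trial_seed = 1000 + i,
                 participant_id = "P01"))
out <- run_participant(trials, "P01", "BBAP")
round(t(out$record[, c("displacement_dynamic_range",
                       "velocity_dynamic_range", "sentence_duration",
                       "la_index")]), 2)
```

```{r laplot, fig.height = 6}
segs <- lapply(trials, function(tr) artikin:::process_trial(tr, default_config()))
plot(la_index(trial_set("P01", "BBAP", segs)))
```

## Problem sizes used in validation

The shipped test-suite and acceptance-script runs use: 200-trial
segmentation-recovery batches per noise level; 50 seeds x 10 trials
per timing-jitter level for LA monotonicity (15 in the script); 2000
null replicates for ANOVA and Levene calibration; 200 replicates at
the emulated cell means/SDs/sizes (43/14/27/13, SD 2.45) for
interaction detection; and one full-pipeline cohort of 97 simulated
participants x 8 trials. These sizes were chosen so Monte-Carlo error
is small relative to each acceptance band.

## Known limitations

* Detection power for the group-by-sex interaction at the emulated
  effect size (cell means 8.3/9.4/10.0/8.6 mm, SD 2.45, unbalanced ns)
  is analytically ≈ 0.60 at α = 0.05; simulations land there. A single
  cohort of this size should not be expected to replicate the
  interaction reliably.
* The mixed ANOVA supports only 2-level within factors; general
  repeated-measures designs need a dedicated package.
* Zero-phase smoothing shifts velocity landmarks by up to ~1 frame
  when gestures crowd together; syllable-level durations are
  correspondingly filter-dependent, which is why validation is against
  simulator ground truth rather than published group tables.
* The LA index deliberately leaves timing variability in (no curve
  registration); it conflates phase and shape variability by design.
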