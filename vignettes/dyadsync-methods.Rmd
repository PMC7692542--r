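---
title: "Quantifying nonverbal synchrony and predicting interpersonal attraction with dyadsync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nonverbal synchrony and predicting interpersonal attraction with dyadsync}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When two people interact, their nonverbal behavior becomes temporally
linked: one partner's movements lead or trail the other's by fractions of
a second to a few seconds.  This *interactional synchrony*, together with
each person's individual movement profile, carries information about the
interaction — including how much the partners like each other.  dyadsync
implements a complete, testable pipeline for quantifying this from
markerless motion tracking of dyads:

1. **Preprocessing** of non-uniformly sampled skeletal joint positions
   (17 upper-body joints × x/y/z, nominal 30 Hz) and facial blendshape
   activations (52 channels in [0, 1]), plus head rotation and gaze.
2. **Extent-of-movement** metrics: per-frame Euclidean joint
   displacement (body) and mean deviation from the neutral face.
3. **Windowed lagged cross-correlation** synchrony with summary scores.
4. **Questionnaire outcomes**: an 8-item interpersonal-attraction
   composite, impression accuracy as a self–observer profile
   correlation, and affective valence as a positive-minus-negative
   emotion-word percentage.
5. A **candidate feature layer** (878 named features per participant),
   **correlation-based feature selection (CFS)** followed by **SVM
   recursive feature elimination**, and **random-forest / multilayer-
   perceptron classification** of high vs. low attraction under a median
   split.

Because raw dyadic motion-tracking corpora of this kind are not publicly
deposited, the package ships a synthetic dyad generator with fully known
ground truth; every stage of the pipeline is validated against it and
against independent oracles.

## Preprocessing model

Raw streams arrive with non-uniform timestamps and tracking dropouts.
`interpolate_uniform()` maps them onto a uniform grid (default 30 Hz) by
linear interpolation between valid frames.  Two deliberate choices:

* **Gap limit** (`max_gap_s`, default 0.2 s = six nominal frames).
  Interpolating across long dropouts would fabricate motion, so grid
  frames bracketed by samples further apart than the limit are marked
  invalid rather than filled.  Those invalid frames then feed the
  window-validity rule below, which is the pipeline's mechanism for
  discarding badly tracked stretches.
* **No extrapolation**: frames before the first or after the last valid
  sample are invalid.

Body streams are then smoothed with a **second-order zero-phase
Butterworth low-pass at 6 Hz** (`butterworth_zero_phase()`): the filter
runs forward and backward, which cancels its phase (so synchrony lags are
not biased) and squares its magnitude response (the two-pass amplitude
ratio at the cutoff is exactly 0.5).  Facial streams are interpolated and
downsampled but not low-pass filtered by default (`filter_faces` turns it
on); blendshape activations are already bounded, slowly varying channel
weights rather than noisy positional data.  Numerically, the filter is
applied per contiguous valid run with odd-reflection padding so the
recursion has settled before real samples begin; runs shorter than three
filter startup lengths pass through unfiltered and are flagged.  Sub-
nanometer per-frame displacements are rounded to exactly zero, because
zero-phase filtering of constant coordinates leaves ~1e-11 ripple that
would otherwise masquerade as (perfectly correlated) motion.

Synchrony operates at 10 Hz (`downsample_series()`), on **consecutive,
non-overlapping 100 s windows** anchored at the session start.  A window
is kept only if at least 90% of its frames are valid — and, for a dyad,
only if it is kept for *both* partners (the conservative conjunction).

## Extent of movement and joint angles

Body extent is the per-frame Euclidean displacement of each joint at
30 Hz (`frame_displacement()`); the composite is the mean across the 17
joints, and a composite frame is valid only when all 17 joints are valid
in both frames of the difference — partial-joint means would shift the
composite's scale across frames.  Face extent averages left/right channel
pairs into 34 single items, excludes items whose variance falls below
`low_variance_threshold` (default 1e-4; near-constant channels mostly
carry spurious tracking values), and averages the rest
(`face_extent()`).

Ten joint angles (elbows, shoulders, wrists, hands, neck, spine) are
defined as ordered joint triples with the angle at the middle joint
(`default_angle_defs()`, configurable).  Extent and angles are invariant
under rigid transforms of the skeleton, and extent scales linearly with
coordinates; the test suite asserts both.

## Windowed lagged cross-correlation

For each kept window and each lag on a grid (±5 s for body, ±1 s for
face, step 0.1 s), `windowed_crosscorr()` computes the Pearson
correlation between `x(t)` and `y(t + lag)` over samples where both
series are valid and both time points fall inside the window.  Positive
lags mean the second partner trails the first.  Cells with fewer than
`n_min_overlap` (default 50 samples = 5 s at 10 Hz) jointly valid
samples are missing, never imputed: tiny overlaps produce high-variance
correlations.  Five summaries aggregate the non-missing cells jointly
over windows and lags: mean, absolute mean, nonnegative mean, maximum,
and the *signed* value of the largest-magnitude cell (absolute maximum).
The per-lag profile (mean over windows) is retained: genuine synchrony
decays toward zero as the lag moves away from the true coupling lag,
which is the standard robustness diagnostic.

Internally the masked correlation sums for all lags are obtained from
FFT cross-correlations of the zero-filled series and their validity
masks, which is algebraically identical to the direct double loop; the
test suite holds the two within 1e-9 on hundreds of random masked
series.

## The synthetic dyad generator

The generator's central device is a scalar **movement drive** per
participant.  A shared smooth band-limited nonnegative process `g(t)`
(bandwidth 1 Hz, well below the 6 Hz cutoff) couples the partners:

```
drive_A(t) = c + g(t) + e_A(t)
drive_B(t) = c + a * g(t - tau) + sqrt(1 - a^2) * e_B(t)
```

with independent smooth noises `e_A`, `e_B` matched in variance to `g`,
coupling strength `a` in [0, 1] and lag `tau`.  The lagged correlation
of the drives peaks at `tau`, by construction.

The drive is propagated to the skeleton so that the *extent* series —
the input of body synchrony — inherits the coupling exactly: each joint
orbits its template position on a randomly oriented circle (radius
0.15 m), advancing per frame by an arc length `gain * drive / rate`,
with a smoothly switching direction sign.  Per-frame displacement is
therefore proportional to the drive, positions stay anatomically bounded
without mean-reversion terms, and the ground-truth lagged correlation is
analytically controlled.  Facial channels receive sparse
attack–sustain–decay activation pulses; partner B mimics each of A's
events with probability `a` at delay `tau` and adds independent events
at the complementary rate, so the event rate itself carries no coupling
information.  Timestamps are the nominal 30 Hz grid plus truncated
jitter (SD 4 ms, bounded below half a frame so time stays monotone),
with geometric-length dropout runs deleted (5% of frames by default).

Latent attraction is a standard-normal dyad variable.  With effect size
`e` (`attraction_effect_size`), one SD of latent attraction shifts the
dyad's coupling strength by `0.15 e` and multiplies its movement gain
and facial event rate by `exp(0.3 e)` — so the attraction signal reaches
the classifiers only through the movement features, as in real data.
Questionnaire items load on the latent variable and are discretized to
the 1–7 Likert scale by rounding with clamping; observer personality
ratings add noise with SD `observer_noise_sd` (0 makes impression
accuracy exactly 1).  A seed hierarchy (cohort seed → dyad seeds →
stream seeds) makes any single dyad reproducible in isolation.

What the generator deliberately does *not* emulate: sensor-specific
noise spectra beyond jitter and dropout, posture semantics (gestures are
isotropic orbits), facial co-articulation structure, or condition
effects of avatar visibility (the 2×2 design cells are carried as
metadata and balanced, but do not modulate the streams).  Passing tests
therefore demonstrate that the *pipeline machinery* recovers known
coupling, lags, and latent-attraction effects — not that any particular
behavioral theory holds in real interactions.

## Feature layer and classification protocol

`participant_features()` assembles 878 uniquely named candidates:
five synchrony summaries for the composite body extent, each of 17
per-joint extents, each of 10 joint angles, the composite face series
and each of 52 unmerged facial channels (405); six statistics (mean, SD,
gradient mean/SD/max, second-gradient max) per joint coordinate (306);
mean/SD of per-joint displacement per 0.1 s computed from the 10 Hz
series (34); four statistics per joint angle (40); head-rotation and
gaze statistics (12 + 4); mean/SD per merged blendshape item (68);
per-stream tracking validity and longest missing run (8); gender (1).
Gradients are signed first differences in per-second units; the
"maximum" statistics are signed maxima.  Left/right facial channels
enter the mean/SD block merged but the synchrony block unmerged, so
asymmetric mimicry remains visible.  Missing features are explicit
`NA`s; columns missing in more than half the cohort are dropped, and the
remainder are median-imputed with a count kept in the table attributes.

The classification protocol (`classify_attraction()`):

1. **Median split** of the attraction composite; ties go low
   (strictly-above defines "high").
2. **70/30 train/test partition**, stratified by class.  By default both
   members of a dyad land on the same side of every split and every CV
   fold, because dyad members share their synchrony features —
   splitting a dyad would leak test information into training.  A
   participant-level mode (`group_by_dyad = FALSE`) is available.
3. **CFS** (greedy forward search on the merit
   `k r_cf / sqrt(k + k(k-1) r_ff)`) followed by **SVM-RFE** (linear
   soft-margin SVM on standardized features, removing the
   smallest-|weight| feature per step) down to 23 features, both fitted
   on training rows only.
4. **Five-fold cross-validation** on the training set, then a final fit
   and one evaluation on the untouched test set: accuracy, confusion
   counts, sensitivity, specificity, and the majority-class baseline of
   the test labels.

Hyperparameters live in `pipeline_config()`.  The random forest uses
500 trees, 20 candidate features per split, at least 7 samples per leaf,
depth capped at 10 (`maxnodes = 2^10`), bootstrap resampling, fixed seed
30; `randomForest` splits on the Gini criterion (it implements no
entropy option).  The MLP is a single hidden layer of 50 logistic units
with L2 penalty 0.03 and at most 200 iterations on features standardized
by training-set statistics, fixed seed 30; `nnet` optimizes the entropy
loss with BFGS rather than a stochastic Adam optimizer, so batch-level
parameters have no analog — with convergence the fitted optimum is the
same penalized-likelihood target.  Non-convergence within the iteration
budget is reported as a warning and the model is still returned.

## Numerical and design choices

* Correlation cells whose variance is at round-off scale relative to the
  sum of squares are treated as undefined (constant segments have no
  correlation); they surface as `NA`, never as 0.
* The lag step must be a whole number of samples at the synchrony rate
  (0.1 s at 10 Hz = 1 sample); anything else is an error, not a silent
  rounding.
* CFS's merit grows like sqrt(k) over equally weak uncorrelated
  features, so on pure noise the greedy search may select several
  features while the merit stays near zero; the informative-feature
  guarantees (tested) are what matter downstream, and SVM-RFE bounds
  the final set size.
* Median imputation never alters observed cells (asserted bit-exactly).
* All randomness flows through explicit seeds; two runs with the same
  seed produce bit-identical feature tables, reports, and fitted-model
  predictions.

## Validation study sizes

The test suite validates the pipeline at the study scale of 124 dyads
(248 participants) with 110 s sessions — one full 100 s analysis window
plus margin — at 30 Hz.  Lag/strength recovery is checked against a
100-replicate Monte-Carlo oracle of the drive model (longer 333 s
series); the end-to-end classification check runs 20 replicate cohorts
at effect size 0.8 (both classifiers must beat the majority baseline by
at least 5 points in at least 90% of replicates) and a null control at
effect size 0 (accuracy within 3 standard errors of baseline, which
also guards against train/test leakage).  Session length and replicate
counts are the package's validation choices: one window per session is
the minimal configuration in which the windowing, validity screening,
and synchrony machinery all operate exactly as at larger scales.

## Known limitations

* The facial-synchrony composite uses the variance-screened merged
  channels; per-channel synchrony features are computed unmerged.  Both
  readings of "facial synchrony" are therefore available, but the
  headline face synchrony number refers to the composite.
* The generator's attraction effect is monotone and linear in the latent
  variable; it cannot probe nonlinear attraction–behavior relationships.
* Sessions much longer than a few windows increase memory linearly; the
  cohort runner streams dyads one at a time, so cohort size is limited
  by time, not memory.
* Impression accuracy uses pairwise-complete items with a floor of 5
  complete pairs; profiles with fewer observer judgments are missing
  rather than guessed.

## A minimal run

```{r, eval = FALSE}
library(dyadsync)
scfg <- synth_config(duration_s = 110, coupling_alpha = 0.6,
                     coupling_lag_s = 0.2, attraction_effect_size = 0.8,
                     seed = 11)
report <- run_pipeline(16, scfg, seed = 11)
print(report)
prof <- report$synchrony$body_profile
plot(prof$lag_s, prof$mean_r, type = "l",
     xlab = "lag (s)", ylab = "mean cross-correlation")
```
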