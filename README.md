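# dyadsync

Quantifies nonverbal behavior in dyadic interactions from markerless
motion tracking, and tests whether automatically tracked nonverbal cues
predict interpersonal attraction.

When two people converse, their body and facial movements become
temporally linked.  dyadsync measures this *interactional synchrony* —
together with each person's individual movement profile — from skeletal
joint positions (17 upper-body joints × x/y/z at a nominal 30 Hz) and
facial blendshape activations (52 channels in [0, 1]), and feeds the
result into a feature-selected classification of high vs. low
interpersonal attraction.  It is aimed at researchers in computational
behavioral science working with depth-camera / face-tracking recordings
of interacting pairs.

## The method

**Preprocessing.** Non-uniform streams are linearly interpolated to
30 Hz (tracking gaps longer than 0.2 s become invalid frames instead of
fabricated motion), body streams are smoothed with a second-order
zero-phase Butterworth low-pass at 6 Hz, and synchrony operates at 10 Hz
on consecutive non-overlapping 100 s windows, keeping a window only if
at least 90% of its frames are valid for *both* partners.

**Extent of movement.** Body: per-frame Euclidean displacement of each
joint, averaged over the 17 joints into a composite.  Face: left/right
channel pairs merged, low-variance channels excluded, the rest averaged
as deviation from the neutral position.

**Synchrony.**  For window *w* and lag τ on a grid (±5 s body, ±1 s
face, step 0.1 s),

&nbsp;&nbsp;&nbsp;&nbsp;*r*(*w*, τ) = corr( *x*(*t*), *y*(*t* + τ) )

over jointly valid samples inside the window.  Five summaries — mean,
absolute mean, nonnegative mean, maximum, signed absolute maximum — plus
the per-lag profile, whose decay away from the true lag is the standard
robustness diagnostic.

**Outcomes.** Attraction = mean of 8 Likert items (reliability via
Cronbach's α); impression accuracy = Pearson profile correlation between
a target's 15-item self-rated personality and the partner's observer
ratings; affective valence = positive − negative emotion-word
percentage.

**Classification.** 878 named candidate features per participant
(synchrony summaries per joint/angle/facial channel, coordinate and
angle statistics, head/gaze statistics, tracking-validity measures,
gender) → median split of attraction → 70/30 dyad-grouped stratified
partition → correlation-based feature selection, then SVM recursive
feature elimination to 23 features (training rows only) → five-fold
cross-validation and held-out evaluation of a 500-tree random forest and
a 50-unit logistic MLP, reported against the majority-class baseline
with sensitivity/specificity.

Because corpora of this kind are not publicly deposited, the package
includes a synthetic dyad generator with analytically controlled
coupling strength and lag and a latent-attraction effect expressed only
through the movement features; the whole pipeline is validated against
it and against independent oracles (see the methods vignette in
`vignettes/dyadsync-methods.Rmd`).

## A worked example

```r
library(dyadsync)
scfg <- synth_config(duration_s = 110, coupling_alpha = 0.6,
                     coupling_lag_s = 0.2, attraction_effect_size = 0.8,
                     seed = 11)
report <- run_pipeline(16, scfg, seed = 11)
print(report)
#> <run_report> 16 dyads (32 participants), seed 11
#>   kept windows: body 16, face 16; dyads without windows: 0
#>   mean synchrony: body 0.017, face 0.256
#>   rf  cv 83.33% (SD 20.41%), test 50.00% (baseline 50.00%)
#>   mlp cv 100.00% (SD 0.00%), test 50.00% (baseline 50.00%)

prof <- report$synchrony$body_profile
prof$lag_s[which.max(prof$mean_r)]   # peak of the lag profile: 0.2 s,
max(prof$mean_r)                     # r = 0.379
```

Reading the output: each of the 16 dyads contributed one kept 100 s
window per channel; the cohort's mean windowed cross-correlation is
higher for faces (0.256) than bodies (0.017) because facial mimicry
events are sparse and sharply coupled while body coupling spreads over
the ±5 s lag grid.  The body lag profile peaks at +0.2 s — the
generator's configured coupling lag — with mean r 0.379 at the peak.
Cross-validation accuracy is far above the 50% baseline, while the test
accuracy of a 10-participant held-out set is noisy at this toy size; at
the realistic scale of 124 dyads, both classifiers' cross-validation
*and* test accuracies run 15–25 points above baseline (see
`scripts/acceptance.R` output).

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/dyadsync.R run --n-dyads 16 --seed 11 --out run_out
Rscript inst/scripts/dyadsync.R generate --n-dyads 4 --seed 1 --out raw_out
```

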