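---
title: "Methods: ocular metrics, synthetic cohorts and risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ocular metrics, synthetic cohorts and risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocufatigue)
```

# Scope and data model

`ocufatigue` analyses brief (one-minute) binocular eye recordings to detect
short-term deterioration of asthenopia. The atomic data object is the
`ocular_trace`: a per-frame, per-eye time series of palpebral fissure
length (eyelid aperture, pixels), pupil diameter (pixels), pupil centroid
(pixels) and a validity flag that is `FALSE` wherever the pupil is not
visible. Recordings follow the convention of 30 frames per second and 1800
frames (exactly one minute); a participant *session* couples a pre-task and
a post-task recording with CVS-Q questionnaire scores and critical flicker
fusion (CFF) values. Everything downstream consumes either traces directly
or per-frame segmentation masks converted to traces by `trace_from_masks()`.

All analysis is restricted to frames 200–1800: the first 200 frames are
discarded to avoid initial eye-opening artefacts. Windowed variability
features additionally use the sub-windows 200–600 ("early"), 600–1200
("mid") and 1200–1800 ("late"), which correspond to the three increasing
difficulty segments of the standardised reading task. Windows are half-open
`[start, end)` on 0-based frames; the boundary frame 600 belongs to the mid
window, not the early one.

# Metric definitions and numerical choices

**Blink detection.** No published detection rule accompanies the metric
definitions, so the package aligns blinks with the PERCLOS criterion: the
open-eye baseline is the 95th percentile of the fissure signal, and a blink
is a maximal run of at least 2 consecutive frames with aperture at or below
20 % of that baseline (i.e. at least 80 % closed). The minimum-run rule
rejects single-frame segmentation noise. Consequences: PERCLOS (the
percentage of analysed frames at least 80 % closed) is always at least the
blink-frame fraction, with equality when closure frames occur only inside
runs of two or more — a property the test suite checks. A trace that is
never open returns no blinks with a warning rather than an error.

**Blink metrics.** Blink rate is events per minute of analysed time; blink
duration is `(end − start + 1) × 1000 / fps` ms; the blink interval is
offset-to-onset (end of blink *i* to start of blink *i + 1*), which is one
of several readings of "time between consecutive blinks" — chosen because
it is the tear-film-relevant open interval. Fewer than two events yield an
`NA` interval rather than a fabricated number.

**Fixations.** Dispersion-threshold identification (I-DT) with a 15 px
bounding-box threshold (`max(range x, range y)`) and a 100 ms minimum
duration, both configurable; invalid (blink) frames terminate a window.
I-DT was chosen over velocity-based classification because centroid noise
at 30 fps makes frame-to-frame velocities unreliable.

**Pupil metrics.** "Pupil size" is operationalised as the area-equivalent
diameter of the pupil mask, `2·sqrt(area/π)` pixels. Constriction speed uses
only negative diameter steps (`v = Δdiameter × fps < 0`); dilation steps are
excluded from both the maximum and the mean, resolving an ambiguity in the
prose definition in favour of the word "constriction". Movement distance
sums Euclidean centroid steps over pairs of consecutive valid frames; pairs
spanning a blink contribute nothing.

**Variability.** Sample SD (n − 1), variance and the coefficient of
variation `100·sd/mean` (percent) per window and signal. Invalid frames are
excluded for the pupil signal (the pupil does not exist during a blink) but
included for the fissure signal (the aperture does). Fewer than two valid
samples give `NA`; a non-positive mean gives an `NA` CV.

**Feature vectors.** Every metric is computed separately on the pre- and
post-task recordings and differenced (post minus pre); raw signals are never
subtracted point-wise. Pupil metrics and movement distance are averaged
over the two eyes. Blink, PERCLOS and fixation metrics use a single primary
eye (default left): the source tables footnote only pupil and movement
metrics as both-eye averages, and binocular blink events are shared anyway.
Variability features use the per-frame binocular mean signal.

# The synthetic cohort as a stated world

No recordings are distributed with the package, so a simulator provides the
inputs. It is a first-class, tested module, and its defaults are fixed
once, not tuned to outcomes:

* Recording: 30 fps, 1800 frames. Blinks: 15/min at rest, duration
  Normal(120, 30) ms — blinks are brief (~100–150 ms) — realised as a
  trapezoidal aperture drop (2-frame close and open ramps around a plateau
  at 5 % of baseline). The ramps stay above the 20 % closure criterion so
  the detected run equals the injected closure exactly, which is what makes
  noise-free parameter recovery an *exact* test rather than a tolerance
  test.
* Fixations: Gamma-distributed plateaus around 250 ms (typical reading
  fixations) separated by saccades of 0.9–1.5 × 20 px with a dominant
  horizontal component. The dominant component guarantees every saccade
  exceeds the default I-DT dispersion in Chebyshev distance, again making
  noise-free plateau recovery exact.
* Pupil: 30 px mean, 0.5 px sinusoidal oscillation with a 5 s period
  (slow hippus), 0.5 px Gaussian frame noise. Eyelid aperture: 40 px mean,
  1.5 px frame noise.
* Group effects (post-task vs pre-task): the deteriorated profile keeps its
  blink rate (+0/min), *shortens* blinks (−5 ms), *damps* mid-window
  (600–1200) variability (×0.85), and drops CFF by 2.97 Hz; the
  non-deteriorated profile blinks more (+4/min), lengthens blinks
  (+12 ms), *amplifies* mid-window variability (×1.35) and drops CFF by
  2.14 Hz. These reproduce the reported sign pattern (deteriorated
  blink-duration change ≤ 0 and below the other group; smaller mid-window
  variability change; larger CFF drop). CVS-Q changes are rounded
  Gaussians clipped at zero — deteriorated mean 4.5 (SD 1.5), so most but
  not all deteriorated-profile sessions cross the ≥ 3-point labelling
  threshold; non-deteriorated mean 1.0 (SD 1.0). Baselines are drawn as
  CVS-Q ~ round(Normal(6.76, 3.76)) and CFF ~ Normal(38, 2) Hz.
* Both eyes share one event schedule and differ only by independent frame
  noise; one integer seed deterministically reproduces a trace, session or
  cohort bit for bit.

What the simulator does **not** emulate: eyelash and glare artefacts,
segmentation failures, asymmetric or partial blinks, saccadic suppression,
luminance-driven pupil responses, or any correlation structure between
features beyond the injected group effects. A green test on synthetic data
therefore establishes that the *computational pipeline* is correct and
well-calibrated — not that the classifiers would reach the reported
real-cohort performance, which derives from an unavailable 38-participant
dataset and is deliberately out of scope.

One design question the source leaves open is whether the reported
76 samples (42 + 34) from 38 participants are per-eye samples. The feature
table therefore exposes `unit = "eye"` (two rows per session, each eye used
as the monocular source in turn; the default, reproducing the 76-sample
geometry) and `unit = "participant"`.

# Segmentation evaluation

Dice and IoU are computed in fractions internally and reported as
percentages. Two empty masks score 1.0 (absence agreeing with absence);
empty vs non-empty scores 0.0 — closed-eye frames are not penalised for
predicting nothing. Instance matching maximises total IoU with the
Hungarian assignment (via `clue::solve_LSAP`, verified in tests against
exhaustive permutation for up to 6 instances), then discards pairs below
the IoU threshold (default 0.5). COCO AP uses greedy confidence-ranked
matching per IoU threshold (0.50 to 0.95 in steps of 0.05), a
precision envelope, and 101-point interpolation; AR is the final recall
averaged over the same thresholds. Geometric predictions carry confidence
1.0; ranking ties are broken by larger area. Macro aggregation is the
unweighted mean across structures (after averaging across eyes); micro
aggregation re-derives Dice/IoU from pooled pixel counts. Both are
reported; no attempt is made to reproduce the published segmentation table,
whose pooling weights are not recoverable.

The geometric segmenter normalises each frame by its brightest pixel
(an anchor on the sclera) rather than min-max scaling — on a closed-eye
frame min-max would promote skin to "darkest" and hallucinate a pupil —
then applies two intensity thresholds and connected-component selection.

# Statistics

Paired pre/post changes use Shapiro-Wilk on the differences to choose
between the paired t test (normality not rejected at .05) and the Wilcoxon
signed-rank test. Group comparisons use the Mann-Whitney U test: exact
(via the exact U distribution) when both groups have ≤ 20 observations and
no ties, otherwise the normal approximation with tie and continuity
corrections — calibrated to a 5 % ± 1.5 % type-I rate in the acceptance
suite. McNemar's test is continuity-corrected. All tests are two-tailed at
α = .05, with no multiplicity correction (matching the source design).
Feature filtering (P < .05, ordered by ascending P, CFF optionally appended
on domain grounds) is performed once on the full dataset and *not*
re-estimated per CV fold; this mirrors the published design, is a known
selection-bias risk, and can emit an explicit warning
(`warn_leakage = TRUE`).

# Risk models and evaluation protocol

Four families: CART decision tree, random forest (bootstrap + per-split
feature subsampling, `mtry = ⌊√p⌋`), gradient-boosted trees (logistic loss,
Newton leaf steps, shrinkage) and an RBF-kernel C-SVM solved as a dual QP
(`quadprog`) on a PCA projection retaining 95 % variance. The trees are
implemented in the package rather than delegated because no tree library is
available in the target environment; the SVM reports
`plogis(decision value)` as a pseudo-probability (documented, not
Platt-calibrated). Default grids: SVM cost {0.1, 1, 10} × γ {0.01, 0.1, 1};
tree depth {3, 5, 7, ∞} × min leaf {1, 2, 4}; forest trees {100, 300} ×
depth {∞, 5, 10}; boosting rounds {100, 300} × depth {3, 5} × learning rate
{0.05, 0.1}.

The protocol is leakage-safe by construction: a stratified 80/20 holdout is
drawn first; grid search and evaluation use stratified five-fold CV on the
training split only; within each fold, z-score statistics are fit on the
fold-train rows and SMOTE oversampling (uniform interpolation between a
minority sample and one of its k = 5 nearest minority neighbours, capped at
minority size − 1) is applied to the fold-train rows only, so validation
and test sets retain the original class distribution. Fitting z-scores per
fold-train rather than once on the whole training set is the stricter
reading of "after z-score normalization" and is the package's choice. The
AUROC CI across folds is the normal approximation `mean ± 1.96·sd/√k`; a
fold whose validation split is single-class yields an `NA` AUROC, excluded
from the mean with a warning. The positive class for F1 is "deteriorated".
Grid ties are broken by balanced accuracy, then grid order. A fixed master
seed makes the entire run — folds, SMOTE draws, bootstrap resamples —
bit-for-bit reproducible, verified by byte-identical holdout predictions
under test-row reorderings.

# Report and CLI

The per-session report mirrors a deployed monitoring app: risk level
(probability ≥ 0.5 → "high"; the boundary is assigned to high), a summary
block (total time, blink count, mean blink duration, fixation count, mean
fixation duration, fixation-duration MSE, PERCLOS) and per-eye time series.
"Mean square error of fixation duration" is interpreted as the mean squared
deviation of fixation durations about their mean (i.e. their population
variance); the report metadata flags this interpretation. Raster export is
provided as numbered PNG (optional `png` package) or plain-text ASCII PGM;
no TIFF writer exists in the supported environment, so multi-page TIFF
export is not offered.

# Known limitations

* The simulator's group effects are idealised and independent across
  sessions; cross-validated AUROCs near 1.0 on defaults say nothing about
  real-world discriminability.
* Fissure "length" is implemented as the vertical aperture extent (the
  PERCLOS-consistent reading), with a horizontal option in
  `trace_from_masks()`; the anatomical term is ambiguous.
* The exact Mann-Whitney path requires tie-free data; heavy ties at small n
  fall back to the normal approximation.
* The pure-R CART stack is adequate for cohort-scale inputs (tens to
  hundreds of rows, ~10–40 features) but is not tuned for large datasets.
* CVS-Q changes are clipped at zero, so simulated symptoms never improve;
  severity banding beyond the ≥ 6 baseline flag and the ≥ 3 change rule is
  not hard-coded.
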