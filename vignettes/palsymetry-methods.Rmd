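---
title: "Methods: objective facial palsy evaluation from symmetry features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: objective facial palsy evaluation from symmetry features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the pipeline

Facial palsy is the loss of voluntary muscle movement on one side of the
face. Peripheral palsy affects the whole half-face; central palsy spares the
forehead and eyes and depresses only the lower half. Distinguishing the two,
and both from healthy variation, guides treatment, and doing it objectively
from photographs removes inter-rater variability.

palsymetry implements a still-image pipeline. A subject is photographed
frontally in four poses: at rest, raising the eyebrows, frowning (screwing
up the nose) and smiling. From each image the pipeline obtains 68 facial
landmarks, reduces them to named salient points (supra-orbital SO,
infra-orbital IO, inner/outer canthus IC/OC, upper eyelid UE, mouth angle
MA, nose tip NT, nostrils), measures paired left/right distances, segments
the visible iris of both eyes, and condenses everything into eleven
symmetry ratios per subject. A two-stage hybrid classifier then separates
healthy from palsy and peripheral (PP) from central (CP) palsy.

Every ratio uses the min/max convention

$$\mathrm{dRatio} = \begin{cases} D_L / D_R & D_R > D_L \\ D_R / D_L & \text{otherwise,} \end{cases}$$

so 1 means perfect symmetry and values fall toward 0 with asymmetry,
regardless of which side is affected.

## The eleven features

| feature | expression | measurement |
|---|---|---|
| f1, f2 | rest | SO–IO and SO–NT distance ratios |
| f3, f4 | raise | SO–IO and SO–NT distance ratios |
| f5, f6, f7 | smile | IC–MA, IO–MA and NT–MA ratios |
| f8, f9 | frown | NT–MA and NT–nostril ratios |
| f10 | raise + frown | visible iris-area ratio, averaged |
| f11 | rest vs raise | eyebrow movement rate |

The total of eleven is fixed; the distance list per expression follows the
salient points each pose exercises (the rest pose uses no mouth point). Two
iris measurements exist (raise and frown); averaging them into the single
f10 preserves the total of eleven. Users who prefer them separate can set
`iris_split = TRUE` in `assemble_features()`/`pipeline_config()`, which
emits `f10a`/`f10b` instead.

The movement rate compares, per side, the change of the SO–IO : SO–NT
ratio between rest and raise; the rate is the smaller change divided by the
larger. A subject who lifts both brows equally scores 1; a one-sided lift
scores near 0. When neither side moves beyond a floor (default 0.005) the
rate is defined as 1: a face that is static on both sides is symmetric.
Movements are compared as absolute ratio changes so the feature shares the
healthy-is-1 polarity of the other ten.

# Landmarking

The landmark machinery is the shape-indexed cascaded-regression family:
gradient-boosted ensembles of depth-limited regression trees whose split
tests threshold the difference of two pixel intensities. Probe positions
are defined once in the mean-shape frame; for each face they are warped
through the similarity transform (closed-form Procrustes alignment via the
SVD of the centered cross-covariance) that maps the current shape estimate
to the mean shape: a probe $i$ anchored to its nearest mean-shape landmark
$v_i$ with offset $\delta = i - \bar{Y}_{v_i}$ lands at
$i' = Y_{v_i} + \frac{1}{s} R^{\mathsf T} \delta$. Probes that warp outside
the image are clamped to the border rather than read undefined memory.

The trainable cascade here is deliberately desk-scale (defaults: 5 stages
of 50 trees, depth 4, shrinkage 0.1, 20 candidate splits per node, probe
pairs drawn with an exponential prior on inter-probe distance). It is
trained and validated on the synthetic faces; training a production model
on real annotated corpora is out of scope. A pretrained external model can
be plugged in as any `function(image, face_box)` returning 68 points, and
precomputed landmark files are accepted through the manifest — the route a
clinical deployment with an established detector would take. HOG and
sliding-window-pyramid scanning are provided as the face-detection
machinery of that family; the trained face scorer itself is pluggable
rather than shipped.

Leaf increments are stored in face-box units so a cascade trained at one
rendering scale transfers across box sizes. Training residuals are
guaranteed non-increasing: each leaf stores the shrunken mean residual of
its samples, which cannot increase the training sum of squares for
shrinkage in (0, 1].

# Iris segmentation under eyelid occlusion

Per eye the pipeline:

1. crops the eye box spanning OC–IC horizontally and UE–IO vertically,
   expanded by a 6 px margin;
2. min–max normalizes the crop, binarizes at a gray threshold of 0.9
   (bright sclera maps to 1), and walks each column top-down for the first
   bright row — the eyelid margin. The polarity deserves a note: selecting
   *dark* pixels and taking the first dark row degenerates to the crop's
   top border whenever the eyelid fills the region above the lash line, so
   the bright-first-row reading (the first sclera pixel under the lid) is
   the one that yields the eyelid margin on any fixture. A column is kept
   only while the variance of the last four accepted rows (candidate
   included) stays below 4 px²; columns crossing the dark iris, where the
   first bright pixel is the below-iris sclera sliver, jump several rows
   and are rejected. The bound of 4 was chosen because legitimate lid
   slopes move about 1 px per column (variance well under 1) while the
   sliver columns jump 4–6 px (variance above 5);
3. fits `y = a x² + b x + c` to the accepted points by least squares
   (exact on three distinct points), after shifting each row by −0.5 px:
   the first bright row sits half a pixel below the true boundary;
4. detects the iris with Daugman's integro-differential operator:
   the maximum over centers and radii of the Gaussian-smoothed radial
   derivative of the circular arc integral of intensity. Centers are
   searched on a stride-2 grid in the central third of the crop with a
   single-pixel refinement pass, radii in 1 px steps between an anatomical
   prior of 25–50 % of the smaller box dimension (an eye box built from
   the canthi cannot contain a much smaller limbus), with a 0.25 px fine
   radial pass at the end. The arc is restricted to the two lateral 90°
   sectors, and samples lying above the fitted eyelid parabola are
   excluded — the lid carries no limbus information. Two robustness
   choices matter: the per-angle radial derivatives are averaged over
   their top 85 % (so a boundary visible on most of the arc outscores a
   sharp transition confined to a small arc fraction), and the smoothing
   SD is 1.0 radius step — at larger SDs the integrated score of a
   sustained multi-row intensity ramp (a small circle lying tangent inside
   the iris disk) can exceed that of the true sharp limbus transition;
5. clips the detected disk to pixels strictly below the fitted parabola
   and strictly above the lower-eyelid polyline drawn through the
   landmark lower-lid points; the pixel count of that mask is the visible
   area. An empty mask is a valid full-occlusion outcome.

`iris_area_pair()` adds a bilateral prior: iris radii are symmetric across
eyes, so when the two detections disagree by more than 1 px the eye with
the weaker operator response is re-segmented under the other eye's radius.
An eye that still fails yields a flagged missing value, later imputed with
the training-set column median (records with fewer than six present
features are rejected).

# The hybrid classifier

Classification runs in two stages, each pairing a decision-tree threshold
rule with a ridge (L2) logistic regression:

* stage 1 (healthy = 0 vs palsy = 1): if rule 1 fires the subject proceeds
  to stage 2 directly; otherwise the stage-1 classifier decides — 0 exits
  as healthy, 1 proceeds;
* stage 2 (PP = 0 vs CP = 1): if rule 2 fires the subject is called CP
  outright; otherwise the stage-2 classifier decides.

The machine-learning half is consulted only for subjects the rules leave
undecided. Rules are extracted by fitting a CART-style tree (Gini
impurity, exhaustive midpoint threshold search, depth limit 2, impurity
ties resolved toward the lowest feature index) to the training set — the
candidate predictors are the eleven features plus their mean — and reading
off the conjunction along the path to the highest-purity positive leaf.
On the synthetic cohort the learned stage-2 rule lands on upper-face or
iris features (CP spares them), mirroring the clinical reading.

The regularization parameter is selected by stratified k-fold
cross-validation of the *hybrid*: per fold, rules are extracted and the
ridge path fitted on the k−1 training folds and the rule-or-classifier
prediction is scored on the left-out fold at every grid value (k = 10 and
a 10-point log-spaced grid from 1e−3 to 1e2 give 100 performance entries
and 10 per-parameter averages). The winner has the highest average
sensitivity, ties broken by specificity, then by grid order (stronger
regularization first); the stage is then refit on the full training set.
Ridge logistic regression is the default family because the rule + RLR
hybrid is the configuration the evaluation protocol selects; the ML slot
also accepts any `function(features) -> 0/1`, which is how alternative
families (or mocks in the tests) plug in.

A note on label coding: stage-2 output is coded 0 = PP, 1 = CP. The
source material for this convention is internally inconsistent (one
passage reverses it); the cascade diagram's coding — rule 2 firing means
CP — is adopted throughout.

Evaluation reports sensitivity (positive = palsy in stage 1, CP in
stage 2), specificity, ROC curves over all score thresholds (score = 1
where the rule fires, else the ridge probability) and trapezoidal AUC,
which the tests verify equals the Mann–Whitney pairwise concordance.
`repeated_evaluation()` repeats split → formation → held-out evaluation
with distinct seeds and averages, the protocol's 20 × 10-fold scheme.

# The synthetic cohort

No public clinical data exist for this task, so the package ships a
generator whose outputs carry analytic ground truth for every stage.

A face is a parametric grayscale cartoon (head ellipse, brow bands, nose,
mouth, eyes with dark iris disks on bright sclera between an upper-lid
parabola and the landmark lower-lid polyline) drawn from an exact 68-point
geometry in the standard layout. Three factors in (0, 1] control the left
(affected) side:

* `upper_asym` (µ): the left brow point is placed at the intersection of
  two circles so that *both* the left SO–IO and SO–NT distances are
  exactly µ times their right counterparts. A single point cannot scale
  its distances to three or more anchors by one exact factor, so the
  construction makes the rest-pose features f1/f2 exact and leaves
  f3/f4 approximate (within a few percent);
* `lower_asym` (λ): the left mouth corner solves the same two-circle
  construction for NT–MA and IC–MA (f5, f7, f8 exact), and the left
  nostril is scaled about the nose tip (f9 exact); the smile IO–MA ratio
  f6 is the approximate one;
* `iris_asym`: the left upper lid is drooped until the analytic visible
  pixel count is the configured fraction of the right eye's. Drooped lids
  are rendered flat (a = 0): a lid whose vertex hides behind the iris
  cannot have its curvature recovered from the lateral wings alone, and a
  flattened arc is also what ptosis looks like.

The raise pose needs care. If the left side were scaled by µ at both rest
and raise, the a/b ratio used by the movement rate would be scale-invariant
and f11 would be identically 1 for everyone. The generator therefore
models a *dynamic deficit*: the left lift magnitude is solved (by
root-finding) so that the left movement equals µ times the right movement,
making f11 recover µ exactly. Healthy subjects (µ = 1) lift symmetrically.

Class-conditional factors in `simulate_cohort()` /
`simulate_feature_table()`: healthy draws `1 − |N(0, 0.02)|` (truncated to
(0, 1]) for all factors; affected factors draw uniform on [0.6, 0.9]; PP
depresses all three, CP only `lower_asym`. The uniform band gives classes
that are separable yet overlapping enough that rule thresholds near 0.95
are meaningful. The magnitudes are conventions — published descriptions of
palsy cohorts do not report asymmetry-factor distributions — and the
rendering adds clipped Gaussian noise (SD 2 gray levels) only; texture,
illumination gradients, pose and occlusions of real photographs are *not*
emulated. Passing tests therefore demonstrate correctness of the
measurement and classification machinery, not clinical performance.

Rendering is bit-reproducible: geometry is deterministic and the only RNG
draw (noise) is seeded per subject and expression.

# Numerical choices and degenerate inputs

* Pixel convention: `image[y, x]`, 1-based, x rightward, y downward;
  landmark IDs 1-based.
* Procrustes alignment refuses coincident source points; the SVD sign
  correction keeps the rotation proper.
* The split test is strict (`difference > τ`), so an exactly-τ difference
  goes right.
* `d_ratio` rejects non-positive distances; a fully occluded iris is area
  0 at the mask level and a flagged missing value at the feature level.
* Parabola fitting requires three distinct x values; collinear points
  degenerate to a line.
* The Daugman operator raises an error when its best response falls below
  5 gray levels per radius step (flat crop, no circular contrast).
* Single-class training sets produce trivial always/never rules and
  constant classifiers rather than errors, so tiny cohorts degrade
  gracefully.
* Preprocessing letterboxes to 960 × 720 rather than distorting: the
  features are ratios of distances and areas, and isotropic scaling leaves
  every one of them unchanged (a tested invariant). Contrast enhancement
  is histogram equalization and denoising a 3 × 3 median filter — the
  named steps of the acquisition protocol name no specific method.

# Problem sizes used by the test-suite

The suite validates at the study scale chosen for the package: a
110-subject cohort (60 healthy, 40 PP, 10 CP; 440 images at 360 × 480),
for which feature extraction recovers the configured factors with MAE
well under 0.05 and the end-to-end protocol (70/30 split, 10-fold
formation) reaches stage-1 sensitivity and specificity above 0.9 on the
held-out set; a 200-face training run for the mini-cascade (at 120 px
width, 5 stages × 25 trees); and 50-spec randomized suites for the iris
operator (detection within ±1 px, clipped area within 5 % of the analytic
count).

# Known limitations

* The cascade is validated in-distribution on synthetic faces; it is a
  faithful miniature of the method, not a production landmark model.
* The Daugman search assumes the iris lies in the central third of the
  eye box and is at least quarter-box sized — true for boxes built from
  the canthi, not for arbitrary crops.
* Under heavy ptosis (more than about half the iris hidden) the visible
  arc underdetermines the circle; the bilateral radius prior mitigates
  but does not eliminate the degradation.
* f3, f4 and f6 are approximate even in the generator's ground truth; the
  recovery tests use the exactly-constructed features.
* The classifier's headline clinical numbers cannot be reproduced without
  the private clinical images; the synthetic cohort tests the protocol,
  not the clinical effect size.
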