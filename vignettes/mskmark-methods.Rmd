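---
title: "From segmentation masks to decisions: the mskmark methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From segmentation masks to decisions: the mskmark methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mskmark)
```

mskmark turns multi-label musculoskeletal MRI segmentation masks into
standardized quantitative biomarkers and drives two decision layers built on
those biomarkers: a specificity-targeted triage cascade for knee MRI, and
landmark-time risk models for total knee replacement (TKR) and incident
radiographic osteoarthritis (OA). Segmentation itself is out of scope: masks
are inputs. Every component is testable without imaging data through a
phantom and cohort simulator with analytically known ground truth. This
vignette explains the models and conventions, the tunable parameters, what
the simulator does and does not emulate, and the numerical choices made
where the design was genuinely open.

## Measurement model

**Medial-axis thickness.** A thin laminar structure (a cartilage plate, a
meniscus) has a well-defined local width: twice the distance from its medial
axis to the nearest boundary. Per 2D slice, the binary compartment mask is
thinned to a one-pixel skeleton (Zhang–Suen), and a spacing-aware exact
Euclidean distance transform (Felzenszwalb–Huttenlocher lower envelope,
computed in millimeters with anisotropic in-plane spacing) is sampled at
every skeleton pixel. Samples are pooled across slices and averaged per
compartment.

Three conventions matter:

* *Boundary position.* The voxel-center distance transform measures the
  distance to the nearest **background voxel center**; the tissue boundary
  lies half a pixel closer. We therefore subtract half the mean in-plane
  spacing from each sample. On slab phantoms this makes the estimate exact
  whenever the slab width is commensurate with the grid.
* *Half vs full width.* "Distance to the nearest boundary" is ambiguous by
  a factor of two. Both are reported: `half_width` is the medial-axis
  boundary distance, `full_width` (the default, and the laminar thickness
  of a plate) is twice it, exactly. The output records which was used.
* *The array edge is not a boundary.* The distance transform only sees
  in-array background, and thinning replicates edge pixels. Structures
  clipped by the field of view are measured as if they continued, which is
  the physically sensible reading of a cropped acquisition.

Compartments with fewer than 5 skeleton samples per volume
(`min_skeleton_px`) return `NaN` with a warning: the medial axis of a blob a
few pixels across is noise, not anatomy. Empty compartments warn and return
`NaN`, never an error.

**Disc height.** Intervertebral disc height is a global cranio-caudal
extent, not a local width. Per slice, connected components identify disc
instances; the axis-aligned bounding-box extent along the declared
cranio-caudal axis (a configuration field, default the row axis — the
source never states axis handling, so it is explicit rather than silent)
times the pixel spacing gives the slice-level height, and the per-level
height is the **maximum across slices**. Instances are associated into
levels by centroid ordering along the cranio-caudal axis, anchored on the
slice with the most instances; ambiguous assignments fall back to
nearest-centroid with a warning. An axis-aligned rather than rotated
minimum-area rectangle is used because the measured quantity *is* the
cranio-caudal extent once the orientation is declared.

**Volume and relaxometry.** Tissue volume is the voxel count times
`sx*sy*sz` in mm³, reported in cm³. Relaxometry means clip map voxels inside
the compartment to 0–100 ms and take the pooled voxel mean across the whole
compartment (the pooled mean was chosen over a mean of slice means; the
alternative aggregation is a one-line change and matters only for strongly
unbalanced slices).

**Z-scoring.** All downstream features are z-scored against a frozen
reference: `fit_reference()` computes per-feature mean and SD on a
designated healthy subset **once, globally** — never per cross-validation
fold — and `zscore()` applies them. The triage reference is knees normal
for both bone and cartilage; the landmark reference is knees with baseline
Kellgren–Lawrence grade 0–1.

## Segmentation evaluation and agreement

Dice and Jaccard are computed per slice (`jaccard = dice / (2 - dice)`
identically), aggregated slice→subject by the mean and subject→structure by
the median, with dataset-level tail summaries (median, 5th percentile,
minimum; percentiles interpolate linearly between order statistics, type 7).
Slices with an empty reference are excluded by default rather than scored 1,
which would inflate averages on sparse structures; a flag scores them 1 when
the prediction is also empty. Models are compared with a Friedman test
followed by paired two-sided Wilcoxon signed-rank tests under
Benjamini–Hochberg control at 5%.

Agreement between model-derived and reference biomarker values is
assumption-gated: Shapiro–Wilk on the paired differences and Levene across
the two arms, both at p ≥ 0.05; the conjunction selects the parametric or
non-parametric arm everywhere downstream, so the gate is a pure function of
two p-values. The parametric arm uses a two-way single-measurement ICC from
the mean-squares decomposition with F-based intervals, mean ± 1.96 SD
Bland–Altman limits, and OLS with R². The non-parametric arm uses a
random-intercept variance-ratio ICC (σ²~subject~ / (σ²~subject~ + σ²~error~),
closed form on balanced two-arm data and identical to the lme4 REML fit,
which the test suite verifies) with percentile intervals from 10,000
subject-level bootstrap resamples, percentile Bland–Altman limits, and
Gaussian-process regression (RBF kernel plus noise variance, inputs
standardized for kernel length-scale stability, predictions de-standardized)
with a 95% pointwise band. Spearman's ρ is always reported, and
Benjamini–Hochberg adjustment is applied across the analysis batch.

The named parametric form mixes two ICC conventions (a "mixed-effects,
absolute agreement, single measurement" label); both the consistency
(two-way mixed) and absolute-agreement (two-way random) estimators are
implemented, consistency is the default, and the result records which was
used rather than silently picking one.

## Triage cascade

Stage A (normal-knee screen) and Stage B (cartilage + bone filter) each
stack three base learners — elastic-net penalized logistic regression
(mixing parameter 0.5, class-balanced weights, penalty chosen by internal
cross-validation), gradient-boosted trees, and a histogram-binned
gradient-boosted variant — via five-fold subject-grouped cross-validation
and a logistic meta-learner on the out-of-fold base probabilities. Every
scan receives exactly one out-of-fold stacked probability and no subject
ever straddles a fold; both are asserted at run time.

Operating points are specificity-targeted: the decision rule at threshold t
forwards probabilities ≥ t (inclusive), candidates are the sorted unique
out-of-fold probabilities (exact, no binning), and the smallest candidate
whose achieved specificity meets the target is selected, resolving ties
toward higher sensitivity. Published thresholds of this design are
data-dependent; they are re-derived on each dataset, not hard-coded.
Stage B is computed only on the Stage-A pass set. Stage C averages a
logistic regression and a gradient-boosted classifier with equal weight per
localization task, fit on the forwarded subset without further
cross-validation — apparent performance with a documented optimism caveat —
and reports calibration in 10 equal-width bins with no recalibration.

Metrics (AUC, sensitivity at the stored threshold, NPV = TN/(TN+FN),
PPV = TP/(TP+FP)) carry percentile 95% intervals from a 2000-draw bootstrap
resampling subjects with replacement; degenerate resamples are redrawn and
counted. Sensitivity at a target is computed at the stored threshold rather
than re-derived per resample. Verification workload is
`forwarded_fraction × per-exam minutes × 1000`, reported per 1000 scans in
minutes and hours.

## Landmark risk models

A landmark design fixes the prediction time t0 (48 months): the risk set
contains knees uncensored and event-free at t0 with complete biomarkers
through 48 months, and the binary outcome is an event in
(t0, t0 + horizon]. Features are thickness levels at the five visits plus
annual changes between consecutive available visits — defined as
(value~t~ − value~t−1~) / Δt in years, since "annual change" is otherwise
underdetermined — z-scored to the KL 0–1 reference, plus age, sex and BMI.
Knees censored inside the window without an event are coded 0 under the
primary convention and flagged; an `exclude` sensitivity path drops them
(the binary-outcome treatment of within-window censoring had to be chosen
here; the flag keeps the choice auditable). A per-knee mean-imputation path
for missing visits is available and provably identical when nothing is
missing. The OA task restricts to baseline KL < 2.

TKR uses a 400-tree random forest (minimum leaf 10, class-balanced
weights) with a logistic-regression baseline; OA uses L2-regularized
logistic regression (ridge penalty 0.01, balanced weights). Cross-validation
is five-fold, grouped by participant (paired knees co-assigned, checked
exhaustively in tests) and stratified by outcome at the group level — the
stratification variable is the class label, the simplest reading. Isotonic
calibration is fit per fold on training data only (random-forest training
predictions are out-of-bag, so the map is not fit on overfit scores) and
applied to the held-out fold; calibrated out-of-fold probabilities are
pooled for reporting. Evaluation reports AUC with a 1000-draw knee-level
percentile bootstrap, Brier scores and logistic calibration slopes for raw
and calibrated probabilities; constant predictions yield an undefined slope,
reported as `NaN` with a warning. With very few events the isotonic map can
be piecewise constant, which collapses the *calibrated* ranking while the
raw ranking is intact — discrimination-only analyses should use the raw
probabilities.

Decision curves follow net benefit,
NB(pt) = TP/n − (FP/n)·pt/(1−pt), with treat-all and treat-none references
and 2000-draw percentile bands. Intervention penalties are implemented as a
constant harm subtracted from the model and treat-all curves, in net-benefit
units — a declared, experimental interpretation, since the penalty's
functional form is not pinned down by its source. Cox proportional-hazards
comparators on month-0 features report Harrell's C (ties one half) and
IPCW C with Kaplan–Meier censoring weights truncated at the horizon (via
`survival::concordance`, cross-checked against exhaustive pair enumeration
in the tests). Kaplan–Meier curves by median-split predicted risk complete
the survival view.

## The synthetic generator

The simulator exists so that every claim above is testable against known
truth; it emulates geometry and tabular statistics, **not** MRI intensities,
noise textures, motion or artifacts.

* **Phantoms** (slab, annulus, ellipsoid, disc stack) rasterize by
  voxel-center inclusion — a voxel belongs to the shape iff its center
  satisfies the implicit inequality — so a brute-force center test is an
  exact oracle. Slabs give analytic thickness, ellipsoids analytic volume
  (4/3·π·abc), disc stacks exact heights when commensurate with the grid.
  Rasterized volume converges to the analytic volume as spacing shrinks,
  but not at a smooth first-order rate: the signed surface error
  fluctuates, so the convergence test asserts monotone decrease and an
  at-least-four-fold error reduction over two halvings rather than exact
  halving per step.
* **Triage cohorts** draw four hierarchical classes (normal,
  cartilage-only, bone-only, both) with class-specific mean shifts on six
  biomarkers in reference-SD units (defaults −1.5 SD on cartilage
  thickness, +1.2 SD on bone volume — severities a radiologist would call
  clearly abnormal but overlapping with normal), unit within-class noise,
  and demographics sampled independently of class so that recovered signal
  is attributable to the biomarkers.
* **Longitudinal cohorts** give each knee a linear per-compartment
  thickness trajectory (baseline ≈ 2–2.5 mm, knee-level slope
  N(−0.05, 0.08²) mm/yr, 0.05 mm visit noise — slow loss with realistic
  heterogeneity) and draw surgery times by inverse-transform sampling from
  a hazard that is piecewise constant over 12-month intervals with
  log-hazard linear in the cumulative loss at the interval start
  (coefficient 1.5 per mm summed over compartments, baseline hazard
  5·10⁻⁵ per month). These defaults were fixed once to give roughly 13%
  events within the 48→96-month window — a plausible TKR rate in an
  at-risk cohort — and are not re-tuned. A zero coefficient decouples
  events from trajectories exactly (the null used in the test suite).

What passing tests on these cohorts shows is that the *pipeline machinery*
— grouping, stacking, thresholding, calibration, survival accounting —
recovers planted signal at the planted strength; it says nothing about the
performance of any segmentation model on real MRI, which requires real
cohorts.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: empty compartments return `NaN`
with warnings; a constant difference vector makes Shapiro–Wilk undefined
and routes to the non-parametric arm; an unreachable specificity target
returns a threshold above all scores with zero sensitivity and a warning;
bootstrap resamples with one class are redrawn and counted; zero total
variance in the ICC is an error. Ties at a probability threshold are
inclusive (p ≥ t acts). All stochastic steps (fold assignment, learner
seeds, bootstraps) are seeded through a single master seed.

Default problem sizes in the tests and the acceptance script — cohorts of
250–1000 knees, 100-replicate coverage simulations, 10 seeds per hazard
level — were chosen as the smallest sizes at which the Monte-Carlo error is
comfortably below the asserted tolerances.

Connectivity defaults are 8 (2D) and 26 (3D); the closing element is the
Chebyshev disc/ball (radius 1 = the full 3×3 neighbourhood), so a radius-1
closing bridges single-pixel gaps including diagonals; boundary smoothing
is an optional 3×3 median filter, off by default. Per-slice refinement is
the default, matching slice-wise annotation; a 3D mode exists.

## Known limitations

Thickness is slice-wise 2D, not a 3D medial surface; strongly oblique
structures are biased toward the in-plane width. Disc-level association is
a centroid heuristic and can mislabel pathological fused or collapsed
levels. Stage C is apparent performance by design. The GP agreement arm
depends on kernel hyperparameter estimation and falls back to
Spearman-only on failure. The simulator's linear trajectories and
interval-wise hazard are deliberately simple; they do not model
nonlinear loss, informative censoring, or correlated bilateral disease
beyond shared participant assignment.
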