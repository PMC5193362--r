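---
title: "Volumetric HOG features and cross-validated classifier selection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric HOG features and cross-validated classifier selection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hogmri)
```

# The problem

Given structural or resting-state functional brain MRI volumes from patients
and healthy controls, the goal is a classifier that labels a new subject as
patient or control.  `hogmri` implements one complete route to such a
classifier: a volumetric *histogram-of-oriented-gradients* (HOG) texture
descriptor of each brain volume, mutual-information-based feature ranking,
and a model-selection procedure that picks one base classifier and one
feature subset by cross-validation on the training set only, followed by a
single evaluation on held-out subjects.

The package operates downstream of spatial preprocessing: volumes are
assumed to already live on a common anatomical grid (the canonical example
is 79 x 95 x 68 voxels at 2 mm, spanning the bounding box from
(-78, -112, -50) mm).  Motion correction, co-registration, non-linear
template normalization and spatial smoothing are out of scope; dedicated
neuroimaging tools do those steps.  What the package *does* implement of
preprocessing are the two intensity-level steps the method itself requires:

* **subject-level z-scoring** -- every voxel (over all time points, for 4D
  scans) is standardized by one global mean and SD per subject, putting
  multi-site intensities on a common scale.  We use the population SD
  (divisor *n*); the choice only rescales all images identically.
  Constant images are rejected rather than zeroed, because a silently
  zeroed image would produce a meaningless all-zero descriptor downstream.
  Z-scoring makes no attempt to mask out-of-brain background voxels: the
  global mean/SD is taken literally over the whole array.
* **temporal averaging** -- a 4D scan is collapsed to the per-voxel mean
  `f(x,y,z) = (1/k) sum_t f(x,y,z,t)`.  Z-scoring is applied *before*
  averaging, matching the order in which the two steps are defined.

# The 3D HOG descriptor

For a volume `f`, central differences in voxel index units give the
gradient `(f_x, f_y, f_z)` and its magnitude.  Each voxel's gradient is
assigned to the orientation bin `b` maximizing the cosine overlap
`alpha(g, b) = (g . b) / (|g||b|)`, where `b` ranges over the 26 nonzero
offset vectors with components in {-1, 0, 1} (8 in the 2D variant).  The
voxel then adds its gradient *magnitude* to that bin of its cell -- hard
assignment, exactly as the `argmax` formulation prescribes, with no soft or
trilinear interpolation.  Cells are non-overlapping boxes of 8^3 voxels;
blocks of 2 x 2 x 2 cells are taken at a stride of one cell, so consecutive
blocks overlap and each cell is re-normalized in up to eight contexts.
Each block's concatenated histograms (8 x 26 = 208 values) are normalized by

    v  ->  v / sqrt(||v||^2 + epsilon^2)

with `epsilon = 1e-5` by default; the constant keeps the map defined on
all-zero blocks and bounds every output entry in [0, 1).  On the canonical
grid this geometry gives floor(79/8) x floor(95/8) x floor(68/8) =
9 x 11 x 8 cells, (9-2+1) x (11-2+1) x (8-2+1) = 560 blocks and 560 x 208 =
116,480 features per subject.

Numerical and boundary choices, all of which tests pin down:

* Trailing partial cells are discarded (floor division), and boundary
  voxels -- where a central difference does not exist -- contribute to no
  bin.  This is what reproduces the 9 x 11 x 8 cell grid above.
* A zero-magnitude gradient has no orientation and is skipped.
* Argmax ties on the cosine are resolved toward the lowest index in the
  fixed direction order (lexicographic, x fastest).  The comparison uses an
  absolute tolerance of 1e-9 on the cosine so that geometrically exact ties
  (e.g. a 2D gradient at exactly 22.5 degrees) resolve by the rule rather
  than by floating-point rounding noise.
* The feature layout is blocks in x-fastest grid order, cells within each
  block in the same order, orientation bins innermost.
  `map_feature_to_space()` inverts this layout and reports the enclosing
  16^3-voxel block's center in voxel and mm coordinates, which is how
  selected features are reported back as brain locations.
* Gradients are taken in voxel-index units with no physical-unit scaling,
  so anisotropic voxel sizes would scale axes differently; the intended
  inputs are isotropic 2 mm grids.

The extractor is validated against an independent per-voxel loop
implementation (agreement to 1e-10 on random volumes), and the bin
bookkeeping against a 90-degree-rotation equivariance test: rotating the
volume permutes the direction set, and the cell histograms must permute
exactly accordingly.

# MRMR feature ranking

With over a hundred thousand features and around a thousand subjects,
classifiers overfit badly without selection.  Features are ranked by the
greedy minimum-redundancy-maximum-relevance rule: the first feature
maximizes the mutual information `MI(f, y)` with the class label; each
subsequent pick maximizes `MI(f, y) - (1/|S|) sum_{s in S} MI(f, s)`.  This
is the *difference* (MID) form of the criterion, the canonical default; the
quotient form is not implemented.  MI is the plug-in estimate on discrete
codes, in bits.  No bias correction is applied -- only the ranking matters,
not the absolute MI values.

Continuous features are discretized per feature into 3 states at
mean +/- SD (the scheme long used with this selection rule); already
discrete columns pass through, and constant columns collapse to a single
state with zero MI.  A quantile scheme with a configurable state count is
available.  Ties in the greedy argmax break toward the lowest feature
index, making rankings deterministic and giving them the prefix property
(the top-k ranking is a prefix of the top-(k+1) ranking), both of which are
tested, the greedy step against a brute-force re-evaluation oracle.

# Selecting the classifier and feature count

The learner bank is fixed: a linear SVM, nine Gaussian-kernel SVMs with
`K(u,v) = exp(-||u-v||^2 / (2 sigma^2))` for sigma = 1..9 (the convention
of the MATLAB-era toolchain this family of kernels is usually quoted in),
Gaussian naive Bayes, a CART decision tree, and 5-nearest-neighbours.  SVM
cost is 1.  Features are standardized by training-fold statistics before
SVMs and KNN, since unscaled columns would otherwise dominate distances.
The positive class for sensitivity/specificity defaults to the healthy
controls (label 0); it is configurable.

`select_classifier()` proceeds as follows.  One seeded, class-stratified
5-fold partition is drawn and reused for *every* (learner, feature-count)
pair, so all CV means are comparable.  Features are added one at a time in
MRMR order; at each count k every learner's 5-fold mean accuracy and fold
range (max - min) are recorded.  The loop stops when no learner has
improved its best mean for `patience` consecutive additions (default 20),
or at `k_max` (default min(d, 1000)).  A plateau rule rather than a
one-step "no increase" test is deliberate: CV curves at small k are noisy
and non-monotone, typically rising to an interior peak and degrading as
uninformative features accumulate, so a single flat step must not stop the
search.  Each learner is then scored by its best visited mean; the five
best learners are retained, and among them the *smallest fold range* wins.
The top means are typically within a fraction of a percentage point of one
another, so the spread across folds -- a stability measure -- is the
deciding criterion.  Remaining ties break toward the higher mean, then bank
order; equal means at the per-learner argmax break toward fewer features.
The winner is refit on the whole training set restricted to its feature
set, and `evaluate_holdout()` applies it once to subjects that took no part
in any training-time decision.

One known caveat is inherent to the procedure as specified: the MRMR
ranking is computed once on the full training set before cross-validating
on that same set, so the CV means themselves are optimistically biased
(feature-selection leakage).  The hold-out estimate is unaffected.  A
strict variant that re-ranks features inside each fold's training part is
available behind `per_fold_ranking = TRUE` (off by default, to match the
procedure as defined); the final feature set still comes from the
full-training ranking.

The exact selection logic -- including both tie-break layers -- is tested
against an exhaustive enumeration oracle over every (learner, k) pair on
small problems.

# Personal characteristics

Phenotypic tables are cleaned by three rules, in order: columns missing for
30% or more of subjects are dropped (identifier and label columns never
are); remaining missing numeric values are imputed with the observed column
mean, and categorical ones -- for which a mean is undefined -- with the
mode; signed handedness scores are recoded to 1 (positive) / 0 (negative).
A score of exactly zero is outside the sign rule; it maps to 1 with a
warning, configurably.  Sex and eye-status encode as 0/1, the imaging site
as a single integer code (one feature), with one-hot encoding behind a
flag since the best encoding for site is genuinely open.  Columns that leak
the diagnosis (symptom scores, medication) are excluded via an explicit
blocklist.  `concat_features()` appends the encoded table to the image
features by subject id -- e.g. 116,480 + 6 = 116,486 columns -- recording
per-column provenance and refusing silently mismatched ids.

# The synthetic cohort generator

Because real multi-site cohorts cannot ship with a package, every stage is
exercised on synthetic phantoms.  A subject volume is Gaussian noise
(`noise_sd`, default 1); class-1 subjects additionally carry a sinusoidal
grating of amplitude `effect` and wavelength 8 voxels, oriented along
(1, 1, 0)/sqrt(2), confined to the central half of the volume along each
axis.  A grating was chosen because its gradients concentrate in exactly
two opposite orientation bins, which is the kind of signal a HOG descriptor
is built to detect -- so recovery of the planted signal is a direct test of
the whole chain.  Defaults are 100 subjects per class on 32^3 volumes with
`effect = 3` (three noise SDs).  One global seed fans out to per-subject
streams so cohorts extend without regenerating.

What the phantom does *not* emulate: brain morphology, hemodynamics,
spatial autocorrelation of scanner noise, or site/batch effects.  Passing
the synthetic checks therefore demonstrates that the implementation works
and that the statistical machinery is calibrated (null cohorts score at
chance; accuracy grows with effect size), not that comparable accuracy is
attainable on real patient data.

The accompanying checks run at deliberately modest problem sizes -- 200
subjects on 32^3 volumes (5,616 features), 20% hold-out, five seeds for the
recovery and null checks and three per effect size for monotonicity, with
the incremental search capped at `k_max = 80` features (the CV peak on
these cohorts occurs far below the cap).  The null calibration interval is
the 95% binomial interval around 50% at hold-out size 40.

# Known limitations

* The plateau stop rule is an interpretation of "no accuracy increase";
  with 13 learners, chance improvements can extend the search, which is why
  `k_max` exists.
* Plug-in MI on 3-state codes discards within-state information; for
  features whose class signal sits inside one SD of the mean, relevance is
  underestimated.
* Fold stratification is by class only; site-blocked folds are not
  implemented.
* The pipeline holds the full subjects-by-features matrix in memory
  (~0.9 GB for 1,000 subjects at 116,480 doubles), which is adequate for
  cohorts of this scale but not for orders of magnitude more subjects.

# A worked miniature

```{r miniature, eval = FALSE}
spec <- cohort_spec(n_per_class = 100, dims = c(32, 32, 32),
                    effect = 3, noise_sd = 1, seed = 11)
ds <- generate_feature_dataset(spec)          # 200 x 5616 HOG features
split <- split_train_test(ds, 0.8, seed = 11)
res <- select_classifier(split$train, seed = 11, k_max = 80)
res
evaluate_holdout(res, split$test)
```

On this cohort the planted grating is separable from the first MRMR-ranked
feature on, the winning learner reaches a 100% CV mean with zero fold
range, and the hold-out accuracy is 100% -- the expected outcome for an
effect of three noise SDs concentrated in known orientation bins.
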