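# hogmri

3D histogram-of-oriented-gradients (HOG) texture features and
cross-validated classifier selection for patient-versus-control
classification from brain MRI.

## What it does

Psychiatric-diagnosis classifiers built from structural or resting-state
functional MRI face two problems at once: each subject is a volume of
~500,000 voxels but cohorts hold only ~1,000 subjects, and multi-site data
carry large intensity and population variability.  `hogmri` implements one
complete, reproducible route through both problems:

1. **Texture description.**  Each (spatially normalized) volume is reduced
   to a 3D HOG descriptor: central-difference gradients
   `f_x = (f(x+1,y,z) − f(x−1,y,z))/2` (likewise `f_y`, `f_z`), each voxel
   assigned to the orientation bin `b` maximizing
   `α(∇f, b) = (∇f·b)/(|∇f||b|)` over the 26 neighbor directions, gradient
   magnitudes accumulated per 8³-voxel cell, and overlapping 2×2×2-cell
   blocks normalized by `v → v/√(‖v‖² + ε²)`.  On the canonical
   79×95×68 grid at 2 mm this yields 116,480 features per subject.
   4D functional scans are first z-scored per subject and averaged over
   time, `f(x,y,z) = (1/k)Σ_t f(x,y,z,t)`.
2. **Feature ranking.**  Greedy minimum-redundancy–maximum-relevance
   (MRMR): pick `argmax_f MI(f, y)`, then repeatedly
   `argmax_f MI(f, y) − (1/|S|)Σ_{s∈S} MI(f, s)`.
3. **Model selection.**  A fixed bank of 13 base learners (linear SVM,
   RBF SVMs with σ = 1…9, naive Bayes, decision tree, 5-NN) is scanned by
   adding MRMR-ranked features one at a time under a shared stratified
   5-fold CV until the accuracy plateau; each learner keeps its best mean
   accuracy `E_acc` and fold range `R_acc`; the five best means are
   retained and the smallest range wins.  The winner is refit on all
   training subjects and evaluated once on a hold-out set (accuracy,
   sensitivity, specificity).

Personal-characteristic tables (age, sex, handedness, IQ, site, …) can be
cleaned by the package's rules (drop columns ≥ 30% missing, mean/mode
imputation, sign-recoded handedness) and concatenated onto the image
features.  A synthetic phantom generator (Gaussian noise plus a planted
oriented grating) makes the whole pipeline testable without any imaging
download.

## Worked example

```r
library(hogmri)

# a synthetic two-class cohort: 100 + 100 subjects, 32^3 voxels,
# class 1 carries an oriented grating of amplitude 3 noise SDs
spec  <- cohort_spec(n_per_class = 100, dims = c(32, 32, 32),
                     effect = 3, noise_sd = 1, seed = 11)
ds    <- generate_feature_dataset(spec)       # HOG features: 200 x 5616
split <- split_train_test(ds, 0.8, seed = 11)
res   <- select_classifier(split$train, seed = 11, k_max = 80)
res
#> <selection_result>
#>   winner: SVM-linear with 1 features
#>   top learners (best CV mean %, range %):
#>     SVM-linear   k=1    mean 100.0  range 0.0
#>     SVM-RBF-1    k=1    mean 100.0  range 0.0
#>     SVM-RBF-2    k=1    mean 100.0  range 0.0
#>     SVM-RBF-3    k=1    mean 100.0  range 0.0
#>     SVM-RBF-4    k=1    mean 100.0  range 0.0
evaluate_holdout(res, split$test)
#> Accuracy 100.0%  Sensitivity 100.0%  Specificity 100.0%
#> counts: tp=20 fn=0 tn=20 fp=0
```

The planted texture concentrates gradient mass in two orientation bins, so
the top MRMR feature alone separates the classes: every learner peaks at a
100% CV mean at one feature, the zero-range linear SVM wins, and the 40
hold-out subjects are classified perfectly.  A null cohort (`effect = 0`)
scores at chance instead.  To locate a selected feature anatomically:

```r
map_feature_to_space(res$best_feature_set[1], extract_hog(generate_volume(1, spec)))
#> block/cell/bin decomposition plus the 16^3-block center in voxel and mm coordinates
```

NIfTI-based workflows use `read_volume()` / `write_volume()`,
`generate_cohort()` to materialize a phantom cohort on disk, and
`run_pipeline(run_config(...))` (or the `inst/cli/hogmri` script with
subcommands `simulate`, `extract`, `run`) for the end-to-end path with a
JSON manifest, selection audit trail and hold-out report.

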