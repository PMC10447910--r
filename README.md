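# maskshape

Difficult mask ventilation (DMV) — the inability to ventilate an
anaesthetised patient adequately through a face mask with a one-handed,
unassisted technique — is rare (a few percent of inductions) but dangerous,
and bedside predictors catch little of it. `maskshape` implements the full
geometric-morphometrics pipeline for predicting DMV from 3D facial surface
scans, together with the clinical scores it is compared against, and a
synthetic-face generator so that every stage can be exercised and tested
without patient data.

The pipeline is the standard dense-correspondence shape analysis of
craniofacial biology:

1. **Quasi-landmarks.** A cleaned reference mesh with *K* vertices is mapped
   onto every scan by anchor-initialised similarity alignment (8 named
   landmarks, Umeyama least squares), rigid ICP with outlier downweighting,
   and smoothed non-rigid deformation (symmetric closest-point pulls,
   graph-Laplacian smoothing with annealed stiffness). Vertex *i* of the
   deformed reference then denotes the same anatomical location on every
   scan.
2. **Generalized Procrustes Analysis.** Size, location and orientation are
   removed: each K×3 configuration is centred, scaled to unit centroid size
   and rotated to an iteratively re-estimated mean shape.
3. **Shape PCA.** The aligned coordinates are decomposed into orthogonal
   modes; per-subject PC scores are the features for prediction.
4. **Prediction.** The number of PCs is selected by a leave-one-out
   cross-validated LDA sweep (pooled out-of-sample scores, one AUC per PC
   count, argmax selected); a ten-algorithm classifier bank (naive Bayes,
   LDA, QDA, logistic regression, RBF-SVM, random forest, extra trees, a
   single-hidden-layer network, AdaBoost over stumps, XGBoost) is evaluated
   under stratified 10-fold cross-validation. Performance is reported as the
   Mann–Whitney AUC with DeLong 95% CI and the Youden-optimal operating
   point with stratified-bootstrap CIs.
5. **Interpretation.** Group mean shapes and a per-vertex distance map
   localise where DMV and easy-ventilation faces differ.

Clinical utilities cover the Langeron inadequate-ventilation predicate
(`label_dmv()`), a configurable 0–18-point DIFFMASK risk score
(`diffmask_score()`), baseline comparison tables (ANOVA, Mann–Whitney,
Fisher; `baseline_table()`), and the Riley et al. minimum sample size for
developing a binary prediction model (`riley_min_n()`).

## Worked example

A synthetic cohort at the package's default study conditions — 600
subjects, 5.23% DMV prevalence, three smooth shape modes, a 3 mm localised
mandibular displacement in DMV cases, nuisance similarity transforms:

```r
library(maskshape)

template <- make_template(grid_resolution = 24)
cohort   <- sample_cohort(template, population_spec(n_subjects = 600, seed = 101))
#> <synthetic_cohort> 600 scans, 33 DMV (5.50%), resample=FALSE

configs <- register_cohort(cohort, mode = "corresponded")
space   <- fit_pca(gpa(configs))
#> <shape_space> 600 samples, 576 landmarks, 599 components
#>   first 3 PCs: 66.76% of variance; 74 PCs reach 75%

curve <- loocv_sweep(space$scores, cohort$labels, pc_range = 1:50)
best_n_pcs(curve)
#> 5        # AUC at 3 PCs is within 0.003 of this maximum: the planted
#>          # signal lives in the first three components

bank <- crossval_bank(space$scores[, 1:3], cohort$labels,
                      algorithms = c("logistic", "lda", "random_forest"),
                      k = 10, seed = 101)
#>       algorithm   auc auc_ci_low auc_ci_high sensitivity specificity
#> 1      logistic 0.810      0.746       0.874       0.636       0.845
#> 2           lda 0.811      0.747       0.876       0.848       0.642
#> 3 random_forest 0.771      0.696       0.847       0.848       0.575
```

The cross-validated AUC ≈ 0.81 recovers the planted effect size (the
generator is calibrated so that a well-specified model sits near the
discrimination reported for real cohorts). The group distance map localises
the difference where it was planted:

```r
gm <- group_mean_shapes(gpa(configs), cohort$labels)
dm <- distance_map(gm$positive, gm$negative)
mean(order(dm, decreasing = TRUE)[1:58] %in% template$mandible_idx)
#> 1        # the whole top decile lies in the mandibular region
```

and the design calculation reproduces the published minimum cohort size:

```r
riley_min_n(c_statistic = 0.825, prevalence = 0.0523, n_parameters = 3)
#> [1] 331
```

`run_pipeline(run_config(...))` chains all eight stages (simulate,
register, gpa, pca, select_pcs, train, diffmask, visualize) into one
reproducible run with a JSON manifest of config, artifact hashes, seeds and
timings.

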