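---
title: "Shape-based prediction of difficult mask ventilation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-based prediction of difficult mask ventilation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`maskshape` turns 3D facial surface scans into a risk prediction for
difficult mask ventilation (DMV) through dense-correspondence geometric
morphometrics. This vignette is the package's own account of the methods:
the model at each stage, the tunable parameters and why their defaults are
what they are, what the synthetic-data generator does and does not emulate,
and the numerical and design decisions a maintainer should know about.

## 1. The measurement model

A facial scan is a triangle mesh in millimetres. Raw meshes are not
comparable across subjects: vertex counts, orderings and poses differ.
The pipeline constructs comparability in three steps.

**Dense registration.** One reference mesh (K vertices) is deformed onto
every scan. Vertex i of each deformed copy then denotes the same anatomical
location in all subjects — a *quasi-landmark*. Registration proceeds as:

* *Anchor initialisation* (`initialize_similarity()`): the least-squares
  similarity transform (Umeyama's method; rotation constrained proper) from
  the reference's eight anchor landmarks — pronasale, earlobes, cheilions,
  chin tip, hyoid, thyroid notch, in fixed order — onto the scan's. Eight
  well-spread points over-determine the seven similarity parameters, so a
  clicking error in one landmark degrades the start gracefully.
* *Rigid ICP* (`rigid_icp()`): iterate closest-surface-point
  correspondence, gate correspondences farther than `inlier_kappa` (3)
  times the median distance, re-fit a weighted similarity. The iterate with
  the smallest mean correspondence distance is returned, so the result is
  never worse than the initialisation.
* *Non-rigid deformation* (`nonrigid_register()`): per-iteration pull field
  from symmetric closest-point correspondences — every reference vertex is
  pulled toward the scan surface, and every scan vertex drags its nearest
  reference vertex, so scan regions not yet covered still attract the
  reference rather than being skipped. The pull field is smoothed by
  solving (I + λL)U = pull with L the uniform graph Laplacian of the
  reference, λ annealed linearly from `stiffness_start` (100) to
  `stiffness_end` (1): early iterations move the surface near-rigidly, late
  ones track local detail. Defaults (30 rigid, 80 non-rigid iterations,
  3-neighbour shortlist before exact point-to-triangle projection, 0.01 mm
  convergence) follow the schedule style of published dense-registration
  toolkits; all are exposed in `registration_params()` because no published
  parameter set exists for this application.

Two honest limitations. First, tangential identifiability: on a smooth,
textureless surface only the normal component of correspondence is pinned
by geometry; tangential position is regularised, not measured. Synthetic
experiments show point-to-surface residuals at the noise scale but
correspondence drift of roughly a fifth of a vertex spacing. Claims that
depend on exact per-vertex correspondence should be read with that floor in
mind. Second, the λ→∞ limit of the smoother is the *mean* pull (a global
translation), not exactly zero displacement, because constants lie in the
Laplacian's null space; "infinitely stiff" therefore reproduces the rigid
result only up to a small translation.

Divergence is declared when the mean correspondence distance sits 50%
above the best value seen for three consecutive iterations — loose enough
to tolerate transient rises while the stiffness anneals, strict enough to
catch a genuinely runaway fit.

**Generalized Procrustes Analysis** (`gpa()`). Full Procrustes: every
configuration is centred, scaled to unit centroid size, and rotated to the
current mean; the mean is recomputed and renormalised until its RMS change
falls below `tol` (1e-8, `max_iter` 100). Full rather than partial
Procrustes because the analysis deliberately removes size along with
location and orientation; an isolated size signal (e.g. BMI-related) is the
clinical covariates' job, not the shape space's. GPA leaves a global
rotation unresolved; we gauge it by rotating the final mean onto the first
sample's normalised configuration, making output deterministic and
order-invariant up to numerical noise. Because unit-size shapes live on a
sphere, the plain average of aligned shapes is slightly inside it; the
returned mean is the renormalised one.

**Shape PCA** (`fit_pca()`). Covariance PCA of the flattened aligned
coordinates — no per-landmark weighting, no correlation scaling, matching
standard geometric-morphometrics practice. Components are capped at the
maximal rank min(n−1, 3K) and signs fixed (largest-magnitude loading
positive) for determinism.

## 2. Prediction and evaluation

**PC-count selection.** For each candidate count p, LDA is fitted n times
leaving one subject out, using the first p PC scores; the n held-out
posterior probabilities are pooled into a single score vector and one AUC
is computed from it (`loocv_sweep()`). The argmax (smallest count on ties)
is selected. Pooling is forced by LOOCV — a single held-out sample has no
per-fold AUC — and is used identically for 10-fold CV so the two protocols
are comparable. The leave-one-out fits use exact mean/scatter downdates
rather than refits; tests verify equality with per-fold refits to 1e-9.

A property worth knowing: pooled LOOCV scores are *pessimistic under the
null*. Removing a sample drags its own class mean away from it, so with
uninformative features the pooled ranking falls below chance — dramatically
so for a single pure-noise feature, mildly for many. The sweep's null level
is therefore at-or-below 0.5, which also produces the characteristic
decline of the AUC curve once noise components are added past the true
signal dimension. Selection by argmax is correspondingly a noisy statistic
when the curve is flat near its top: counts beyond the signal dimension can
win by Monte-Carlo margins of a few thousandths of AUC.

**Classifier bank** (`crossval_bank()`). Ten algorithms under stratified
k-fold CV (folds dealt per class, so positive counts differ by less than
one). Hyperparameters are plain defaults — RBF-SVM at unit cost, 500-tree
forests, one hidden layer of 5 units with weight decay 0.01, 100 boosting
rounds at depth 3 — deliberately untuned; the bank ranks algorithm
families, it does not optimise any of them. No class rebalancing is applied
despite ~5% prevalence, matching how such banks are usually reported.
AdaBoost is implemented in-package as discrete boosting over depth-1 rpart
stumps (no boosting-of-stumps package is a dependency); all other members
wrap the standard implementations.

**Metrics.** AUC is the Mann–Whitney pair-counting estimator (ties ½). Its
95% CI is the DeLong variance-based normal interval, truncated to [0, 1];
degenerate data (AUC exactly 0 or 1) yields a point interval with a
warning. The operating point maximises the Youden index over observed
scores, ties broken toward higher sensitivity then lower threshold, with a
1e-9 tolerance when comparing index values so floating-point noise cannot
split a genuine tie. Sensitivity/specificity CIs are stratified bootstrap
percentile intervals (2,000 seeded resamples). The CI methods are our
choices, stated rather than claimed to match any particular prior report.

## 3. Clinical components

`label_dmv()` applies the Langeron criteria disjunctively (SpO₂ < 92% on
100% O₂, major leak, >15 L/min flow with repeated flush, no chest movement,
two-handed rescue, operator substitution) plus a tidal-volume rule
(< 5 mL/kg ideal body weight). Ideal body weight defaults to the Devine
formula and is a separate, replaceable function.

`diffmask_score()` sums a ten-component point table (age, sex, BMI, TMD,
Mallampati class, snoring, neck radiation, previous difficult intubation,
sleep apnea, beard) to a 0–18 range with an at-risk cut-off of 4. The
packaged table is a synthetic default honouring the published structure —
the exact published allocation is not redistributable — and is validated
(max exactly 18, monotone in every component) and replaceable via YAML.

`riley_min_n()` evaluates the three Riley criteria for binary-outcome
model development: expected shrinkage ≥ 0.9, apparent-R² optimism ≤ 0.05
of the maximal Cox–Snell R², and outcome-proportion precision ± 0.05; it
returns the ceiling of the largest. The anticipated Cox–Snell R² comes
from the C statistic and prevalence under a binormal score model. The
default conversion reproduces the reference implementation's convention
exactly — a seeded 10⁶-draw simulation with a logistic calibration fit and
4-decimal rounding — because that is what published sample-size numbers
were computed with; `method = "integration"` evaluates the same quantity by
exact numerical integration (they agree to ~0.3%, which can move the
ceiling by one case). Note that the overall minimum n is *not* globally
monotone in prevalence: the shrinkage criterion relaxes as the outcome
becomes less rare, but the proportion-precision criterion grows with
prevalence(1−prevalence) and takes over well before 0.5.

## 4. The synthetic-face generator

`make_template()` samples a closed-form parametric surface — a
half-ellipsoid depth field with a nose bump and a protruding jaw lobe — on
an r×r grid (r² vertices, 2(r−1)² triangles), designates eight anchor
vertices at fixed anatomical (u, v) targets, and records the mandibular
vertex mask. `sample_cohort()` then draws, per subject:

* mode scores bᵢ ~ N(0, mode_sdᵢ²) on smooth z-displacement fields —
  defaults: a broad global mode (SD 4 mm), an upper-face mode (SD 3 mm),
  and the mandibular field (SD 2 mm);
* for DMV cases (prevalence 0.0523), an additional displacement of
  `effect_size` (3 mm) along the mandibular field — a smooth plateau
  covering the mandibular region and rolling to zero exactly at the mask
  boundary. Making the case effect region-wide (not a narrow bump) and
  collinear with a population mode are deliberate: the planted group
  difference then lies inside the span of the leading PCs and inside the
  mask, which is what the recovery tests assert;
* iid vertex noise (SD 0.5 mm, the scale of scanner accuracy), a random
  similarity transform (rotation ≤ 20°, translation ≤ 30 mm, scale
  0.9–1.1 — large enough that alignment is non-trivial, small enough that
  anchor initialisation converges), and optionally re-evaluation on a
  jittered grid of different resolution (`resample`), which destroys
  trivial vertex correspondence the way real scanners do;
* clinical covariates with label-conditional shifts (age 34.3 ± 11.4 vs
  40.9 ± 12.6 years; BMI 21.9 ± 3.2 vs 27.3 ± 3.6 kg/m²; male 42.3% vs
  74.3%; snoring 40.4% vs 74.3%; rare flags at their cohort rates; no
  beards), reproducing the baseline contrasts of the clinical setting.

The effect size was fixed at 3 mm — 1.5 mandibular-mode SDs — so that a
well-specified 3-PC model has population discrimination near the AUCs
reported for real cohorts (≈ 0.82–0.86); with ~31 cases per 600 subjects
the cross-validated estimate fluctuates around that by ±0.04.

What the generator does **not** emulate: correlation between covariates
and shape (age/BMI/sex all shape the face in reality; here they are
independent channels, so the synthetic DIFFMASK score can outperform the
shape model in a way real data would not license); soft-tissue texture,
beards, holes and scanning artefacts; non-Gaussian shape variation; any
facial asymmetry modes. Passing tests therefore certify the *machinery* —
registration, alignment, decomposition, validation protocol, reporting —
not clinical performance on real faces.

## 5. Problem sizes and numerical choices

The test suite runs the full study conditions (600 subjects, template
resolution 24, K = 576, PC sweep 1–50, five pre-registered seeds) in the
fast corresponded-registration path, and exercises full registration on
meshes of 144–256 vertices and cohorts of up to 60 scans — sizes chosen so
the whole suite completes in a few minutes on one CPU. Registration cost
scales as K² per iteration (brute-force nearest neighbours); the K = 9,578
regime of real reference meshes parses and round-trips in the I/O layer
but is not registered in the tests.

Numerical conventions worth recording: proper rotations everywhere
(reflections never introduced, enforced via the SVD sign trick); zero
centroid size raises an error rather than producing NaNs; PCA signs and the
GPA gauge fix otherwise-arbitrary orientations; the Youden tie tolerance is
1e-9; the acceptance checks compare the rotation search of ordinary
Procrustes against a multi-start Euler-grid brute force to 1e-4. Stage
seeds in `run_pipeline()` derive deterministically from the master seed
(seed + 1000·stage), so any stage can be re-run in isolation and artifacts
reproduce bit for bit; functions with internal randomness (bootstrap CIs,
the Riley conversion) save and restore the caller's RNG state.

## 6. Known limitations

* Reference-mesh choice perturbs downstream AUC by a few hundredths at
  desk scale (0.03–0.04 on a 60-subject cohort); the invariance degrades if
  registration fidelity falls below the effect size, so coarse meshes and
  featureless regions are the enemy.
* The PC-count argmax is unstable when the sweep curve is flat past the
  signal dimension; selections a few counts above the true dimension carry
  essentially identical pooled AUC.
* The DIFFMASK default weights are structural stand-ins, not the published
  allocation; replace them before any use against real records.
* Full registration is O(K²) per iteration and single-threaded; it is a
  desk-scale research implementation, not a production registrar.
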