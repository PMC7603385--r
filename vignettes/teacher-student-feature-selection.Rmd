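---
title: "Teacher–student distillation feature selection for functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Teacher–student distillation feature selection for functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Resting-state fMRI yields, for each subject, a time series of BOLD activity
in each parcel of a brain atlas. The functional connectivity between two
regions is the Pearson correlation of their time series; over `R` regions
this gives a symmetric `R x R` matrix whose `R(R-1)/2` upper-triangle
entries form the subject's feature vector (4005 features for the 90-region
AAL parcellation). Case–control differences in a disorder such as autism
are expressed as *altered connectivity* in a subset of region pairs, and
the analysis problem is to find that subset when the feature dimension far
exceeds the number of subjects.

`tsfs` implements a three-stage feature-selection pipeline for this
setting:

1. **Teacher.** A deep funnel classifier (input `n` → progressively
   narrower hidden layers → a small *code* layer → 2-unit softmax head) is
   trained to discriminate cases from controls on the connectivity
   features. The code layer (5 units by default) is a learned
   low-dimensional embedding that concentrates whatever the network found
   discriminative.
2. **Student.** The codes are standardized per dimension (zero mean, unit
   population sd) and a one-hidden-layer network (`n` → 100 relu units →
   `d` linear outputs) is distilled to reproduce them from the raw
   features, with a sparsity penalty on the input weight matrix `W`
   (`n x h`). The importance of feature `i` is `s_i = sum_j W_ij^2`, the
   `i`-th diagonal entry of `W W'`: a feature can only earn a large squared
   row norm if the student leans on it to reproduce the codes.
3. **Forward selection.** Features are ranked by decreasing `s_i` and a
   cumulative forward scan evaluates nested prefixes (step size 50 by
   default) by stratified k-fold accuracy of a conventional classifier,
   returning the prefix with the best mean accuracy (ties go to the
   smaller prefix).

Selected features are then mapped back to region pairs for anatomical
reporting: lobe-wise and hemisphere-wise count tables, and node/edge files
for BrainNet Viewer.

## Model assumptions

* Connectivity is linear and stationary: plain Pearson correlation over
  the full series, no partial correlation or tangent-space embedding.
* Labels are binary with class 1 the case (positive) class; sensitivity is
  reported for class 1.
* Feature importance is meaningful only because the student is *shallow*
  and *regularized*: with one hidden layer, each input feature's entire
  influence flows through its weight row, so the squared row norm is an
  honest budget of how much the network uses that feature. The default
  penalty is a row-wise group lasso (`strength * sum_i ||W_i.||_2`),
  which switches whole features off rather than individual weights; plain
  L1 is available.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| teacher depth | 17 layers incl. input/output | deep funnel; widths interpolate geometrically from `n` to the code width |
| code width `d` | 5 | small enough to force compression, large enough to carry class structure |
| teacher activation | tanh | correlations are signed in `[-1, 1]`; relu would discard the negative half |
| teacher dropout | 0.3 → 0 linearly to the code layer | regularizes the wide early layers, leaves the code clean |
| teacher optimizer | Adadelta, lr 0.001, 500 epochs, batch 16 | scale-adaptive updates; low rate with many epochs for stable loss |
| student hidden `h` | 100 relu units | enough capacity to reproduce 5 codes; relu is safe here because inputs to it are the (signed) features times learned weights and the output layer is linear |
| student loss / lr | MSE, Adadelta lr 0.01, 500 epochs | reproduction task; the one-hidden-layer network tolerates (and needs) a higher rate |
| student penalty strength | 1e-4 | light default; see the calibration note below |
| selection step | 50 | coarse scan to keep classifier refits affordable at `n = 4005` |
| cv folds | 10 combined / 5 site-wise | convention for this cohort size |

Classifiers available to the scan and the evaluation reports: `lr`
(ridge-penalized logistic regression, lambda `1/m`), `svm` (linear kernel,
cost 1), `ld` (linear discriminant), `rf` (100 trees), `dt` (decision
tree). All are seeded; `lr` is the default.

## The synthetic cohort generator

Because multi-site clinical rs-fMRI data cannot be shipped, the package
generates two-class cohorts with *planted* class-discriminative
correlations. Under the latent-factor model, every subject's region series
is white Gaussian noise with sd `noise_sd`; for class-1 subjects each
planted pair `(j, k)` additionally mixes a shared standard-normal latent
series into both regions with weight `a = noise_sd * sqrt(effect / (1 -
effect))`, so the pair's population correlation is exactly `effect` in
class 1 and 0 in class 0, while non-planted pairs are identically
distributed in both classes. Sites are dealt round-robin within class so
site-wise evaluation always sees both classes.

What the generator does **not** emulate: BOLD autocorrelation, scanner
drift, motion artifacts, site-specific covariance structure, or
between-subject heterogeneity of the planted correlation. Consequently a
planted effect of 0.6 at `T = 200` time points is a *much* cleaner signal
than any real clinical effect: the between-class offset (0.6) dwarfs the
within-class sampling noise of a correlation estimate (about 0.05–0.07).
Passing the recovery tests therefore shows that the pipeline's machinery
is correct and well-calibrated, not that it would reach the same accuracy
on real cohorts.

One visible consequence, computed by the package's own acceptance tests:
on the reduced planted cohort the 10-fold accuracy curve over cumulative
prefixes is flat at 1.0 from the very first prefix — a single planted
feature already separates the classes — so the classic underfit → peak →
overfit arc does not appear there; the smallest-prefix tie-break still
returns a compact selection. The arc is a property of marginally
informative, heterogeneous features, which the clean generator does not
produce at this effect size.

## Reduced study configuration

The test suite and `scripts/acceptance.R` use a desk-scale configuration
so the full pipeline runs in seconds: 40 subjects per class, `R = 20`
regions (190 features), `T = 200` time points, 10 disjoint planted pairs
at effect 0.6, noise sd 0.5; teacher = the default 17-layer funnel from
190 features trained 100 epochs at Adadelta lr 0.01; student trained 500
epochs at lr 0.01 with row-group penalty strength 0.02. The two learning
rates and the penalty strength were calibrated once on this reduced
cohort with a small pilot over five seeds — at the paper-scale defaults
(lr 0.001, strength 1e-4) the 500 Adadelta updates available in a
100-epoch desk run barely move the deep net, and the lightly penalized
student spreads weight over many features; strength 0.02 concentrated all
ten planted pairs into the top 20 ranks on every pilot seed. Package
defaults are unchanged; the reduced values are experiment configuration.

## Numerical and design choices

* **Upper-triangle order.** Features are the row-major upper triangle over
  1-based indices: `(1,2), (1,3), ..., (1,R), (2,3), ...`. All rankings,
  selections and exports use this fixed bijection (`feature_to_pair()` /
  `pair_to_feature()`).
* **Codes post-activation.** The embedding is taken as the code layer's
  activation output (tanh), matching what the next layer of the teacher
  sees; `extract_codes(pre_activation = TRUE)` gives the pre-activation.
* **Standardization.** Population sd (divide by `m`); parameters are kept
  so the identical transform can be applied to held-out subjects.
* **`W` orientation.** The scored matrix is features × hidden units —
  the orientation in which `diag(W W')` indexes features.
* **Sort direction.** Scores sort descending (large squared row norm =
  heavily used feature); `rank_features(decreasing = FALSE)` inverts.
* **Forward-scan stop rule.** The full curve is always recorded and the
  argmax prefix returned; an accuracy threshold, when supplied, acts as
  an early stop (`accuracy >= threshold`) rather than an equality test.
* **Tie-breaks.** Equal scores rank by lower feature index; equal
  accuracies select the smaller prefix.
* **Zero-variance regions** are a hard error naming the region, never a
  silent NaN; zero-denominator sensitivity/specificity is NA with a
  warning, never 0 or 1.
* **Site-wise evaluation** reuses the features selected on the combined
  cohort (re-selection per site is available by simply running the
  pipeline on a site subset); sites with fewer than two subjects in
  either class are skipped with a warning, and the fold count within a
  site is capped at the smaller class count.
* **Determinism.** Every stochastic step (initialization, batch
  shuffling, dropout, fold assignment, forest growing) draws from a
  seeded stream; repeated calls with the same specs are identical.
* **Leakage scope.** Codes are extracted, and the ranking computed, on
  the full cohort by design — the distillation is a representation of the
  whole dataset, not a predictive model. Cross-validated accuracies
  downstream therefore carry a small optimism under the null (the
  acceptance tests measure it at roughly +0.06 on 80-subject null
  cohorts); leakage-free protocols should re-run the ranking inside each
  training fold.

## The packaged atlas

`aal90_atlas()` ships the standard AAL-90 region names and hemispheres
with the package's lobe partition (Frontal, Insula, Limbic,
Medial-Temporal, Occipital, Parietal, Subcortical, Temporal). The centroid
coordinates in the fixture are synthetic approximations (the file is named
`aal90_atlas_synthetic.csv` accordingly): they make the BrainNet export
format complete and testable but are not measured AAL centroids. Supply a
real atlas table through `read_atlas()` for anatomical work.

## Worked example

```{r, eval = FALSE}
library(tsfs)

spec <- cohort_spec(
  n_per_class = 40, R = 20, T_len = 200,
  planted_pairs = sample_planted_pairs(10, 20, seed = 99),
  effect = 0.6, noise_sd = 0.5, seed = 7
)
cohort <- generate_cohort(spec)
design <- build_design_matrix(cohort)

ranking <- rank_pipeline(
  design$X, design$labels,
  teacher = default_teacher_spec(ncol(design$X), epochs = 100,
                                 learning_rate = 0.01, seed = 8),
  student = student_spec(learning_rate = 0.01, epochs = 500,
                         strength = 0.02, seed = 9)
)

sel <- sffs_select(design$X, design$labels, ranking,
                   selection_config(step = 5, classifier = "lr",
                                    cv_folds = 10, seed = 10))
kfold_evaluate(design$X, design$labels, "lr", k = 10, seed = 11,
               selected = sel$selected_indices)
```

## Known limitations

* The MLP engine is plain R matrix code: fine at desk scale and for
  AAL-sized cohorts, but a 4005-feature teacher at 500 epochs is minutes,
  not seconds, of CPU.
* `ld` (MASS discriminant) degrades when the prefix width approaches the
  fold's training size; the scan records whatever accuracy results.
* The generator's cleanliness means thresholds validated here transfer to
  real data only directionally (see above).
* Model checkpointing is plain R serialization of the weight lists via
  `saveRDS()` by the user; no exchange format is defined.
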