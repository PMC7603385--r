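# tsfs — teacher–student distillation feature selection for functional connectivity

`tsfs` finds the region-pair connectivity features that discriminate two
groups of subjects — e.g. a clinical case group against healthy controls —
from resting-state fMRI. It is aimed at connectomics researchers who work
with parcellated ROI time series (AAL-90 and similar atlases) and want a
compact, anatomically reportable feature set rather than a black-box
classifier.

## The method

Each subject's `T x R` ROI time-series matrix becomes a symmetric `R x R`
Pearson connectivity matrix `C`, and its `n = R(R-1)/2` upper-triangle
entries form the feature vector (4005 features for `R = 90`). Selection
then runs in three stages:

1. **Teacher.** A deep funnel network (17 layers by default, widths
   shrinking geometrically from `n` through a 5-unit *code* layer to a
   2-unit softmax head) is trained with binary cross-entropy and Adadelta
   to classify subjects. The code layer is a learned 5-dimensional
   embedding of each subject.
2. **Student.** The standardized codes are distilled into a one-hidden-
   layer network (`n` → 100 relu → 5 linear) trained with MSE and a
   row-sparsity penalty on its input weight matrix `W` (`n x h`). Feature
   importance is

   `s_i = Σ_j W_ij² = diag(W Wᵀ)_i`,

   the squared norm of feature `i`'s weight row — large only if the
   student relies on that feature to reproduce the codes.
3. **Cumulative forward selection.** Features are ranked by decreasing
   `s_i`; nested prefixes (step 50 by default) are scored by stratified
   k-fold accuracy of a standard classifier (logistic regression, linear
   SVM, LDA, random forest or decision tree), and the best prefix wins
   (ties go to fewer features).

Selected features map back to region pairs for anatomical reporting:
lobe-wise and hemisphere-wise count tables and BrainNet Viewer
`.node`/`.edge` exports.

Because clinical rs-fMRI cohorts cannot be redistributed, the package
includes a seeded synthetic-cohort generator that plants class-
discriminative correlations into chosen region pairs at a configurable
effect size, so the whole pipeline is testable end to end.

## Worked example

Generate a cohort of 40 + 40 subjects over 20 regions with 10 planted
pairs at correlation effect 0.6, rank features, and select:

```r
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
planted <- pair_to_feature(spec$planted_pairs[, 1], spec$planted_pairs[, 2], 20)
sum(planted %in% head(ranking$order, 20))

sel <- sffs_select(design$X, design$labels, ranking,
                   selection_config(step = 5, classifier = "lr",
                                    cv_folds = 10, seed = 10))
sel
kfold_evaluate(design$X, design$labels, "lr", k = 10, seed = 11,
               selected = sel$selected_indices)
```

Output:

```
synthetic cohort: 80 subjects (40 case / 40 control), T=200, R=20, 10 planted pair(s)
[1] 10
forward selection [lr]: best step 1 (5 features), accuracy 1.000 over 38 prefixes
[lr, combined] 10-fold accuracy 1.000, sensitivity 1.000, specificity 1.000
```

All 10 planted pairs land in the top 20 of 190 ranked features; the
forward scan keeps only 5 features (smallest prefix at the accuracy
ceiling — the planted signal at this effect size is strong enough that
accuracy saturates immediately), and those 5 features alone classify the
held-out folds perfectly. On a zero-effect cohort the same pipeline shows
no planted enrichment and chance-level accuracy.

Anatomical reporting on a real-scale selection:

```r
atlas <- aal90_atlas()   # names/lobes real; centroids synthetic, see docs
edges <- features_to_edges(selected_indices, R = 90)
lobe_counts(edges, atlas)
hemisphere_counts(edges, atlas)
export_brainnet(edges, atlas, "sel.node", "sel.edge", top_k = 50)
```

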