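# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays fast.

# The reduced study cohort used by the recovery and selection tests:
# 40 subjects per class, 20 regions (190 features), 200 time points,
# 10 disjoint planted pairs at effect 0.6, noise sd 0.5.
study_cohort_spec <- function(seed = 7, effect = 0.6) {
  cohort_spec(
    n_per_class = 40, R = 20, T_len = 200,
    planted_pairs = sample_planted_pairs(10, 20, seed = 99),
    effect = effect, noise_sd = 0.5, seed = seed
  )
}

planted_feature_idx <- function(spec) {
  pair_to_feature(spec$planted_pairs[, 1], spec$planted_pairs[, 2], spec$R)
}

# Desk-scale network settings used with the reduced cohort. Chosen once
# from pre-build pilot runs; documented in the methods vignette.
reduced_teacher <- function(n, seed = 1) {
  default_teacher_spec(n, epochs = 100L, learning_rate = 0.01, seed = seed)
}

reduced_student <- function(seed = 2) {
  student_spec(learning_rate = 0.01, epochs = 500L, strength = 0.02, seed = seed)
}

# Two well-separated Gaussian blobs.
toy_blobs <- function(n_per_class = 30, sep = 4, seed = 42, dim = 2) {
  set.seed(seed)
  X <- rbind(
    matrix(rnorm(dim * n_per_class), ncol = dim),
    matrix(rnorm(dim * n_per_class, mean = sep), ncol = dim)
  )
  list(X = X, y = rep(c(0L, 1L), each = n_per_class))
}

# Tiny atlas with two lobes and both hemispheres, for count tests.
toy_atlas <- function() {
  df <- data.frame(
    index = 1:6,
    name = c("FrA_L", "FrA_R", "FrB_L", "FrB_R", "ParA_L", "ParA_R"),
    lobe = c("Frontal", "Frontal", "Frontal", "Frontal", "Parietal", "Parietal"),
    hemisphere = c("L", "R", "L", "R", "L", "R"),
    x = c(-10, 10, -20, 20, -30, 30), y = 0, z = 0
  )
  class(df) <- c("atlas_info", "data.frame")
  df
}

random_edges <- function(n_edges, R, seed = 1) {
  set.seed(seed)
  features_to_edges(sample.int(n_features(R), n_edges), R)
}
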