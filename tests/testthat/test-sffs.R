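test_that("cumulative prefixes are nested with the declared sizes", {
  ord <- sample(4005)
  sets <- cumulative_sets(ord, step = 50)
  expect_length(sets[[1]], 50)
  expect_length(sets[[2]], 100)
  expect_identical(sets[[2]][1:50], sets[[1]])
  expect_length(sets[[length(sets)]], 4005)
  # truncation at max_features
  sizes <- vapply(cumulative_sets(ord, 50, max_features = 120), length, 0L)
  expect_identical(sizes, c(50L, 100L, 120L))
  # step 1 enumerates singleton growth
  s3 <- cumulative_sets(c(7L, 2L, 9L), step = 1)
  expect_identical(s3, list(7L, c(7L, 2L), c(7L, 2L, 9L)))
  expect_error(cumulative_sets(integer(0), 1), "empty")
  # nestedness on a random case
  sets2 <- cumulative_sets(sample(100), step = 7)
  for (t in seq_len(length(sets2) - 1)) {
    expect_identical(sets2[[t]], sets2[[t + 1]][seq_along(sets2[[t]])])
  }
})

test_that("argmax picks the peak and ties break toward fewer features", {
  expect_identical(tsfs:::.select_best(c(0.5, 0.7, 0.6)), 2L)
  expect_identical(tsfs:::.select_best(c(0.7, 0.7)), 1L)
})

test_that("sffs_select equals an exhaustive prefix scan with shared folds", {
  set.seed(50)
  m <- 40
  X <- cbind(matrix(rnorm(m * 2, mean = rep(c(0, 1.5), each = m / 2)), m, 2),
             matrix(rnorm(m * 6), m, 6))
  y <- rep(c(0L, 1L), each = m / 2)
  cfg <- selection_config(step = 2, classifier = "lr", cv_folds = 5, seed = 9)
  res <- sffs_select(X, y, 1:8, cfg)
  # oracle: evaluate every prefix independently with the same fold split
  folds <- stratified_folds(y, 5, 9)
  oracle_acc <- vapply(cumulative_sets(1:8, 2), function(idx) {
    mean(vapply(1:5, function(f) {
      tr <- folds != f
      set.seed(9 + f)
      fit <- glmnet::glmnet(X[tr, idx, drop = FALSE], factor(y[tr], levels = c(0, 1)),
                            family = "binomial", alpha = 0, lambda = 1 / sum(tr))
      pred <- as.integer(predict(fit, X[!tr, idx, drop = FALSE],
                                 type = "response")[, 1] > 0.5)
      mean(pred == y[!tr])
    }, 0))
  }, 0)
  expect_equal(res$accuracies, oracle_acc, tolerance = 1e-12)
  expect_identical(res$best_step, which.max(oracle_acc))
  expect_identical(res$selected_indices, (1:8)[seq_len(res$steps[res$best_step])])
  expect_true(all(res$accuracies >= 0 & res$accuracies <= 1))
})

test_that("selection is deterministic and the threshold branch stops early", {
  set.seed(51)
  X <- matrix(rnorm(30 * 6), 30, 6)
  X[, 1] <- X[, 1] + rep(c(0, 3), each = 15)
  y <- rep(c(0L, 1L), each = 15)
  cfg <- selection_config(step = 2, classifier = "lr", cv_folds = 3, seed = 4)
  a <- sffs_select(X, y, 1:6, cfg)
  b <- sffs_select(X, y, 1:6, cfg)
  expect_identical(a$accuracies, b$accuracies)
  cfg_thr <- selection_config(step = 2, classifier = "lr", cv_folds = 3,
                              threshold = 0.5, seed = 4)
  res <- sffs_select(X, y, 1:6, cfg_thr)
  expect_true(res$stopped_early)
  expect_lt(length(res$accuracies), 3)
  expect_gte(res$accuracies[res$best_step], 0.5)
})

test_that("unknown classifiers and degenerate labels are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(sffs_select(X, rep(0L, 10), 1:2, selection_config(step = 1, cv_folds = 2)),
               "both classes")
  expect_error(get_classifier("boosted-mystery"), "unknown classifier")
})

test_that("accuracy_curve_report summarises one row per classifier", {
  r1 <- structure(list(steps = c(2L, 4L), accuracies = c(.6, .7), best_step = 2L,
                       selected_indices = 1:4, classifier = "lr"),
                  class = "selection_result")
  r2 <- structure(list(steps = c(2L, 4L), accuracies = c(.8, .6), best_step = 1L,
                       selected_indices = 1:2, classifier = "svm"),
                  class = "selection_result")
  tab <- accuracy_curve_report(list(r1, r2))
  expect_identical(nrow(tab), 2L)
  expect_identical(names(tab), c("Sr No.", "Classifier Name",
                                 "Max Cumulative Feature Step", "Features Count"))
  expect_identical(tab$`Features Count`,
                   vapply(list(r1, r2), function(r) length(r$selected_indices), 0L))
})

test_that("common_features intersects selections", {
  expect_identical(common_features(c(1L, 2L, 3L), c(2L, 3L, 4L)), c(2L, 3L))
  expect_identical(common_features(c(1L, 5L), c(1L, 5L), c(5L, 1L)), c(1L, 5L))
  expect_warning(out <- common_features(c(1L, 2L), c(3L, 4L)), "no features")
  expect_length(out, 0)
  expect_error(common_features(c(1L, 2L)), "at least two")
})
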