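test_that("confusion metrics match hand counts and edge cases", {
  # TP=1 FN=1 TN=2 FP=0
  m <- confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
  expect_equal(unname(m), c(0.75, 0.5, 1.0))
  expect_equal(unname(confusion_metrics(c(1, 0, 1), c(1, 0, 1))), c(1, 1, 1))
  expect_equal(unname(confusion_metrics(c(1, 0), c(0, 1))), c(0, 0, 0))
  expect_warning(m0 <- confusion_metrics(c(0, 0), c(0, 1)), "sensitivity undefined")
  expect_true(is.na(m0["sensitivity"]))
  expect_false(is.na(m0["specificity"]))
  expect_error(confusion_metrics(c(1, 0), c(1)), "length mismatch")
  expect_error(confusion_metrics(c(2, 0), c(1, 0)), "0/1")
})

test_that("metrics swap under simultaneous 0/1 relabeling", {
  set.seed(12)
  y <- rbinom(40, 1, 0.5)
  p <- rbinom(40, 1, 0.5)
  a <- confusion_metrics(y, p)
  b <- confusion_metrics(1 - y, 1 - p)
  expect_equal(a[["accuracy"]], b[["accuracy"]])
  expect_equal(a[["sensitivity"]], b[["specificity"]])
  expect_equal(a[["specificity"]], b[["sensitivity"]])
})

test_that("stratified folds preserve class balance and respect limits", {
  y <- rep(c(0L, 1L), c(30, 20))
  f <- stratified_folds(y, 10, seed = 1)
  expect_true(all(table(f) == 5))
  expect_true(all(table(f[y == 1]) == 2))
  expect_error(stratified_folds(rep(c(0L, 1L), c(30, 4)), 5), "at least k")
  expect_identical(stratified_folds(y, 10, seed = 1), f)
})

test_that("k-fold evaluation scores separable data perfectly and is seeded", {
  blobs <- toy_blobs(n_per_class = 20, sep = 6, seed = 14)
  rep1 <- kfold_evaluate(blobs$X, blobs$y, "lr", k = 5, seed = 3)
  expect_equal(rep1$accuracy, 1)
  expect_equal(rep1$sensitivity, 1)
  expect_equal(rep1$specificity, 1)
  expect_identical(nrow(rep1$per_fold), 5L)
  rep2 <- kfold_evaluate(blobs$X, blobs$y, "lr", k = 5, seed = 3)
  expect_identical(rep1$per_fold, rep2$per_fold)
  # aggregate equals the mean of per-fold values
  expect_equal(rep1$accuracy, mean(rep1$per_fold$accuracy))
})

test_that("majority baseline accuracy equals the majority class fraction", {
  y <- rep(c(0L, 1L), c(28, 12))
  set.seed(5)
  X <- matrix(rnorm(80), 40, 2)
  majority <- list(
    fit = function(X, y) as.integer(names(which.max(table(y)))),
    predict = function(model, X) rep(model, nrow(X))
  )
  rep <- kfold_evaluate(X, y, majority, k = 4, seed = 2)
  expect_equal(rep$accuracy, 0.7, tolerance = 1e-12)
})

test_that("label permutation drives accuracy to chance", {
  spec <- cohort_spec(20, 8, 60, rbind(c(1, 2), c(3, 4)), effect = 0.7, seed = 6)
  d <- build_design_matrix(generate_cohort(spec))
  set.seed(99)
  accs <- vapply(1:10, function(i) {
    kfold_evaluate(d$X, sample(d$labels), "lr", k = 5, seed = i)$accuracy
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("site-wise evaluation reports per site and skips one-class sites", {
  spec <- cohort_spec(20, 8, 60, rbind(c(1, 2)), effect = 0.8,
                      sites = c("s1", "s2"), seed = 9)
  d <- build_design_matrix(generate_cohort(spec))
  reps <- site_wise_evaluate(d$X, d$labels, d$sites, classifier = "lr",
                             k = 5, seed = 1)
  expect_named(reps, c("s1", "s2"))
  expect_identical(reps$s1$scope, "site:s1")
  # a site holding only controls is skipped with a warning
  sites2 <- d$sites
  sites2[d$labels == 1 & d$sites == "s2"] <- "s1"
  expect_warning(reps2 <- site_wise_evaluate(d$X, d$labels, sites2, k = 5),
                 "skipped")
  expect_named(reps2, "s1")
})

test_that("report tables carry the published layouts", {
  blobs <- toy_blobs(n_per_class = 15, sep = 5, seed = 20)
  reps <- lapply(c("lr", "dt"), function(clf) {
    kfold_evaluate(blobs$X, blobs$y, clf, k = 3, seed = 1)
  })
  tab <- combined_report_table(reps)
  expect_identical(names(tab),
                   c("Sr No.", "Classifier Name", "Accuracy", "Sensitivity", "Specificity"))
  expect_identical(tab$`Classifier Name`, c("lr", "dt"))
  spec <- cohort_spec(12, 6, 40, rbind(c(1, 2)), effect = 0.8,
                      sites = c("s1", "s2"), seed = 10)
  d <- build_design_matrix(generate_cohort(spec))
  site_reps <- suppressWarnings(list( # glmnet grumbles at tiny per-site folds
    lr = site_wise_evaluate(d$X, d$labels, d$sites, classifier = "lr", k = 3),
    dt = site_wise_evaluate(d$X, d$labels, d$sites, classifier = "dt", k = 3)
  ))
  stab <- site_report_table(site_reps)
  expect_identical(names(stab), c("Sr", "Site", "lr", "dt"))
  expect_identical(stab$Site, c("s1", "s2"))
})
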