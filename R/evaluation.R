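#' Stratified cross-validation fold assignment
#'
#' Shuffles each class separately and deals its members over the folds
#' cyclically, so every fold keeps the cohort's class balance as closely
#' as integer counts allow.
#'
#' @param labels 0/1 vector.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  stopifnot(k >= 2)
  if (min(table(labels)) < k) {
    stop("need at least k = ", k, " subjects in each class for stratified folds")
  }
  set.seed(seed)
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Accuracy, sensitivity and specificity from labels
#'
#' Positive class is 1 (case). Sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP). A zero denominator (no positives, or no negatives, in
#' `y_true`) yields NA with a warning — never a silent 0 or 1.
#'
#' @param y_true,y_pred equal-length 0/1 vectors.
#' @return named numeric vector `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 1) stop("empty input")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop("labels must be 0/1")
  }
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  sens <- if (tp + fn == 0) {
    warning("no positive subjects: sensitivity undefined (NA)")
    NA_real_
  } else tp / (tp + fn)
  spec <- if (tn + fp == 0) {
    warning("no negative subjects: specificity undefined (NA)")
    NA_real_
  } else tn / (tn + fp)
  c(accuracy = (tp + tn) / length(y_true), sensitivity = sens, specificity = spec)
}

.new_metrics_report <- function(classifier, scope, per_fold) {
  structure(list(
    classifier = classifier, scope = scope, folds = nrow(per_fold),
    accuracy = mean(per_fold$accuracy, na.rm = TRUE),
    sensitivity = mean(per_fold$sensitivity, na.rm = TRUE),
    specificity = mean(per_fold$specificity, na.rm = TRUE),
    per_fold = per_fold
  ), class = "metrics_report")
}

#' Stratified k-fold evaluation of a feature subset
#'
#' Trains the classifier on k-1 folds and scores the held-out fold;
#' aggregates are unweighted means over folds (folds whose held-out part
#' lacks a class contribute NA to that metric and are dropped from its
#' mean).
#'
#' @param X m x n design matrix (already restricted to the features of
#'   interest, or use `selected`).
#' @param labels 0/1 vector.
#' @param classifier name or custom list, see [get_classifier()].
#' @param k folds (default 10).
#' @param seed integer seed for fold assignment and the classifier fits.
#' @param selected optional feature (column) indices to use.
#' @return object of class `metrics_report`.
#' @export
kfold_evaluate <- function(X, labels, classifier = "lr", k = 10L, seed = 1L,
                           selected = NULL) {
  X <- as.matrix(X)
  if (!is.null(selected)) X <- X[, selected, drop = FALSE]
  labels <- as.integer(labels)
  folds <- stratified_folds(labels, k, seed)
  clf <- get_classifier(classifier)
  per_fold <- do.call(rbind, lapply(seq_len(k), function(f) {
    tr <- folds != f
    set.seed(seed + f) # seeds any stochastic fit (rf)
    model <- clf$fit(X[tr, , drop = FALSE], labels[tr])
    pred <- clf$predict(model, X[!tr, , drop = FALSE])
    m <- suppressWarnings(confusion_metrics(labels[!tr], pred))
    data.frame(fold = f, accuracy = m["accuracy"], sensitivity = m["sensitivity"],
               specificity = m["specificity"], row.names = NULL)
  }))
  name <- if (is.character(classifier)) classifier else "custom"
  .new_metrics_report(name, "combined", per_fold)
}

#' Site-wise k-fold evaluation of a fixed feature subset
#'
#' Evaluates the same selected features separately within each
#' acquisition site, which probes whether a selection made on the
#' combined cohort survives site heterogeneity. Features are *not*
#' re-selected per site. Sites with fewer than 2 subjects in either class
#' are skipped with a warning; within an included site the fold count is
#' capped at the smaller class count.
#'
#' @param X m x n design matrix.
#' @param labels 0/1 vector.
#' @param sites character vector of site ids.
#' @param selected feature indices fixed across sites.
#' @param classifier see [get_classifier()].
#' @param k folds per site (default 5).
#' @param seed integer seed.
#' @return named list of `metrics_report`, one per evaluated site.
#' @export
site_wise_evaluate <- function(X, labels, sites, selected = NULL,
                               classifier = "lr", k = 5L, seed = 1L) {
  X <- as.matrix(X)
  labels <- as.integer(labels)
  stopifnot(length(sites) == nrow(X))
  out <- list()
  for (s in unique(sites)) {
    idx <- which(sites == s)
    cls <- table(factor(labels[idx], levels = c(0, 1)))
    if (min(cls) < 2) {
      warning("site '", s, "' skipped: fewer than 2 subjects in a class")
      next
    }
    k_eff <- min(k, min(cls))
    rep <- kfold_evaluate(X[idx, , drop = FALSE], labels[idx], classifier,
                          k = k_eff, seed = seed, selected = selected)
    rep$scope <- paste0("site:", s)
    out[[s]] <- rep
  }
  out
}

#' Combined-cohort report table
#'
#' One row per classifier's `metrics_report`, in the layout of the
#' package's combined-cohort results table.
#'
#' @param reports list of `metrics_report`s.
#' @return data frame with columns `Sr No.`, `Classifier Name`,
#'   `Accuracy`, `Sensitivity`, `Specificity`.
#' @export
combined_report_table <- function(reports) {
  stopifnot(length(reports) >= 1)
  df <- data.frame(
    seq_along(reports),
    vapply(reports, `[[`, "", "classifier"),
    vapply(reports, `[[`, 0, "accuracy"),
    vapply(reports, `[[`, 0, "sensitivity"),
    vapply(reports, `[[`, 0, "specificity"),
    check.names = FALSE
  )
  names(df) <- c("Sr No.", "Classifier Name", "Accuracy", "Sensitivity", "Specificity")
  df
}

#' Site-wise report table
#'
#' One row per site, one accuracy column per classifier, in the layout of
#' the package's site-wise results table.
#'
#' @param site_reports named list (by classifier) of lists of per-site
#'   `metrics_report`s, as returned by [site_wise_evaluate()].
#' @return data frame with columns `Sr`, `Site`, then one column per
#'   classifier.
#' @export
site_report_table <- function(site_reports) {
  stopifnot(length(site_reports) >= 1)
  sites <- unique(unlist(lapply(site_reports, names)))
  df <- data.frame(Sr = seq_along(sites), Site = sites, check.names = FALSE)
  for (clf in names(site_reports)) {
    df[[clf]] <- vapply(sites, function(s) {
      r <- site_reports[[clf]][[s]]
      if (is.null(r)) NA_real_ else r$accuracy
    }, 0)
  }
  df
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("[%s, %s] %d-fold accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
              x$classifier, x$scope, x$folds, x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}
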