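#' Configuration for cumulative forward feature selection
#'
#' The scan walks nested prefixes of the ranked feature list in
#' increments of `step`, measures stratified k-fold accuracy at each
#' prefix, and returns the prefix with the highest mean accuracy (ties
#' broken toward fewer features). If `threshold` is set, the scan stops
#' early at the first prefix whose accuracy reaches it.
#'
#' @param step features added per forward step (default 50).
#' @param max_features cap on the scan (default `Inf` = all ranked
#'   features).
#' @param classifier `"lr"`, `"svm"`, `"ld"`, `"rf"`, `"dt"`, or a custom
#'   fit/predict list.
#' @param cv_folds stratified folds (default 10).
#' @param threshold optional early-stop accuracy in `[0, 1]`.
#' @param seed integer seed (folds + stochastic classifiers).
#' @return object of class `selection_config`.
#' @export
selection_config <- function(step = 50L, max_features = Inf, classifier = "lr",
                             cv_folds = 10L, threshold = NULL, seed = 1L) {
  stopifnot(step >= 1, cv_folds >= 2)
  if (!is.null(threshold) && (threshold < 0 || threshold > 1)) {
    stop("threshold must lie in [0, 1]")
  }
  structure(list(step = as.integer(step), max_features = max_features,
                 classifier = classifier, cv_folds = as.integer(cv_folds),
                 threshold = threshold, seed = as.integer(seed)),
            class = "selection_config")
}

#' Nested cumulative prefixes of a ranking
#'
#' Prefix t holds the first `min(t * step, max_features)` ranked feature
#' indices; prefixes are nested by construction.
#'
#' @param order integer vector of ranked feature indices (best first), or
#'   an `importance_ranking`.
#' @param step features per step.
#' @param max_features cap (default all of `order`).
#' @return list of integer vectors.
#' @export
cumulative_sets <- function(order, step = 50L, max_features = Inf) {
  if (inherits(order, "importance_ranking")) order <- order$order
  if (length(order) == 0) stop("empty ranking")
  stopifnot(step >= 1)
  limit <- min(length(order), max_features)
  sizes <- unique(pmin(seq(step, limit + step - 1L, by = step), limit))
  lapply(sizes, function(s) order[seq_len(s)])
}

.select_best <- function(accuracies) {
  # argmax with smallest-prefix tie-break (which.max takes the first max)
  which.max(accuracies)
}

#' Cumulative sequential forward feature selection
#'
#' Evaluates every cumulative prefix of the ranked features by stratified
#' k-fold accuracy (same folds for every prefix) and selects the argmax
#' prefix. Records the full accuracy curve, whose typical shape is
#' underfit (too few features) -> peak -> overfit (too many).
#'
#' @param X m x n design matrix.
#' @param labels 0/1 vector.
#' @param order ranked feature indices (best first) or an
#'   `importance_ranking`.
#' @param config a [selection_config()].
#' @return object of class `selection_result`: `steps` (cumulative
#'   feature counts), `accuracies`, `best_step` (index into `steps`),
#'   `selected_indices`, `classifier`, `stopped_early`.
#' @export
sffs_select <- function(X, labels, order, config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  X <- as.matrix(X)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  prefixes <- cumulative_sets(order, config$step, config$max_features)
  folds <- stratified_folds(labels, config$cv_folds, config$seed)
  clf <- get_classifier(config$classifier)
  accuracies <- numeric(0)
  stopped <- FALSE
  for (t in seq_along(prefixes)) {
    acc_folds <- vapply(seq_len(config$cv_folds), function(f) {
      tr <- folds != f
      Xp <- X[, prefixes[[t]], drop = FALSE]
      set.seed(config$seed + f)
      model <- clf$fit(Xp[tr, , drop = FALSE], labels[tr])
      mean(clf$predict(model, Xp[!tr, , drop = FALSE]) == labels[!tr])
    }, 0)
    accuracies[t] <- mean(acc_folds)
    if (!is.null(config$threshold) && accuracies[t] >= config$threshold) {
      stopped <- TRUE
      break
    }
  }
  evaluated <- seq_along(accuracies)
  best <- .select_best(accuracies)
  name <- if (is.character(config$classifier)) config$classifier else "custom"
  structure(list(
    steps = vapply(prefixes[evaluated], length, 0L),
    accuracies = accuracies,
    best_step = best,
    selected_indices = prefixes[[best]],
    classifier = name,
    stopped_early = stopped
  ), class = "selection_result")
}

#' Summary table of selection results across classifiers
#'
#' @param results list of `selection_result`s.
#' @return data frame with columns `Sr No.`, `Classifier Name`,
#'   `Max Cumulative Feature Step`, `Features Count`.
#' @export
accuracy_curve_report <- function(results) {
  stopifnot(length(results) >= 1)
  df <- data.frame(
    seq_along(results),
    vapply(results, `[[`, "", "classifier"),
    vapply(results, `[[`, 0L, "best_step"),
    vapply(results, function(r) length(r$selected_indices), 0L),
    check.names = FALSE
  )
  names(df) <- c("Sr No.", "Classifier Name", "Max Cumulative Feature Step",
                 "Features Count")
  df
}

#' Features common to several selections
#'
#' Intersection of the selected index sets, used to distil a consensus
#' feature set from the best-performing classifiers.
#'
#' @param ... two or more `selection_result`s (or bare index vectors); a
#'   single list may also be passed.
#' @return sorted integer vector (possibly empty, with a warning).
#' @export
common_features <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.list(args[[1]]) &&
      !inherits(args[[1]], "selection_result")) {
    args <- args[[1]]
  }
  if (length(args) < 2) stop("need at least two selections")
  sets <- lapply(args, function(a) {
    if (inherits(a, "selection_result")) a$selected_indices else as.integer(a)
  })
  common <- sort(Reduce(intersect, sets))
  if (length(common) == 0) warning("selections share no features")
  common
}

#' Export a selection result
#'
#' Writes the accuracy curve as CSV and the selected indices as JSON.
#'
#' @param result a `selection_result`.
#' @param curve_path CSV path for the per-step curve.
#' @param indices_path JSON path for the selected indices.
#' @return `result`, invisibly.
#' @export
write_selection <- function(result, curve_path, indices_path) {
  stopifnot(inherits(result, "selection_result"))
  utils::write.csv(
    data.frame(step = seq_along(result$steps), n_features = result$steps,
               accuracy = result$accuracies),
    curve_path, row.names = FALSE
  )
  jsonlite::write_json(
    list(classifier = result$classifier,
         best_step = result$best_step,
         selected_indices = result$selected_indices),
    indices_path, auto_unbox = TRUE
  )
  invisible(result)
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("forward selection [%s]: best step %d (%d features), accuracy %.3f over %d prefixes\n",
              x$classifier, x$best_step, length(x$selected_indices),
              x$accuracies[x$best_step], length(x$steps)))
  invisible(x)
}
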