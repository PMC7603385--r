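#' Student network specification
#'
#' The student is a one-hidden-layer network (n inputs, `hidden_size`
#' relu units, d linear outputs) distilled to reproduce the standardized
#' teacher codes from the raw connectivity features, with mean squared
#' error loss and Adadelta updates. A sparsity-inducing penalty on the
#' input-to-hidden weight matrix concentrates each feature's influence,
#' which is what makes the squared row norms diag(W W') a meaningful
#' per-feature importance score. The default penalty is a row-wise group
#' lasso (sum over features of the Euclidean norm of the feature's weight
#' row); plain L1 is available as an alternative.
#'
#' @param hidden_size hidden-layer width (default 100).
#' @param regularizer `"group_row_l2"`, `"l1"`, or `"none"`.
#' @param strength non-negative penalty weight (default 1e-4).
#' @param learning_rate Adadelta step multiplier (default 0.01).
#' @param epochs,batch_size training schedule (defaults 500 / 16,
#'   mirroring the teacher).
#' @param seed integer seed.
#' @return object of class `student_spec`.
#' @export
student_spec <- function(hidden_size = 100L,
                         regularizer = c("group_row_l2", "l1", "none"),
                         strength = 1e-4, learning_rate = 0.01,
                         epochs = 500L, batch_size = 16L, seed = 1L) {
  regularizer <- match.arg(regularizer)
  stopifnot(hidden_size >= 1, strength >= 0)
  structure(list(
    hidden_size = as.integer(hidden_size), regularizer = regularizer,
    strength = strength, activation = "relu", optimizer = "adadelta",
    learning_rate = learning_rate, loss = "mse",
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    seed = as.integer(seed)
  ), class = "student_spec")
}

#' Train the student network on teacher codes
#'
#' Fits input -> relu hidden -> linear output to reproduce the codes, and
#' returns the input-to-hidden weight matrix W (n features x h hidden)
#' that drives feature scoring. Codes are expected standardized; raw
#' codes are standardized automatically with a warning.
#'
#' @param X m x n design matrix.
#' @param codes m x d `code_matrix` (standardized).
#' @param spec a [student_spec()].
#' @return object of class `student_model` with elements `W` (n x h),
#'   `net`, `spec`, `loss_history`.
#' @export
train_student <- function(X, codes, spec = student_spec()) {
  stopifnot(inherits(spec, "student_spec"))
  X <- as.matrix(X)
  if (anyNA(X) || !all(is.finite(X))) stop("non-finite values in X")
  if (nrow(X) != nrow(codes)) {
    stop("X and codes must have the same number of rows")
  }
  if (!isTRUE(attr(codes, "standardized"))) {
    warning("codes are not standardized; standardizing before distillation")
    codes <- standardize_codes(codes)
  }
  Y <- unclass(codes)
  sizes <- c(ncol(X), spec$hidden_size, ncol(Y))
  acts <- c(spec$activation, "linear")
  reg <- list(type = spec$regularizer, strength = spec$strength)
  set.seed(spec$seed)
  net <- mlp_init(sizes)
  fit <- mlp_train(net, X, Y, acts, "mse",
                   epochs = spec$epochs, batch_size = spec$batch_size,
                   lr = spec$learning_rate, reg = reg)
  structure(list(W = fit$net$W[[1L]], net = fit$net, spec = spec,
                 loss_history = fit$history),
            class = "student_model")
}

#' Per-feature importance scores diag(W W')
#'
#' Score of feature i is the squared Euclidean norm of row i of the
#' student's input-to-hidden weight matrix — the i-th diagonal entry of
#' W W', computed without forming the n x n product.
#'
#' @param W n x h weight matrix, or a `student_model`.
#' @return non-negative numeric vector of length n.
#' @export
score_features <- function(W) {
  if (inherits(W, "student_model")) W <- W$W
  W <- as.matrix(W)
  if (anyNA(W) || !all(is.finite(W))) stop("non-finite weights")
  rowSums(W^2)
}

#' Rank features by decreasing importance
#'
#' Ties are broken by the lower feature index, so rankings are fully
#' deterministic. Set `decreasing = FALSE` to invert the sort direction.
#'
#' @param scores numeric vector of non-negative importance scores.
#' @param decreasing sort direction (default TRUE: highest score first).
#' @return object of class `importance_ranking`: `scores`, `order`
#'   (permutation of `1..n`, best feature first), `n`.
#' @export
rank_features <- function(scores, decreasing = TRUE) {
  if (anyNA(scores) || !all(is.finite(scores))) stop("non-finite scores")
  key <- if (decreasing) -scores else scores
  ord <- order(key, seq_along(scores)) # secondary key = feature index
  structure(list(scores = as.numeric(scores), order = as.integer(ord),
                 n = length(scores)),
            class = "importance_ranking")
}

#' Full teacher-student feature ranking
#'
#' One seeded call composing the pipeline: train the teacher, extract and
#' standardize its codes, distil the student, score features by
#' diag(W W'), and rank them.
#'
#' @param X m x n design matrix.
#' @param labels 0/1 vector.
#' @param teacher a [teacher_spec()]; default [default_teacher_spec()] for
#'   `ncol(X)`.
#' @param student a [student_spec()].
#' @param keep_models attach the fitted models as attributes.
#' @return an `importance_ranking`.
#' @export
rank_pipeline <- function(X, labels, teacher = NULL, student = student_spec(),
                          keep_models = FALSE) {
  X <- as.matrix(X)
  if (is.null(teacher)) teacher <- default_teacher_spec(ncol(X))
  tm <- train_teacher(X, labels, teacher)
  codes <- standardize_codes(extract_codes(tm, X))
  sm <- train_student(X, codes, student)
  ranking <- rank_features(score_features(sm))
  if (keep_models) {
    attr(ranking, "teacher") <- tm
    attr(ranking, "student") <- sm
  }
  ranking
}

#' Write a feature ranking as CSV
#'
#' Columns `feature_index,region_a,region_b,score,rank`; region names are
#' resolved from an atlas table when one is supplied.
#'
#' @param ranking an `importance_ranking`.
#' @param R region count consistent with `ranking$n = R(R-1)/2`.
#' @param path output CSV path.
#' @param atlas optional atlas data frame (see [read_atlas()]).
#' @return the written data frame, invisibly.
#' @export
write_ranking <- function(ranking, R, path, atlas = NULL) {
  stopifnot(inherits(ranking, "importance_ranking"))
  if (n_features(R) != ranking$n) stop("ranking length does not match R(R-1)/2")
  pairs <- feature_to_pair(ranking$order, R)
  nm <- function(idx) {
    if (is.null(atlas)) as.character(idx) else atlas$name[idx]
  }
  df <- data.frame(
    feature_index = ranking$order,
    region_a = nm(pairs[, "j"]), region_b = nm(pairs[, "k"]),
    score = ranking$scores[ranking$order],
    rank = seq_along(ranking$order)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @export
print.importance_ranking <- function(x, ...) {
  cat(sprintf("importance ranking of %d features; top 5: %s\n", x$n,
              paste(utils::head(x$order, 5), collapse = ", ")))
  invisible(x)
}
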