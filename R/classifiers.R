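# Classifier registry used by the forward-selection scan and the
# evaluation reports. Each entry wraps an established implementation
# behind a fit(X, y) -> model / predict(model, X) -> 0/1 interface.
# Defaults: lr = ridge-penalized logistic regression (lambda = 1/m,
# mirroring C = 1), svm = linear kernel cost 1, ld = linear discriminant,
# rf = 100 trees, dt = default-depth decision tree. All seeded by the
# caller via set.seed before fit.

.fit_lr <- function(X, y) {
  if (ncol(X) >= 2) {
    glmnet::glmnet(X, factor(y, levels = c(0, 1)), family = "binomial",
                   alpha = 0, lambda = 1 / nrow(X))
  } else {
    df <- data.frame(y = y, X1 = X[, 1])
    suppressWarnings(stats::glm(y ~ X1, data = df, family = stats::binomial()))
  }
}

.predict_lr <- function(model, X) {
  if (inherits(model, "glmnet")) {
    as.integer(stats::predict(model, X, type = "response")[, 1] > 0.5)
  } else {
    as.integer(stats::predict(model, data.frame(X1 = X[, 1]), type = "response") > 0.5)
  }
}

.fit_svm <- function(X, y) {
  e1071::svm(X, factor(y, levels = c(0, 1)), type = "C-classification",
             kernel = "linear", cost = 1, scale = FALSE)
}

.fit_ld <- function(X, y) {
  suppressWarnings(MASS::lda(X, grouping = factor(y, levels = c(0, 1))))
}

.fit_rf <- function(X, y) {
  randomForest::randomForest(X, factor(y, levels = c(0, 1)), ntree = 100)
}

.fit_dt <- function(X, y) {
  df <- data.frame(y = factor(y, levels = c(0, 1)), X)
  rpart::rpart(y ~ ., data = df, method = "class")
}

.classifier_registry <- function() {
  list(
    lr = list(fit = .fit_lr, predict = .predict_lr),
    svm = list(fit = .fit_svm,
               predict = function(m, X) as.integer(as.character(stats::predict(m, X)))),
    ld = list(fit = .fit_ld,
              predict = function(m, X) as.integer(as.character(stats::predict(m, X)$class))),
    rf = list(fit = .fit_rf,
              predict = function(m, X) as.integer(as.character(stats::predict(m, X)))),
    dt = list(fit = .fit_dt,
              predict = function(m, X) {
                as.integer(as.character(stats::predict(m, data.frame(X), type = "class")))
              })
  )
}

#' Resolve a classifier by name
#'
#' @param classifier one of `"lr"`, `"svm"`, `"ld"`, `"rf"`, `"dt"`, or a
#'   custom `list(fit = function(X, y), predict = function(model, X))`.
#' @return a `list(fit, predict)` pair.
#' @export
get_classifier <- function(classifier) {
  if (is.list(classifier) && all(c("fit", "predict") %in% names(classifier))) {
    return(classifier)
  }
  reg <- .classifier_registry()
  if (!classifier %in% names(reg)) {
    stop("unknown classifier '", classifier, "'; available: ",
         paste(names(reg), collapse = ", "))
  }
  reg[[classifier]]
}
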