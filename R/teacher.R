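#' Teacher network specification
#'
#' The teacher is a deep funnel classifier: input layer of size n (the
#' connectivity feature count), hidden layers whose widths shrink toward a
#' small code layer, and a 2-unit softmax head (case vs control). Training
#' uses Adadelta and binary cross-entropy; hidden activations are tanh
#' because correlation features are signed. The activations of the code
#' layer are the subject "codes" distilled into the student.
#'
#' @param layer_sizes integer vector including input and output sizes; the
#'   code layer size must appear exactly once and sizes must not increase
#'   from the input to the code layer.
#' @param code_layer_size width of the code layer (default 5).
#' @param activation hidden activation (default `"tanh"`).
#' @param dropout_schedule per-hidden-layer dropout rates in `[0, 1)`.
#' @param learning_rate Adadelta step multiplier (default 0.001).
#' @param epochs training epochs (default 500).
#' @param batch_size mini-batch size (default 16).
#' @param seed integer seed governing initialization, shuffling, dropout.
#' @return object of class `teacher_spec`.
#' @export
teacher_spec <- function(layer_sizes, code_layer_size = 5L,
                         activation = "tanh", dropout_schedule = NULL,
                         learning_rate = 0.001, epochs = 500L,
                         batch_size = 16L, seed = 1L) {
  layer_sizes <- as.integer(layer_sizes)
  L <- length(layer_sizes)
  if (L < 3) stop("need at least input, code and output layers")
  if (layer_sizes[L] != 2L) stop("output layer must have 2 units (binary classes)")
  hidden_idx <- 2:(L - 1L)
  code_idx <- hidden_idx[layer_sizes[hidden_idx] == code_layer_size]
  if (length(code_idx) != 1L) {
    stop("code_layer_size must appear exactly once among the hidden layers")
  }
  if (any(diff(layer_sizes[1:code_idx]) > 0)) {
    stop("layer sizes must be non-increasing from input to code layer")
  }
  n_hidden <- L - 2L
  if (is.null(dropout_schedule)) dropout_schedule <- rep(0, n_hidden)
  if (length(dropout_schedule) != n_hidden ||
      any(dropout_schedule < 0 | dropout_schedule >= 1)) {
    stop("dropout_schedule must give one rate in [0,1) per hidden layer")
  }
  structure(list(
    layer_sizes = layer_sizes, code_layer_size = as.integer(code_layer_size),
    code_index = code_idx, activation = activation,
    dropout_schedule = dropout_schedule,
    optimizer = "adadelta", learning_rate = learning_rate,
    loss = "binary cross-entropy",
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    seed = as.integer(seed)
  ), class = "teacher_spec")
}

#' Default 17-layer teacher for a given feature count
#'
#' Produces the package's standard architecture: 17 layers counting input
#' and output, with 15 hidden widths interpolated geometrically from n
#' down to the code layer (5 units), then the 2-unit head. For n = 4005
#' this gives 4005, 2575, 1656, ..., 8, 6, 5, 2. Dropout decreases
#' linearly from 0.3 after the first hidden layer to 0 at the code layer.
#'
#' @param n input feature count (>= 2).
#' @param epochs,learning_rate,batch_size,seed passed to [teacher_spec()].
#' @return object of class `teacher_spec`.
#' @export
default_teacher_spec <- function(n, epochs = 500L, learning_rate = 0.001,
                                 batch_size = 16L, seed = 1L) {
  stopifnot(n >= 2)
  code <- min(5L, as.integer(n)) # degenerate inputs narrower than the code
  n_hidden <- 15L
  # geometric interpolation input -> code over the hidden stack
  h <- round(exp(seq(log(n), log(code), length.out = n_hidden + 1L)))[-1L]
  h <- as.integer(pmin(h, n))
  h[n_hidden] <- code
  # keep the code width unique: every earlier hidden layer stays above it
  if (n_hidden > 1L) h[1:(n_hidden - 1L)] <- pmax(h[1:(n_hidden - 1L)], code + 1L)
  h <- as.integer(cummin(h)) # enforce the funnel under rounding
  h[n_hidden] <- code
  sizes <- c(as.integer(n), h, 2L)
  drop_sched <- c(seq(0.3, 0, length.out = n_hidden), 0)
  teacher_spec(sizes, code_layer_size = code,
               dropout_schedule = drop_sched[seq_len(length(sizes) - 2L)],
               learning_rate = learning_rate, epochs = epochs,
               batch_size = batch_size, seed = seed)
}

.teacher_activations <- function(spec) {
  L <- length(spec$layer_sizes) - 1L
  c(rep(spec$activation, L - 1L), "softmax")
}

#' Train the teacher classifier
#'
#' Fits the funnel network on the connectivity design matrix with a
#' 2-unit softmax head and binary cross-entropy loss, using Adadelta
#' mini-batch updates. Fully reproducible from `spec$seed`.
#'
#' @param X m x n design matrix (subjects by connectivity features).
#' @param labels integer 0/1 vector; both classes must be present.
#' @param spec a [teacher_spec()]; its first layer size must equal
#'   `ncol(X)`.
#' @return object of class `teacher_model` with elements `net`, `spec`,
#'   `loss_history` (one entry per epoch).
#' @export
train_teacher <- function(X, labels, spec) {
  stopifnot(inherits(spec, "teacher_spec"))
  X <- as.matrix(X)
  if (anyNA(X) || !all(is.finite(X))) stop("non-finite values in X")
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present in labels")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (spec$layer_sizes[1] != ncol(X)) {
    stop("spec input size (", spec$layer_sizes[1], ") != ncol(X) (", ncol(X), ")")
  }
  Y <- cbind(control = 1 - labels, case = labels) # column 2 = class 1
  acts <- .teacher_activations(spec)
  dropout <- c(spec$dropout_schedule, 0)
  set.seed(spec$seed)
  net <- mlp_init(spec$layer_sizes)
  fit <- mlp_train(net, X, Y, acts, "softmax_ce",
                   epochs = spec$epochs, batch_size = spec$batch_size,
                   lr = spec$learning_rate, dropout = dropout)
  structure(list(net = fit$net, spec = spec, loss_history = fit$history),
            class = "teacher_model")
}

#' Class probabilities / labels from a trained teacher
#'
#' @param object a `teacher_model`.
#' @param X design matrix.
#' @param type `"prob"` for the m x 2 softmax matrix, `"label"` for 0/1.
#' @param ... unused.
#' @export
predict.teacher_model <- function(object, X, type = c("label", "prob"), ...) {
  type <- match.arg(type)
  P <- mlp_predict(object$net, as.matrix(X), .teacher_activations(object$spec))
  if (type == "prob") return(P)
  as.integer(P[, 2] > P[, 1])
}

#' Extract subject codes from a trained teacher
#'
#' Runs the forward pass up to the code layer and returns its activations
#' (post-activation by default) for every subject.
#'
#' @param model a `teacher_model`.
#' @param X m x n design matrix.
#' @param pre_activation return the code layer's pre-activation instead of
#'   its activation output.
#' @return m x d matrix of class `code_matrix`, unstandardized.
#' @export
extract_codes <- function(model, X, pre_activation = FALSE) {
  if (!inherits(model, "teacher_model")) stop("model must be a trained teacher_model")
  spec <- model$spec
  acts <- .teacher_activations(spec)
  fwd <- mlp_forward(model$net, as.matrix(X), acts)
  ci <- spec$code_index # index into layer_sizes; layer l output is A[[l+1]]
  codes <- if (pre_activation) fwd$Z[[ci - 1L]] else fwd$A[[ci]]
  structure(codes, class = c("code_matrix", "matrix"),
            standardized = FALSE)
}

#' Standardize code columns to zero mean and unit sd
#'
#' Uses the population standard deviation (divide by m) per column; the
#' fitted centres and scales are retained as attributes so the same
#' transform can be reapplied to new subjects.
#'
#' @param codes m x d `code_matrix` (m >= 2).
#' @param center,scale optionally reuse previously fitted parameters.
#' @return standardized `code_matrix` with attributes `center`, `scale`,
#'   `standardized = TRUE`.
#' @export
standardize_codes <- function(codes, center = NULL, scale = NULL) {
  Z <- unclass(codes)
  if (nrow(Z) < 2) stop("need at least 2 rows to standardize (sd undefined for m = 1)")
  if (is.null(center)) center <- colMeans(Z)
  if (is.null(scale)) {
    scale <- sqrt(colMeans(sweep(Z, 2L, center)^2)) # population sd
  }
  if (any(scale == 0)) stop("zero-sd code column(s): ", paste(which(scale == 0), collapse = ", "))
  Z <- sweep(sweep(Z, 2L, center), 2L, scale, "/")
  structure(Z, class = c("code_matrix", "matrix"),
            standardized = TRUE, center = center, scale = scale)
}

#' @export
print.teacher_model <- function(x, ...) {
  cat(sprintf("teacher network: %d layers (%s), trained %d epochs, final loss %.4f\n",
              length(x$spec$layer_sizes),
              paste(x$spec$layer_sizes, collapse = "-"),
              length(x$loss_history),
              if (length(x$loss_history)) utils::tail(x$loss_history, 1) else NA))
  invisible(x)
}
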