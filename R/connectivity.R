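#' Pearson correlation of two time series
#'
#' Mean-centred cross-product over the product of centred norms. Errors on
#' zero-variance input rather than returning NaN, because a silent NaN in
#' one region poisons every downstream network input.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 time points")
  if (anyNA(x) || anyNA(y) || !all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values in input")
  dx <- x - mean(x)
  dy <- y - mean(y)
  sx <- sqrt(sum(dx^2))
  sy <- sqrt(sum(dy^2))
  if (sx == 0 || sy == 0) stop("zero-variance input: correlation undefined")
  r <- sum(dx * dy) / (sx * sy)
  min(1, max(-1, r))
}

#' Connectivity matrix of one subject
#'
#' R x R matrix of pairwise Pearson correlations between region time
#' series; symmetric with unit diagonal.
#'
#' @param record a `subject_record` (or bare T x R matrix).
#' @return numeric R x R matrix.
#' @export
connectivity_matrix <- function(record) {
  ts <- if (inherits(record, "subject_record")) record$timeseries else record
  if (!is.matrix(ts)) stop("timeseries must be a matrix")
  if (nrow(ts) < 3) stop("need at least 3 time points")
  if (anyNA(ts) || !all(is.finite(ts))) stop("non-finite values in time series")
  v <- apply(ts, 2L, stats::var)
  if (any(v == 0)) {
    stop("zero-variance region(s): ", paste(which(v == 0), collapse = ", "))
  }
  C <- stats::cor(ts)
  C[C > 1] <- 1
  C[C < -1] <- -1
  diag(C) <- 1
  C <- (C + t(C)) / 2
  dimnames(C) <- NULL
  C
}

#' Number of unique region-pair features
#'
#' @param R number of regions.
#' @return `R * (R - 1) / 2`; 4005 for the 90-region AAL parcellation.
#' @export
n_features <- function(R) {
  stopifnot(R >= 2)
  as.integer(R * (R - 1) / 2)
}

#' Map a feature index to its region pair, and back
#'
#' The upper triangle is vectorized row by row over 1-based indices:
#' (1,2), (1,3), ..., (1,R), (2,3), ..., (R-1,R). All downstream feature
#' indices (rankings, selections, reports) follow this fixed order.
#'
#' @param p feature index in `1..R(R-1)/2` (vectorized).
#' @param j,k region indices with `j < k` after reordering.
#' @param R number of regions.
#' @return `feature_to_pair`: integer matrix with columns `j`, `k`;
#'   `pair_to_feature`: integer vector of feature indices.
#' @export
feature_to_pair <- function(p, R) {
  n <- n_features(R)
  p <- as.integer(p)
  if (length(p) == 0) return(cbind(j = integer(0), k = integer(0)))
  if (any(p < 1 | p > n)) stop("feature index out of range 1..", n)
  # features completed after finishing row j: cum[j] = sum_{i<=j} (R - i)
  cum <- cumsum((R - 1):1)
  j <- findInterval(p - 1L, c(0L, cum)) # row whose block contains p
  before <- c(0L, cum)[j]
  k <- j + (p - before)
  cbind(j = as.integer(j), k = as.integer(k))
}

#' @rdname feature_to_pair
#' @export
pair_to_feature <- function(j, k, R) {
  if (any(j < 1 | j > R | k < 1 | k > R)) stop("region index out of range 1..", R)
  if (any(j == k)) stop("j and k must differ")
  lo <- pmin(j, k)
  hi <- pmax(j, k)
  as.integer((lo - 1) * R - lo * (lo - 1) / 2 + (hi - lo))
}

#' Vectorize the upper triangle of a connectivity matrix
#'
#' @param C symmetric R x R matrix.
#' @return numeric vector of length `R(R-1)/2` in the row-major order
#'   declared by [feature_to_pair()].
#' @export
vectorize_upper <- function(C) {
  if (!is.matrix(C) || nrow(C) != ncol(C)) stop("C must be a square matrix")
  if (max(abs(C - t(C))) > 1e-8) stop("C must be symmetric")
  # column-major lower triangle of a symmetric matrix == row-major upper triangle
  C[lower.tri(C)]
}

#' Rebuild a symmetric matrix from its upper-triangle vector
#'
#' @param F_vec vector of length `R(R-1)/2`.
#' @param R number of regions.
#' @param diag_value value placed on the diagonal (1 for correlations).
#' @return symmetric R x R matrix.
#' @export
devectorize_upper <- function(F_vec, R, diag_value = 1) {
  if (length(F_vec) != n_features(R)) {
    stop("length(F_vec) must be R(R-1)/2 = ", n_features(R))
  }
  C <- matrix(0, R, R)
  C[lower.tri(C)] <- F_vec
  C <- C + t(C)
  diag(C) <- diag_value
  C
}

#' Build the subjects-by-features design matrix
#'
#' Row i is the upper-triangle connectivity vector of subject i; the
#' columns follow the fixed feature order of [feature_to_pair()].
#'
#' @param cohort a `cohort` or list of `subject_record`s.
#' @return A list of class `conn_design`: `X` (m x R(R-1)/2), `labels`,
#'   `sites`, `subject_ids`, `R`.
#' @export
build_design_matrix <- function(cohort) {
  subjects <- if (inherits(cohort, "cohort")) cohort$subjects else cohort
  if (length(subjects) == 0) stop("no subjects")
  Rs <- vapply(subjects, function(s) ncol(s$timeseries), 0L)
  if (length(unique(Rs)) != 1) stop("inconsistent region count across subjects")
  R <- Rs[1]
  X <- t(vapply(subjects, function(s) vectorize_upper(connectivity_matrix(s)),
                numeric(n_features(R))))
  structure(list(
    X = X,
    labels = vapply(subjects, `[[`, 0L, "label"),
    sites = vapply(subjects, `[[`, "", "site"),
    subject_ids = vapply(subjects, `[[`, "", "subject_id"),
    R = R
  ), class = "conn_design")
}

#' Write / read a design matrix as CSV plus a sidecar JSON
#'
#' The sidecar records `R` and the index-map convention so a reader can
#' reconstruct region pairs from column positions.
#'
#' @param design a `conn_design`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path` (write) or a `conn_design` (read), invisibly/visibly.
#' @export
write_design_matrix <- function(design, path) {
  stopifnot(inherits(design, "conn_design"))
  df <- data.frame(subject_id = design$subject_ids, site = design$sites,
                   label = design$labels, design$X, check.names = FALSE)
  names(df)[-(1:3)] <- paste0("f", seq_len(ncol(design$X)))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(R = design$R, n_features = ncol(design$X),
         index_order = "row-major upper triangle, 1-based: (1,2),(1,3),...,(R-1,R)"),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_design_matrix
#' @export
read_design_matrix <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  df <- utils::read.csv(path, check.names = FALSE)
  X <- as.matrix(df[, -(1:3), drop = FALSE])
  dimnames(X) <- NULL
  structure(list(
    X = X, labels = as.integer(df$label), sites = as.character(df$site),
    subject_ids = as.character(df$subject_id), R = as.integer(meta$R)
  ), class = "conn_design")
}
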