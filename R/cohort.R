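#' Specify a synthetic two-class connectivity cohort
#'
#' Defines a cohort of ROI time series in which a chosen set of region
#' pairs carries a class-discriminative correlation. Class 1 ("case")
#' subjects mix a shared latent signal into both regions of every planted
#' pair so that the population correlation of the pair is approximately
#' `effect`; class 0 ("control") subjects, and all non-planted pairs in
#' both classes, have population correlation 0. The generator is a
#' latent-factor model: region j of a class-1 subject with planted pair
#' (j,k) is `a*z_t + e_jt` with `z` a standard normal latent series shared
#' by j and k, `e` independent Gaussian noise with sd `noise_sd`, and
#' `a = noise_sd * sqrt(effect / (1 - effect))`, which gives
#' corr = a^2 / (a^2 + noise_sd^2) = effect.
#'
#' @param n_per_class subjects per class (positive integer).
#' @param R number of regions (>= 2).
#' @param T_len time points per subject (>= 3).
#' @param planted_pairs 2-column matrix (or list of length-2 vectors) of
#'   unordered region pairs, 1-based, j != k. May be empty.
#' @param effect target population correlation of planted pairs in class 1,
#'   in `[0, 1)`. 0 means no class difference.
#' @param noise_sd sd of the per-region Gaussian noise (> 0).
#' @param sites character vector of site labels, assigned round-robin
#'   within each class.
#' @param seed integer seed; the cohort is fully reproducible from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class, R, T_len, planted_pairs = NULL,
                        effect = 0.6, noise_sd = 1,
                        sites = c("siteA", "siteB"), seed = 1L) {
  stopifnot(n_per_class >= 1, length(n_per_class) == 1)
  if (R < 2) stop("R must be >= 2")
  if (T_len < 3) stop("T_len must be >= 3 (correlation needs at least 3 time points)")
  if (effect < 0 || effect >= 1) stop("effect must lie in [0, 1)")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  pp <- .as_pair_matrix(planted_pairs)
  if (nrow(pp) > 0) {
    if (any(pp < 1) || any(pp > R)) stop("planted pair region index out of range 1..R")
    if (any(pp[, 1] == pp[, 2])) stop("planted pairs must join two distinct regions")
  }
  structure(list(
    n_per_class = as.integer(n_per_class), R = as.integer(R),
    T_len = as.integer(T_len), planted_pairs = pp,
    effect = effect, noise_sd = noise_sd,
    sites = as.character(sites), seed = as.integer(seed)
  ), class = "cohort_spec")
}

.as_pair_matrix <- function(pairs) {
  if (is.null(pairs)) return(matrix(integer(0), 0, 2))
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  # canonical orientation j < k, dropping duplicates
  sw <- pairs[, 1] > pairs[, 2]
  pairs[sw, ] <- pairs[sw, c(2, 1)]
  unique(pairs)
}

#' Sample a set of disjoint region pairs
#'
#' Convenience helper for planting: draws `n_pairs` pairs that share no
#' region, so each planted correlation is undiluted by overlap.
#'
#' @param n_pairs number of pairs; requires `2 * n_pairs <= R`.
#' @param R number of regions.
#' @param seed integer seed.
#' @return integer matrix with `n_pairs` rows and columns `j < k`.
#' @export
sample_planted_pairs <- function(n_pairs, R, seed = 1L) {
  if (2 * n_pairs > R) stop("need 2 * n_pairs <= R for disjoint pairs")
  set.seed(seed)
  regions <- sample.int(R, 2 * n_pairs)
  pp <- matrix(regions, ncol = 2)
  .as_pair_matrix(pp)
}

#' Generate a synthetic cohort of ROI time series
#'
#' Draws `2 * n_per_class` subjects under the latent-factor model described
#' in [cohort_spec()]. Class labels are 1 (case) and 0 (control); sites are
#' assigned round-robin within class so both classes appear at every site.
#'
#' @param spec a [cohort_spec()].
#' @return A list of class `cohort` with elements `subjects` (a list of
#'   `subject_record`s, each with `subject_id`, `site`, `label`,
#'   `timeseries` T x R) and `planted_pairs` (the ground-truth pair matrix).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_per_class
  labels <- rep(c(1L, 0L), each = n)
  mix <- spec$noise_sd * sqrt(spec$effect / (1 - spec$effect))
  subjects <- vector("list", 2L * n)
  for (i in seq_along(labels)) {
    ts <- matrix(stats::rnorm(spec$T_len * spec$R, sd = spec$noise_sd),
                 spec$T_len, spec$R)
    if (labels[i] == 1L && nrow(spec$planted_pairs) > 0 && mix > 0) {
      for (p in seq_len(nrow(spec$planted_pairs))) {
        z <- stats::rnorm(spec$T_len)
        jk <- spec$planted_pairs[p, ]
        ts[, jk[1]] <- ts[, jk[1]] + mix * z
        ts[, jk[2]] <- ts[, jk[2]] + mix * z
      }
    }
    within_class <- ((i - 1L) %% n)
    subjects[[i]] <- structure(list(
      subject_id = sprintf("sub-%03d", i),
      site = spec$sites[(within_class %% length(spec$sites)) + 1L],
      label = labels[i],
      timeseries = ts
    ), class = "subject_record")
  }
  structure(list(subjects = subjects, planted_pairs = spec$planted_pairs,
                 spec = spec), class = "cohort")
}

#' Write a cohort to delimited text files
#'
#' Writes `phenotype.csv` (columns `subject_id,site,label`) plus one
#' headerless CSV of T rows x R columns per subject, named
#' `<subject_id>_timeseries.csv`.
#'
#' @param cohort a `cohort` or plain list of `subject_record`s.
#' @param dir output directory (created if absent).
#' @param header write a region header row in the time-series files.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, header = FALSE) {
  subjects <- if (inherits(cohort, "cohort")) cohort$subjects else cohort
  if (length(subjects) == 0) stop("empty subject list")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pheno <- data.frame(
    subject_id = vapply(subjects, `[[`, "", "subject_id"),
    site = vapply(subjects, `[[`, "", "site"),
    label = vapply(subjects, `[[`, 0L, "label")
  )
  utils::write.csv(pheno, file.path(dir, "phenotype.csv"), row.names = FALSE)
  for (s in subjects) {
    utils::write.table(s$timeseries,
      file.path(dir, paste0(s$subject_id, "_timeseries.csv")),
      sep = ",", row.names = FALSE,
      col.names = if (header) paste0("region_", seq_len(ncol(s$timeseries))) else FALSE
    )
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory holding `phenotype.csv` and the per-subject
#'   time-series files.
#' @param header whether the time-series files carry a header row.
#' @return A list of class `cohort` (with `planted_pairs = NULL`).
#' @export
read_cohort <- function(dir, header = FALSE) {
  pheno_path <- file.path(dir, "phenotype.csv")
  if (!file.exists(pheno_path)) stop("no phenotype.csv in ", dir)
  pheno <- utils::read.csv(pheno_path, colClasses = c("character", "character", "integer"))
  subjects <- lapply(seq_len(nrow(pheno)), function(i) {
    ts <- as.matrix(utils::read.csv(
      file.path(dir, paste0(pheno$subject_id[i], "_timeseries.csv")),
      header = header
    ))
    dimnames(ts) <- NULL
    structure(list(
      subject_id = pheno$subject_id[i], site = pheno$site[i],
      label = pheno$label[i], timeseries = ts
    ), class = "subject_record")
  })
  structure(list(subjects = subjects, planted_pairs = NULL), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  n <- length(x$subjects)
  labs <- vapply(x$subjects, `[[`, 0L, "label")
  dims <- dim(x$subjects[[1]]$timeseries)
  cat(sprintf("synthetic cohort: %d subjects (%d case / %d control), T=%d, R=%d, %d planted pair(s)\n",
              n, sum(labs == 1L), sum(labs == 0L), dims[1], dims[2],
              if (is.null(x$planted_pairs)) 0L else nrow(x$planted_pairs)))
  invisible(x)
}
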