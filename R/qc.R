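#' Quality-control filters for expression-difference matrices
#'
#' Three filters mirror the corpus curation used throughout the package:
#' genes observed in too few experiments are dropped, experiments with
#' too little gene coverage are dropped, and experiments whose mean
#' absolute log difference is large (a symptom of normalisation
#' problems) are dropped. All three thresholds are strict inequalities.
#'
#' @param x a [delta_matrix()].
#' @param max_missing a gene is removed when its number of unobserved
#'   entries is strictly greater than this (default 250).
#' @return A filtered `delta_matrix`; the number of removals is attached
#'   as attribute `"removed"`.
#' @name expression_qc
NULL

empty_result_error <- function(msg) {
  stop(errorCondition(msg, class = c("exprdof_empty_result", "error")))
}

#' @rdname expression_qc
#' @export
filter_genes_by_missingness <- function(x, max_missing = 250) {
  stopifnot(inherits(x, "delta_matrix"), max_missing >= 0)
  n_missing <- rowSums(!x$observed)
  keep <- n_missing <= max_missing
  if (!any(keep)) empty_result_error("no genes pass the missingness filter")
  out <- subset_delta(x, genes = keep)
  attr(out, "removed") <- sum(!keep)
  out
}

#' @param min_genes an experiment is removed when it observes strictly
#'   fewer than this many genes (default 4000).
#' @rdname expression_qc
#' @export
filter_experiments_by_coverage <- function(x, min_genes = 4000) {
  stopifnot(inherits(x, "delta_matrix"), min_genes >= 1)
  n_obs <- colSums(x$observed)
  keep <- n_obs >= min_genes
  if (!any(keep)) empty_result_error("no experiments pass the coverage filter")
  out <- subset_delta(x, experiments = keep)
  attr(out, "removed") <- sum(!keep)
  out
}

#' @param threshold an experiment is removed when its mean absolute
#'   observed log difference is strictly greater than this (default 0.5).
#' @rdname expression_qc
#' @export
filter_experiments_by_mean_abs <- function(x, threshold = 0.5) {
  stopifnot(inherits(x, "delta_matrix"), threshold > 0)
  n_obs <- colSums(x$observed)
  v <- x$values
  v[!x$observed] <- NA_real_
  mean_abs <- colMeans(abs(v), na.rm = TRUE)
  # an experiment with nothing observed cannot be assessed: remove it
  if (any(n_obs == 0))
    warning(sprintf("%d experiment(s) with no observed entries removed",
                    sum(n_obs == 0)))
  keep <- n_obs > 0 & mean_abs <= threshold
  if (!any(keep)) empty_result_error("no experiments pass the mean-|delta| filter")
  out <- subset_delta(x, experiments = keep)
  attr(out, "removed") <- sum(!keep)
  out
}

#' Column-centre an expression matrix and impute missing entries
#'
#' Subtracts each experiment's mean over its observed entries, making
#' every experiment a contrast among genes, then sets unobserved entries
#' to 0 -- the post-centering column mean -- so that downstream dense
#' linear algebra (SVD) can run. Shape and identifiers are preserved.
#'
#' @param x a [delta_matrix()] with at least one observed entry per
#'   experiment.
#' @param means optional numeric vector of column means to use instead of
#'   the matrix's own (used to centre held-out blocks with training
#'   statistics).
#' @return A centred `delta_matrix` (`centered = TRUE`); the column means
#'   that were subtracted are attached as attribute `"column_means"`.
#' @export
center_and_impute <- function(x, means = NULL) {
  stopifnot(inherits(x, "delta_matrix"))
  n_obs <- colSums(x$observed)
  if (is.null(means)) {
    if (any(n_obs == 0))
      stop("every experiment needs at least one observed entry to be centred")
    v <- x$values
    v[!x$observed] <- NA_real_
    means <- colMeans(v, na.rm = TRUE)
  } else {
    stopifnot(length(means) == ncol(x$values))
  }
  v <- sweep(x$values, 2, means, "-")
  v[!x$observed] <- 0
  out <- delta_matrix(v, observed = x$observed, gene_ids = x$gene_ids,
                      experiment_ids = x$experiment_ids, centered = TRUE)
  attr(out, "column_means") <- means
  out
}

#' Run the canonical QC pipeline
#'
#' Applies the three filters in canonical order (gene missingness, then
#' experiment coverage, then experiment mean-|delta|) followed by
#' centring and imputation, and records the count removed at each stage.
#'
#' @inheritParams expression_qc
#' @inheritParams filter_experiments_by_coverage
#' @inheritParams filter_experiments_by_mean_abs
#' @param center apply [center_and_impute()] at the end (default TRUE).
#' @return A list with elements `data` (the filtered, optionally centred
#'   `delta_matrix`) and `report` (named removal counts plus final
#'   dimensions).
#' @export
qc_pipeline <- function(x, max_missing = 250, min_genes = 4000,
                        threshold = 0.5, center = TRUE) {
  x1 <- filter_genes_by_missingness(x, max_missing)
  x2 <- filter_experiments_by_coverage(x1, min_genes)
  x3 <- filter_experiments_by_mean_abs(x2, threshold)
  report <- list(
    genes_removed_missingness = attr(x1, "removed"),
    experiments_removed_coverage = attr(x2, "removed"),
    experiments_removed_mean_abs = attr(x3, "removed"),
    n_genes = nrow(x3$values),
    n_experiments = ncol(x3$values))
  data <- if (center) center_and_impute(x3) else x3
  list(data = data, report = report)
}

subset_delta <- function(x, genes = TRUE, experiments = TRUE) {
  out <- delta_matrix(x$values[genes, experiments, drop = FALSE],
                      observed = x$observed[genes, experiments, drop = FALSE],
                      gene_ids = x$gene_ids[genes],
                      experiment_ids = x$experiment_ids[experiments],
                      centered = x$centered)
  out
}
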