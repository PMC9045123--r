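#' Gene-by-experiment matrix of log expression differences
#'
#' The central data container of the package: a numeric matrix of
#' log-scale expression differences (one row per gene, one column per
#' experiment/contrast) together with an observation mask. Missing
#' entries are stored as `NA` in `values` and `FALSE` in `observed`;
#' after [center_and_impute()] they hold 0 (the post-centering column
#' mean) while the mask still records that they were unobserved.
#'
#' @param values numeric matrix, genes x experiments; `NA` marks missing.
#' @param observed logical matrix of the same shape; defaults to
#'   `!is.na(values)`.
#' @param gene_ids,experiment_ids unique row/column identifiers; default
#'   to the dimnames of `values` (generated if absent).
#' @param centered logical flag: have columns been mean-centered?
#' @return An object of class `delta_matrix`: a list with elements
#'   `values`, `observed`, `gene_ids`, `experiment_ids`, `centered`.
#' @export
delta_matrix <- function(values, observed = !is.na(values),
                         gene_ids = rownames(values),
                         experiment_ids = colnames(values),
                         centered = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- sprintf("g%04d", seq_len(nrow(values)))
  if (is.null(experiment_ids)) experiment_ids <- sprintf("e%04d", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  experiment_ids <- as.character(experiment_ids)
  if (!is.matrix(observed) || !identical(dim(observed), dim(values)))
    stop("'observed' must be a logical matrix with the same shape as 'values'")
  storage.mode(observed) <- "logical"
  if (anyDuplicated(gene_ids)) stop("duplicated gene_ids")
  if (anyDuplicated(experiment_ids)) stop("duplicated experiment_ids")
  if (length(gene_ids) != nrow(values) || length(experiment_ids) != ncol(values))
    stop("identifier lengths do not match matrix shape")
  if (any(!is.finite(values[observed])))
    stop("non-finite values at observed entries")
  dimnames(values) <- list(gene_ids, experiment_ids)
  dimnames(observed) <- dimnames(values)
  structure(list(values = values, observed = observed,
                 gene_ids = gene_ids, experiment_ids = experiment_ids,
                 centered = isTRUE(centered)),
            class = "delta_matrix")
}

#' @export
dim.delta_matrix <- function(x) dim(x$values)

#' @export
print.delta_matrix <- function(x, ...) {
  cat(sprintf("delta_matrix: %d genes x %d experiments (%.1f%% observed%s)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(x$observed),
              if (x$centered) ", centered" else ""))
  invisible(x)
}

#' Read / write an expression-difference matrix as TSV
#'
#' Plain tab-separated text: first column gene id, remaining columns one
#' per experiment, `NA` for missing entries. This is the interchange
#' format for the whole pipeline.
#'
#' @param path file path.
#' @return `read_delta_tsv` returns a [delta_matrix()].
#' @export
read_delta_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, row.names = 1,
                           comment.char = "", quote = "")
  delta_matrix(as.matrix(tab))
}

#' @param x a `delta_matrix`.
#' @rdname read_delta_tsv
#' @export
write_delta_tsv <- function(x, path) {
  stopifnot(inherits(x, "delta_matrix"))
  v <- x$values
  v[!x$observed] <- NA_real_
  tab <- data.frame(gene_id = x$gene_ids, v, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
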