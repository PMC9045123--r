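#' Build a transcriptional coordinate system
#'
#' Truncates a state basis to its top `m` dimensions and packages the
#' coordinate basis `X = U_m S_m` as a universal coordinate system: any
#' expression-change vector over (a subset of) the same genes can be
#' projected onto it with [project()]. The default dimension is 450,
#' the ceiling put on the degree of freedom of yeast gene expression.
#' Provenance (a fingerprint of the gene universe and build parameters)
#' travels with the basis so projections against a mismatched basis
#' fail loudly.
#'
#' @param basis a `state_basis` from [svd_decompose()].
#' @param m number of dimensions to retain (default 450, capped by the
#'   available rank -- exceeding it is an error).
#' @param params optional list of build parameters recorded in the
#'   provenance block (seed, QC thresholds, ...).
#' @return An object of class `tcsy`: list with `X`, `gene_ids`, `m`,
#'   `sigma` (retained singular values) and `provenance`.
#' @export
build_tcsy <- function(basis, m = 450, params = list()) {
  stopifnot(inherits(basis, "state_basis"))
  r <- length(basis$sigma)
  if (m > r) stop(sprintf("m = %d exceeds the available rank %d", m, r))
  X <- basis$U[, seq_len(m), drop = FALSE] %*% diag(basis$sigma[seq_len(m)], m)
  gene_ids <- basis$gene_ids
  if (is.null(gene_ids)) gene_ids <- sprintf("g%05d", seq_len(nrow(X)))
  rownames(X) <- gene_ids
  colnames(X) <- sprintf("sv%03d", seq_len(m))
  prov <- list(fingerprint = tcsy_fingerprint(gene_ids, m, basis$sigma[seq_len(m)], params),
               m = m, params = params)
  structure(list(X = X, gene_ids = gene_ids, m = as.integer(m),
                 sigma = basis$sigma[seq_len(m)], provenance = prov),
            class = "tcsy")
}

tcsy_fingerprint <- function(gene_ids, m, sigma, params) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(c(gene_ids, as.character(m), sprintf("%.17g", sigma),
               vapply(params, function(p) paste(format(p), collapse = ","),
                      character(1))), tf)
  unname(tools::md5sum(tf))
}

#' @export
print.tcsy <- function(x, ...) {
  cat(sprintf("tcsy basis: %d genes x %d dimensions\n", nrow(x$X), x$m))
  cat(sprintf("  fingerprint %s\n", x$provenance$fingerprint))
  invisible(x)
}

#' Serialize / load a TCSY basis as text
#'
#' The basis matrix is written as a TSV with full (`%.17g`) double
#' precision and the metadata (gene ids, dimension, singular values,
#' provenance) as JSON, so a save -> load cycle reproduces the basis
#' bit-exactly from plain-text artifacts.
#'
#' @param tcsy a `tcsy` basis.
#' @param prefix path prefix; writes `<prefix>.tsv` and `<prefix>.json`.
#' @return `write_tcsy` returns the two paths invisibly; `read_tcsy`
#'   returns the `tcsy` object.
#' @export
write_tcsy <- function(tcsy, prefix) {
  stopifnot(inherits(tcsy, "tcsy"))
  tsv <- paste0(prefix, ".tsv")
  json <- paste0(prefix, ".json")
  header <- paste(c("gene_id", colnames(tcsy$X)), collapse = "\t")
  rows <- vapply(seq_len(nrow(tcsy$X)), function(i) {
    paste(c(tcsy$gene_ids[i], sprintf("%.17g", tcsy$X[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), tsv)
  meta <- list(m = tcsy$m, sigma = sprintf("%.17g", tcsy$sigma),
               provenance = tcsy$provenance)
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv = tsv, json = json))
}

#' @rdname write_tcsy
#' @export
read_tcsy <- function(prefix) {
  tab <- utils::read.table(paste0(prefix, ".tsv"), header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  gene_ids <- tab[[1]]
  X <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- gene_ids
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  structure(list(X = X, gene_ids = gene_ids, m = as.integer(meta$m),
                 sigma = as.numeric(meta$sigma),
                 provenance = as.list(meta$provenance)),
            class = "tcsy")
}

#' Project an expression-change vector into TCSY coordinates
#'
#' Least-squares projection `V_hat = (X'X)^-1 X' delta`, restricted to
#' the genes that are both observed in `delta` and present in the
#' basis; this masking is what makes the projection robust to missing
#' values. Genes in the query but absent from the basis are dropped
#' with a warning. Refuses to project when fewer observed genes than
#' dimensions remain.
#'
#' @param tcsy a `tcsy` basis.
#' @param delta named numeric vector of per-gene expression changes
#'   (`NA` allowed), or an unnamed vector in basis gene order.
#' @return An object of class `tcsy_coords`: `v_hat` (length m),
#'   `n_genes_used`, `residual_fraction`.
#' @export
project <- function(tcsy, delta) {
  stopifnot(inherits(tcsy, "tcsy"))
  if (!is.null(names(delta))) {
    extra <- setdiff(names(delta), tcsy$gene_ids)
    if (length(extra) > 0)
      warning(sprintf("%d gene(s) absent from the basis dropped", length(extra)))
    f <- delta[match(tcsy$gene_ids, names(delta))]
  } else {
    if (length(delta) != nrow(tcsy$X))
      stop("unnamed delta must match the basis gene count")
    f <- delta
  }
  obs <- !is.na(f)
  if (sum(obs) < tcsy$m) {
    miss <- tcsy$gene_ids[!obs]
    stop(sprintf(paste0("only %d observed genes for %d dimensions; ",
                        "first missing genes: %s"),
                 sum(obs), tcsy$m,
                 paste(utils::head(miss, 5), collapse = ", ")))
  }
  Xo <- tcsy$X[obs, , drop = FALSE]
  fo <- as.numeric(f[obs])
  v_hat <- solve_normal(Xo, fo)
  fitted <- drop(Xo %*% v_hat)
  tss <- sum(fo^2)
  rf <- if (tss > 0) sum((fo - fitted)^2) / tss else 0
  structure(list(v_hat = stats::setNames(v_hat, colnames(tcsy$X)),
                 n_genes_used = sum(obs),
                 residual_fraction = min(max(rf, 0), 1)),
            class = "tcsy_coords")
}

#' @export
print.tcsy_coords <- function(x, ...) {
  cat(sprintf("tcsy_coords: %d dimensions from %d genes (residual fraction %.3f)\n",
              length(x$v_hat), x$n_genes_used, x$residual_fraction))
  cat("  leading coordinates:",
      paste(signif(utils::head(x$v_hat, 5), 4), collapse = ", "), "...\n")
  invisible(x)
}

#' Project new expression data with a TCSY basis
#'
#' @param object a `tcsy` basis.
#' @param newdata a named numeric vector, a matrix with genes in rows
#'   and conditions in columns, or a [delta_matrix()].
#' @param ... unused.
#' @return For a vector, a `tcsy_coords`; otherwise a list of
#'   `tcsy_coords`, one per column.
#' @export
predict.tcsy <- function(object, newdata, ...) {
  if (inherits(newdata, "delta_matrix")) {
    v <- newdata$values
    v[!newdata$observed] <- NA_real_
    newdata <- v
  }
  if (is.matrix(newdata)) {
    out <- lapply(seq_len(ncol(newdata)), function(j)
      project(object, stats::setNames(newdata[, j], rownames(newdata))))
    names(out) <- colnames(newdata)
    return(out)
  }
  project(object, newdata)
}

#' Variance explained by each TCSY dimension
#'
#' Fraction of the total sum of squares of a centred data matrix that
#' falls along each basis direction (squared projection onto the unit
#' left singular vectors), with cumulative totals. On the training
#' corpus itself the fractions are the squared singular values over the
#' total and are non-increasing.
#'
#' @param tcsy a `tcsy` basis.
#' @param data a centred [delta_matrix()] on the basis gene set.
#' @return data.frame with `dimension`, `fraction`, `cumulative`.
#' @export
variance_explained <- function(tcsy, data) {
  stopifnot(inherits(data, "delta_matrix"))
  if (!data$centered) stop("data must be centred")
  v <- data$values
  v[!data$observed] <- 0
  idx <- match(tcsy$gene_ids, data$gene_ids)
  if (anyNA(idx)) stop("data is missing basis genes")
  v <- v[idx, , drop = FALSE]
  tot <- sum(v^2)
  if (tot == 0) stop("zero total variance")
  Un <- sweep(tcsy$X, 2, sqrt(colSums(tcsy$X^2)), "/")  # unit directions
  proj <- crossprod(Un, v)                              # m x experiments
  frac <- rowSums(proj^2) / tot
  data.frame(dimension = seq_along(frac), fraction = frac,
             cumulative = cumsum(frac))
}

#' Correlate transcriptional states
#'
#' Pearson (or Spearman) correlation matrix across conditions, either
#' on raw expression-change vectors (rows = genes) or on TCSY
#' coordinate vectors (rows = dimensions). Pairs involving a
#' zero-variance vector are undefined and reported as `NA` with a
#' warning.
#'
#' @param x numeric matrix with conditions in columns, or a list of
#'   `tcsy_coords`.
#' @param method correlation method (default "pearson").
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
compare_states <- function(x, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.list(x) && all(vapply(x, inherits, logical(1), "tcsy_coords")))
    x <- vapply(x, function(ci) ci$v_hat, numeric(length(x[[1]]$v_hat)))
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 conditions")
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs",
                                   method = method))
  if (any(sds == 0, na.rm = TRUE)) {
    warning("zero-variance condition(s): correlations reported as NA")
    bad <- which(sds == 0)
    r[bad, ] <- NA_real_; r[, bad] <- NA_real_
  }
  diag(r) <- 1
  r
}

#' Export coordinates for a parallel-coordinate plot
#'
#' Long-format TSV -- one row per (condition, dimension) -- with the
#' coordinate value, the condition's group label, and the per-dimension
#' standard deviation across the conditions of the same group, ready
#' for any plotting layer.
#'
#' @param coords list of `tcsy_coords` (or a matrix, dimensions x
#'   conditions).
#' @param path output TSV path, or `NULL` to skip writing.
#' @param groups optional character vector of group labels per
#'   condition (defaults to one group).
#' @return The long-format data.frame, invisibly when written.
#' @export
export_parallel_coordinates <- function(coords, path = NULL, groups = NULL) {
  if (is.list(coords))
    coords <- vapply(coords, function(ci) ci$v_hat,
                     numeric(length(coords[[1]]$v_hat)))
  coords <- as.matrix(coords)
  n_cond <- ncol(coords)
  m <- nrow(coords)
  cond <- colnames(coords)
  if (is.null(cond)) cond <- sprintf("cond%02d", seq_len(n_cond))
  if (is.null(groups)) groups <- rep("all", n_cond)
  stopifnot(length(groups) == n_cond)
  sd_by_group <- matrix(NA_real_, m, n_cond)
  for (g in unique(groups)) {
    cols <- which(groups == g)
    s <- if (length(cols) > 1) apply(coords[, cols, drop = FALSE], 1, stats::sd)
         else rep(NA_real_, m)
    sd_by_group[, cols] <- s
  }
  out <- data.frame(condition = rep(cond, each = m),
                    dimension = rep(seq_len(m), n_cond),
                    value = as.numeric(coords),
                    group = rep(groups, each = m),
                    group_sd = as.numeric(sd_by_group),
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
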