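#' Select extreme-weight motifs per state variable
#'
#' For each state variable, ranks all motifs by weight and marks the top
#' `ceiling(fraction * N)` positive-weight motifs with +1 and the bottom
#' `floor(fraction * N)` negative-weight motifs with -1, all others 0.
#' With the full 65,536-motif universe and the default 1\% fraction this
#' selects 656 + 655 = 1,311 motifs per variable. Ties are broken by
#' lexicographic motif string so the selection is deterministic.
#'
#' @param weights a `motif_weights` matrix (motifs x variables) from
#'   [map_all_motifs()].
#' @param fraction tail fraction per sign, in (0, 0.5) (default 0.01).
#' @return An integer matrix (motifs x variables) of class
#'   `selection_matrix` with entries in \{-1, 0, +1\} and the same
#'   dimnames as `weights`.
#' @export
select_extreme_motifs <- function(weights, fraction = 0.01) {
  if (fraction <= 0 || fraction >= 0.5)
    stop("fraction must be in (0, 0.5)")
  N <- nrow(weights)
  m <- ncol(weights)
  keys <- rownames(weights)
  if (is.null(keys)) keys <- sprintf("m%06d", seq_len(N))
  n_pos <- ceiling(fraction * N)
  n_neg <- floor(fraction * N)
  config <- matrix(0L, N, m, dimnames = dimnames(weights))
  for (j in seq_len(m)) {
    w <- weights[, j]
    ord_desc <- order(-w, keys)   # ties -> lexicographically smaller first
    ord_asc <- order(w, keys)
    pos <- ord_desc[seq_len(n_pos)]
    # tails stay disjoint even under heavy ties across the median
    neg <- setdiff(ord_asc, pos)[seq_len(n_neg)]
    config[pos, j] <- 1L
    config[neg, j] <- -1L
  }
  structure(config, class = c("selection_matrix", class(config)))
}

#' Shannon information capacity of a motif-selection configuration
#'
#' Partitions the motif rows into groups with identical selection
#' configurations across the state variables and returns the Shannon
#' entropy of the group-size distribution,
#' `H = -sum_i p_i log2(p_i)` with `p_i` the fraction of motifs in
#' group i. The theoretical maximum for 8-mer motifs is
#' `log2(65536) = 16` bits (every motif its own group); identical rows
#' give 0 bits.
#'
#' @param config a `selection_matrix` (or any matrix whose rows are the
#'   per-motif configurations).
#' @return Entropy in bits.
#' @export
group_entropy <- function(config) {
  key <- do.call(paste, c(as.data.frame(unclass(config)), sep = ","))
  p <- table(key) / nrow(config)
  -sum(p * log2(p))
}

#' Overlap of selected-motif sets across state variables
#'
#' A motif belongs to a variable's set when its selection entry is
#' nonzero. Returns the histogram of motifs selected in exactly
#' 1, 2, ..., `length(variables)` of the chosen sets, together with the
#' union size (the histogram sums to the union).
#'
#' @param config a `selection_matrix`.
#' @param variables column indices of the variables to compare.
#' @return List with `counts` (named integer vector, `exactly_1` ...)
#'   and `union_size`.
#' @export
overlap_counts <- function(config, variables) {
  stopifnot(length(variables) >= 1)
  nz <- unclass(config)[, variables, drop = FALSE] != 0
  k <- rowSums(nz)
  counts <- tabulate(k[k > 0], nbins = length(variables))
  names(counts) <- paste0("exactly_", seq_along(variables))
  list(counts = counts, union_size = sum(k > 0))
}

#' Information capacity of a single promoter
#'
#' For gene j whose promoter contains k motifs from the union of
#' selected sets, each present selected motif i has
#' `q_i = (# variables selecting i) / m`, and the promoter capacity is
#' `H(j) = -(1/k) * sum_i q_i log2(q_i)` bits. A motif selected by every
#' variable (`q = 1`) contributes nothing; genes with k = 0 have no
#' defined capacity and are excluded from rankings.
#'
#' @param config a `selection_matrix` (motifs x m).
#' @param presence sparse presence matrix from [motif_presence()] on the
#'   same motif universe.
#' @param gene gene identifier (row name of `presence`) or row index.
#' @return List of class `promoter_capacity`: `gene_id`, `k`,
#'   `q_values`, `h` (bits); `NULL` when k = 0.
#' @export
promoter_capacity <- function(config, presence, gene) {
  if (ncol(presence) != nrow(config))
    stop("presence and selection matrix use different motif universes")
  sel <- which(rowSums(unclass(config) != 0) > 0)
  q_all <- rowSums(unclass(config)[sel, , drop = FALSE] != 0) / ncol(config)
  g <- if (is.character(gene)) match(gene, rownames(presence)) else gene
  if (is.na(g)) stop("gene not found in presence matrix: ", gene)
  present <- which(as.logical(presence[g, sel]))
  k <- length(present)
  if (k == 0L) return(NULL)
  q <- q_all[present]
  h <- -sum(q * log2(q)) / k
  structure(list(gene_id = if (is.character(gene)) gene else rownames(presence)[g],
                 k = k, q_values = q, h = h),
            class = "promoter_capacity")
}

#' Rank genes by promoter information capacity
#'
#' Computes `H(j)` for every gene (vectorised over the presence matrix)
#' and sorts eligible genes by capacity, ascending (low-capacity
#' promoters first). Genes whose promoters contain no selected motif
#' are excluded and reported via a message.
#'
#' @inheritParams promoter_capacity
#' @return data.frame with columns `gene_id`, `k`, `h`, sorted by `h`
#'   ascending; excluded gene ids attached as attribute `"excluded"`.
#' @export
rank_genes_by_capacity <- function(config, presence) {
  if (ncol(presence) != nrow(config))
    stop("presence and selection matrix use different motif universes")
  sel <- which(rowSums(unclass(config) != 0) > 0)
  q <- rowSums(unclass(config)[sel, , drop = FALSE] != 0) / ncol(config)
  sub <- presence[, sel, drop = FALSE]
  k <- Matrix::rowSums(sub)
  contrib <- as.numeric(sub %*% (-q * log2(q)))
  eligible <- k > 0
  if (any(!eligible))
    message(sum(!eligible), " gene(s) with no selected motif excluded from ranking")
  out <- data.frame(gene_id = rownames(presence)[eligible],
                    k = as.integer(k[eligible]),
                    h = contrib[eligible] / k[eligible],
                    stringsAsFactors = FALSE)
  out <- out[order(out$h, out$gene_id), ]
  rownames(out) <- NULL
  attr(out, "excluded") <- rownames(presence)[!eligible]
  out
}

#' Write / read a preranked gene list (.rnk)
#'
#' Two tab-separated columns -- gene id and score -- with no header, the
#' format consumed by preranked enrichment tools. Row order is the
#' ranking order and scores are written in full double precision so the
#' file round-trips exactly.
#'
#' @param ranking data.frame with `gene_id` and a score column (`h` by
#'   default), e.g. from [rank_genes_by_capacity()].
#' @param path output path.
#' @param score name of the score column (default "h").
#' @return `write_rnk` returns `path` invisibly; `read_rnk` returns a
#'   data.frame with `gene_id` and `score`.
#' @export
write_rnk <- function(ranking, path, score = "h") {
  if (nrow(ranking) == 0) stop("refusing to write an empty ranking")
  lines <- sprintf("%s\t%.17g", ranking$gene_id, ranking[[score]])
  tryCatch(writeLines(lines, path),
           error = function(e) stop("failed to write ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}

#' @rdname write_rnk
#' @export
read_rnk <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("gene_id", "score"),
                           colClasses = c("character", "numeric"))
  tab
}
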