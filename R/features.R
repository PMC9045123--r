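#' Encode / decode 8-mer motifs
#'
#' Bijection between motif strings and 1-based row indices of the
#' 65,536-row motif universe: base-4 big-endian with A=0, C=1, G=2, T=3
#' (first base most significant). This matches the alphabetical k-mer
#' column order used by `Biostrings::oligonucleotideFrequency`.
#'
#' @param motifs character vector of k-mers over ACGT.
#' @param width motif width (default 8).
#' @return `encode_motif`: integer indices in `1:4^width`;
#'   `decode_motif`: motif strings.
#' @export
encode_motif <- function(motifs, width = 8L) {
  if (any(nchar(motifs) != width)) stop("all motifs must have width ", width)
  lut <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  vapply(motifs, function(s) {
    digits <- lut[strsplit(s, "")[[1]]]
    if (anyNA(digits)) stop("non-ACGT character in motif: ", s)
    sum(digits * 4^((width - 1):0)) + 1L
  }, numeric(1), USE.NAMES = FALSE)
}

#' @param idx integer indices in `1:4^width`.
#' @rdname encode_motif
#' @export
decode_motif <- function(idx, width = 8L) {
  stopifnot(all(idx >= 1), all(idx <= 4^width))
  alphabet <- c("A", "C", "G", "T")
  vapply(idx - 1, function(i) {
    digits <- integer(width)
    for (j in width:1) { digits[j] <- i %% 4; i <- i %/% 4 }
    paste(alphabet[digits + 1L], collapse = "")
  }, character(1))
}

#' Extract upstream promoter regions from a genome
#'
#' For each annotated gene, returns the `upstream` bases immediately 5'
#' of the transcription start: for plus-strand genes the bases before
#' the annotated start, for minus-strand genes the bases after the
#' annotated end, reverse-complemented so every promoter reads 5'->3'
#' toward its gene. Regions are truncated (never padded) at contig
#' boundaries; genes whose promoter is fully truncated away are kept
#' with an empty sequence and a warning.
#'
#' @param genome path to a FASTA file, or a `Biostrings::DNAStringSet`.
#' @param annotation path to a GFF3 or BED file (dialect inferred from
#'   the extension and converted internally to 1-based inclusive), or a
#'   `GenomicRanges::GRanges`.
#' @param upstream promoter length (default 500).
#' @return A `promoter_set` (see [simulate_promoters()]).
#' @export
extract_promoters <- function(genome, annotation, upstream = 500) {
  if (is.character(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (is.character(annotation)) {
    fmt <- if (grepl("\\.bed$", annotation, ignore.case = TRUE)) "BED" else "GFF3"
    gr <- rtracklayer::import(annotation, format = fmt)
  } else gr <- annotation
  md <- S4Vectors::mcols(gr)
  if (!is.null(md$type) && any(md$type == "gene"))
    gr <- gr[md$type == "gene"]
  md <- S4Vectors::mcols(gr)
  ids <- NULL
  for (f in c("Name", "name", "ID", "gene_id")) {
    if (!is.null(md[[f]])) { ids <- as.character(md[[f]]); break }
  }
  if (is.null(ids)) ids <- sprintf("gene_%05d", seq_along(gr))
  chroms <- as.character(GenomeInfoDb::seqnames(gr))
  missing_ctg <- !(chroms %in% names(genome))
  if (any(missing_ctg))
    stop("gene(s) on contig absent from the genome: ",
         paste(unique(chroms[missing_ctg]), collapse = ", "))
  GenomeInfoDb::seqlevels(gr) <- names(genome)
  GenomeInfoDb::seqlengths(gr) <- Biostrings::width(genome)
  # promoters() warns about ranges running off the contig; trim() resolves them
  prom <- suppressWarnings(GenomicRanges::promoters(gr, upstream = upstream,
                                                    downstream = 0))
  prom <- GenomicRanges::trim(prom)
  st <- as.character(BiocGenerics::strand(prom))
  st[st == "*"] <- "+"
  starts <- GenomicRanges::start(prom)
  ends <- GenomicRanges::end(prom)
  seqs <- character(length(prom))
  for (i in seq_along(prom)) {
    if (ends[i] < starts[i]) { seqs[i] <- ""; next }
    s <- Biostrings::subseq(genome[[chroms[i]]], starts[i], ends[i])
    if (st[i] == "-") s <- Biostrings::reverseComplement(s)
    seqs[i] <- as.character(s)
  }
  if (any(seqs == ""))
    warning(sprintf("%d gene(s) with zero-length promoter at a contig edge",
                    sum(seqs == "")))
  names(seqs) <- ids
  structure(list(seq = seqs,
                 info = data.frame(gene_id = ids, contig = chroms,
                                   start = starts, end = ends, strand = st,
                                   stringsAsFactors = FALSE)),
            class = "promoter_set")
}

#' Binary motif-presence matrix over the 8-mer universe
#'
#' Entry (g, w) is 1 when 8-mer w occurs at least once as a
#' forward-orientation substring of gene g's promoter (multiplicity is
#' ignored; windows containing non-ACGT characters contribute nothing).
#' Counting is done by `Biostrings::oligonucleotideFrequency` in blocks
#' of genes and stored sparsely: a promoter of length L can contain at
#' most L-7 distinct 8-mers of the 65,536 possible.
#'
#' @param promoters a `promoter_set`, or a named character vector of
#'   sequences.
#' @param width motif width (default 8).
#' @return A sparse logical `Matrix` (genes x `4^width`) with motif
#'   strings as column names.
#' @export
motif_presence <- function(promoters, width = 8L) {
  seqs <- if (inherits(promoters, "promoter_set")) promoters$seq else promoters
  n <- length(seqs)
  block <- 500L
  parts <- vector("list", ceiling(n / block))
  for (b in seq_along(parts)) {
    idx <- ((b - 1L) * block + 1L):min(b * block, n)
    dss <- Biostrings::DNAStringSet(seqs[idx])
    counts <- Biostrings::oligonucleotideFrequency(dss, width = width)
    parts[[b]] <- methods::as(counts > 0, "CsparseMatrix")
  }
  out <- do.call(rbind, parts)
  rownames(out) <- names(seqs)
  out
}

#' Map a per-gene feature vector onto the state variables
#'
#' Least-squares projection of a gene-indexed feature (a motif-presence
#' indicator, a GO-membership indicator, or an expression-change vector)
#' onto the coordinate basis `X = U_m S_m`:
#' `V_hat = (X'X)^-1 X' f`. The feature is centred over the genes with
#' observed values (configurable), and the normal equations are solved
#' on the observed rows only, which is what makes the projection robust
#' to missing entries. A tiny ridge (`1e-10 * trace(X'X)/m`) guards
#' degenerate observation masks; `X`'s columns are orthogonal by
#' construction so conditioning is otherwise benign.
#'
#' @param basis a `state_basis` (from [svd_decompose()]) or an object
#'   with an `X` matrix (e.g. a `tcsy` basis).
#' @param feature numeric vector indexed by the basis's genes (names are
#'   matched when present); `NA` marks genes without a value.
#' @param center subtract the observed-gene mean first (default TRUE).
#' @return Numeric weight vector of length `m`.
#' @export
map_feature <- function(basis, feature, center = TRUE) {
  X <- basis$X
  m <- ncol(X)
  f <- align_feature(feature, basis)
  obs <- !is.na(f)
  if (sum(obs) < m)
    stop(sprintf("underdetermined: %d observed genes for %d dimensions",
                 sum(obs), m))
  Xo <- X[obs, , drop = FALSE]
  fo <- f[obs]
  if (center) fo <- fo - mean(fo)
  solve_normal(Xo, fo)
}

align_feature <- function(feature, basis) {
  gids <- basis$gene_ids
  if (is.null(gids)) gids <- rownames(basis$X)
  if (!is.null(names(feature)) && !is.null(gids)) {
    f <- feature[match(gids, names(feature))]
  } else {
    if (length(feature) != nrow(basis$X))
      stop("feature length does not match the basis gene set")
    f <- feature
  }
  as.numeric(f)
}

solve_normal <- function(X, y_or_Y) {
  XtX <- crossprod(X)
  m <- ncol(X)
  ridge <- 1e-10 * sum(diag(XtX)) / m
  drop(solve(XtX + diag(ridge, m), crossprod(X, y_or_Y)))
}

#' Map every 8-mer motif onto the state variables
#'
#' Applies the least-squares map of [map_feature()] to each motif's
#' centred presence column in one batched solve. The result is the
#' motif weight table: one row per motif in the universe, one column
#' per state variable.
#'
#' @param basis a `state_basis` or `tcsy` basis.
#' @param presence sparse presence matrix from [motif_presence()],
#'   rows matching the basis gene set.
#' @param center centre each presence column over genes (default TRUE).
#' @return A numeric matrix (motifs x m) of class `motif_weights`, with
#'   motif strings as row names.
#' @export
map_all_motifs <- function(basis, presence, center = TRUE) {
  X <- basis$X
  if (nrow(presence) != nrow(X))
    stop("presence must be computed on the basis's gene set")
  m <- ncol(X)
  XtF <- as.matrix(Matrix::crossprod(X, presence))       # m x N
  if (center) {
    cm <- Matrix::colMeans(presence)
    XtF <- XtF - outer(colSums(X), as.numeric(cm))
  }
  XtX <- crossprod(X)
  ridge <- 1e-10 * sum(diag(XtX)) / m
  W <- solve(XtX + diag(ridge, m), XtF)                  # m x N
  out <- t(W)
  rownames(out) <- colnames(presence)
  colnames(out) <- sprintf("sv%03d", seq_len(m))
  class(out) <- c("motif_weights", class(out))
  out
}

#' Summarise motif weights on one state variable
#'
#' Reports the tail counts beyond `+/- threshold`, the mean and SD of
#' the weight distribution, and the motifs with the most extreme
#' weights on the chosen variable.
#'
#' @param weights a `motif_weights` matrix from [map_all_motifs()].
#' @param variable state-variable column (default 1, the primary one).
#' @param threshold tail cut-off on the weight scale (default 0.5).
#' @param top_n how many extreme motifs per tail to list (default 10).
#' @return A list with `n_below`, `n_above`, `mean`, `sd`,
#'   `top_negative`, `top_positive` (named weight vectors).
#' @export
summarize_weights <- function(weights, variable = 1, threshold = 0.5, top_n = 10) {
  w <- weights[, variable]
  ord <- order(w)
  list(n_below = sum(w < -threshold),
       n_above = sum(w > threshold),
       mean = mean(w), sd = stats::sd(w),
       top_negative = w[utils::head(ord, top_n)],
       top_positive = w[rev(utils::tail(ord, top_n))])
}

#' Map GO terms onto the state variables
#'
#' Each term's binary gene-membership indicator is centred and mapped by
#' the same least-squares formula as the motifs. Terms with no member
#' gene in the basis are skipped with a warning.
#'
#' @param basis a `state_basis` or `tcsy` basis.
#' @param go_table data.frame with columns `gene_id` and `term_id`
#'   (optional `term_name`).
#' @param center centre indicators (default TRUE).
#' @return Numeric matrix (terms x m) with term ids as row names and a
#'   `"term_name"` attribute when names are available.
#' @export
map_go_terms <- function(basis, go_table, center = TRUE) {
  stopifnot(all(c("gene_id", "term_id") %in% names(go_table)))
  gids <- basis$gene_ids
  if (is.null(gids)) gids <- rownames(basis$X)
  terms <- unique(go_table$term_id)
  keep <- logical(length(terms))
  G <- nrow(basis$X)
  ind <- matrix(0, G, length(terms))
  for (t in seq_along(terms)) {
    members <- go_table$gene_id[go_table$term_id == terms[t]]
    hit <- gids %in% members
    keep[t] <- any(hit)
    ind[, t] <- as.numeric(hit)
  }
  if (!all(keep)) {
    warning(sprintf("%d term(s) with no member gene in the basis skipped",
                    sum(!keep)))
    terms <- terms[keep]
    ind <- ind[, keep, drop = FALSE]
  }
  if (center) ind <- sweep(ind, 2, colMeans(ind), "-")
  W <- t(solve_normal(basis$X, ind))
  if (length(terms) == 1L) W <- matrix(W, nrow = 1)
  rownames(W) <- terms
  colnames(W) <- sprintf("sv%03d", seq_len(ncol(basis$X)))
  if ("term_name" %in% names(go_table)) {
    nm <- go_table$term_name[match(terms, go_table$term_id)]
    attr(W, "term_name") <- stats::setNames(nm, terms)
  }
  W
}
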