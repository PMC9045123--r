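#' Ground truth for synthetic expression worlds
#'
#' Bundles the parameters of the synthetic generator: the true rank of
#' the low-rank signal, its singular-value profile, the observation
#' noise, the missing-at-random rate, the seed, and any motifs to plant
#' in promoters in correlation with state-variable loadings.
#'
#' @param rank true dimension of the planted signal (>= 1).
#' @param singular_values strictly positive, non-increasing profile of
#'   length `rank`.
#' @param noise_sd standard deviation of i.i.d. Gaussian observation
#'   noise (>= 0).
#' @param missing_rate fraction of entries masked at random, in `[0, 1)`.
#' @param seed integer seed driving every random draw of the generator.
#' @param planted_motifs optional data.frame with columns `motif`
#'   (8-mer over ACGT), `variable` (target state-variable index) and
#'   `enrichment` (insertion probability for the top-loading genes).
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(rank, singular_values = seq(10 * rank, 10, length.out = rank),
                            noise_sd = 0.1, missing_rate = 0, seed = 1,
                            planted_motifs = NULL) {
  stopifnot(rank >= 1, length(singular_values) == rank,
            all(singular_values > 0),
            all(diff(singular_values) <= 0),
            noise_sd >= 0)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (!is.null(planted_motifs)) {
    stopifnot(is.data.frame(planted_motifs),
              all(c("motif", "variable", "enrichment") %in% names(planted_motifs)))
    if (any(nchar(planted_motifs$motif) != 8) ||
        any(grepl("[^ACGT]", planted_motifs$motif)))
      stop("planted motifs must be 8-mers over {A,C,G,T}")
  }
  structure(list(rank = as.integer(rank),
                 singular_values = as.numeric(singular_values),
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 seed = as.integer(seed), planted_motifs = planted_motifs),
            class = "synthetic_truth")
}

random_orthonormal <- function(n, k) {
  q <- qr.Q(qr(matrix(stats::rnorm(n * k), n, k)))
  q[, seq_len(k), drop = FALSE]
}

#' Simulate a low-rank-plus-noise expression-difference matrix
#'
#' Draws random orthonormal gene-side and experiment-side frames (QR of
#' seeded Gaussian matrices, giving Haar-uniform directions), scales by
#' the truth's singular-value profile, adds i.i.d. Gaussian noise and
#' applies a missing-at-random mask -- the generative model that the
#' cross-validated SVD rank estimator assumes.
#'
#' @param n_genes,n_experiments dimensions, both > `truth$rank`.
#' @param truth a [synthetic_truth()].
#' @return A list with `delta` (a [delta_matrix()]), and the ground-truth
#'   factors `U` (genes x rank), `sigma`, `V` (experiments x rank), and
#'   `truth` itself.
#' @export
simulate_low_rank_delta <- function(n_genes, n_experiments, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_genes <= truth$rank || n_experiments <= truth$rank)
    stop("both dimensions must exceed the true rank")
  if (n_genes < 1 || n_experiments < 1) stop("non-positive dimensions")
  set.seed(truth$seed)
  r <- truth$rank
  U <- random_orthonormal(n_genes, r)
  V <- random_orthonormal(n_experiments, r)
  signal <- U %*% (truth$singular_values * t(V))
  noise <- if (truth$noise_sd > 0)
    matrix(stats::rnorm(n_genes * n_experiments, sd = truth$noise_sd),
           n_genes, n_experiments)
  else 0
  values <- signal + noise
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  experiment_ids <- sprintf("e%05d", seq_len(n_experiments))
  observed <- matrix(TRUE, n_genes, n_experiments)
  if (truth$missing_rate > 0) {
    observed[] <- stats::runif(n_genes * n_experiments) >= truth$missing_rate
    values[!observed] <- NA_real_
  }
  dimnames(values) <- list(gene_ids, experiment_ids)
  list(delta = delta_matrix(values, observed = observed,
                            gene_ids = gene_ids, experiment_ids = experiment_ids),
       U = U, sigma = truth$singular_values, V = V, truth = truth)
}

#' A linear state-space system for gene regulation
#'
#' The discrete-time model `x(t+1) = A x(t) + B u(t)`,
#' `y(t) = C x(t) + D u(t)`: `x` holds the hidden state variables, `u`
#' the experimental control inputs, and `y` the observed log expression
#' of the genes. `A` encodes interactions between state variables, `B`
#' how inputs drive the state, `C` how the state determines expression,
#' and `D` a direct feedforward (often absent, i.e. zero).
#'
#' @param A state matrix (r x r).
#' @param B input matrix (r x p).
#' @param C output matrix (genes x r).
#' @param D feedforward matrix (genes x p); defaults to all zeros.
#' @param x0 initial state (length r, default zeros).
#' @param treatment_time integer time step at which the treated
#'   trajectory switches to its own input.
#' @return An object of class `state_space_system`.
#' @export
state_space_system <- function(A, B, C, D = NULL, x0 = NULL, treatment_time = 0L) {
  A <- as.matrix(A); B <- as.matrix(B); C <- as.matrix(C)
  r <- nrow(A)
  if (ncol(A) != r) stop("A must be square")
  if (nrow(B) != r) stop("B must have as many rows as A")
  if (ncol(C) != r) stop("C must have as many columns as A")
  p <- ncol(B)
  if (is.null(D)) D <- matrix(0, nrow(C), p)
  D <- as.matrix(D)
  if (!identical(dim(D), c(nrow(C), p))) stop("D dimensions inconsistent with C and B")
  if (is.null(x0)) x0 <- numeric(r)
  stopifnot(length(x0) == r)
  structure(list(A = A, B = B, C = C, D = D, x0 = x0,
                 treatment_time = as.integer(treatment_time),
                 r = r, p = p, n_genes = nrow(C)),
            class = "state_space_system")
}

#' Simulate expression differences from a state-space system
#'
#' For each contrast (a treated input `u_star` against a control input
#' `u`), propagates both trajectories through the system -- the treated
#' one switching from `u` to `u_star` at the system's `treatment_time`
#' -- and returns the per-gene expression difference
#' `delta_y = y_star(t) - y(t)` at the requested horizon, plus optional
#' Gaussian observation noise. With zero feedforward and no noise the
#' resulting matrix has rank at most `r`, the number of state
#' variables, and is linear in `u_star - u`.
#'
#' @param system a [state_space_system()].
#' @param contrasts list of contrasts, each a list with elements
#'   `u_star` and `u` (length-p input vectors).
#' @param horizon_t time step at which the difference is read out; must
#'   exceed the treatment time.
#' @param noise_sd observation noise standard deviation.
#' @param seed integer seed for the noise.
#' @return A [delta_matrix()] with one column per contrast.
#' @export
simulate_state_space <- function(system, contrasts, horizon_t,
                                 noise_sd = 0, seed = 1) {
  stopifnot(inherits(system, "state_space_system"))
  if (horizon_t <= system$treatment_time)
    stop("horizon_t must exceed the treatment time")
  propagate <- function(u_fun) {
    x <- system$x0
    for (t in seq_len(horizon_t) - 1L) {     # t = 0 .. horizon-1
      x <- system$A %*% x + system$B %*% u_fun(t)
    }
    drop(system$C %*% x + system$D %*% u_fun(horizon_t))
  }
  cols <- vapply(contrasts, function(ct) {
    u <- as.numeric(ct$u); us <- as.numeric(ct$u_star)
    if (length(u) != system$p || length(us) != system$p)
      stop("input vector length does not match the system's input dimension")
    y_ctrl <- propagate(function(t) u)
    y_trt <- propagate(function(t) if (t >= system$treatment_time) us else u)
    y_trt - y_ctrl
  }, numeric(system$n_genes))
  cols <- matrix(cols, nrow = system$n_genes)
  if (noise_sd > 0) {
    set.seed(seed)
    cols <- cols + matrix(stats::rnorm(length(cols), sd = noise_sd),
                          nrow = nrow(cols))
  }
  delta_matrix(cols,
               gene_ids = sprintf("g%05d", seq_len(nrow(cols))),
               experiment_ids = sprintf("c%04d", seq_len(ncol(cols))))
}

#' Simulate promoter sequences with planted motifs, plus a toy genome
#'
#' Generates a uniform-random 500-nt (by default) promoter for every
#' gene and inserts each planted motif with a probability that grows
#' with the gene's loading rank on the motif's target state variable:
#' insertion probability = `enrichment * min(1, r/0.9)` where `r` is the
#' gene's loading percentile, so genes in the top decile receive the
#' motif with the full enrichment probability. When `dir` is given, also
#' writes a toy genome FASTA and BED6/GFF3 annotations laid out so that
#' [extract_promoters()] recovers exactly the simulated sequences: one
#' contig per 1000 genes, genes on alternating strands, and the first
#' gene of each contig with its promoter truncated at the contig edge.
#'
#' @param gene_ids character vector of gene identifiers.
#' @param length promoter length in nucleotides (>= 8; default 500).
#' @param truth a [synthetic_truth()] (supplies seed and planted motifs).
#' @param loadings numeric matrix (genes x variables) of state-variable
#'   loadings used to rank genes for motif planting; may be `NULL` when
#'   no motifs are planted.
#' @param dir optional output directory for `genome.fa`, `genes.bed`,
#'   `genes.gff3`.
#' @param truncate_first length of the truncated first-gene promoter per
#'   contig (default 300; set to `length` to disable truncation).
#' @return A `promoter_set`: list with `seq` (named character vector,
#'   5'->3' toward the gene), and `info` (data.frame of gene, contig,
#'   1-based inclusive promoter coordinates, strand).
#' @export
simulate_promoters <- function(gene_ids, length = 500, truth, loadings = NULL,
                               dir = NULL, truncate_first = 300) {
  stopifnot(inherits(truth, "synthetic_truth"), length >= 8)
  pm <- truth$planted_motifs
  if (!is.null(pm) && any(nchar(pm$motif) > length))
    stop("planted motif longer than the promoter")
  n <- base::length(gene_ids)
  set.seed(truth$seed + 7L)
  alphabet <- c("A", "C", "G", "T")
  prom_len <- rep(length, n)
  genes_per_contig <- 1000L
  first_of_contig <- (seq_len(n) - 1L) %% genes_per_contig == 0L
  prom_len[first_of_contig] <- min(truncate_first, length)
  seqs <- vapply(prom_len, function(L)
    paste(sample(alphabet, L, replace = TRUE), collapse = ""), character(1))
  # plant motifs in correlation with loadings on the target variable
  if (!is.null(pm) && nrow(pm) > 0) {
    if (is.null(loadings)) stop("loadings required to plant motifs")
    loadings <- as.matrix(loadings)
    if (nrow(loadings) != n) stop("loadings must be indexed by gene")
    for (i in seq_len(nrow(pm))) {
      v <- pm$variable[i]
      rk <- rank(loadings[, v], ties.method = "first") / n
      p_ins <- pm$enrichment[i] * pmin(1, rk / 0.9)
      do_ins <- stats::runif(n) < p_ins
      for (g in which(do_ins)) {
        L <- prom_len[g]
        if (L < 8) next
        pos <- sample.int(L - 7L, 1)
        substr(seqs[g], pos, pos + 7L) <- pm$motif[i]
      }
    }
  }
  names(seqs) <- gene_ids
  # lay out a toy genome: [promoter][body] for +, [body][revcomp(promoter)] for -
  body_len <- 60L
  spacer <- 20L
  contig_of <- (seq_len(n) - 1L) %/% genes_per_contig + 1L
  strand <- ifelse(seq_len(n) %% 2L == 1L, "+", "-")
  info <- data.frame(gene_id = gene_ids, contig = sprintf("ctg%02d", contig_of),
                     start = NA_integer_, end = NA_integer_, strand = strand,
                     gene_start = NA_integer_, gene_end = NA_integer_,
                     stringsAsFactors = FALSE)
  contig_seqs <- character(0)
  for (ctg in unique(info$contig)) {
    idx <- which(info$contig == ctg)
    parts <- character(0)
    pos <- 0L
    for (g in idx) {
      L <- prom_len[g]
      body <- paste(sample(alphabet, body_len, replace = TRUE), collapse = "")
      if (strand[g] == "+") {
        info$start[g] <- pos + 1L
        info$end[g] <- pos + L
        info$gene_start[g] <- pos + L + 1L
        info$gene_end[g] <- pos + L + body_len
        parts <- c(parts, seqs[g], body)
      } else {
        info$gene_start[g] <- pos + 1L
        info$gene_end[g] <- pos + body_len
        info$start[g] <- pos + body_len + 1L
        info$end[g] <- pos + body_len + L
        parts <- c(parts, body, revcomp(seqs[g]))
      }
      pos <- pos + L + body_len
      sp <- paste(sample(alphabet, spacer, replace = TRUE), collapse = "")
      parts <- c(parts, sp)
      pos <- pos + spacer
    }
    contig_seqs[ctg] <- paste(parts, collapse = "")
  }
  out <- structure(list(seq = seqs,
                        info = info[, c("gene_id", "contig", "start", "end", "strand")],
                        gene_info = info),
                   class = "promoter_set")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    genome <- Biostrings::DNAStringSet(contig_seqs)
    Biostrings::writeXStringSet(genome, file.path(dir, "genome.fa"), width = 60L)
    bed <- data.frame(chrom = info$contig, start = info$gene_start - 1L,
                      end = info$gene_end, name = info$gene_id, score = 0L,
                      strand = info$strand)
    utils::write.table(bed, file.path(dir, "genes.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    gff <- data.frame(seqid = info$contig, source = "exprdof", type = "gene",
                      start = info$gene_start, end = info$gene_end,
                      score = ".", strand = info$strand, phase = ".",
                      attributes = sprintf("ID=%s;Name=%s", info$gene_id, info$gene_id))
    writeLines(c("##gff-version 3",
                 apply(gff, 1, paste, collapse = "\t")),
               file.path(dir, "genes.gff3"))
    attr(out, "files") <- list(genome = file.path(dir, "genome.fa"),
                               bed = file.path(dir, "genes.bed"),
                               gff3 = file.path(dir, "genes.gff3"))
  }
  out
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("promoter_set: %d promoters, lengths %d-%d nt\n",
              length(x$seq), min(nchar(x$seq)), max(nchar(x$seq))))
  invisible(x)
}

#' Simulate GO annotations coupled to state-variable loadings
#'
#' Each synthetic term is a gene set whose membership probability
#' increases with the gene's loading rank on a designated state variable
#' (terms cycle through the variables). With `coupling = 0` membership
#' is independent of the loadings at the base rate; as `coupling` grows
#' the top-loading genes' membership probability approaches 1. The
#' membership model is logistic:
#' `P(member) = plogis(qlogis(base_rate) + coupling * (rank_pct - 0.5))`.
#'
#' @param gene_ids character vector of genes.
#' @param n_terms number of synthetic terms (>= 1).
#' @param coupling coupling strength (>= 0).
#' @param loadings genes x variables loading matrix (required when
#'   `coupling > 0`).
#' @param base_rate baseline membership probability (default 0.1).
#' @param seed integer seed.
#' @return data.frame with columns `gene_id`, `term_id`, `term_name`,
#'   `aspect`; attribute `"target_variable"` maps each term to the state
#'   variable it is coupled to.
#' @export
simulate_go_annotations <- function(gene_ids, n_terms, coupling = 0,
                                    loadings = NULL, base_rate = 0.1, seed = 1) {
  stopifnot(n_terms >= 1, coupling >= 0, base_rate > 0, base_rate < 1)
  n <- length(gene_ids)
  if (coupling > 0) {
    if (is.null(loadings)) stop("loadings required when coupling > 0")
    loadings <- as.matrix(loadings)
    stopifnot(nrow(loadings) == n)
  }
  set.seed(seed)
  aspects <- c("BP", "MF", "CC")
  rows <- vector("list", n_terms)
  target <- integer(n_terms)
  for (t in seq_len(n_terms)) {
    v <- if (coupling > 0) ((t - 1L) %% ncol(loadings)) + 1L else 1L
    target[t] <- v
    eta <- stats::qlogis(base_rate)
    if (coupling > 0) {
      rk <- rank(loadings[, v], ties.method = "first") / n
      eta <- eta + coupling * (rk - 0.5)
    }
    member <- stats::runif(n) < stats::plogis(eta)
    if (any(member))
      rows[[t]] <- data.frame(gene_id = gene_ids[member],
                              term_id = sprintf("SYN:%07d", t),
                              term_name = sprintf("synthetic term %d (var %d)", t, v),
                              aspect = aspects[(t - 1L) %% 3L + 1L],
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "target_variable") <- stats::setNames(target, sprintf("SYN:%07d", seq_len(n_terms)))
  out
}
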