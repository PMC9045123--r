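test_that("motif index encoding round-trips over the full universe", {
  idx <- c(1L, 2L, 4L, 5L, 256L, 65536L, sample.int(65536, 200))
  expect_identical(encode_motif(decode_motif(idx)), as.numeric(idx))
  expect_identical(decode_motif(1), "AAAAAAAA")
  expect_identical(decode_motif(65536), "TTTTTTTT")
  expect_identical(encode_motif("AAAAAAAC"), 2)   # big-endian, last base fastest
  expect_error(encode_motif("ACGTACGN"), "non-ACGT")
  expect_error(encode_motif("ACGT"), "width")
})

test_that("motif universe enumeration has exactly 4^8 distinct members", {
  all_motifs <- decode_motif(seq_len(4^8))
  expect_equal(length(all_motifs), 65536)
  expect_false(anyDuplicated(all_motifs) > 0)
})

with_toy_genome <- function(code) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  # contig of 1200 nt; gene A on + strand starting at 501; gene B on -
  # strand ending at 700 (promoter = revcomp of 701..1200)
  set.seed(101)
  contig <- paste(sample(c("A", "C", "G", "T"), 1200, replace = TRUE),
                  collapse = "")
  writeLines(c(">chr1", contig), file.path(dir, "genome.fa"))
  bed <- data.frame(chrom = "chr1", start = c(500L, 599L), end = c(560L, 700L),
                    name = c("geneA", "geneB"), score = 0L,
                    strand = c("+", "-"))
  write.table(bed, file.path(dir, "genes.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  list(dir = dir, contig = contig)
}

test_that("promoter extraction honours strand and coordinates", {
  tg <- with_toy_genome()
  prom <- extract_promoters(file.path(tg$dir, "genome.fa"),
                            file.path(tg$dir, "genes.bed"), upstream = 500)
  # + strand gene at 1-based start 501: promoter = contig[1..500]
  expect_identical(unname(prom$seq["geneA"]), substr(tg$contig, 1, 500))
  # - strand gene ending at 700: promoter = revcomp(contig[701..1200])
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(tg$contig, 701, 1200))))
  expect_identical(unname(prom$seq["geneB"]), rc)
})

test_that("promoter extraction errors on genes from unknown contigs", {
  tg <- with_toy_genome()
  bad <- data.frame(chrom = "chrX", start = 10L, end = 60L, name = "g",
                    score = 0L, strand = "+")
  bp <- file.path(tg$dir, "bad.bed")
  write.table(bad, bp, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  expect_error(extract_promoters(file.path(tg$dir, "genome.fa"), bp),
               "absent from the genome")
})

test_that("simulated promoters round-trip through FASTA/BED and FASTA/GFF3", {
  truth <- synthetic_truth(rank = 2, singular_values = c(8, 4), noise_sd = 0,
                           seed = 51)
  sim <- simulate_low_rank_delta(60, 20, truth)
  dir <- withr::local_tempdir()
  prom <- simulate_promoters(sim$delta$gene_ids, truth = truth,
                             loadings = sim$U, dir = dir)
  for (ann in c("genes.bed", "genes.gff3")) {
    ext <- extract_promoters(file.path(dir, "genome.fa"), file.path(dir, ann))
    expect_identical(unname(prom$seq),
                     unname(ext$seq[prom$info$gene_id]))
  }
  # first gene of the contig is truncated at the edge, not padded
  expect_equal(nchar(prom$seq[[1]]), 300)
})

test_that("motif presence matches a sliding-window scan oracle", {
  # homopolymer: exactly one 8-mer present
  p1 <- motif_presence(c(polyA = strrep("A", 500)))
  expect_equal(sum(p1), 1)
  expect_equal(colnames(p1)[which(p1[1, ] > 0)], "AAAAAAAA")
  # hand-enumerated 12-mer: 5 windows, first and fifth coincide
  p2 <- motif_presence(c(g = "ACGTACGTACGT"))
  expect_equal(sum(p2), 4)
  expect_setequal(colnames(p2)[which(p2[1, ] > 0)],
                  oracle_present_motifs("ACGTACGTACGT"))
  # random sequences with Ns against the oracle
  set.seed(61)
  seqs <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T", "N"), 60, replace = TRUE,
                 prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = ""),
    character(1))
  names(seqs) <- paste0("s", 1:5)
  pres <- motif_presence(seqs)
  for (i in 1:5) {
    expect_setequal(colnames(pres)[which(pres[i, ] > 0)],
                    oracle_present_motifs(seqs[[i]]))
  }
  # a length-L promoter holds at most L - 7 distinct 8-mers
  expect_lte(max(Matrix::rowSums(pres)), 60 - 7)
  expect_equal(ncol(pres), 65536)
})

test_that("presence column order agrees with the motif index encoding", {
  pres <- motif_presence(c(x = strrep("ACGT", 5)))
  expect_identical(colnames(pres), decode_motif(seq_len(65536)))
})

test_that("map_feature inverts members of the basis column space", {
  w <- make_world(n_genes = 40, n_experiments = 12, rank = 4, seed = 71)
  basis <- svd_decompose(center_and_impute(w$delta), m = 4)
  for (j in 1:4) {
    f <- setNames(basis$X[, j], rownames(basis$X))
    v <- map_feature(basis, f, center = FALSE)
    expect_equal(unname(v), as.numeric(seq_len(4) == j), tolerance = 1e-6)
  }
  # a feature orthogonal to the column space maps to zero
  set.seed(72)
  g <- rnorm(40)
  g <- g - basis$U[, 1:12] %*% crossprod(basis$U[, 1:12], g)  # full residual
  v0 <- map_feature(basis, as.numeric(g), center = FALSE)
  expect_lt(max(abs(v0)), 1e-8)
})

test_that("map_feature matches a hand-rolled Gaussian-elimination oracle", {
  set.seed(73)
  for (i in 1:5) {
    X <- matrix(rnorm(30 * 4), 30, 4)
    y <- rnorm(30)
    fake_basis <- list(X = X, gene_ids = NULL)
    got <- map_feature(fake_basis, y, center = TRUE)
    want <- oracle_normal_equations(X, y, center = TRUE)
    expect_equal(unname(got), want, tolerance = 1e-6)
  }
})

test_that("map_feature is linear and refuses underdetermined systems", {
  w <- make_world(n_genes = 30, n_experiments = 10, rank = 3, seed = 74)
  basis <- svd_decompose(center_and_impute(w$delta), m = 3)
  set.seed(75)
  f <- rnorm(30); g <- rnorm(30)
  lhs <- map_feature(basis, 2 * f + 3 * g)
  rhs <- 2 * map_feature(basis, f) + 3 * map_feature(basis, g)
  expect_equal(lhs, rhs, tolerance = 1e-8)
  too_few <- c(rnorm(2), rep(NA, 28))
  expect_error(map_feature(basis, too_few), "underdetermined")
})

test_that("map_all_motifs agrees with per-motif map_feature", {
  w <- make_world(n_genes = 50, n_experiments = 15, rank = 3, seed = 76)
  basis <- svd_decompose(center_and_impute(w$delta), m = 3)
  set.seed(77)
  seqs <- vapply(seq_len(50), function(i)
    paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = ""),
    character(1))
  names(seqs) <- w$delta$gene_ids
  pres <- motif_presence(seqs)
  W <- map_all_motifs(basis, pres)
  expect_equal(dim(W), c(65536, 3))
  nz <- which(Matrix::colSums(pres) > 0)[1:5]
  for (j in nz) {
    f <- setNames(as.numeric(pres[, j]), w$delta$gene_ids)
    expect_equal(unname(W[j, ]), unname(map_feature(basis, f)),
                 tolerance = 1e-8)
  }
  # a motif absent everywhere has zero weight after centering
  absent <- which(Matrix::colSums(pres) == 0)[1]
  expect_lt(max(abs(W[absent, ])), 1e-12)
})

test_that("summarize_weights counts tails and lists extremes", {
  W <- matrix(c(-0.8, -0.6, 0, 0.2, 0.7, 0.9), ncol = 1,
              dimnames = list(paste0("m", 1:6), "sv001"))
  class(W) <- c("motif_weights", class(W))
  s <- summarize_weights(W, variable = 1, threshold = 0.5, top_n = 2)
  expect_equal(s$n_below, 2)
  expect_equal(s$n_above, 2)
  expect_equal(names(s$top_negative), c("m1", "m2"))
  expect_equal(names(s$top_positive), c("m6", "m5"))
  expect_equal(s$mean, mean(W[, 1]))
})

test_that("map_go_terms maps indicators and skips empty terms", {
  w <- make_world(n_genes = 60, n_experiments = 20, rank = 3, seed = 78)
  basis <- svd_decompose(center_and_impute(w$delta), m = 3)
  gids <- w$delta$gene_ids
  go <- rbind(
    data.frame(gene_id = gids, term_id = "T:ALL", term_name = "everything"),
    data.frame(gene_id = gids[1:10], term_id = "T:SOME", term_name = "subset"),
    data.frame(gene_id = "not_a_gene", term_id = "T:NONE", term_name = "empty"))
  expect_warning(W <- map_go_terms(basis, go), "skipped")
  expect_setequal(rownames(W), c("T:ALL", "T:SOME"))
  # all-gene term: centred indicator is identically zero
  expect_lt(max(abs(W["T:ALL", ])), 1e-12)
  ind <- setNames(as.numeric(gids %in% gids[1:10]), gids)
  expect_equal(unname(W["T:SOME", ]), unname(map_feature(basis, ind)),
               tolerance = 1e-10)
})
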