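# Independent brute-force oracles used across the suite. These stay
# deliberately naive (explicit loops, no linear-algebra shortcuts) so
# they cannot share a bug with the implementation they check.

# E_approx by explicit element-wise matrix arithmetic: build
# M = I - P P' + diag(P P') with loops, apply it to every test row.
oracle_cv_error <- function(test_block, P) {
  E <- ncol(test_block)
  PPt <- matrix(0, E, E)
  if (!is.null(P) && length(P) > 0) {
    for (a in seq_len(E)) for (b in seq_len(E))
      for (j in seq_len(ncol(P))) PPt[a, b] <- PPt[a, b] + P[a, j] * P[b, j]
  }
  M <- diag(E) - PPt + diag(diag(PPt), E)
  total <- 0
  for (i in seq_len(nrow(test_block))) {
    row <- numeric(E)
    for (b in seq_len(E)) for (a in seq_len(E))
      row[b] <- row[b] + test_block[i, a] * M[a, b]
    total <- total + sum(row^2)
  }
  total
}

# Normal equations solved by hand-rolled Gaussian elimination with
# partial pivoting (no solve(), no chol()).
oracle_normal_equations <- function(X, y, center = TRUE) {
  if (center) y <- y - mean(y)
  m <- ncol(X)
  A <- matrix(0, m, m)
  b <- numeric(m)
  for (j in seq_len(m)) {
    for (k in seq_len(m)) A[j, k] <- sum(X[, j] * X[, k])
    b[j] <- sum(X[, j] * y)
  }
  aug <- cbind(A, b)
  for (col in seq_len(m)) {
    piv <- which.max(abs(aug[col:m, col])) + col - 1L
    if (piv != col) aug[c(col, piv), ] <- aug[c(piv, col), ]
    aug[col, ] <- aug[col, ] / aug[col, col]
    for (r in seq_len(m)[-col])
      aug[r, ] <- aug[r, ] - aug[r, col] * aug[col, ]
  }
  aug[, m + 1]
}

# Sliding-window 8-mer scan; windows containing non-ACGT contribute
# nothing. Returns the sorted set of distinct present motifs.
oracle_present_motifs <- function(seq, width = 8L) {
  n <- nchar(seq)
  if (n < width) return(character(0))
  found <- character(0)
  for (i in seq_len(n - width + 1L)) {
    w <- substr(seq, i, i + width - 1L)
    if (!grepl("[^ACGT]", w)) found <- c(found, w)
  }
  sort(unique(found))
}

# Shannon entropy of row-configuration groups by direct enumeration.
oracle_group_entropy <- function(config) {
  keys <- apply(config, 1, paste, collapse = "/")
  h <- 0
  for (g in unique(keys)) {
    p <- sum(keys == g) / nrow(config)
    h <- h - p * log2(p)
  }
  h
}

# Small centred low-rank world shared by several files.
make_world <- function(n_genes = 120, n_experiments = 40, rank = 4,
                       noise_sd = 0, seed = 1, missing_rate = 0) {
  truth <- synthetic_truth(rank = rank,
                           singular_values = seq(10 + 5 * rank, 10,
                                                 length.out = rank),
                           noise_sd = noise_sd, missing_rate = missing_rate,
                           seed = seed)
  simulate_low_rank_delta(n_genes, n_experiments, truth)
}
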