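#' Singular value decomposition of a centred expression matrix
#'
#' Thin SVD of the (centred, imputed) gene x experiment matrix,
#' `delta = U diag(sigma) t(V)`, with a deterministic sign convention:
#' the largest-magnitude entry of each left singular vector is made
#' positive, so serialized bases are reproducible across runs and
#' platforms. The left singular vectors describe gene-side contributions
#' of each state variable; the right singular vectors describe the
#' experimental inputs.
#'
#' @param x a centred [delta_matrix()] (see [center_and_impute()]), or a
#'   plain numeric matrix assumed centred.
#' @param m retained dimension for the coordinate basis `X = U_m S_m`;
#'   defaults to the full thin rank.
#' @return An object of class `state_basis`: list with `U`, `sigma`,
#'   `V`, `m`, `X` (= `U[, 1:m] %*% diag(sigma[1:m])`), `gene_ids`,
#'   `experiment_ids`.
#' @export
svd_decompose <- function(x, m = NULL) {
  if (inherits(x, "delta_matrix")) {
    if (!x$centered)
      stop("svd_decompose expects a centred matrix; run center_and_impute() first")
    v <- x$values
    v[!x$observed] <- 0
    gene_ids <- x$gene_ids
    experiment_ids <- x$experiment_ids
  } else {
    v <- as.matrix(x)
    gene_ids <- rownames(v)
    experiment_ids <- colnames(v)
  }
  if (any(!is.finite(v))) stop("non-finite entries in input matrix")
  s <- svd(v)
  # sign convention: largest-|entry| of each U column positive
  flip <- vapply(seq_len(ncol(s$u)), function(j) {
    i <- which.max(abs(s$u[, j]))
    s$u[i, j] < 0
  }, logical(1))
  s$u[, flip] <- -s$u[, flip]
  s$v[, flip] <- -s$v[, flip]
  r <- length(s$d)
  if (is.null(m)) m <- r
  if (m > r) stop("m exceeds available rank")
  state_basis(U = s$u, sigma = s$d, V = s$v, m = m,
              gene_ids = gene_ids, experiment_ids = experiment_ids)
}

state_basis <- function(U, sigma, V, m = length(sigma),
                        gene_ids = NULL, experiment_ids = NULL) {
  stopifnot(ncol(U) == length(sigma), ncol(V) == length(sigma),
            m >= 1, m <= length(sigma))
  X <- U[, seq_len(m), drop = FALSE] %*% diag(sigma[seq_len(m)], m)
  if (!is.null(gene_ids)) rownames(X) <- gene_ids
  structure(list(U = U, sigma = sigma, V = V, m = m, X = X,
                 gene_ids = gene_ids, experiment_ids = experiment_ids),
            class = "state_basis")
}

#' @export
print.state_basis <- function(x, ...) {
  cat(sprintf("state_basis: %d genes x %d experiments, %d singular values, m = %d\n",
              nrow(x$U), nrow(x$V), length(x$sigma), x$m))
  cat("  leading sigma:", paste(signif(utils::head(x$sigma, 5), 4), collapse = ", "),
      if (length(x$sigma) > 5) "..." else "", "\n")
  invisible(x)
}

#' Cross-validated approximation error for a candidate dimension
#'
#' For a held-out block of genes (rows) and the matrix `P` holding the
#' first `k` right singular vectors of the training block, computes
#' \deqn{E_{approx} = \sum_i \| [I - P P' + diag(P P')] \, x_i \|^2}
#' where the bracketed operator acts on the experiment axis of each
#' held-out gene row \eqn{x_i}. The `diag(PP')` term is the leave-out
#' correction that keeps the error from decreasing monotonically in `k`:
#' at `k = 0` and at `k` equal to the full experiment dimension the
#' error equals the squared Frobenius norm of the block, so the minimum
#' over `k` is interior for structured data.
#'
#' @param test_block numeric matrix, held-out genes x experiments,
#'   centred with the training column means.
#' @param P experiments x k matrix with orthonormal columns (first k
#'   right singular vectors of the training block); `k = 0` is allowed
#'   (a zero-column matrix or `NULL`).
#' @return Non-negative scalar error.
#' @export
cv_error <- function(test_block, P) {
  test_block <- as.matrix(test_block)
  if (is.null(P) || length(P) == 0L)
    return(sum(test_block^2))
  P <- as.matrix(P)
  if (ncol(test_block) != nrow(P))
    stop("column count of test_block must equal row count of P")
  d <- rowSums(P^2)                       # diag(P P')
  tm <- test_block - (test_block %*% P) %*% t(P) +
    sweep(test_block, 2, d, "*")
  sum(tm^2)
}

#' Golden-section search for an integer unimodal minimum
#'
#' Golden-ratio bracket shrinking on the integer lattice: probe points
#' are rounded to the nearest integer (perturbed by one on collision),
#' evaluations are memoized, and once the bracket width is at most 3 the
#' remaining integers are evaluated exhaustively. Ties are broken toward
#' the smaller argument (parsimony).
#'
#' @param f function of a single integer returning a numeric score;
#'   assumed unimodal on `[lo, hi]` (not verified).
#' @param lo,hi integer bracket, `lo < hi`.
#' @return The integer argmin over all evaluated points, with the full
#'   evaluation trace attached as attribute `"evaluations"` (a
#'   data.frame of `k` and `value`).
#' @export
golden_section_min <- function(f, lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (!(lo < hi)) stop("need lo < hi")
  memo <- new.env(parent = emptyenv())
  fm <- function(k) {
    key <- as.character(k)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- as.numeric(f(k))
    memo[[key]] <- v
    v
  }
  invphi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  while ((b - a) > 3L) {
    h <- b - a
    c <- as.integer(round(b - invphi * h))
    d <- as.integer(round(a + invphi * h))
    if (c <= a) c <- a + 1L
    if (d >= b) d <- b - 1L
    if (c >= d) { c <- max(a + 1L, d - 1L); if (c >= d) d <- c + 1L }
    if (fm(c) <= fm(d)) b <- d else a <- c
  }
  for (k in a:b) fm(k)
  ks <- sort(as.integer(ls(memo)))
  vals <- vapply(as.character(ks), function(key) memo[[key]], numeric(1))
  best <- ks[which.min(vals)]             # ks sorted: ties -> smaller k
  structure(best, evaluations = data.frame(k = ks, value = unname(vals)))
}

#' Estimate the degree of freedom of gene expression
#'
#' The central fitting function. The degree of freedom (DOF) is the
#' minimum number of state variables needed to represent genome-wide
#' expression changes in a linear state-space model; it is estimated
#' here by gene-split cross-validation of the SVD. Each repeat draws a
#' random split of the genes into a training set and a held-out set,
#' centres both blocks with the training column means, takes the right
#' singular vectors of the training block, and minimises the
#' cross-validated error [cv_error()] over the candidate dimension `k`
#' with an integer golden-section search.
#'
#' @param x a [delta_matrix()] (uncentred is fine: each repeat centres
#'   with its own training statistics).
#' @param n_train number of training genes per repeat (default 4000; the
#'   remaining genes form the held-out set).
#' @param n_repeats number of random splits (default 15).
#' @param seed integer seed; repeat `r` uses `seed + r` so all
#'   randomness flows from one value.
#' @param bracket integer search bracket for `k`; the default is
#'   `c(1, 800)` capped at the rank bound of the training block.
#' @return An object of class `dof_estimate` with the per-repeat
#'   selected dimensions and summary statistics; see
#'   [print.dof_estimate()], [summary.dof_estimate()],
#'   [plot.dof_estimate()].
#' @examples
#' truth <- synthetic_truth(rank = 5, singular_values = seq(30, 10, length.out = 5),
#'                          noise_sd = 0.1, seed = 1)
#' sim <- simulate_low_rank_delta(300, 80, truth)
#' fit <- estimate_dof(sim$delta, n_train = 240, n_repeats = 3, seed = 1,
#'                     bracket = c(1, 40))
#' fit
#' @export
estimate_dof <- function(x, n_train = 4000, n_repeats = 15, seed = 1,
                         bracket = c(1, 800)) {
  stopifnot(inherits(x, "delta_matrix"))
  n_genes <- nrow(x$values)
  n_exp <- ncol(x$values)
  if (n_train >= n_genes)
    stop("n_train must be smaller than the number of genes")
  if (n_exp < 2) stop("need at least 2 experiments")
  rank_bound <- min(n_train, n_exp)
  lo <- max(1L, as.integer(bracket[1]))
  hi <- min(as.integer(bracket[2]), rank_bound - 1L)
  if (hi <= lo) hi <- lo + 1L
  runs <- integer(n_repeats)
  traces <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    set.seed(seed + r)
    train_idx <- sample.int(n_genes, n_train)
    test_idx <- setdiff(seq_len(n_genes), train_idx)
    train <- subset_delta(x, genes = sort(train_idx))
    test <- subset_delta(x, genes = test_idx)
    train_c <- center_and_impute(train)
    mu <- attr(train_c, "column_means")
    test_c <- center_and_impute(test, means = mu)
    sv <- svd(train_c$values, nu = 0)     # right singular vectors only
    V <- sv$v
    tb <- test_c$values
    k_star <- golden_section_min(function(k) {
      cv_error(tb, V[, seq_len(k), drop = FALSE])
    }, lo, hi)
    runs[r] <- as.integer(k_star)
    traces[[r]] <- attr(k_star, "evaluations")
  }
  structure(list(runs = runs,
                 mean = mean(runs), sd = stats::sd(runs),
                 min = min(runs), max = max(runs),
                 n_repeats = n_repeats,
                 n_train_genes = n_train, n_test_genes = n_genes - n_train,
                 n_experiments = n_exp,
                 bracket = c(lo, hi), seed = seed,
                 traces = traces, call = match.call()),
            class = "dof_estimate")
}

#' @export
print.dof_estimate <- function(x, ...) {
  cat("Degree-of-freedom estimate (gene-split cross-validated SVD)\n")
  cat(sprintf("  %d repeats, %d training / %d held-out genes, %d experiments\n",
              x$n_repeats, x$n_train_genes, x$n_test_genes, x$n_experiments))
  cat(sprintf("  selected k: mean %.1f, sd %.2f, range %d-%d\n",
              x$mean, x$sd, x$min, x$max))
  invisible(x)
}

#' @export
summary.dof_estimate <- function(object, ...) {
  out <- list(runs = object$runs, mean = object$mean, sd = object$sd,
              min = object$min, max = object$max,
              n_repeats = object$n_repeats, bracket = object$bracket)
  class(out) <- "summary.dof_estimate"
  out
}

#' @export
print.summary.dof_estimate <- function(x, ...) {
  cat("Per-repeat selected dimensions:\n")
  print(x$runs)
  cat(sprintf("mean %.2f  sd %.3f  min %d  max %d  (bracket %d-%d)\n",
              x$mean, x$sd, x$min, x$max, x$bracket[1], x$bracket[2]))
  invisible(x)
}

#' @param x a `dof_estimate`.
#' @param repeats which repeats' cross-validation error traces to draw.
#' @param ... passed to [plot()].
#' @rdname estimate_dof
#' @export
plot.dof_estimate <- function(x, repeats = 1, ...) {
  tr <- do.call(rbind, lapply(repeats, function(r) {
    cbind(x$traces[[r]], repeat_id = r)
  }))
  plot(tr$k, tr$value, xlab = "candidate dimension k",
       ylab = "cross-validated error", ...)
  graphics::abline(v = x$runs[repeats], lty = 2, col = "grey40")
  invisible(x)
}

#' DOF as a function of data-set size
#'
#' Re-estimates the DOF on seeded subsamples of the experiment axis (or
#' gene axis) to study how the estimate grows with the amount of data.
#' Each requested size gets `n_repeats` independent subsamples drawn
#' without replacement; each subsample is estimated with a single
#' cross-validation split.
#'
#' @inheritParams estimate_dof
#' @param sizes integer vector of subsample sizes.
#' @param axis `"experiments"` (default) or `"genes"`.
#' @param n_train training genes for the inner estimate; when
#'   subsampling genes it is capped at 80\% of the subsample.
#' @return A data.frame of class `dof_curve` with one row per size:
#'   `size`, `mean_dof`, `sd_dof`, plus the successive increments of the
#'   mean attached as attribute `"increments"` (a data.frame of
#'   midpoint size and increment).
#' @export
dof_vs_datasize <- function(x, sizes, axis = c("experiments", "genes"),
                            n_repeats = 15, n_train = 4000, seed = 1,
                            bracket = c(1, 800)) {
  axis <- match.arg(axis)
  stopifnot(inherits(x, "delta_matrix"))
  avail <- if (axis == "experiments") ncol(x$values) else nrow(x$values)
  if (any(sizes > avail))
    stop("requested size exceeds available ", axis)
  per_run <- matrix(NA_integer_, length(sizes), n_repeats)
  for (i in seq_along(sizes)) {
    for (r in seq_len(n_repeats)) {
      sub_seed <- seed + 1000L * i + r
      set.seed(sub_seed)
      idx <- sample.int(avail, sizes[i])
      sub <- if (axis == "experiments")
        subset_delta(x, experiments = sort(idx))
      else subset_delta(x, genes = sort(idx))
      nt <- min(n_train, nrow(sub$values) - max(1L, round(0.2 * nrow(sub$values))))
      fit <- estimate_dof(sub, n_train = nt, n_repeats = 1,
                          seed = sub_seed, bracket = bracket)
      per_run[i, r] <- fit$runs[1]
    }
  }
  out <- data.frame(size = sizes,
                    mean_dof = rowMeans(per_run),
                    sd_dof = apply(per_run, 1, stats::sd))
  if (length(sizes) > 1) {
    inc <- diff(out$mean_dof)
    attr(out, "increments") <- data.frame(
      size = (sizes[-1] + sizes[-length(sizes)]) / 2, increment = inc)
  }
  attr(out, "runs") <- per_run
  class(out) <- c("dof_curve", "data.frame")
  out
}

#' Extrapolate the DOF-versus-size curve
#'
#' `extrapolate_quadric` fits an ordinary least-squares parabola
#' `y = a x^2 + b x + c` to (size, mean DOF) points and returns its
#' vertex `(-b/2a, c - b^2/4a)`; the leading coefficient must be
#' negative for the vertex to be a maximum. `extrapolate_linear_increments`
#' fits a straight line to the successive increments and returns the
#' size at which the fitted increment crosses zero.
#'
#' @param sizes numeric vector of data-set sizes (>= 3 points for the
#'   quadratic, >= 2 for the line).
#' @param mean_dofs mean DOF estimates at those sizes.
#' @return `extrapolate_quadric`: list with `vertex_size`, `vertex_dof`
#'   and the fitted `coefficients`. `extrapolate_linear_increments`:
#'   list with `zero_crossing_size` and `coefficients`.
#' @export
extrapolate_quadric <- function(sizes, mean_dofs) {
  if (length(sizes) < 3) stop("need at least 3 points for a quadratic fit")
  if (length(unique(sizes)) < 3) stop("degenerate design: collinear sizes")
  fit <- stats::lm(mean_dofs ~ sizes + I(sizes^2))
  co <- stats::coef(fit)
  a <- co[[3]]; b <- co[[2]]; c0 <- co[[1]]
  if (!(a < 0))
    stop("leading coefficient is non-negative: fitted curve has no maximum")
  vx <- -b / (2 * a)
  list(vertex_size = vx, vertex_dof = c0 + b * vx + a * vx^2,
       coefficients = c(intercept = c0, linear = b, quadratic = a))
}

#' @param increments successive increments of the mean DOF between
#'   consecutive sizes.
#' @rdname extrapolate_quadric
#' @export
extrapolate_linear_increments <- function(sizes, increments) {
  if (length(sizes) < 2) stop("need at least 2 points for a linear fit")
  fit <- stats::lm(increments ~ sizes)
  co <- stats::coef(fit)
  if (co[[2]] == 0) stop("flat line: no zero crossing")
  list(zero_crossing_size = -co[[1]] / co[[2]],
       coefficients = c(intercept = co[[1]], slope = co[[2]]))
}
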