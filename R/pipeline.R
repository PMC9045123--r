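#' Configuration for the end-to-end pipeline
#'
#' Collects paths, QC thresholds, DOF settings, basis dimension,
#' selection fraction and the seed in one validated list. Defaults are
#' the corpus-scale values used throughout the package; synthetic runs
#' override them with sizes matched to the simulated world.
#'
#' @param out_dir output directory for all stage artifacts.
#' @param expression path to an expression TSV (ignored with
#'   `simulate = TRUE`).
#' @param genome,annotation,go_table paths for promoter extraction and
#'   GO mapping; optional (those stages are skipped when absent).
#' @param simulate generate a synthetic world instead of reading inputs.
#' @param sim list of synthetic-world settings: `n_genes`,
#'   `n_experiments`, `rank`, `noise_sd`, `missing_rate`.
#' @param max_missing,min_genes,max_mean_abs QC thresholds (defaults
#'   250, 4000, 0.5).
#' @param n_train,n_repeats,bracket DOF-estimation settings (defaults
#'   4000, 15, c(1, 800)).
#' @param m TCSY dimension (default 450; capped at the available rank).
#' @param fraction extreme-motif selection fraction (default 0.01).
#' @param seed integer seed; mandatory for any stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, expression = NULL, genome = NULL,
                            annotation = NULL, go_table = NULL,
                            simulate = FALSE,
                            sim = list(n_genes = 500, n_experiments = 200,
                                       rank = 10, noise_sd = 0.1,
                                       missing_rate = 0.02),
                            max_missing = 250, min_genes = 4000,
                            max_mean_abs = 0.5,
                            n_train = 4000, n_repeats = 15,
                            bracket = c(1, 800), m = 450,
                            fraction = 0.01, seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory")
  stopifnot(max_missing >= 0, min_genes >= 1, max_mean_abs > 0,
            n_train >= 1, n_repeats >= 1, m >= 1,
            fraction > 0, fraction < 0.5)
  structure(list(out_dir = out_dir, expression = expression,
                 genome = genome, annotation = annotation,
                 go_table = go_table, simulate = simulate, sim = sim,
                 max_missing = max_missing, min_genes = min_genes,
                 max_mean_abs = max_mean_abs, n_train = n_train,
                 n_repeats = n_repeats, bracket = bracket, m = m,
                 fraction = fraction, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the canonical stage order -- simulate/ingest, QC, DOF
#' estimation, basis construction, feature mapping, information
#' capacity, projection -- writing per-stage artifacts under
#' `config$out_dir` and a machine-readable manifest
#' (`manifest.json`: seed, stage parameters, artifact checksums, QC
#' counts, DOF summary). A stage failure halts the run with the failing
#' stage named; artifacts of completed stages are preserved.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of stages to run (default all, in order).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("input", "qc", "dof", "basis",
                                    "features", "capacity", "project")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list(), artifacts = list())
  art <- function(name, path) {
    manifest$artifacts[[name]] <<- list(path = path,
                                        md5 = unname(tools::md5sum(path)))
  }
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    manifest$stages[[name]] <<- list(elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))
    res
  }
  env <- new.env()

  if ("input" %in% stages) run_stage("input", function() {
    if (config$simulate) {
      s <- config$sim
      truth <- synthetic_truth(rank = s$rank,
                               noise_sd = s$noise_sd,
                               missing_rate = s$missing_rate,
                               seed = config$seed,
                               planted_motifs = s$planted_motifs)
      sim <- simulate_low_rank_delta(s$n_genes, s$n_experiments, truth)
      env$delta <- sim$delta
      env$truth <- sim
      p <- file.path(config$out_dir, "expression.tsv")
      write_delta_tsv(sim$delta, p)
      art("expression", p)
      prom <- simulate_promoters(sim$delta$gene_ids, truth = truth,
                                 loadings = sim$U,
                                 dir = file.path(config$out_dir, "genome"))
      env$promoters <- prom
      config$genome <<- attr(prom, "files")$genome
      config$annotation <<- attr(prom, "files")$bed
      go <- simulate_go_annotations(sim$delta$gene_ids, n_terms = 20,
                                    coupling = 6, loadings = sim$U,
                                    seed = config$seed)
      gp <- file.path(config$out_dir, "go.tsv")
      utils::write.table(go, gp, sep = "\t", quote = FALSE, row.names = FALSE)
      art("go_table", gp)
      config$go_table <<- gp
    } else {
      if (is.null(config$expression) || !file.exists(config$expression))
        stop("expression TSV not found")
      env$delta <- read_delta_tsv(config$expression)
    }
  })

  if ("qc" %in% stages) run_stage("qc", function() {
    # coverage threshold cannot exceed the gene universe of this run
    # (80% floor leaves headroom for missing-at-random masks)
    mg <- min(config$min_genes, ceiling(0.8 * nrow(env$delta$values)))
    qc <- qc_pipeline(env$delta, max_missing = config$max_missing,
                      min_genes = mg,
                      threshold = config$max_mean_abs)
    env$centered <- qc$data
    manifest$qc <<- qc$report
    p <- file.path(config$out_dir, "qc_report.json")
    jsonlite::write_json(qc$report, p, auto_unbox = TRUE)
    art("qc_report", p)
  })

  if ("dof" %in% stages) run_stage("dof", function() {
    nt <- min(config$n_train, nrow(env$centered$values) -
                max(1L, round(0.2 * nrow(env$centered$values))))
    fit <- estimate_dof(env$centered, n_train = nt,
                        n_repeats = config$n_repeats, seed = config$seed,
                        bracket = config$bracket)
    env$dof <- fit
    manifest$dof <<- list(runs = fit$runs, mean = fit$mean, sd = fit$sd,
                          min = fit$min, max = fit$max)
    p <- file.path(config$out_dir, "dof.json")
    jsonlite::write_json(manifest$dof, p, auto_unbox = TRUE, digits = NA)
    art("dof", p)
  })

  if ("basis" %in% stages) run_stage("basis", function() {
    basis <- svd_decompose(env$centered)
    m_eff <- min(config$m, length(basis$sigma))
    env$tcsy <- build_tcsy(basis, m = m_eff,
                           params = list(seed = config$seed,
                                         max_missing = config$max_missing,
                                         min_genes = config$min_genes,
                                         max_mean_abs = config$max_mean_abs))
    paths <- write_tcsy(env$tcsy, file.path(config$out_dir, "tcsy"))
    art("tcsy_tsv", paths[["tsv"]]); art("tcsy_json", paths[["json"]])
    ve <- variance_explained(env$tcsy, env$centered)
    p <- file.path(config$out_dir, "variance_explained.tsv")
    utils::write.table(ve, p, sep = "\t", quote = FALSE, row.names = FALSE)
    art("variance_explained", p)
  })

  if ("features" %in% stages) run_stage("features", function() {
    if (is.null(config$genome) || is.null(config$annotation))
      stop("genome/annotation required for feature mapping")
    prom <- extract_promoters(config$genome, config$annotation)
    env$presence <- motif_presence(prom)
    keep <- match(env$tcsy$gene_ids, rownames(env$presence))
    env$presence <- env$presence[keep, , drop = FALSE]
    env$weights <- map_all_motifs(env$tcsy, env$presence)
    s <- summarize_weights(env$weights)
    manifest$motif_weights <<- list(n_below = s$n_below, n_above = s$n_above,
                                    mean = s$mean, sd = s$sd)
    p <- file.path(config$out_dir, "motif_weight_summary.json")
    jsonlite::write_json(list(summary = manifest$motif_weights,
                              top_negative = as.list(s$top_negative),
                              top_positive = as.list(s$top_positive)),
                         p, auto_unbox = TRUE, digits = NA)
    art("motif_weight_summary", p)
    if (!is.null(config$go_table)) {
      go <- utils::read.table(config$go_table, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
      gw <- map_go_terms(env$tcsy, go)
      p2 <- file.path(config$out_dir, "go_weights.tsv")
      utils::write.table(data.frame(term_id = rownames(gw), gw,
                                    check.names = FALSE),
                         p2, sep = "\t", quote = FALSE, row.names = FALSE)
      art("go_weights", p2)
    }
  })

  if ("capacity" %in% stages) run_stage("capacity", function() {
    sel <- select_extreme_motifs(env$weights, fraction = config$fraction)
    h_sys <- group_entropy(sel)
    ranking <- rank_genes_by_capacity(sel, env$presence)
    manifest$capacity <<- list(group_entropy_bits = h_sys,
                               mean_promoter_bits = mean(ranking$h),
                               sd_promoter_bits = stats::sd(ranking$h),
                               n_ranked = nrow(ranking))
    p <- file.path(config$out_dir, "capacity.json")
    jsonlite::write_json(manifest$capacity, p, auto_unbox = TRUE, digits = NA)
    art("capacity", p)
    rp <- file.path(config$out_dir, "genes_by_capacity.rnk")
    write_rnk(ranking, rp)
    art("rnk", rp)
  })

  if ("project" %in% stages) run_stage("project", function() {
    n_show <- min(4L, ncol(env$centered$values))
    coords <- predict(env$tcsy, subset_delta(env$centered,
                                             experiments = seq_len(n_show)))
    p <- file.path(config$out_dir, "parallel_coordinates.tsv")
    export_parallel_coordinates(coords, path = p)
    art("parallel_coordinates", p)
    v <- env$centered$values[, seq_len(n_show), drop = FALSE]
    r <- compare_states(v)
    p2 <- file.path(config$out_dir, "state_correlations.tsv")
    utils::write.table(round(r, 6), p2, sep = "\t", quote = FALSE)
    art("state_correlations", p2)
  })

  mp <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
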