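#' Predicted marker-positive percentages for a gene
#'
#' Accounting used to compare a predicted subtype marker against in-situ
#' quantification: the home cluster's share of all cells (`pct_home`), the
#' share of cells outside the home cluster that nonetheless express the
#' gene above `detect_thr` (`pct_other`, the low-expressing tail), and
#' their sum (`pct_total`), the percentage of cells expected to score
#' positive in situ.  Percentages are relative to all labeled cells,
#' including cluster 0.
#'
#' @param em an [rgc_ne].
#' @param cr an `rgc_clusters`.
#' @param gene gene identifier.
#' @param home_cluster the marker's cluster.
#' @param detect_thr NE detection threshold separating expressing from
#'   non-expressing cells (default 0: any nonzero NE).
#' @return list with `pct_home`, `pct_other`, `pct_total`.
#' @export
predicted_positive_pct <- function(em, cr, gene, home_cluster,
                                   detect_thr = 0) {
  stopifnot(inherits(em, "rgc_ne"), inherits(cr, "rgc_clusters"))
  if (!gene %in% colnames(em$ne)) stop("unknown gene: ", gene)
  labels <- align_labels(em, cr)
  n <- length(labels)
  home <- labels == home_cluster
  pct_home <- 100 * sum(home) / n
  expr_other <- (!home) & (em$ne[, gene] > detect_thr)
  pct_other <- 100 * sum(expr_other) / n
  list(pct_home = pct_home, pct_other = pct_other,
       pct_total = pct_home + pct_other)
}

#' One-sample t-test from summary statistics
#'
#' Used to compare an experimentally quantified percentage (mean, SD over
#' N replicates) against a predicted population value.
#'
#' @param mean,sd,n sample mean, standard deviation and size (n >= 2,
#'   sd > 0).
#' @param mu0 the hypothesized population mean.
#' @return list with `t` and `p` (two-tailed, df = n - 1).
#' @export
one_sample_t <- function(mean, sd, n, mu0) {
  if (n < 2) stop("need n >= 2")
  if (sd <= 0) stop("need sd > 0")
  t <- (mean - mu0) / (sd / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  list(t = t, p = p)
}

#' Concordance between single-cell averages and bulk RNA-seq
#'
#' Pearson correlation between each gene's average NE across all cells
#' and its bulk expression value, restricted to genes at or above
#' `min_fpkm` in the bulk data (lower values are noise-dominated).
#'
#' @param em an [rgc_ne].
#' @param bulk_table data.frame with gene identifiers in the first column
#'   and bulk expression (e.g. FPKM) in the second.
#' @param min_fpkm bulk expression cutoff.
#' @return list with `r`, `p` (two-tailed), `n_genes`.
#' @export
bulk_concordance <- function(em, bulk_table, min_fpkm = 1.0) {
  stopifnot(inherits(em, "rgc_ne"))
  bulk <- stats::setNames(as.numeric(bulk_table[[2]]),
                          as.character(bulk_table[[1]]))
  bulk <- bulk[bulk >= min_fpkm]
  shared <- intersect(names(bulk), colnames(em$ne))
  if (length(shared) < 3)
    stop("fewer than 3 genes shared between bulk table and NE matrix")
  avg <- Matrix::colSums(em$ne[, shared, drop = FALSE]) / nrow(em$ne)
  ct <- stats::cor.test(avg, bulk[shared])
  list(r = unname(ct$estimate), p = ct$p.value, n_genes = length(shared))
}

#' Run the full pipeline on synthetic or on-disk data
#'
#' Executes simulate/ingest, quality filtering, NE normalization,
#' two-round clustering with contaminant removal, marker discovery,
#' laterality statistics, hierarchical diversification, TF combinatorics
#' and the validation report, writing every table to `out_dir`.
#' Idempotent for a fixed seed: reruns produce byte-identical outputs.
#'
#' @param config list of pipeline settings; see [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list of the main in-memory results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "pipeline.log")
  log_line <- function(...) cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                                "|", ..., "\n", file = logf, append = TRUE)
  cat("", file = logf)
  stage <- function(name, expr) {
    log_line("stage", name, "start")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE))
  }

  dat <- stage("ingest", {
    if (!is.null(config$input_dir)) {
      cm <- read_counts(file.path(config$input_dir, "matrix.mtx"),
                        file.path(config$input_dir, "genes.tsv"),
                        file.path(config$input_dir, "barcodes.tsv"))
      list(counts = cm, truth = NULL,
           panels = config$panels)
    } else {
      g <- generate(config$sim)
      list(counts = g$counts, truth = g$truth, panels = g$truth$panels)
    }
  })
  log_line("seed", config$seed, "min_genes", config$min_genes,
           "n_dispersed", config$n_dispersed, "eps", config$eps,
           "minpts", config$minpts)

  qc <- stage("qc", filter_low_coverage(dat$counts, config$min_genes))
  writeLines(qc$removed_cells, file.path(out_dir, "qc_removed_cells.txt"))
  em <- stage("normalize", normalize_ne(qc$counts))
  tr <- stage("cluster", two_round(
    em, dat$panels, seed = config$seed, n_genes = config$n_dispersed,
    eps = config$eps, minpts = config$minpts,
    perplexity = config$perplexity, max_iter = config$max_iter))
  writeLines(tr$excluded_cells, file.path(out_dir, "excluded_cells.txt"))
  cr <- tr$clusters
  em2 <- tr$em
  utils::write.table(
    data.frame(barcode = names(cr$labels), cr$embedding$coords,
               cluster = cr$labels),
    file.path(out_dir, "embedding.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  prof <- stage("profile", cluster_profile(em2, cr))
  mk <- stage("markers", unique_markers(em2, cr, prof,
                                        fold_thr = config$fold_thr,
                                        min_ne = config$min_ne))
  utils::write.csv(mk, file.path(out_dir, "markers.csv"),
                   row.names = FALSE)
  census <- stage("census", homogeneity_census(prof, dat$panels$tf))
  utils::write.csv(census, file.path(out_dir, "census.csv"),
                   row.names = FALSE)

  lat <- stage("laterality", {
    tab <- build_table(cr, em2)
    list(table = tab, chisq = chi_square(tab),
         props = column_proportion_tests(tab, alpha = config$alpha),
         prop_r = eye_proportion_correlation(tab))
  })
  utils::write.csv(as.data.frame(unclass(lat$table)),
                   file.path(out_dir, "eye_cluster_table.csv"))
  utils::write.csv(lat$props, file.path(out_dir, "laterality.csv"),
                   row.names = FALSE)

  hier <- stage("hierarchy", {
    tree <- build_tree(prof)
    n_isp <- min(config$n_isp, cr$k)
    n_super <- min(config$n_super, n_isp)
    isps <- cut_isps(tree, n_super = n_super, n_isp = n_isp)
    write_tree_newick(tree, file.path(out_dir, "subtype_tree.nwk"))
    utils::write.csv(
      data.frame(cluster = names(isps$cluster_isp),
                 isp = isps$cluster_isp,
                 supercluster = isps$isp_supercluster[isps$cluster_isp]),
      file.path(out_dir, "isp_assignment.csv"), row.names = FALSE)
    list(tree = tree, isps = isps)
  })

  combos <- stage("tfcombos", cross_reference(
    prof, dat$panels$tf, min_ne = config$tf_min_ne,
    fold_strict = config$tf_fold, fold_relaxed = config$tf_fold_relaxed,
    max_k = config$tf_max_k))
  utils::write.csv(combos, file.path(out_dir, "tf_combos.csv"),
                   row.names = FALSE)

  smry <- stage("report", {
    pct <- prop.table(table(factor(cr$labels,
                                   levels = 0:cr$k))) * 100
    list(n_cells_qc = nrow(qc$counts$counts),
         n_cells_final = length(cr$labels),
         excluded_fraction = tr$excluded_fraction,
         k = cr$k,
         cluster_pct = as.list(stats::setNames(as.numeric(pct),
                                               names(pct))),
         chisq = lat$chisq,
         eye_proportion_r = lat$prop_r$r,
         n_markers = nrow(mk),
         n_combos = nrow(combos))
  })
  jsonlite::write_json(smry, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("done")
  invisible(list(counts = dat$counts, truth = dat$truth, em = em2,
                 clusters = cr, two_round = tr, profile = prof,
                 markers = mk, laterality = lat, hierarchy = hier,
                 combos = combos, summary = smry))
}

#' Default pipeline configuration
#'
#' A flat list of every pipeline setting.  `sim` holds the synthetic
#' generator config used when `input_dir` is NULL; with `input_dir` set,
#' `panels` must supply the gene panels.
#'
#' @param ... overrides of the defaults.
#' @export
pipeline_config <- function(...) {
  cfg <- list(input_dir = NULL, panels = NULL,
              sim = sim_config(),
              seed = 1L, min_genes = 600, n_dispersed = 1000,
              eps = 5.0, minpts = 15, perplexity = 30, max_iter = 1000,
              fold_thr = 1.8, min_ne = 0.05, alpha = 0.001,
              n_super = 2, n_isp = 4,
              tf_min_ne = 0.5, tf_fold = 2.0, tf_fold_relaxed = 1.5,
              tf_max_k = 3)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read a flat key = value pipeline config file
#'
#' Lines of the form `key = value`; values are parsed as numbers when
#' possible.  Unknown keys are rejected.
#'
#' @param path config file.
#' @return a [pipeline_config()] list with the file's overrides applied.
#' @export
read_pipeline_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- lapply(kv, function(x) {
    v <- x[2]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  base <- pipeline_config()
  unknown <- setdiff(keys, names(base))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  base[keys] <- vals
  base
}
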