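# Shared fixtures, generated once per test run, and independent oracles.

.fixture_env <- new.env(parent = emptyenv())

# Desk-scale fixture (3000 cells x 2000 genes x 8 clusters), with the NE
# matrix restricted to QC-passing RGC cells and clusters taken from the
# planted truth (clustering itself is exercised separately).
desk_fixture <- function() {
  if (is.null(.fixture_env$desk)) {
    g <- generate(sim_config(seed = 7))
    f <- filter_low_coverage(g$counts, 600)
    em <- normalize_ne(f$counts)
    lab <- g$truth$cell_cluster[em$cell_meta$barcode]
    keep <- lab > 0
    em_rgc <- rgc_ne(em$ne[keep, , drop = FALSE],
                     em$cell_meta[keep, , drop = FALSE], M = em$M)
    cr <- truth_clusters(lab[keep])
    .fixture_env$desk <- list(counts = g$counts, truth = g$truth,
                              em_all = em, em = em_rgc, cr = cr,
                              prof = cluster_profile(em_rgc, cr))
  }
  .fixture_env$desk
}

# Small fixture for cheap end-to-end runs (real t-SNE + DBSCAN).
small_config <- function(seed = 3, ...) {
  sim_config(n_cells = 800, n_genes = 700, n_clusters = 4, n_isps = 2,
             n_superclusters = 1, markers_per_cluster = 15,
             tf_panel_size = 12, seed = seed, ...)
}

# Wrap a named label vector as a cluster result.
truth_clusters <- function(labels) {
  structure(list(labels = labels, k = max(labels), embedding = NULL,
                 round = NA_integer_), class = "rgc_clusters")
}

# Wrap a bare genes x clusters mean matrix as a profile.
profile_of <- function(mean_ne, n_cells = NULL) {
  if (is.null(n_cells)) n_cells <- rep(10L, ncol(mean_ne))
  if (is.null(colnames(mean_ne)))
    colnames(mean_ne) <- as.character(seq_len(ncol(mean_ne)))
  structure(list(mean_ne = mean_ne, median_ne = mean_ne,
                 n_cells = stats::setNames(n_cells, colnames(mean_ne))),
            class = "cluster_profile")
}

# Build an NE container from a dense cells x genes matrix.
ne_of <- function(m, eye = "unknown", barcodes = NULL) {
  if (is.null(barcodes)) barcodes <- sprintf("c%04d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("g%03d", seq_len(ncol(m)))
  rgc_ne(Matrix::Matrix(m, sparse = TRUE),
         data.frame(barcode = barcodes,
                    eye = rep_len(eye, nrow(m)),
                    stringsAsFactors = FALSE))
}

# Exhaustive unique-combination oracle: enumerate every TF subset up to
# max_k with no pruning, keep AND-patterns of sum 1, then apply the
# minimality rule by explicit proper-subset pattern checks.
oracle_unique_combos <- function(ind, max_k) {
  storage.mode(ind) <- "logical"
  Tn <- nrow(ind)
  clusters <- colnames(ind)
  if (is.null(clusters)) clusters <- as.character(seq_len(ncol(ind)))
  pat_of <- function(idx) {
    p <- rep(TRUE, ncol(ind))
    for (i in idx) p <- p & ind[i, ]
    p
  }
  cand <- list()
  for (k in seq_len(max_k)) {
    if (k > Tn) break
    cc <- utils::combn(Tn, k)
    for (j in seq_len(ncol(cc))) {
      idx <- cc[, j]
      p <- pat_of(idx)
      if (sum(p) == 1)
        cand[[length(cand) + 1]] <- list(idx = idx, k = k,
                                         cluster = clusters[which(p)])
    }
  }
  is_unique_subset <- function(idx) {
    for (k in seq_len(length(idx) - 1)) {
      cc <- utils::combn(idx, k)
      for (j in seq_len(ncol(cc)))
        if (sum(pat_of(cc[, j])) == 1) return(TRUE)
    }
    FALSE
  }
  keep <- vapply(cand, function(e)
    length(e$idx) == 1 || !is_unique_subset(e$idx), logical(1))
  cand <- cand[keep]
  if (!length(cand))
    return(data.frame(cluster = character(), tfs = character(),
                      k = integer()))
  tf_names <- rownames(ind)
  if (is.null(tf_names)) tf_names <- as.character(seq_len(Tn))
  data.frame(
    cluster = vapply(cand, `[[`, character(1), "cluster"),
    tfs = vapply(cand, function(e)
      paste(tf_names[e$idx], collapse = "+"), character(1)),
    k = vapply(cand, `[[`, integer(1), "k"),
    stringsAsFactors = FALSE)
}

# Random binary matrix with every row containing at least one 0 and one 1.
random_binary_matrix <- function(n_tf, n_cl, p = 0.3) {
  m <- matrix(stats::rbinom(n_tf * n_cl, 1, p), n_tf, n_cl,
              dimnames = list(sprintf("T%02d", seq_len(n_tf)),
                              as.character(seq_len(n_cl))))
  for (i in seq_len(n_tf)) {
    if (all(m[i, ] == 1)) m[i, sample(n_cl, 1)] <- 0
    if (all(m[i, ] == 0)) m[i, sample(n_cl, 1)] <- 1
  }
  m
}

# Eye x cluster table from raw label/eye vectors (for constructed cases).
table_of <- function(labels, eye) {
  cr <- truth_clusters(stats::setNames(labels,
                                       sprintf("c%04d", seq_along(labels))))
  meta <- data.frame(barcode = sprintf("c%04d", seq_along(labels)),
                     eye = eye, stringsAsFactors = FALSE)
  build_table(cr, meta)
}
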