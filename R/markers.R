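#' Per-cluster expression profile
#'
#' Mean and median NE of every gene in every cluster (cluster 0, the
#' unassigned cells, is excluded).  This genes x clusters table is the
#' substrate for marker discovery, the gene census, the subtype dendrogram
#' and TF combinatorics.
#'
#' @param em an [rgc_ne] object.
#' @param cr an `rgc_clusters` result on the same cells.
#' @return An object of class `cluster_profile`: list with `mean_ne` and
#'   `median_ne` (genes x clusters matrices, columns `"1"..."K"`) and
#'   `n_cells` (per-cluster sizes).
#' @export
cluster_profile <- function(em, cr) {
  stopifnot(inherits(em, "rgc_ne"), inherits(cr, "rgc_clusters"))
  if (cr$k < 1) stop("no clusters (K = 0)")
  labels <- align_labels(em, cr)
  G <- ncol(em$ne)
  mean_ne <- matrix(0, G, cr$k,
                    dimnames = list(colnames(em$ne), as.character(seq_len(cr$k))))
  median_ne <- mean_ne
  n_cells <- integer(cr$k)
  for (k in seq_len(cr$k)) {
    cells <- which(labels == k)
    if (!length(cells)) stop("cluster ", k, " is empty")
    n_cells[k] <- length(cells)
    sub <- em$ne[cells, , drop = FALSE]
    mean_ne[, k] <- Matrix::colSums(sub) / length(cells)
    median_ne[, k] <- sparse_col_medians(sub)
  }
  structure(list(mean_ne = mean_ne, median_ne = median_ne,
                 n_cells = stats::setNames(n_cells,
                                           as.character(seq_len(cr$k)))),
            class = "cluster_profile")
}

# Match cluster labels to the cells of an NE matrix by barcode when names
# are available, else require equal length.
align_labels <- function(em, cr) {
  bc <- em$cell_meta$barcode
  if (!is.null(names(cr$labels)) && all(bc %in% names(cr$labels)))
    return(cr$labels[bc])
  if (length(cr$labels) != nrow(em$ne))
    stop("cluster labels do not match the NE matrix cells")
  cr$labels
}

# Column medians of a sparse matrix without densifying: a gene's median is
# 0 whenever fewer than half its values are nonzero.
sparse_col_medians <- function(x) {
  n <- nrow(x)
  out <- numeric(ncol(x))
  xc <- methods::as(x, "CsparseMatrix")
  nnz <- diff(xc@p)
  need <- which(nnz > n / 2)
  for (j in need) {
    v <- xc@x[(xc@p[j] + 1):xc@p[j + 1]]
    out[j] <- stats::median(c(v, numeric(n - length(v))))
  }
  out
}

#' Discover uniquely enriched subtype markers
#'
#' A gene is a candidate marker of a cluster when its mean NE exceeds
#' `fold_thr` times the mean NE of every other cluster (strictly) and its
#' home mean NE exceeds `min_ne`.  For up to `top_n_tested` candidates per
#' cluster (ranked by worst-case fold), per-comparison two-tailed t-tests
#' and Mann-Whitney U tests on per-cell NE values assign a significance
#' tier from the worst p across the K-1 comparisons:
#' `strict` (both tests p <= 0.05), `relaxed` (t <= 0.05 and MWU <= 0.1),
#' `weak` (exactly one test <= 0.05 while the other > 0.1), else `ns`.
#' Remaining candidates are emitted untested (`tier = NA`).
#'
#' A zero denominator counts as satisfying the fold criterion when the
#' home mean clears `min_ne`.
#'
#' @param em an [rgc_ne].
#' @param cr an `rgc_clusters` with K >= 2.
#' @param prof the matching [cluster_profile()]; recomputed if `NULL`.
#' @param fold_thr minimum fold of home mean NE over every other cluster.
#' @param min_ne minimum home-cluster mean NE.
#' @param top_n_tested number of fold-ranked candidates per cluster to
#'   p-value test.
#' @param small_cluster_min clusters smaller than this emit markers with
#'   `small_cluster = TRUE` (their p-values are underpowered).
#' @return data.frame with columns `gene`, `cluster`, `min_fold`, `expr`,
#'   `p_t_max`, `p_mwu_max`, `tier`, `small_cluster`.
#' @export
unique_markers <- function(em, cr, prof = NULL, fold_thr = 1.8,
                           min_ne = 0.05, top_n_tested = 5,
                           small_cluster_min = 30) {
  stopifnot(fold_thr > 0, min_ne > 0)
  if (is.null(prof)) prof <- cluster_profile(em, cr)
  K <- ncol(prof$mean_ne)
  if (K < 2) stop("fold enrichment undefined for K < 2 clusters")
  labels <- align_labels(em, cr)
  rows <- list()
  for (k in seq_len(K)) {
    home <- prof$mean_ne[, k]
    other <- prof$mean_ne[, -k, drop = FALSE]
    max_other <- matrixStats::rowMaxs(other)
    min_fold <- ifelse(max_other > 0, home / max_other,
                       ifelse(home > min_ne, Inf, 0))
    pass <- which(min_fold > fold_thr & home > min_ne)
    if (!length(pass)) next
    pass <- pass[order(-min_fold[pass], rownames(prof$mean_ne)[pass])]
    genes <- rownames(prof$mean_ne)[pass]
    tested <- seq_along(pass) <= top_n_tested
    p_t <- p_u <- rep(NA_real_, length(pass))
    for (i in which(tested)) {
      g <- genes[i]
      v_home <- em$ne[labels == k, g]
      pt <- pu <- -Inf
      for (kk in setdiff(seq_len(K), k)) {
        v_o <- em$ne[labels == kk, g]
        pt <- max(pt, stats::t.test(v_home, v_o)$p.value)
        pu <- max(pu, suppressWarnings(
          stats::wilcox.test(v_home, v_o)$p.value))
      }
      p_t[i] <- pt
      p_u[i] <- pu
    }
    tier <- rep(NA_character_, length(pass))
    tier[tested] <- marker_tier(p_t[tested], p_u[tested])
    rows[[length(rows) + 1]] <- data.frame(
      gene = genes, cluster = k, min_fold = min_fold[pass],
      expr = home[pass], p_t_max = p_t, p_mwu_max = p_u, tier = tier,
      small_cluster = prof$n_cells[k] < small_cluster_min,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), cluster = integer(),
               min_fold = numeric(), expr = numeric(),
               p_t_max = numeric(), p_mwu_max = numeric(),
               tier = character(), small_cluster = logical())
  rownames(out) <- NULL
  out
}

# Tier from worst-case p-values of the two tests.
marker_tier <- function(p_t, p_u) {
  vapply(seq_along(p_t), function(i) {
    pt <- p_t[i]; pu <- p_u[i]
    if (pt <= 0.05 && pu <= 0.05) "strict"
    else if (pt <= 0.05 && pu <= 0.1) "relaxed"
    else if (xor(pt <= 0.05, pu <= 0.05) && max(pt, pu) > 0.1) "weak"
    else "ns"
  }, character(1))
}

#' Census of homogeneous versus non-homogeneous genes
#'
#' At each expression threshold, among genes whose maximum cluster mean NE
#' exceeds the threshold, counts genes expressed homogeneously across
#' clusters (max/min cluster-mean ratio <= `fold_band`) versus
#' non-homogeneously (ratio > `fold_band`), split into TFs and other
#' genes.  Percentages are normalized within each of the four categories
#' relative to its count at the lowest threshold (> 0 NE), quantifying how
#' much expression variability distinguishes subtype identity from
#' cell-type identity.
#'
#' @param prof a [cluster_profile()].
#' @param tfs [gene_panel] of transcription factors, or `NULL` to skip the
#'   TF split.
#' @param thresholds ascending NE thresholds (the first is typically 0).
#' @param fold_band homogeneity band (max/min cluster-mean ratio).
#' @return data.frame with `threshold`, `category` (`homogeneous` /
#'   `non_homogeneous`), `class` (`tf` / `other`), `count`, `pct`.
#' @export
homogeneity_census <- function(prof, tfs = NULL,
                               thresholds = c(0, 0.2, 0.4, 0.8, 1.6),
                               fold_band = 1.5) {
  stopifnot(!is.unsorted(thresholds))
  mx <- matrixStats::rowMaxs(prof$mean_ne)
  mn <- matrixStats::rowMins(prof$mean_ne)
  homog <- ifelse(mn > 0, mx / mn <= fold_band, mx == 0)
  is_tf <- if (is.null(tfs)) rep(FALSE, nrow(prof$mean_ne)) else
    rownames(prof$mean_ne) %in% tfs$genes
  classes <- if (is.null(tfs)) "other" else c("tf", "other")
  rows <- list()
  for (tau in thresholds) {
    inc <- mx > tau
    for (cat in c("homogeneous", "non_homogeneous")) {
      h <- if (cat == "homogeneous") homog else !homog
      for (cls in classes) {
        t_sel <- if (cls == "tf") is_tf else !is_tf
        rows[[length(rows) + 1]] <- data.frame(
          threshold = tau, category = cat, class = cls,
          count = sum(inc & h & t_sel), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  base <- out[out$threshold == thresholds[1], ]
  key <- paste(out$category, out$class)
  base_key <- stats::setNames(base$count, paste(base$category, base$class))
  out$pct <- ifelse(base_key[key] > 0,
                    100 * out$count / base_key[key], NA_real_)
  rownames(out) <- NULL
  out
}

#' Pairwise cluster correlations and per-cluster mean r
#'
#' Pearson correlation between cluster mean-NE profiles, plus each
#' cluster's mean correlation to all other clusters (the similarity
#' ranking of subtypes).  Zero-variance profiles yield NA.
#'
#' @param prof a [cluster_profile()] with K >= 2.
#' @return list with `r` (K x K correlation matrix) and `mean_r`
#'   (per-cluster mean correlation to the others, ranked columns as in the
#'   profile).
#' @export
cluster_correlations <- function(prof) {
  K <- ncol(prof$mean_ne)
  if (K < 2) stop("need K >= 2 clusters")
  sds <- matrixStats::colSds(prof$mean_ne)
  r <- suppressWarnings(stats::cor(prof$mean_ne))
  r[, sds == 0] <- NA_real_
  r[sds == 0, ] <- NA_real_
  diag(r) <- 1
  mean_r <- vapply(seq_len(K), function(k) mean(r[-k, k]), numeric(1))
  names(mean_r) <- colnames(prof$mean_ne)
  list(r = r, mean_r = mean_r)
}

#' Row-wise z-scored profile matrix for heatmap export
#'
#' @param prof a [cluster_profile()].
#' @return genes x clusters matrix of row z-scores (genes with zero
#'   variance across clusters are dropped).
#' @export
zscore_profile <- function(prof) {
  m <- prof$mean_ne
  sds <- matrixStats::rowSds(m)
  m <- m[sds > 0, , drop = FALSE]
  (m - rowMeans(m)) / matrixStats::rowSds(m)
}
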