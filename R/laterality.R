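#' Build the eye-by-cluster contingency table
#'
#' Counts cells per cluster per eye of origin.  Cells with unknown eye are
#' always excluded; cluster 0 (unassigned) is excluded by default.
#'
#' @param cr an `rgc_clusters` result.
#' @param meta data.frame with `barcode` and `eye`, or an [rgc_ne] /
#'   [rgc_counts] whose `cell_meta` is used.
#' @param include_cluster0 keep cluster-0 cells as their own column.
#' @return An object of class `eye_cluster_table`: integer matrix with
#'   rows `left`, `right` and one column per cluster, plus attribute
#'   `eye_totals`.
#' @export
build_table <- function(cr, meta, include_cluster0 = FALSE) {
  stopifnot(inherits(cr, "rgc_clusters"))
  if (inherits(meta, "rgc_ne") || inherits(meta, "rgc_counts"))
    meta <- meta$cell_meta
  eye <- stats::setNames(meta$eye, meta$barcode)[names(cr$labels)]
  keep <- eye %in% c("left", "right") &
    (include_cluster0 | cr$labels > 0)
  if (!any(eye %in% c("left", "right")))
    stop("no cells with known eye of origin")
  lab <- cr$labels[keep]
  ey <- factor(eye[keep], levels = c("left", "right"))
  cl <- factor(lab, levels = sort(unique(lab)))
  tab <- as.matrix(table(ey, cl))
  names(dimnames(tab)) <- NULL
  rownames(tab) <- c("left", "right")
  if (!all(rowSums(tab) > 0)) stop("need at least one cell per eye")
  structure(tab, eye_totals = rowSums(tab), class = "eye_cluster_table")
}

#' Pearson chi-squared test of eye-by-cluster association
#'
#' Standard Pearson chi-squared on the 2 x K contingency table;
#' df = K - 1.  Significance indicates that cluster membership and eye of
#' origin are not independent, i.e. at least one subtype is lateralized.
#'
#' @param t an `eye_cluster_table`.
#' @return list with `statistic`, `df`, `p`.
#' @export
chi_square <- function(t) {
  stopifnot(inherits(t, "eye_cluster_table"))
  m <- unclass(t)
  attr(m, "eye_totals") <- NULL
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero row or column total")
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(E == 0)) stop("expected count of zero")
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Per-cluster two-proportion z-tests of eye enrichment
#'
#' For each cluster, compares the cluster's share of the left eye's cells
#' with its share of the right eye's cells by a pooled two-proportion
#' z-test, Bonferroni-adjusted across the K clusters.  Clusters with fewer
#' than 2 cells are reported untestable.
#'
#' @param t an `eye_cluster_table`.
#' @param alpha significance level applied to the adjusted p.
#' @param correction `"bonferroni"` or `"none"`.
#' @return data.frame with `cluster`, `left_pct`, `right_pct`, `z`, `p`,
#'   `p_adj`, `enriched_eye` (`left`/`right`/`none`), `testable`.
#' @export
column_proportion_tests <- function(t, alpha = 0.001,
                                    correction = c("bonferroni", "none")) {
  stopifnot(inherits(t, "eye_cluster_table"))
  correction <- match.arg(correction)
  m <- unclass(t)
  nL <- sum(m["left", ]); nR <- sum(m["right", ])
  K <- ncol(m)
  res <- data.frame(cluster = colnames(m),
                    left_pct = 100 * m["left", ] / nL,
                    right_pct = 100 * m["right", ] / nR,
                    z = NA_real_, p = NA_real_, p_adj = NA_real_,
                    enriched_eye = "none",
                    testable = colSums(m) >= 2,
                    stringsAsFactors = FALSE)
  for (j in seq_len(K)) {
    if (!res$testable[j]) next
    pL <- m["left", j] / nL
    pR <- m["right", j] / nR
    pp <- (m["left", j] + m["right", j]) / (nL + nR)
    se <- sqrt(pp * (1 - pp) * (1 / nL + 1 / nR))
    z <- if (se > 0) (pR - pL) / se else 0
    p <- 2 * stats::pnorm(-abs(z))
    res$z[j] <- z
    res$p[j] <- p
  }
  mult <- if (correction == "bonferroni") sum(res$testable) else 1
  res$p_adj <- pmin(1, res$p * mult)
  sig <- !is.na(res$p_adj) & res$p_adj < alpha
  res$enriched_eye[sig] <- ifelse(res$z[sig] > 0, "right", "left")
  rownames(res) <- NULL
  res
}

#' Mirror-symmetry of eye-specific cluster transcriptomes
#'
#' Computes each cluster's mean-NE profile separately for left-eye and
#' right-eye cells, then compares Pearson correlations of same-cluster
#' left/right profile pairs against all cross-cluster left/right pairs
#' with an independent two-sample two-tailed t-test.  Mirror-symmetric
#' subtypes give same-cluster correlations exceeding cross-cluster ones.
#'
#' @param em an [rgc_ne].
#' @param cr an `rgc_clusters`.
#' @param meta per-cell metadata (defaults to `em$cell_meta`).
#' @param min_cells_per_eye clusters with fewer cells than this in either
#'   eye are skipped.
#' @return list with `same_cluster_r`, `diff_cluster_r`, `t_test_p`, and
#'   `clusters_used`.
#' @export
eye_mirror_correlations <- function(em, cr, meta = NULL,
                                    min_cells_per_eye = 2) {
  stopifnot(inherits(em, "rgc_ne"), inherits(cr, "rgc_clusters"))
  if (is.null(meta)) meta <- em$cell_meta
  labels <- align_labels(em, cr)
  eye <- meta$eye
  usable <- integer(0)
  profL <- profR <- list()
  for (k in seq_len(cr$k)) {
    iL <- which(labels == k & eye == "left")
    iR <- which(labels == k & eye == "right")
    if (length(iL) < min_cells_per_eye || length(iR) < min_cells_per_eye)
      next
    usable <- c(usable, k)
    profL[[as.character(k)]] <- Matrix::colSums(em$ne[iL, , drop = FALSE]) /
      length(iL)
    profR[[as.character(k)]] <- Matrix::colSums(em$ne[iR, , drop = FALSE]) /
      length(iR)
  }
  if (length(usable) < 2)
    stop("fewer than 2 clusters with >= ", min_cells_per_eye,
         " cells per eye")
  same_r <- vapply(as.character(usable), function(k)
    stats::cor(profL[[k]], profR[[k]]), numeric(1))
  diff_r <- c()
  for (a in as.character(usable)) for (b in as.character(usable))
    if (a != b) diff_r <- c(diff_r, stats::cor(profL[[a]], profR[[b]]))
  tt <- stats::t.test(same_r, diff_r)
  list(same_cluster_r = same_r, diff_cluster_r = diff_r,
       t_test_p = tt$p.value, clusters_used = usable)
}

#' Correlation of per-cluster left and right eye percentages
#'
#' Pearson correlation between the percent of each eye's cells falling in
#' each cluster — a whole-population summary of how proportionally the
#' subtypes are represented in the two eyes.
#'
#' @param t an `eye_cluster_table` with at least 2 clusters.
#' @return list with `r`, `p` (two-tailed), and the two percentage
#'   vectors.  `r` is NA when either percentage vector has zero variance.
#' @export
eye_proportion_correlation <- function(t) {
  stopifnot(inherits(t, "eye_cluster_table"))
  m <- unclass(t)
  if (ncol(m) < 2) stop("need at least 2 clusters")
  pctL <- 100 * m["left", ] / sum(m["left", ])
  pctR <- 100 * m["right", ] / sum(m["right", ])
  if (stats::sd(pctL) == 0 || stats::sd(pctR) == 0)
    return(list(r = NA_real_, p = NA_real_, left_pct = pctL,
                right_pct = pctR))
  if (ncol(m) < 3) {            # r is defined but the test needs n >= 3
    return(list(r = stats::cor(pctL, pctR), p = NA_real_,
                left_pct = pctL, right_pct = pctR))
  }
  ct <- stats::cor.test(pctL, pctR)
  list(r = unname(ct$estimate), p = ct$p.value, left_pct = pctL,
       right_pct = pctR)
}
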