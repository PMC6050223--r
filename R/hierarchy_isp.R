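#' Build the subtype dendrogram
#'
#' Agglomerative hierarchical clustering over the cluster mean-NE columns,
#' by default with Chebyshev (maximum) distance and Ward linkage — the
#' canonical tree used for cutting into superclusters and intermediate
#' subpopulations.  A maximum-distance + complete-linkage alternative is
#' available for heatmap-style dendrograms.
#'
#' @param prof a [cluster_profile()] with K >= 2.
#' @param metric distance over profiles: `"chebyshev"` (alias
#'   `"maximum"`) or any [stats::dist()] method.
#' @param linkage `"ward"` (Ward's method, `ward.D2`) or any
#'   [stats::hclust()] method such as `"complete"`.
#' @return An object of class `subtype_tree`: list with `hclust`, `metric`,
#'   `linkage`, and `n_cells` carried from the profile.
#' @export
build_tree <- function(prof, metric = "chebyshev", linkage = "ward") {
  stopifnot(inherits(prof, "cluster_profile"))
  K <- ncol(prof$mean_ne)
  if (K < 2) stop("need K >= 2 clusters to build a tree")
  dmethod <- if (metric %in% c("chebyshev", "maximum")) "maximum" else metric
  lmethod <- if (linkage == "ward") "ward.D2" else linkage
  d <- stats::dist(t(prof$mean_ne), method = dmethod)
  hc <- stats::hclust(d, method = lmethod)
  structure(list(hclust = hc, metric = metric, linkage = linkage,
                 n_cells = prof$n_cells),
            class = "subtype_tree")
}

#' Export a subtype tree in newick format
#'
#' @param tree a [build_tree()] result.
#' @param path output file.
#' @return invisibly, the newick string.
#' @export
write_tree_newick <- function(tree, path) {
  phy <- ape::as.phylo(tree$hclust)
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Cut the subtype tree into superclusters and ISPs
#'
#' Horizontal cuts of the dendrogram producing exactly `n_super`
#' superclusters and `n_isp` intermediate subpopulations (ISPs).  Cuts of
#' the same tree are nested, so every ISP falls inside exactly one
#' supercluster.  ISP prevalence is the fraction of clustered cells whose
#' cluster belongs to the ISP (when cell counts are available).
#'
#' @param tree a [build_tree()] result.
#' @param n_super number of superclusters (1 <= n_super <= n_isp).
#' @param n_isp number of ISPs (n_isp <= K).
#' @return An object of class `isp_assignment`: list with `cluster_isp`
#'   (named integer, cluster -> ISP), `isp_supercluster` (ISP ->
#'   supercluster), and `isp_prevalence` (fractions summing to 1, or NULL
#'   without cell counts).
#' @export
cut_isps <- function(tree, n_super = 4, n_isp = 10) {
  stopifnot(inherits(tree, "subtype_tree"))
  K <- length(tree$hclust$labels)
  if (!(n_super >= 1 && n_super <= n_isp && n_isp <= K))
    stop("need 1 <= n_super <= n_isp <= K (K = ", K, ")")
  isp <- stats::cutree(tree$hclust, k = n_isp)
  sup <- stats::cutree(tree$hclust, k = n_super)
  isp_super <- integer(n_isp)
  for (i in seq_len(n_isp)) {
    s <- unique(sup[isp == i])
    if (length(s) != 1)
      stop("inconsistent nesting of cuts (tied merge heights?)")
    isp_super[i] <- s
  }
  prevalence <- NULL
  if (!is.null(tree$n_cells)) {
    tot <- sum(tree$n_cells)
    prevalence <- vapply(seq_len(n_isp), function(i)
      sum(tree$n_cells[names(isp)[isp == i]]) / tot, numeric(1))
    names(prevalence) <- seq_len(n_isp)
  }
  structure(list(cluster_isp = isp, isp_supercluster = isp_super,
                 isp_prevalence = prevalence),
            class = "isp_assignment")
}

#' Genes and TFs uniquely enriched at the ISP level
#'
#' Clusters of each ISP are merged into one pseudo-cluster; the unique
#' enrichment rule (fold over every other ISP above `fold_thr`, expression
#' above `min_ne`) is applied to the merged profiles.  Each candidate is
#' then re-verified per member cluster: its mean NE in every member
#' cluster must exceed `fold_thr` times the best mean among clusters
#' outside the ISP, dropping genes whose ISP-level enrichment is carried
#' by a subset of member clusters.
#'
#' @param em an [rgc_ne].
#' @param cr an `rgc_clusters`.
#' @param isps a [cut_isps()] assignment (cluster names must match the
#'   profile columns).
#' @param fold_thr,min_ne enrichment thresholds (NE-ratio units, NE).
#' @param verify_per_cluster apply the per-member-cluster check.
#' @param tfs optional [gene_panel] used to tag TFs in the output.
#' @param prof optional precomputed [cluster_profile()].
#' @return data.frame with `gene`, `isp`, `min_fold` (ISP-merged fold),
#'   `expr`, `is_tf`, `verified`.
#' @export
isp_enriched <- function(em, cr, isps, fold_thr = 1.8, min_ne = 0.05,
                         verify_per_cluster = TRUE, tfs = NULL,
                         prof = NULL) {
  stopifnot(inherits(isps, "isp_assignment"))
  labels <- align_labels(em, cr)
  cluster_isp <- isps$cluster_isp
  isp_of_cell <- ifelse(labels > 0,
                        cluster_isp[as.character(labels)], 0L)
  n_isp <- max(cluster_isp)
  # merged ISP profile
  isp_cr <- structure(list(labels = stats::setNames(as.integer(isp_of_cell),
                                                    names(labels)),
                           k = n_isp, embedding = NULL, round = NA_integer_),
                      class = "rgc_clusters")
  isp_prof <- cluster_profile(em, isp_cr)
  if (is.null(prof)) prof <- cluster_profile(em, cr)
  rows <- list()
  for (i in seq_len(n_isp)) {
    home <- isp_prof$mean_ne[, i]
    other <- isp_prof$mean_ne[, -i, drop = FALSE]
    max_other <- if (ncol(other)) matrixStats::rowMaxs(other) else
      rep(0, length(home))
    min_fold <- ifelse(max_other > 0, home / max_other,
                       ifelse(home > min_ne, Inf, 0))
    pass <- which(min_fold > fold_thr & home > min_ne)
    if (!length(pass)) next
    genes <- rownames(isp_prof$mean_ne)[pass]
    verified <- rep(TRUE, length(genes))
    if (verify_per_cluster && n_isp > 1) {
      members <- names(cluster_isp)[cluster_isp == i]
      outside <- setdiff(colnames(prof$mean_ne), members)
      for (gi in seq_along(genes)) {
        g <- genes[gi]
        best_out <- max(prof$mean_ne[g, outside])
        ok <- if (best_out > 0)
          all(prof$mean_ne[g, members] / best_out > fold_thr)
        else all(prof$mean_ne[g, members] > min_ne)
        verified[gi] <- ok
      }
    }
    keep <- if (verify_per_cluster) verified else rep(TRUE, length(genes))
    if (!any(keep)) next
    rows[[length(rows) + 1]] <- data.frame(
      gene = genes[keep], isp = i, min_fold = min_fold[pass][keep],
      expr = home[pass][keep],
      is_tf = if (is.null(tfs)) FALSE else genes[keep] %in% tfs$genes,
      verified = verified[keep], stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), isp = integer(), min_fold = numeric(),
               expr = numeric(), is_tf = logical(), verified = logical())
  rownames(out) <- NULL
  out
}
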