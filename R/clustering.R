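#' Embed cells into 3 dimensions with Barnes-Hut t-SNE
#'
#' Runs Barnes-Hut t-SNE (via Rtsne) on the NE values of the supplied gene
#' set, producing a 3-dimensional embedding on which density clustering
#' operates.  Deterministic for a given seed.
#'
#' @param em an [rgc_ne] object.
#' @param genes character vector of gene identifiers to embed on
#'   (typically from [select_overdispersed()]).
#' @param seed integer seed.
#' @param perplexity t-SNE perplexity (default 30).
#' @param max_iter number of t-SNE iterations (default 1000).
#' @return An object of class `rgc_embedding`: list with `coords` (cells x
#'   3 matrix, rownames = barcodes), `seed`, and `params`.
#' @export
embed <- function(em, genes, seed = 1L, perplexity = 30, max_iter = 1000) {
  stopifnot(inherits(em, "rgc_ne"))
  genes <- intersect(genes, colnames(em$ne))
  if (!length(genes)) stop("none of the requested genes are present")
  n <- nrow(em$ne)
  min_cells <- 3 * perplexity + 2
  if (n < min_cells)
    stop("too few cells (", n, ") for perplexity ", perplexity,
         "; need >= ", min_cells)
  x <- as.matrix(em$ne[, genes, drop = FALSE])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fit <- Rtsne::Rtsne(x, dims = 3, perplexity = perplexity,
                      max_iter = max_iter, check_duplicates = FALSE,
                      pca = TRUE, verbose = FALSE, num_threads = 1)
  coords <- fit$Y
  rownames(coords) <- em$cell_meta$barcode
  colnames(coords) <- c("V1", "V2", "V3")
  structure(list(coords = coords, seed = as.integer(seed),
                 params = list(perplexity = perplexity,
                               max_iter = max_iter, dims = 3,
                               theta = 0.5, genes = length(genes))),
            class = "rgc_embedding")
}

# Epsilon-neighborhood DBSCAN with grid-binned region queries.
# minpts counts the point itself (the classical definition).  Returns
# integer labels with 0 for noise; clusters renumbered 1..K by decreasing
# size (ties by first-occurrence order).
dbscan_grid <- function(coords, eps, minpts) {
  n <- nrow(coords)
  d <- ncol(coords)
  # integer grid cells of side eps; neighbors of a point can only lie in
  # the 3^d adjacent grid cells
  keys <- floor(coords / eps)
  keystr <- apply(keys, 1, paste, collapse = ",")
  bins <- split(seq_len(n), keystr)
  offsets <- as.matrix(expand.grid(rep(list(-1:1), d)))
  tc <- t(coords)
  neigh_of <- function(i) {
    kk <- keys[i, ]
    cand <- integer(0)
    for (r in seq_len(nrow(offsets))) {
      key <- paste(kk + offsets[r, ], collapse = ",")
      b <- bins[[key]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    dd2 <- colSums((tc[, cand, drop = FALSE] - coords[i, ])^2)
    cand[dd2 <= eps^2]
  }
  labels <- rep(-1L, n)   # -1 unvisited, 0 noise
  k <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != -1L) next
    nb <- neigh_of(i)
    if (length(nb) < minpts) { labels[i] <- 0L; next }
    k <- k + 1L
    labels[i] <- k
    # claim the whole seed neighborhood, then expand from core members
    fresh <- nb[labels[nb] <= 0L & nb != i]
    labels[fresh] <- k
    queue <- fresh
    head <- 1L
    while (head <= length(queue)) {
      j <- queue[head]
      head <- head + 1L
      nb_j <- neigh_of(j)
      if (length(nb_j) >= minpts) {          # j is core: expand
        fresh <- nb_j[labels[nb_j] <= 0L]
        fresh <- fresh[labels[fresh] != k]   # not yet claimed
        labels[fresh] <- k
        queue <- c(queue, fresh)
      }
    }
  }
  relabel_by_size(labels)
}

# Renumber nonzero labels 1..K by decreasing cluster size (ties broken by
# first occurrence); label 0 is preserved.
relabel_by_size <- function(labels) {
  nz <- labels[labels > 0]
  if (!length(nz)) return(labels)
  sizes <- table(nz)
  first <- vapply(names(sizes), function(l) match(as.integer(l), labels),
                  integer(1))
  ord <- names(sizes)[order(-as.integer(sizes), first)]
  map <- stats::setNames(seq_along(ord), ord)
  out <- labels
  out[labels > 0] <- map[as.character(labels[labels > 0])]
  as.integer(out)
}

#' Density clustering of an embedding with DBSCAN
#'
#' Classical DBSCAN (eps-neighborhood, minpts including the point itself)
#' on the embedding coordinates.  Noise points are mapped to cluster 0 —
#' cells that do not fit uniquely to any one cluster — and clusters are
#' renumbered 1..K by decreasing size.
#'
#' @param emb an `rgc_embedding` (or a bare numeric matrix of
#'   coordinates).
#' @param eps neighborhood radius in embedding units.
#' @param minpts minimum neighborhood size (including the point) for a
#'   core point.
#' @return An object of class `rgc_clusters`: list with `labels` (integer
#'   per cell, named by barcode where available), `k` (number of
#'   clusters), `embedding`, and `round` (set by [two_round()]).
#' @export
density_cluster <- function(emb, eps = 5.0, minpts = 15) {
  stopifnot(eps > 0, minpts >= 1)
  coords <- if (inherits(emb, "rgc_embedding")) emb$coords else as.matrix(emb)
  labels <- dbscan_grid(coords, eps, minpts)
  names(labels) <- rownames(coords)
  structure(list(labels = labels, k = max(labels),
                 embedding = if (inherits(emb, "rgc_embedding")) emb else NULL,
                 round = NA_integer_),
            class = "rgc_clusters")
}

#' @exportS3Method base::print
print.rgc_clusters <- function(x, ...) {
  cat("rgc_clusters:", length(x$labels), "cells in", x$k,
      "clusters;", sum(x$labels == 0), "unassigned (cluster 0)\n")
  invisible(x)
}

#' Flag clusters dominated by contaminant (non-RGC) markers
#'
#' A cluster is flagged when its mean NE over the contaminant marker panel
#' exceeds its mean NE over the pan-RGC marker panel — the signature of
#' amacrine or other non-RGC cells that survive immunopanning.
#'
#' @param cr an `rgc_clusters` result.
#' @param em the [rgc_ne] matrix the clustering was computed on.
#' @param contaminant,rgc [gene_panel]s of non-RGC and pan-RGC markers.
#' @return integer vector of flagged cluster ids (possibly empty).
#' @export
flag_contaminants <- function(cr, em, contaminant, rgc) {
  stopifnot(inherits(cr, "rgc_clusters"), inherits(em, "rgc_ne"))
  cg <- resolve_panel(contaminant, colnames(em$ne))
  rg <- resolve_panel(rgc, colnames(em$ne))
  flagged <- integer(0)
  for (k in seq_len(cr$k)) {
    cells <- which(cr$labels == k)
    m_cont <- sum(em$ne[cells, cg, drop = FALSE]@x) /
      (length(cells) * length(cg))
    m_rgc <- sum(em$ne[cells, rg, drop = FALSE]@x) /
      (length(cells) * length(rg))
    if (m_cont > m_rgc) flagged <- c(flagged, k)
  }
  flagged
}

#' Two-round embedding and density clustering with contaminant removal
#'
#' Round 1: select over-dispersed genes, embed, cluster, and flag clusters
#' whose contaminant-panel expression dominates the pan-RGC panel.  Cells
#' of flagged clusters are excluded; over-dispersed genes are re-selected
#' on the remaining cells, which are re-embedded and re-clustered.
#'
#' @param em an [rgc_ne] for all QC-passing cells.
#' @param panels named list with `contaminant`, `rgc` and optionally `sex`
#'   [gene_panel]s; sex genes are excluded from gene selection.
#' @param seed integer seed (round 2 uses `seed + 1`).
#' @param n_genes number of over-dispersed genes per round.
#' @param eps,minpts DBSCAN parameters.
#' @param perplexity,max_iter t-SNE parameters.
#' @return list with `clusters` (final `rgc_clusters`, round 2), `round1`
#'   (round-1 `rgc_clusters`), `excluded_cells` (barcodes removed as
#'   contaminants), `excluded_fraction` (share of round-1 cells removed),
#'   and `em` (the NE matrix restricted to retained cells).
#' @export
two_round <- function(em, panels, seed = 1L, n_genes = 1000,
                      eps = 5.0, minpts = 15, perplexity = 30,
                      max_iter = 1000) {
  stopifnot(inherits(em, "rgc_ne"))
  sex <- panels$sex
  g1 <- select_overdispersed(em, n = min(n_genes, ncol(em$ne)),
                             exclude = sex)
  emb1 <- embed(em, g1, seed = seed, perplexity = perplexity,
                max_iter = max_iter)
  cr1 <- density_cluster(emb1, eps = eps, minpts = minpts)
  cr1$round <- 1L
  flagged <- flag_contaminants(cr1, em, panels$contaminant, panels$rgc)
  excluded <- names(cr1$labels)[cr1$labels %in% flagged]
  if (!length(flagged)) {
    cr1b <- cr1
    cr1b$round <- 2L
    return(list(clusters = cr1b, round1 = cr1,
                excluded_cells = character(0), excluded_fraction = 0,
                em = em))
  }
  keep <- !(em$cell_meta$barcode %in% excluded)
  em2 <- rgc_ne(em$ne[keep, , drop = FALSE],
                em$cell_meta[keep, , drop = FALSE],
                M = em$M, provenance = paste0(em$provenance,
                                              " | round-2 subset"))
  g2 <- select_overdispersed(em2, n = min(n_genes, ncol(em2$ne)),
                             exclude = sex)
  emb2 <- embed(em2, g2, seed = seed + 1L, perplexity = perplexity,
                max_iter = max_iter)
  cr2 <- density_cluster(emb2, eps = eps, minpts = minpts)
  cr2$round <- 2L
  list(clusters = cr2, round1 = cr1, excluded_cells = excluded,
       excluded_fraction = length(excluded) / length(cr1$labels),
       em = em2)
}
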