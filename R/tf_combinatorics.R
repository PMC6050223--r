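#' Binarize TF enrichment across clusters
#'
#' A TF is scored 1 in a cluster when its mean NE there exceeds `min_ne`
#' AND exceeds `fold` times its unweighted mean NE across all clusters.
#' Rows that end up all-zero or all-one carry no combinatorial
#' information and are dropped (recorded in the `dropped` attribute).
#'
#' @param prof a [cluster_profile()].
#' @param tfs [gene_panel] of transcription factors.
#' @param min_ne minimum NE for enrichment (default 0.5).
#' @param fold fold over the TF's cross-cluster mean (default 2).
#' @return An object of class `tf_binary`: list with `indicator` (TFs x
#'   clusters 0/1 matrix), `min_ne`, `fold`; attribute `dropped` lists the
#'   removed TFs.
#' @export
binarize <- function(prof, tfs, min_ne = 0.5, fold = 2.0) {
  stopifnot(inherits(prof, "cluster_profile"), min_ne > 0, fold > 0)
  genes <- intersect(tfs$genes, rownames(prof$mean_ne))
  if (!length(genes)) stop("no TF panel genes present in the profile")
  m <- prof$mean_ne[genes, , drop = FALSE]
  cross_mean <- rowMeans(m)
  ind <- (m > min_ne) & (m > fold * cross_mean)
  storage.mode(ind) <- "integer"
  rs <- rowSums(ind)
  keep <- rs >= 1 & rs < ncol(ind)
  dropped <- rownames(ind)[!keep]
  structure(list(indicator = ind[keep, , drop = FALSE],
                 min_ne = min_ne, fold = fold),
            dropped = dropped, class = "tf_binary")
}

#' Enumerate TF combinations uniquely enriched in single clusters
#'
#' For every subset of TFs up to size `max_k`, the combination's
#' enrichment pattern is the element-wise AND of its member rows.
#' Combinations whose pattern has exactly one 1 are unique signatures of
#' the corresponding cluster.  Minimality is enforced: a combination is
#' dropped when a proper subset of it is itself unique (the combination,
#' not any smaller part of it, must carry the uniqueness).  All-zero
#' patterns are discarded, and since AND patterns shrink monotonically,
#' supersets of all-zero or unique combinations are pruned.
#'
#' Output is ordered by increasing combination size, then lexicographic
#' TF order.
#'
#' @param bm a [binarize()] result (or a bare 0/1 TFs x clusters matrix).
#' @param max_k maximum combination size (1-5).
#' @param max_tfs guard against combinatorial explosion; an error is
#'   raised when the panel exceeds this size (raise deliberately for
#'   large panels).
#' @return data.frame with `cluster`, `tfs` (members joined by `+`), `k`.
#' @export
unique_combos <- function(bm, max_k = 5, max_tfs = 200) {
  ind <- if (inherits(bm, "tf_binary")) bm$indicator else as.matrix(bm)
  stopifnot(max_k >= 1, max_k <= 5)
  Tn <- nrow(ind)
  if (Tn > max_tfs)
    stop(Tn, " TFs exceeds max_tfs = ", max_tfs,
         "; raise max_tfs explicitly to enumerate")
  if (Tn == 0)
    return(data.frame(cluster = character(), tfs = character(),
                      k = integer()))
  tf_names <- rownames(ind)
  clusters <- colnames(ind)
  if (is.null(clusters)) clusters <- as.character(seq_len(ncol(ind)))
  storage.mode(ind) <- "logical"
  results <- list()
  unique_sets <- list()            # emitted minimal unique index sets
  # frontier entries: list(idx = member indices, pat = logical pattern)
  frontier <- lapply(seq_len(Tn), function(i)
    list(idx = i, pat = ind[i, ]))
  for (k in seq_len(max_k)) {
    next_frontier <- list()
    for (e in frontier) {
      s <- sum(e$pat)
      if (s == 0) next
      if (s == 1) {
        # minimality: a combo containing an already-unique subset (it can
        # arrive via a different branch) is not a signature of its own
        minimal <- !any(vapply(unique_sets, function(u)
          all(u %in% e$idx), logical(1)))
        if (minimal) {
          results[[length(results) + 1]] <-
            list(idx = e$idx, cluster = clusters[which(e$pat)], k = k)
          unique_sets[[length(unique_sets) + 1]] <- e$idx
        }
        next                       # supersets are never minimal
      }
      if (k < max_k) {
        last <- e$idx[length(e$idx)]
        if (last < Tn)
          for (j in (last + 1):Tn) {
            pat <- e$pat & ind[j, ]
            if (any(pat))
              next_frontier[[length(next_frontier) + 1]] <-
                list(idx = c(e$idx, j), pat = pat)
          }
      }
    }
    frontier <- next_frontier
  }
  if (!length(results))
    return(data.frame(cluster = character(), tfs = character(),
                      k = integer()))
  data.frame(
    cluster = vapply(results, `[[`, character(1), "cluster"),
    tfs = vapply(results, function(r)
      paste(tf_names[r$idx], collapse = "+"), character(1)),
    k = vapply(results, `[[`, integer(1), "k"),
    stringsAsFactors = FALSE)
}

#' Two-threshold cross-referenced unique TF combinations
#'
#' Runs [binarize()] + [unique_combos()] at a strict fold and again at a
#' relaxed fold, returning only combinations found in both runs (same
#' cluster, same TF set).  The relaxed run admits more enriched TFs, so a
#' combination that gains a second cluster there — meaning its uniqueness
#' was marginal — is eliminated, widening the enrichment gap between a
#' signature and its next-best cluster match.
#'
#' @param prof a [cluster_profile()].
#' @param tfs [gene_panel] of TFs.
#' @param min_ne minimum NE for enrichment.
#' @param fold_strict,fold_relaxed the two fold thresholds
#'   (`fold_relaxed < fold_strict`).
#' @param max_k maximum combination size.
#' @return data.frame as [unique_combos()], the intersection of the two
#'   runs.
#' @export
cross_reference <- function(prof, tfs, min_ne = 0.5, fold_strict = 2.0,
                            fold_relaxed = 1.5, max_k = 5) {
  stopifnot(fold_relaxed < fold_strict)
  strict <- unique_combos(binarize(prof, tfs, min_ne, fold_strict), max_k)
  relaxed <- unique_combos(binarize(prof, tfs, min_ne, fold_relaxed), max_k)
  key <- function(d) paste(d$cluster, d$tfs)
  out <- strict[key(strict) %in% key(relaxed), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Interaction p-value of a mixed-design ANOVA: TF identity is the
# within-subject factor, cluster the between-subject factor, sphericity
# assumed (univariate aov with an Error(cell/tf) stratum).
anova_interaction_p <- function(em, labels, tf_genes, k1, k2) {
  cells1 <- which(labels == k1)
  cells2 <- which(labels == k2)
  if (length(cells1) < 3 || length(cells2) < 3) return(NA_real_)
  cells <- c(cells1, cells2)
  m <- as.matrix(em$ne[cells, tf_genes, drop = FALSE])
  d <- data.frame(
    ne = as.vector(m),
    tf = factor(rep(tf_genes, each = length(cells))),
    cluster = factor(rep(c(rep("a", length(cells1)),
                           rep("b", length(cells2))), length(tf_genes))),
    cell = factor(rep(seq_along(cells), length(tf_genes))))
  fit <- stats::aov(ne ~ cluster * tf + Error(cell / tf), data = d)
  s <- summary(fit)
  within <- s[["Error: cell:tf"]][[1]]
  p <- within[trimws(rownames(within)) == "cluster:tf", "Pr(>F)"]
  if (!length(p)) NA_real_ else p
}

#' Interaction ANOVA support for a TF combination
#'
#' For a combination of two or more TFs assigned to a focal cluster, runs
#' a mixed-design repeated-measures ANOVA (TF identity as the
#' within-subject factor, cluster as the between-subject factor,
#' sphericity assumed) of the focal cluster against every other cluster,
#' and averages the TF x cluster interaction p-values (`p_focal`).  For
#' calibration, the same analysis over all pairs of non-focal clusters
#' gives `p_between_others`; a genuine signature shows a strong
#' interaction only when the focal cluster is involved.
#'
#' @param em an [rgc_ne].
#' @param cr an `rgc_clusters`.
#' @param combo one row of a [unique_combos()] result, or a
#'   `list(cluster =, tfs =)` with `tfs` a character vector or
#'   `+`-joined string.
#' @param min_cells clusters with fewer cells are skipped in the
#'   averages.
#' @return list with `p_focal`, `p_between_others`, `applicable`
#'   (FALSE for single-TF combinations, whose enrichment is a plain
#'   differential-expression question, not an interaction).
#' @export
interaction_anova <- function(em, cr, combo, min_cells = 3) {
  tfs <- combo$tfs
  if (length(tfs) == 1 && grepl("+", tfs, fixed = TRUE))
    tfs <- strsplit(tfs, "+", fixed = TRUE)[[1]]
  if (length(tfs) < 2)
    return(list(p_focal = NA_real_, p_between_others = NA_real_,
                applicable = FALSE))
  tfs <- intersect(tfs, colnames(em$ne))
  stopifnot(length(tfs) >= 2)
  labels <- align_labels(em, cr)
  focal <- as.integer(combo$cluster)
  others <- setdiff(seq_len(cr$k), focal)
  others <- others[vapply(others, function(k)
    sum(labels == k) >= min_cells, logical(1))]
  p_f <- vapply(others, function(k)
    anova_interaction_p(em, labels, tfs, focal, k), numeric(1))
  pairs <- utils::combn(others, 2)
  p_o <- apply(pairs, 2, function(pr)
    anova_interaction_p(em, labels, tfs, pr[1], pr[2]))
  list(p_focal = mean(p_f, na.rm = TRUE),
       p_between_others = mean(p_o, na.rm = TRUE),
       applicable = TRUE)
}
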