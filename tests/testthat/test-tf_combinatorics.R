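test_that("binarization follows the threshold arithmetic and drops
           uninformative rows", {
  m <- rbind(TFa = c(4, 0.1, 0.1),     # cross mean 1.4; only col 1 passes
             TFb = c(1, 1, 1),         # no zero possible -> dropped
             TFc = c(0.6, 0.6, 0.1))   # 0.6 < 2 x 0.433 -> all zero
  prof <- profile_of(m)
  tfs <- gene_panel("tf", rownames(m), "tf")
  bm <- binarize(prof, tfs)
  expect_equal(unname(bm$indicator["TFa", ]), c(1L, 0L, 0L))
  expect_false("TFb" %in% rownames(bm$indicator))
  expect_false("TFc" %in% rownames(bm$indicator))
  expect_setequal(attr(bm, "dropped"), c("TFb", "TFc"))
  expect_error(binarize(prof, gene_panel("tf", "absent", "tf")),
               "no TF panel genes")
})

test_that("the hand-enumerable three-TF pattern yields the three pair
           signatures and singletons stay minimal", {
  ind <- rbind(TF1 = c(1, 1, 0), TF2 = c(0, 1, 1), TF3 = c(1, 0, 1))
  colnames(ind) <- as.character(1:3)
  out <- unique_combos(ind, max_k = 3)
  expect_identical(out$tfs, c("TF1+TF2", "TF1+TF3", "TF2+TF3"))
  expect_identical(out$cluster, c("2", "1", "3"))
  expect_true(all(out$k == 2))

  ind2 <- rbind(S = c(0, 1, 0), A = c(1, 1, 0), B = c(0, 1, 1))
  colnames(ind2) <- as.character(1:3)
  out2 <- unique_combos(ind2, max_k = 3)
  expect_true("S" %in% out2$tfs)
  # no emitted combo contains the singleton S
  expect_false(any(grepl("S\\+|\\+S", out2$tfs)))
})

test_that("enumeration equals the exhaustive oracle and is invariant to
           row and column permutation", {
  set.seed(11)
  for (rep in 1:30) {
    ind <- random_binary_matrix(12, 6)
    out <- unique_combos(ind, max_k = 3)
    orc <- oracle_unique_combos(ind, max_k = 3)
    norm <- function(d) {
      d <- d[order(d$k, d$tfs), ]
      rownames(d) <- NULL
      d
    }
    expect_identical(norm(out), norm(orc))
    # every emitted combo re-evaluates to an AND-sum of exactly 1
    for (i in seq_len(nrow(out))) {
      members <- strsplit(out$tfs[i], "+", fixed = TRUE)[[1]]
      pat <- apply(ind[members, , drop = FALSE], 2, prod)
      expect_equal(sum(pat), 1)
      expect_identical(colnames(ind)[pat == 1], out$cluster[i])
    }
  }
  ind <- random_binary_matrix(10, 5)
  perm_r <- sample(nrow(ind)); perm_c <- sample(ncol(ind))
  a <- unique_combos(ind, max_k = 3)
  b <- unique_combos(ind[perm_r, perm_c], max_k = 3)
  key <- function(d) sort(paste(d$cluster,
                                vapply(strsplit(d$tfs, "+", fixed = TRUE),
                                       function(x) paste(sort(x),
                                                         collapse = "+"),
                                       character(1))))
  expect_identical(key(a), key(b))
})

test_that("two-threshold cross-referencing removes marginal signatures", {
  # TFx alone is unique at the strict fold, but at the relaxed fold its
  # pattern gains a second cluster -> eliminated
  m <- rbind(TFx = c(3, 1.5, 0.2, 0.2, 0.2, 0.2),
             TFy = c(3, 0.2, 3, 0.2, 0.2, 0.2),
             TFz = c(3, 3, 0.2, 0.2, 0.2, 0.2))
  prof <- profile_of(m)
  tfs <- gene_panel("tf", rownames(m), "tf")
  strict <- unique_combos(binarize(prof, tfs, fold = 2.0), max_k = 2)
  relaxed <- unique_combos(binarize(prof, tfs, fold = 1.5), max_k = 2)
  xr <- cross_reference(prof, tfs, max_k = 2)
  expect_true("TFx" %in% strict$tfs)
  expect_false("TFx" %in% relaxed$tfs)
  expect_false("TFx" %in% xr$tfs)
  expect_true("TFy+TFz" %in% xr$tfs)       # robust at both thresholds
  key <- paste(xr$cluster, xr$tfs)
  expect_true(all(key %in% paste(strict$cluster, strict$tfs)))
})

test_that("planted combinations are recovered with full recall", {
  fx <- desk_fixture()
  xr <- cross_reference(fx$prof, fx$truth$panels$tf, max_k = 3)
  key <- paste(xr$cluster, xr$tfs)
  for (pc in fx$truth$combo_map)
    expect_true(paste(pc$cluster, paste(pc$tfs, collapse = "+")) %in% key)
})

test_that("interaction ANOVA: null is flat, planted crossing is
           significant, singletons are not applicable", {
  set.seed(21)
  base <- cbind(TFp = rnorm(12, 2, 0.3), TFq = rnorm(12, 0.7, 0.3))
  ne <- abs(rbind(base, base))             # cluster 2 copies cluster 1
  em <- ne_of(ne)
  cr <- truth_clusters(stats::setNames(rep(1:2, each = 12),
                                       em$cell_meta$barcode))
  p_null <- rgcsubtypes:::anova_interaction_p(em, cr$labels,
                                              c("TFp", "TFq"), 1, 2)
  expect_equal(p_null, 1)                  # zero interaction SS exactly

  cross <- abs(rbind(base, base[, 2:1]))   # reversed levels: crossing
  colnames(cross) <- c("TFp", "TFq")
  em2 <- ne_of(cross)
  p_cross <- rgcsubtypes:::anova_interaction_p(em2, cr$labels,
                                               c("TFp", "TFq"), 1, 2)
  expect_lt(p_cross, 0.05)

  out <- interaction_anova(em2, truth_clusters(cr$labels),
                           list(cluster = 1, tfs = "TFp"))
  expect_false(out$applicable)
})

test_that("planted combos interact with the focal cluster more than
           non-focal clusters do among themselves", {
  # at atlas scale (40 clusters) a 2-way combo's members tile nearly all
  # non-focal clusters, so every focal comparison shows a TF x cluster
  # interaction while most non-focal pairs are parallel
  cfg <- sim_config(n_cells = 4000, n_genes = 150, n_clusters = 40,
                    n_isps = 10, n_superclusters = 4,
                    markers_per_cluster = 0, isp_markers_per_isp = 0,
                    super_markers_per_supercluster = 0, tf_panel_size = 8,
                    planted_combos = list(
                      list(cluster = 5L, tfs = c("TF01", "TF02"))),
                    contaminant_fraction = 0, low_quality_fraction = 0,
                    seed = 29)
  g <- generate(cfg)
  em <- normalize_ne(g$counts)
  cr <- truth_clusters(g$truth$cell_cluster[em$cell_meta$barcode])
  out <- interaction_anova(em, cr, list(cluster = 5, tfs = "TF01+TF02"))
  expect_true(out$applicable)
  expect_lt(out$p_focal, 0.1)
  expect_lt(out$p_focal, out$p_between_others)
})
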