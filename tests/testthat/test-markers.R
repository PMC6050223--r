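test_that("profiles compute per-cluster means and medians, excluding
           cluster 0", {
  ne <- matrix(0, 5, 2, dimnames = list(NULL, c("gA", "gB")))
  ne[, 1] <- c(1, 2, 3, 9, 9)   # cells 4-5 are cluster 0 / other
  ne[, 2] <- c(0, 0, 1, 5, 5)
  em <- ne_of(ne)
  cr <- truth_clusters(stats::setNames(c(1L, 1L, 1L, 0L, 2L),
                                       em$cell_meta$barcode))
  prof <- cluster_profile(em, cr)
  expect_equal(prof$mean_ne["gA", "1"], 2)
  expect_equal(prof$median_ne["gA", "1"], 2)
  expect_equal(prof$median_ne["gB", "1"], 0)   # majority zeros
  expect_equal(unname(prof$n_cells), c(3L, 1L))
  expect_equal(prof$mean_ne["gA", "2"], 9)     # cluster-0 cell not included
})

test_that("unique markers honor fold and expression boundaries", {
  # gene at fold exactly 1.8 vs the other cluster is rejected; > 1.8 passes
  ne <- cbind(hit = c(rep(1.9, 6), rep(1, 6)),
              edge = c(rep(1.8, 6), rep(1, 6)),
              dim = c(rep(0.04, 6), rep(0.001, 6)))
  em <- ne_of(ne)
  cr <- truth_clusters(stats::setNames(rep(1:2, each = 6),
                                       em$cell_meta$barcode))
  mk <- unique_markers(em, cr, top_n_tested = 0)
  expect_identical(mk$gene, "hit")
  expect_identical(mk$cluster, 1L)
  expect_equal(mk$min_fold, 1.9)
  # "dim" passes fold 40x but fails min_ne 0.05
  expect_false("dim" %in% mk$gene)
  expect_error(unique_markers(em, truth_clusters(
    stats::setNames(rep(1L, 12), em$cell_meta$barcode))), "K < 2")
})

test_that("a gene is a unique marker of at most one cluster, matching the
           argmax oracle at fold 1", {
  set.seed(5)
  ne <- matrix(rexp(40 * 30, 1), 40, 30)
  em <- ne_of(ne)
  cr <- truth_clusters(stats::setNames(sample(1:4, 40, replace = TRUE),
                                       em$cell_meta$barcode))
  mk <- unique_markers(em, cr, fold_thr = 1.0, min_ne = 1e-12,
                       top_n_tested = 0)
  expect_false(anyDuplicated(mk$gene) > 0)
  # argmax oracle: home mean strictly above every other cluster mean
  prof <- cluster_profile(em, cr)
  oracle <- unlist(lapply(seq_len(ncol(ne)), function(j) {
    mus <- prof$mean_ne[j, ]
    top <- which(mus == max(mus))
    if (length(top) == 1 && max(mus) > max(mus[-top]) &&
        max(mus) > 1e-12) rownames(prof$mean_ne)[j] else NULL
  }))
  expect_setequal(mk$gene, oracle)
})

test_that("marker tiers follow the dual-test thresholds", {
  tier <- rgcsubtypes:::marker_tier
  expect_identical(tier(c(0.01, 0.01, 0.2, 0.01, 0.06),
                        c(0.01, 0.08, 0.01, 0.3, 0.2)),
                   c("strict", "relaxed", "weak", "weak", "ns"))
})

test_that("planted markers are recovered from per-cell data with the
           significance machinery engaged", {
  fx <- desk_fixture()
  mk <- unique_markers(fx$em, fx$cr, fx$prof, top_n_tested = 5)
  truth_pairs <- unlist(lapply(names(fx$truth$marker_map), function(k)
    paste(fx$truth$marker_map[[k]], k)))
  found_pairs <- paste(mk$gene, mk$cluster)
  recall <- mean(truth_pairs %in% found_pairs)
  precision <- mean(found_pairs %in% truth_pairs)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
  # tested markers on abundant clusters come out significant
  tested <- mk[!is.na(mk$tier) & !mk$small_cluster, ]
  expect_gt(mean(tested$tier == "strict"), 0.9)
})

test_that("homogeneity census matches a brute-force recount and is
           monotone in the threshold", {
  set.seed(9)
  m <- matrix(rexp(200 * 6), 200, 6,
              dimnames = list(sprintf("g%03d", 1:200), 1:6))
  m[1:40, ] <- rep(runif(40, 0.5, 2), 6)          # exactly homogeneous
  prof <- profile_of(m)
  tfs <- gene_panel("tf", sprintf("g%03d", 1:50), "tf")
  thr <- c(0, 0.3, 0.6, 1.2)
  cen <- homogeneity_census(prof, tfs, thresholds = thr, fold_band = 1.5)
  # independent nested-loop recount
  for (i in seq_len(nrow(cen))) {
    n <- 0
    for (g in rownames(m)) {
      v <- m[g, ]
      if (max(v) <= cen$threshold[i]) next
      hom <- if (min(v) > 0) max(v) / min(v) <= 1.5 else max(v) == 0
      cat_ok <- (cen$category[i] == "homogeneous") == hom
      tf_ok <- (cen$class[i] == "tf") == (g %in% tfs$genes)
      if (cat_ok && tf_ok) n <- n + 1
    }
    expect_equal(cen$count[i], n)
  }
  for (cat in unique(cen$category)) for (cls in unique(cen$class)) {
    v <- cen$count[cen$category == cat & cen$class == cls]
    expect_true(all(diff(v) <= 0))
  }
  # a gene with means {1.0, 1.6} is non-homogeneous at band 1.5
  p2 <- profile_of(matrix(c(1.0, 1.6), 1, 2,
                          dimnames = list("gx", NULL)))
  c2 <- homogeneity_census(p2, NULL, thresholds = 0, fold_band = 1.5)
  expect_equal(c2$count[c2$category == "non_homogeneous"], 1)
})

test_that("cluster correlations behave on identical, disjoint, and
           hierarchical profiles", {
  m <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  cc <- cluster_correlations(profile_of(m))
  expect_equal(unname(cc$r["a", "b"]), 1)
  ind <- cbind(a = c(1, 0, 0, 0), b = c(0, 1, 0, 0))
  expect_lt(cluster_correlations(profile_of(ind))$r["a", "b"], 0)
  # zero variance column -> NA
  z <- cbind(a = c(1, 2, 3), b = c(2, 2, 2))
  expect_true(is.na(cluster_correlations(profile_of(z))$r["a", "b"]))

  # within-ISP similarity exceeds across-ISP similarity
  fx <- desk_fixture()
  cc <- cluster_correlations(fx$prof)
  isp <- fx$truth$cluster_isp
  same <- outer(isp, isp, "==") & upper.tri(cc$r)
  diff <- outer(isp, isp, "!=") & upper.tri(cc$r)
  expect_gt(mean(cc$r[same]), mean(cc$r[diff]))
})
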