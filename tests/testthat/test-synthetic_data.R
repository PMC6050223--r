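test_that("generation is seed-deterministic and degenerate configs work", {
  cfg <- small_config(seed = 5)
  g1 <- generate(cfg)
  g2 <- generate(cfg)
  expect_identical(as.matrix(g1$counts$counts), as.matrix(g2$counts$counts))
  expect_identical(g1$truth$cell_eye, g2$truth$cell_eye)

  one <- sim_config(n_cells = 300, n_genes = 300, n_clusters = 1,
                    n_isps = 1, n_superclusters = 1,
                    markers_per_cluster = 0, planted_combos = list(),
                    contaminant_fraction = 0, seed = 2)
  g <- generate(one)
  expect_true(all(g$truth$cell_cluster == 1))
  expect_true(all(lengths(g$truth$marker_map) == 0))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_clusters = 2, n_isps = 4), "n_clusters >= n_isps")
  expect_error(sim_config(cluster_proportions = rep(0.2, 8)), "sum to 1")
  expect_error(sim_config(planted_combos =
    list(list(cluster = 1L, tfs = c("NOPE", "TF01")))), "not in the TF panel")
  # a 5-way combination cannot keep all members binarizable with 8 clusters
  expect_error(sim_config(planted_combos =
    list(list(cluster = 1L, tfs = sprintf("TF%02d", 1:5)))), "infeasible")
})

test_that("planted cluster proportions and eye labels are recovered", {
  cfg <- sim_config(seed = 21, n_cells = 2500,
                    right_eye_prob_per_cluster = c(2 / 3, rep(0.5, 7)))
  g <- generate(cfg)
  cl <- g$truth$cell_cluster
  cl <- cl[cl > 0]
  emp <- as.numeric(table(factor(cl, levels = 1:8))) / length(cl)
  # binomial sampling error: 4 sd of a proportion at n ~ 2400
  tol <- 4 * sqrt(cfg$cluster_proportions * (1 - cfg$cluster_proportions) /
                    length(cl))
  expect_true(all(abs(emp - cfg$cluster_proportions) < tol))
  eye1 <- g$truth$cell_eye[names(cl)[cl == 1]]
  expect_gt(mean(eye1 == "right"), 0.55)
})

test_that("planted markers reach the required empirical NE fold", {
  # recompute the fold directly from a generated matrix
  cfg <- sim_config(seed = 9, n_cells = 5000, marker_fold = 3)
  g <- generate(cfg)
  f <- filter_low_coverage(g$counts, 600)
  em <- normalize_ne(f$counts)
  lab <- g$truth$cell_cluster[em$cell_meta$barcode]
  keep <- lab > 0
  em2 <- rgc_ne(em$ne[keep, , drop = FALSE],
                em$cell_meta[keep, , drop = FALSE], M = em$M)
  prof <- cluster_profile(em2, truth_clusters(lab[keep]))
  folds <- unlist(lapply(seq_len(8), function(k) {
    mk <- g$truth$marker_map[[k]]
    prof$mean_ne[mk, k] /
      matrixStats::rowMaxs(prof$mean_ne[mk, -k, drop = FALSE])
  }))
  expect_true(all(folds >= 2))
  # markers clear the minimum-NE threshold
  home_ne <- unlist(lapply(seq_len(8), function(k)
    prof$mean_ne[g$truth$marker_map[[k]], k]))
  expect_true(all(home_ne > 0.05))
})

test_that("the genes-per-cell rule removes planted low-quality cells", {
  g <- generate(sim_config(seed = 13))
  f <- filter_low_coverage(g$counts, 600)
  lq <- g$truth$low_quality_cells
  expect_gte(mean(lq %in% f$removed_cells), 0.95)
  # removal rate tracks the planted rate
  expect_lt(abs(length(f$removed_cells) / nrow(g$counts$counts) -
                  g$truth$config$low_quality_fraction), 0.03)
})

test_that("fixtures round-trip through the readers and hash stably", {
  cfg <- sim_config(n_cells = 100, n_genes = 160, n_clusters = 2,
                    n_isps = 2, n_superclusters = 1,
                    markers_per_cluster = 5, isp_markers_per_isp = 0,
                    super_markers_per_supercluster = 0, tf_panel_size = 4,
                    planted_combos = list(), seed = 4)
  g <- generate(cfg)
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  write_fixture(g$counts, g$truth, d1)
  write_fixture(generate(cfg)$counts, g$truth, d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "matrix.mtx"))),
                   unname(tools::md5sum(file.path(d2, "matrix.mtx"))))
  cm <- read_counts(file.path(d1, "matrix.mtx"),
                    file.path(d1, "genes.tsv"),
                    file.path(d1, "barcodes.tsv"))
  expect_identical(as.matrix(cm$counts), as.matrix(g$counts$counts))
  expect_identical(cm$cell_meta$eye, g$counts$cell_meta$eye)
  tr <- read_truth(d1)
  expect_identical(sort(unlist(tr$marker_map)),
                   sort(unlist(g$truth$marker_map)))
  # marker sets disjoint across clusters
  expect_false(anyDuplicated(unlist(g$truth$marker_map)) > 0)

  # empty matrix: header-only files are still valid
  d3 <- file.path(tempdir(), "fx3")
  empty <- rgc_counts(Matrix::Matrix(0, 3, 2, sparse = TRUE),
                      c("a", "b", "c"), "left", c("g1", "g2"))
  write_fixture(empty, NULL, d3)
  cm3 <- read_counts(file.path(d3, "matrix.mtx"),
                     file.path(d3, "genes.tsv"),
                     file.path(d3, "barcodes.tsv"))
  expect_equal(sum(cm3$counts), 0)
  expect_equal(dim(cm3$counts), c(3L, 2L))
})

test_that("label nesting in the truth is consistent", {
  g <- generate(small_config(seed = 8))
  tr <- g$truth
  for (k in seq_along(tr$cluster_isp)) {
    cells <- names(tr$cell_cluster)[tr$cell_cluster == k]
    expect_true(all(tr$cell_isp[cells] == tr$cluster_isp[k]))
    expect_true(all(tr$cell_supercluster[cells] ==
                      tr$isp_supercluster[tr$cluster_isp[k]]))
  }
})
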