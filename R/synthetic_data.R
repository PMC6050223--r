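#' Configuration for the synthetic RGC count-matrix generator
#'
#' Describes the generative conditions for a synthetic droplet scRNA-seq
#' experiment with hierarchical subtype structure: clusters (terminal
#' subtypes) nested in intermediate subpopulations (ISPs) nested in
#' superclusters, per-cluster unique marker genes, transcription factors
#' enriched only as combinations, per-cluster left/right-eye imbalance, a
#' low-coverage cell sub-peak, and a small contaminant (non-RGC) cell
#' fraction.
#'
#' Defaults are desk-scale: 3000 cells x 2000 genes x 8 clusters in 4 ISPs
#' and 2 superclusters, with strong cluster separation.  [sim_config_full()]
#' mirrors the scale of a full study (6225 cells, 40 clusters, 10 ISPs,
#' 4 superclusters).
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param n_superclusters,n_isps,n_clusters nested hierarchy sizes
#'   (`n_clusters >= n_isps >= n_superclusters >= 1`).
#' @param cluster_proportions probability vector over clusters (sums to 1,
#'   all positive).  Default: linearly decreasing, unequal.
#' @param right_eye_prob_per_cluster per-cluster probability that a cell
#'   comes from the right eye (default 0.5 everywhere: no laterality).
#' @param markers_per_cluster number of unique marker genes planted per
#'   cluster.
#' @param marker_fold planted marker enrichment (>= 1) in mean-NE ratio
#'   units — the unit of the downstream enrichment rule; the home-cluster
#'   count mean is back-solved to give this expected mean-NE fold.
#' @param isp_markers_per_isp,super_markers_per_supercluster number of
#'   genes planted as enriched in every cluster of an ISP (respectively a
#'   supercluster), at a stronger NE fold than terminal-cluster markers.
#'   These mirror subpopulation-level markers and make the planted
#'   hierarchy recoverable from profile distances; only groups with at
#'   least two member clusters receive them.
#' @param tf_panel_size number of transcription-factor genes in the panel.
#' @param planted_combos list of `list(cluster =, tfs =)` entries; each TF
#'   tuple (size 1-5) is planted so the combination's joint enrichment is
#'   unique to `cluster` while no proper sub-combination is.  `NULL` plants
#'   a default set (2-way, 2-way, 3-way, 1-way in the first four clusters).
#' @param nb_dispersion negative-binomial dispersion (1/size) of UMI
#'   counts.
#' @param size_factor_lognorm_sigma sdlog of the per-cell log-normal size
#'   factors.
#' @param low_quality_fraction,low_quality_scale fraction of cells whose
#'   size factor is multiplied by `low_quality_scale` (in (0,1)), producing
#'   the low-coverage sub-peak removed by the genes-per-cell filter.
#' @param contaminant_fraction fraction of cells drawn from a separate
#'   non-RGC expression profile enriched for the contaminant panel.
#' @param seed integer seed; the same config generates bit-identical data.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cells = 3000, n_genes = 2000,
                       n_superclusters = 2, n_isps = 4, n_clusters = 8,
                       cluster_proportions = NULL,
                       right_eye_prob_per_cluster = NULL,
                       markers_per_cluster = 20,
                       marker_fold = 2.5,
                       isp_markers_per_isp = 10,
                       super_markers_per_supercluster = 10,
                       tf_panel_size = 24,
                       planted_combos = NULL,
                       nb_dispersion = 0.15,
                       size_factor_lognorm_sigma = 0.3,
                       low_quality_fraction = 0.1,
                       low_quality_scale = 0.2,
                       contaminant_fraction = 0.04,
                       seed = 1L) {
  if (!(n_clusters >= n_isps && n_isps >= n_superclusters &&
        n_superclusters >= 1))
    stop("need n_clusters >= n_isps >= n_superclusters >= 1")
  if (is.null(cluster_proportions)) {
    raw <- seq(2, 0.8, length.out = n_clusters)
    cluster_proportions <- raw / sum(raw)
  }
  if (abs(sum(cluster_proportions) - 1) > 1e-9 ||
      any(cluster_proportions <= 0))
    stop("cluster_proportions must be positive and sum to 1")
  if (length(cluster_proportions) != n_clusters)
    stop("cluster_proportions length != n_clusters")
  if (is.null(right_eye_prob_per_cluster))
    right_eye_prob_per_cluster <- rep(0.5, n_clusters)
  if (length(right_eye_prob_per_cluster) != n_clusters)
    stop("right_eye_prob_per_cluster length != n_clusters")
  tf_names <- sprintf("TF%02d", seq_len(tf_panel_size))
  if (is.null(planted_combos))
    planted_combos <- default_planted_combos(n_clusters, tf_names)
  for (pc in planted_combos) {
    if (!all(pc$tfs %in% tf_names))
      stop("planted combo TFs not in the TF panel: ",
           paste(setdiff(pc$tfs, tf_names), collapse = ", "))
    if (length(pc$tfs) < 1 || length(pc$tfs) > 5)
      stop("planted combo size must be 1-5")
    if (pc$cluster < 1 || pc$cluster > n_clusters)
      stop("planted combo cluster out of range")
    if (length(pc$tfs) >= 2 &&
        (n_clusters < length(pc$tfs) + 1 ||
         length(pc$tfs) > planted_e_max(n_clusters)))
      stop("infeasible combo planting: a unique ", length(pc$tfs),
           "-way combination with non-unique, binarization-surviving ",
           "members is impossible with ", n_clusters, " clusters")
  }
  if (anyDuplicated(unlist(lapply(planted_combos, `[[`, "tfs"))))
    stop("infeasible combo planting: each TF may appear in one combo only")
  n_special <- n_clusters * markers_per_cluster +
    n_isps * isp_markers_per_isp +
    n_superclusters * super_markers_per_supercluster + tf_panel_size + 23
  if (n_genes < n_special + 100)
    stop("n_genes too small: need >= ", n_special + 100,
         " for markers, panels and baseline genes")
  structure(list(n_cells = as.integer(n_cells),
                 n_genes = as.integer(n_genes),
                 n_superclusters = as.integer(n_superclusters),
                 n_isps = as.integer(n_isps),
                 n_clusters = as.integer(n_clusters),
                 cluster_proportions = cluster_proportions,
                 right_eye_prob_per_cluster = right_eye_prob_per_cluster,
                 markers_per_cluster = as.integer(markers_per_cluster),
                 marker_fold = marker_fold,
                 isp_markers_per_isp = as.integer(isp_markers_per_isp),
                 super_markers_per_supercluster =
                   as.integer(super_markers_per_supercluster),
                 tf_panel_size = as.integer(tf_panel_size),
                 tf_names = tf_names,
                 planted_combos = planted_combos,
                 nb_dispersion = nb_dispersion,
                 size_factor_lognorm_sigma = size_factor_lognorm_sigma,
                 low_quality_fraction = low_quality_fraction,
                 low_quality_scale = low_quality_scale,
                 contaminant_fraction = contaminant_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Full-study-scale generator configuration
#'
#' 6225 cells, 40 clusters in 10 ISPs and 4 superclusters — the scale of a
#' complete RGC atlas.  Heavier than the desk-scale default; intended for
#' exploratory runs rather than routine tests.
#'
#' @param ... overrides passed to [sim_config()].
#' @export
sim_config_full <- function(...) {
  args <- list(n_cells = 6225, n_genes = 5000,
               n_superclusters = 4, n_isps = 10, n_clusters = 40,
               markers_per_cluster = 10)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# Default planted TF combinations: 2-way, 2-way, 3-way, 1-way in the first
# clusters, as far as the cluster count allows.
default_planted_combos <- function(n_clusters, tf_names) {
  combos <- list()
  e_max <- planted_e_max(n_clusters)
  if (n_clusters >= 3 && e_max >= 2 && length(tf_names) >= 2)
    combos <- c(combos, list(list(cluster = 1L, tfs = tf_names[1:2])))
  if (n_clusters >= 3 && e_max >= 2 && length(tf_names) >= 4)
    combos <- c(combos, list(list(cluster = 2L, tfs = tf_names[3:4])))
  if (n_clusters >= 7 && e_max >= 3 && length(tf_names) >= 7)
    combos <- c(combos, list(list(cluster = 3L, tfs = tf_names[5:7])))
  if (n_clusters >= 4 && length(tf_names) >= 8)
    combos <- c(combos, list(list(cluster = 4L, tfs = tf_names[8])))
  combos
}

# Maximum number of clusters a planted TF may be enriched in while still
# clearing the "> 2 x cross-cluster mean NE" binarization rule (enriched
# NE ~1.5, background ~0.15): e_max ~ 0.44 K.
planted_e_max <- function(K) max(1L, floor(0.44 * K))

# Expected mean of log2(x + 1) for x ~ NB(mu, size): the expected NE of a
# gene at count mean mu under unit library scaling.
ne_mean_nb <- function(mu, size) {
  if (mu <= 0) return(0)
  xmax <- max(10, stats::qnbinom(1 - 1e-10, mu = mu, size = size))
  x <- seq_len(xmax)
  sum(stats::dnbinom(x, mu = mu, size = size) * log2(x + 1))
}

# Back-solve the home-cluster count mean giving an expected mean-NE ratio
# of `fold` over a baseline count mean `mu0`.
solve_marker_mean <- function(mu0, fold, size) {
  target <- fold * ne_mean_nb(mu0, size)
  f <- function(m) ne_mean_nb(m, size) - target
  stats::uniroot(f, lower = mu0, upper = 1e4, extendInt = "upX",
                 tol = 1e-8)$root
}

# Nested assignment of clusters to ISPs and ISPs to superclusters,
# contiguous and near-equal.
nested_assignment <- function(n_clusters, n_isps, n_superclusters) {
  cluster_isp <- sort(rep_len(seq_len(n_isps), n_clusters))
  isp_super <- sort(rep_len(seq_len(n_superclusters), n_isps))
  list(cluster_isp = cluster_isp, isp_super = isp_super)
}

#' Generate a synthetic count matrix with planted ground truth
#'
#' Gene baseline mean counts are log-normal; multiplicative supercluster,
#' ISP and cluster offsets are applied in nested fashion, so clusters in
#' the same ISP correlate more than clusters across ISPs.  Marker genes
#' have their mean multiplied by `marker_fold` in their home cluster only.
#' Planted TF combinations are constructed pattern-first: each member TF is
#' enriched in its target cluster and in a distinct set of decoy clusters,
#' chosen so no proper sub-combination is unique while the full
#' intersection is unique to the target.  Counts are negative-binomial with
#' log-normal per-cell size factors; low-quality cells have their size
#' factor shrunk so they fall below the genes-per-cell cutoff; contaminant
#' cells are drawn from a separate profile enriched for the contaminant
#' panel.  Eye labels are Bernoulli with per-cluster right-eye probability.
#'
#' The same config (including its seed) always produces bit-identical
#' output.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (an [rgc_counts]) and `truth` (an
#'   `rgc_truth`: planted `cell_cluster`, `cell_isp`, `cell_supercluster`,
#'   `cell_eye`, `marker_map`, `combo_map`, `contaminant_cells`,
#'   `low_quality_cells`, the gene `panels`, and the config).
#' @export
generate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  K <- config$n_clusters
  G <- config$n_genes
  N <- config$n_cells
  nest <- nested_assignment(K, config$n_isps, config$n_superclusters)

  ## -- gene space layout ------------------------------------------------
  tf_names <- config$tf_names
  rgc_names <- sprintf("RGCM%02d", 1:10)
  cont_names <- sprintf("CNTM%02d", 1:10)
  sex_names <- c("SEXG1", "SEXG2", "SEXG3")
  n_named <- length(tf_names) + 23
  base_names <- sprintf("G%05d", seq_len(G - n_named))
  gene_ids <- c(base_names, tf_names, rgc_names, cont_names, sex_names)

  ## -- baseline means and hierarchical offsets --------------------------
  mu <- numeric(G)
  names(mu) <- gene_ids
  mu[base_names] <- stats::rlnorm(length(base_names),
                                  meanlog = log(0.8), sdlog = 1.0)
  mu[tf_names] <- 0.08
  mu[rgc_names] <- 4
  mu[cont_names] <- 0.05
  mu[sex_names] <- c(1.5, 0.6, 0.6)

  # markers drawn from the low-moderate expression range so the NE fold
  # survives the log transform
  n_mk <- config$markers_per_cluster
  if (n_mk > 0) {
    marker_pool <- sample(base_names, K * n_mk)
    marker_map <- split(marker_pool, rep(seq_len(K), each = n_mk))
    names(marker_map) <- as.character(seq_len(K))
    mu[marker_pool] <- stats::rlnorm(length(marker_pool),
                                     meanlog = log(0.6), sdlog = 0.4)
  } else {
    marker_map <- stats::setNames(rep(list(character(0)), K),
                                  as.character(seq_len(K)))
  }

  # genes x clusters mean matrix via nested multiplicative offsets
  sup_of_cluster <- nest$isp_super[nest$cluster_isp]
  off_sup <- matrix(stats::rlnorm(G * config$n_superclusters, 0, 0.25),
                    G, config$n_superclusters)
  off_isp <- matrix(stats::rlnorm(G * config$n_isps, 0, 0.18),
                    G, config$n_isps)
  off_clu <- matrix(stats::rlnorm(G * K, 0, 0.08), G, K)
  mu_gk <- mu * off_sup[, sup_of_cluster, drop = FALSE] *
    off_isp[, nest$cluster_isp, drop = FALSE] * off_clu
  rownames(mu_gk) <- gene_ids

  # markers: fold applied in home cluster only; hierarchy offsets flattened
  # for marker genes so the planted fold is the dominant signal.  The fold
  # is planted in mean-NE ratio units (the unit of the enrichment rule):
  # the home-cluster count mean is back-solved so the expected mean NE is
  # marker_fold times the baseline mean NE.
  size <- 1 / config$nb_dispersion
  for (k in seq_len(K)) {
    mk <- marker_map[[k]]
    mu_gk[mk, ] <- mu[mk]
    mu_gk[mk, k] <- vapply(mu[mk], solve_marker_mean, numeric(1),
                           fold = config$marker_fold, size = size)
  }

  ## -- ISP and supercluster marker genes --------------------------------
  # enriched (stronger than cluster markers) in every member cluster of
  # the group, giving the dendrogram a recoverable nested structure
  used <- if (n_mk > 0) marker_pool else character(0)
  plant_group_markers <- function(groups_of_cluster, per_group, fold) {
    gmap <- list()
    for (gr in sort(unique(groups_of_cluster))) {
      members <- which(groups_of_cluster == gr)
      gmap[[as.character(gr)]] <- character(0)
      if (length(members) < 2 || per_group < 1) next
      pool <- setdiff(base_names, used)
      gsel <- sample(pool, per_group)
      used <<- c(used, gsel)
      mu[gsel] <<- stats::rlnorm(per_group, meanlog = log(0.6),
                                 sdlog = 0.4)
      mu_gk[gsel, ] <<- mu[gsel]
      mu_gk[gsel, members] <<- vapply(mu[gsel], solve_marker_mean,
                                      numeric(1), fold = fold,
                                      size = size)
      gmap[[as.character(gr)]] <- gsel
    }
    gmap
  }
  isp_marker_map <- plant_group_markers(nest$cluster_isp,
                                        config$isp_markers_per_isp, 4)
  super_marker_map <- plant_group_markers(sup_of_cluster,
                                          config$super_markers_per_supercluster,
                                          6)

  ## -- planted TF combinations (pattern first, means second) ------------
  combo_map <- config$planted_combos
  used_tfs <- unlist(lapply(combo_map, `[[`, "tfs"))
  tf_high <- 2.2
  tf_low <- 0.08
  for (pc in combo_map) {
    m <- length(pc$tfs)
    k <- pc$cluster
    if (m == 1) {
      mu_gk[pc$tfs, ] <- tf_low
      mu_gk[pc$tfs, k] <- tf_high
    } else {
      # Partition design: a covered set U of non-focal clusters is split
      # into m groups; member i is enriched in {k} + (U minus group i).
      # Every proper sub-combination keeps its group's clusters (not
      # unique); the full intersection is exactly {k}.  The covered set is
      # capped so each member stays enriched in < ~44% of clusters and
      # therefore survives the 2-fold binarization rule.
      e_max <- planted_e_max(K)
      others <- setdiff(seq_len(K), k)
      cover <- min(length(others),
                   max(m, floor((e_max - 1) * m / (m - 1))))
      U <- others[seq_len(cover)]
      for (i in seq_len(m)) {
        grp <- U[seq(i, cover, by = m)]
        enriched <- c(k, setdiff(U, grp))
        mu_gk[pc$tfs[i], ] <- tf_low
        mu_gk[pc$tfs[i], enriched] <- tf_high
      }
    }
  }
  # remaining TFs: enriched in a random pair of clusters (realistic rows,
  # not unique anywhere by construction of two ones)
  for (tf in setdiff(tf_names, used_tfs)) {
    if (K >= 3) {
      enriched <- sample(seq_len(K), 2)
      mu_gk[tf, ] <- tf_low
      mu_gk[tf, enriched] <- tf_high
    }
  }

  ## -- cell-level structure ---------------------------------------------
  n_cont <- round(config$contaminant_fraction * N)
  n_rgc <- N - n_cont
  cl <- sample(seq_len(K), n_rgc, replace = TRUE,
               prob = config$cluster_proportions)
  is_cont <- c(rep(FALSE, n_rgc), rep(TRUE, n_cont))
  cell_cluster <- c(cl, rep(0L, n_cont))
  p_right <- ifelse(is_cont, 0.5,
                    config$right_eye_prob_per_cluster[pmax(cell_cluster, 1)])
  cell_eye <- ifelse(stats::runif(N) < p_right, "right", "left")
  sf <- stats::rlnorm(N, 0, config$size_factor_lognorm_sigma)
  lowq <- stats::runif(N) < config$low_quality_fraction
  sf[lowq] <- sf[lowq] * config$low_quality_scale
  barcodes <- sprintf("cell%05d", seq_len(N))

  # contaminant profile: own baseline, contaminant panel high, RGC low
  mu_cont <- stats::rlnorm(G, meanlog = log(0.8), sdlog = 1.0)
  names(mu_cont) <- gene_ids
  mu_cont[tf_names] <- 0.08
  mu_cont[rgc_names] <- 0.05
  mu_cont[cont_names] <- 4
  mu_cont[sex_names] <- c(1.5, 0.6, 0.6)

  ## -- draw counts (chunked over cells) ---------------------------------
  size <- 1 / config$nb_dispersion
  chunks <- split(seq_len(N), ceiling(seq_len(N) / 500))
  blocks <- vector("list", length(chunks))
  for (ci in seq_along(chunks)) {
    idx <- chunks[[ci]]
    mu_cells <- matrix(0, length(idx), G)
    for (j in seq_along(idx)) {
      i <- idx[j]
      m <- if (is_cont[i]) mu_cont else mu_gk[, cell_cluster[i]]
      mu_cells[j, ] <- m * sf[i]
    }
    x <- stats::rnbinom(length(mu_cells), mu = as.vector(mu_cells),
                        size = size)
    blocks[[ci]] <- Matrix::Matrix(matrix(x, length(idx), G),
                                   sparse = TRUE)
  }
  counts <- do.call(rbind, blocks)
  cm <- rgc_counts(counts, barcodes, cell_eye, gene_ids)

  panels <- list(
    rgc = gene_panel("pan_rgc_markers", rgc_names, "rgc_marker"),
    contaminant = gene_panel("non_rgc_markers", cont_names,
                             "contaminant_marker"),
    tf = gene_panel("tf_catalog", tf_names, "tf"),
    sex = gene_panel("sex_genes", sex_names, "sex"))

  truth <- structure(list(
    cell_cluster = stats::setNames(cell_cluster, barcodes),
    cell_isp = stats::setNames(
      ifelse(cell_cluster > 0, nest$cluster_isp[pmax(cell_cluster, 1)], 0L),
      barcodes),
    cell_supercluster = stats::setNames(
      ifelse(cell_cluster > 0, sup_of_cluster[pmax(cell_cluster, 1)], 0L),
      barcodes),
    cell_eye = stats::setNames(cell_eye, barcodes),
    marker_map = marker_map,
    isp_marker_map = isp_marker_map,
    super_marker_map = super_marker_map,
    combo_map = combo_map,
    contaminant_cells = barcodes[is_cont],
    low_quality_cells = barcodes[lowq],
    cluster_isp = nest$cluster_isp,
    isp_supercluster = nest$isp_super,
    panels = panels,
    config = config), class = "rgc_truth")

  list(counts = cm, truth = truth)
}

#' Write a synthetic fixture to disk as plain-text files
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate, genes x cells in the 10x
#' convention), `genes.tsv`, `barcodes.tsv` (second column = eye label),
#' `truth.json`, one panel text file per gene panel, and the generator
#' config as a flat `key = value` file.  The triplet round-trips losslessly
#' through [read_counts()].
#'
#' @param cm an [rgc_counts].
#' @param truth the matching `rgc_truth`, or `NULL` to skip truth/panels.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_fixture <- function(cm, truth, dir) {
  stopifnot(inherits(cm, "rgc_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mtx = file.path(dir, "matrix.mtx"),
             genes = file.path(dir, "genes.tsv"),
             barcodes = file.path(dir, "barcodes.tsv"))
  Matrix::writeMM(Matrix::t(cm$counts), paths[["mtx"]])
  writeLines(cm$gene_ids, paths[["genes"]])
  utils::write.table(cm$cell_meta[, c("barcode", "eye")],
                     paths[["barcodes"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(truth)) {
    paths[["truth"]] <- file.path(dir, "truth.json")
    tr <- truth
    tr$panels <- lapply(tr$panels, unclass)
    tr$config <- NULL
    jsonlite::write_json(unclass(tr), paths[["truth"]], auto_unbox = TRUE,
                         digits = NA)
    for (p in truth$panels) {
      f <- file.path(dir, paste0(p$name, ".txt"))
      writeLines(p$genes, f)
      paths[[p$name]] <- f
    }
    cfg <- truth$config
    paths[["config"]] <- file.path(dir, "sim_config.txt")
    scalar <- vapply(cfg, function(v)
      is.atomic(v) && length(v) == 1, logical(1))
    writeLines(sprintf("%s = %s", names(cfg)[scalar],
                       vapply(cfg[scalar], as.character, character(1))),
               paths[["config"]])
  }
  invisible(paths)
}

#' Read a fixture's planted truth back from truth.json
#'
#' @param dir fixture directory written by [write_fixture()].
#' @return list mirroring the `rgc_truth` fields (panels as plain lists).
#' @export
read_truth <- function(dir) {
  jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
}
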