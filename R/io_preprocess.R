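#' Read a 10x-style MTX triplet into a count matrix
#'
#' Reads a MatrixMarket coordinate file in the 10x convention (genes as
#' rows, cells as columns) together with `genes.tsv` (gene identifiers,
#' first column) and `barcodes.tsv` (barcode in the first column, optional
#' eye label `left`/`right`/`unknown` in the second).  The matrix is
#' transposed to the package's cells x genes orientation.
#'
#' A file whose header dimensions match the barcode count in rows rather
#' than columns was written transposed; it is rejected, not silently fixed.
#'
#' @param mtx_path path to the MatrixMarket file.
#' @param genes_path path to the gene TSV (no header).
#' @param barcodes_path path to the barcode TSV (no header).
#' @return An [rgc_counts] object.
#' @export
read_counts <- function(mtx_path, genes_path, barcodes_path) {
  for (p in c(mtx_path, genes_path, barcodes_path))
    if (!file.exists(p)) stop("file not found: ", p)
  m <- tryCatch(Matrix::readMM(mtx_path),
                error = function(e) stop("malformed MTX file '", mtx_path,
                                         "': ", conditionMessage(e)))
  genes <- utils::read.delim(genes_path, header = FALSE,
                             stringsAsFactors = FALSE)
  bc <- utils::read.delim(barcodes_path, header = FALSE,
                          stringsAsFactors = FALSE)
  gene_ids <- as.character(genes[[1]])
  barcodes <- as.character(bc[[1]])
  eye <- if (ncol(bc) >= 2) as.character(bc[[2]]) else "unknown"
  if (nrow(m) == length(barcodes) && ncol(m) == length(gene_ids) &&
      length(barcodes) != length(gene_ids))
    stop("MTX appears transposed (cells x genes); expected genes x cells")
  if (nrow(m) != length(gene_ids))
    stop("MTX has ", nrow(m), " rows but genes file lists ",
         length(gene_ids), " genes")
  if (ncol(m) != length(barcodes))
    stop("MTX has ", ncol(m), " columns but barcodes file lists ",
         length(barcodes), " cells")
  rgc_counts(Matrix::t(m), barcodes, eye, gene_ids)
}

#' Remove cells below a genes-per-cell coverage cutoff
#'
#' Droplet libraries show a low-coverage sub-peak of cells detecting far
#' fewer genes than the main population; these are excluded before
#' normalization.  The default cutoff of 3000 detected genes suits
#' full-transcriptome data averaging ~5000 genes per cell and should be
#' scaled down for reduced gene spaces.
#'
#' @param cm an [rgc_counts] object.
#' @param min_genes minimum number of detected genes for a cell to be kept.
#' @return list with `counts` (filtered [rgc_counts]) and `removed_cells`
#'   (barcodes of the excluded cells, for audit).
#' @export
filter_low_coverage <- function(cm, min_genes = 3000) {
  stopifnot(inherits(cm, "rgc_counts"), min_genes >= 0)
  keep <- genes_detected(cm) >= min_genes
  if (!any(keep))
    stop("all ", nrow(cm$counts), " cells fall below min_genes = ",
         min_genes)
  out <- rgc_counts(cm$counts[keep, , drop = FALSE],
                    cm$cell_meta$barcode[keep],
                    cm$cell_meta$eye[keep],
                    cm$gene_ids)
  list(counts = out, removed_cells = cm$cell_meta$barcode[!keep])
}

#' Normalize UMI counts to NE units
#'
#' Each cell's counts are scaled by the median of total transcripts across
#' all cells divided by the cell's own total, then log2-transformed with a
#' +1 pseudocount:
#' \deqn{NE_{gc} = \log_2(x_{gc} \cdot M / T_c + 1)}
#' where \eqn{T_c} is the cell's total UMI count and \eqn{M} the median of
#' all \eqn{T_c} (mean of the two middle values for an even cell count).
#' Zero counts map exactly to NE 0, and within a cell NE is strictly
#' increasing in the count.
#'
#' @param cm an [rgc_counts] object; every cell must have a positive total.
#' @return An [rgc_ne] object carrying the scaling constant `M`.
#' @export
normalize_ne <- function(cm) {
  stopifnot(inherits(cm, "rgc_counts"))
  totals <- Matrix::rowSums(cm$counts)
  if (any(totals == 0))
    stop("cell(s) with zero total transcripts: ",
         paste(utils::head(cm$cell_meta$barcode[totals == 0], 5),
               collapse = ", "))
  M <- stats::median(totals)
  ne <- cm$counts
  # scale the nonzeros in place: x * M / T_c, then log2(+1)
  tpc <- methods::as(ne, "TsparseMatrix")
  tpc@x <- log2(tpc@x * M / totals[tpc@i + 1L] + 1)
  ne <- methods::as(tpc, "CsparseMatrix")
  rgc_ne(ne, cm$cell_meta, M = M,
         provenance = sprintf("normalize_ne(filtered counts), M=%g", M))
}

#' Select over-dispersed genes for clustering
#'
#' Ranks genes by NE dispersion (variance/mean of NE across cells, among
#' genes with mean NE > 0) and returns the top `n`, after removing any
#' excluded panels (typically sex-specific genes, which track animal sex
#' rather than cell identity).  Ties are broken by gene-identifier order.
#'
#' @param em an [rgc_ne] object.
#' @param n number of genes to select.
#' @param exclude a [gene_panel], list of panels, or character vector of
#'   gene identifiers to exclude; `NULL` for none.
#' @return character vector of the selected gene identifiers, most
#'   dispersed first.  If fewer than `n` genes are eligible, all eligible
#'   genes are returned with a warning.
#' @export
select_overdispersed <- function(em, n = 1000, exclude = NULL) {
  stopifnot(inherits(em, "rgc_ne"), n >= 1)
  excl <- character()
  if (!is.null(exclude)) {
    if (inherits(exclude, "gene_panel")) exclude <- list(exclude)
    if (is.list(exclude))
      excl <- unlist(lapply(exclude, function(p) p$genes))
    else excl <- as.character(exclude)
  }
  x <- em$ne
  nc <- nrow(x)
  mu <- Matrix::colSums(x) / nc
  ex2 <- Matrix::colSums(x^2) / nc
  v <- (ex2 - mu^2) * nc / (nc - 1)
  disp <- ifelse(mu > 0, v / mu, -Inf)
  ids <- colnames(x)
  eligible <- which(mu > 0 & !(ids %in% excl))
  ord <- eligible[order(-disp[eligible], ids[eligible])]
  if (length(ord) < n) {
    warning("only ", length(ord), " eligible genes (requested ", n, ")")
    return(ids[ord])
  }
  ids[ord[seq_len(n)]]
}
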