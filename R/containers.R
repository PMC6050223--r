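#' @importFrom Matrix Matrix readMM writeMM rowSums colSums t
#' @importFrom methods as is
NULL

#' Construct a UMI count-matrix container
#'
#' Bundles a sparse cells x genes matrix of non-negative integer UMI counts
#' with per-cell metadata (barcode and eye of origin).  This is the raw input
#' unit of the pipeline; all quality filtering happens on this object, before
#' normalization.
#'
#' @param counts sparse or dense cells x genes matrix of non-negative
#'   integers.  Coerced to `dgCMatrix`.
#' @param barcodes character vector of unique cell barcodes, one per row.
#' @param eye per-cell eye of origin, each `"left"`, `"right"` or
#'   `"unknown"`.  Recycled if length 1.
#' @param gene_ids character vector of unique gene identifiers, one per
#'   column.
#' @return An object of class `rgc_counts`: a list with elements `counts`
#'   (cells x genes `dgCMatrix`), `cell_meta` (data.frame with `barcode`,
#'   `eye`) and `gene_ids`.
#' @export
rgc_counts <- function(counts, barcodes, eye = "unknown", gene_ids) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop("count matrix has negative entries")
  if (length(barcodes) != nrow(counts))
    stop("barcodes length (", length(barcodes), ") != number of cells (",
         nrow(counts), ")")
  if (length(gene_ids) != ncol(counts))
    stop("gene_ids length (", length(gene_ids), ") != number of genes (",
         ncol(counts), ")")
  if (anyDuplicated(barcodes)) stop("duplicate cell barcodes")
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers")
  eye <- rep_len(as.character(eye), length(barcodes))
  bad <- setdiff(unique(eye), c("left", "right", "unknown"))
  if (length(bad))
    stop("invalid eye labels: ", paste(bad, collapse = ", "))
  dimnames(counts) <- list(as.character(barcodes), as.character(gene_ids))
  structure(list(counts = counts,
                 cell_meta = data.frame(barcode = as.character(barcodes),
                                        eye = eye,
                                        stringsAsFactors = FALSE),
                 gene_ids = as.character(gene_ids)),
            class = "rgc_counts")
}

#' @exportS3Method base::print
print.rgc_counts <- function(x, ...) {
  cat("rgc_counts:", nrow(x$counts), "cells x", ncol(x$counts), "genes;",
      format(Matrix::nnzero(x$counts), big.mark = ","), "nonzero UMIs\n")
  cat("  eyes:", paste(sprintf("%s=%d", names(table(x$cell_meta$eye)),
                               table(x$cell_meta$eye)), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.rgc_counts <- function(x) dim(x$counts)

#' Number of genes detected per cell
#'
#' A gene is detected in a cell when its UMI count is greater than zero.
#'
#' @param cm an [rgc_counts] object.
#' @return integer vector, one entry per cell, named by barcode.
#' @export
genes_detected <- function(cm) {
  stopifnot(inherits(cm, "rgc_counts"))
  d <- Matrix::rowSums(cm$counts > 0)
  stats::setNames(as.integer(d), cm$cell_meta$barcode)
}

#' Construct a normalized-expression (NE) matrix container
#'
#' Usually produced by [normalize_ne()]; the constructor is exported for
#' tests and for assembling NE matrices from external sources.
#'
#' @param ne sparse cells x genes matrix of NE values (non-negative reals).
#' @param cell_meta data.frame with `barcode` and `eye` columns.
#' @param M the median-of-totals scaling constant used (NA if unknown).
#' @param provenance free-text note on the source count matrix.
#' @return An object of class `rgc_ne`.
#' @export
rgc_ne <- function(ne, cell_meta, M = NA_real_, provenance = "") {
  ne <- methods::as(methods::as(methods::as(ne, "dMatrix"),
                                "generalMatrix"), "CsparseMatrix")
  if (any(ne@x < 0)) stop("NE matrix has negative entries")
  stopifnot(nrow(ne) == nrow(cell_meta))
  structure(list(ne = ne, cell_meta = cell_meta, M = M,
                 provenance = provenance),
            class = "rgc_ne")
}

#' @exportS3Method base::print
print.rgc_ne <- function(x, ...) {
  cat("rgc_ne:", nrow(x$ne), "cells x", ncol(x$ne),
      "genes (NE units, M =", format(x$M), ")\n")
  invisible(x)
}

#' @export
dim.rgc_ne <- function(x) dim(x$ne)

#' Construct a gene panel
#'
#' A named list of gene identifiers with a role tag.  Panels drive sex-gene
#' exclusion from clustering, contaminant-cluster flagging (amacrine and
#' other non-RGC markers versus pan-RGC markers), and the TF catalog for
#' combinatorial analysis.
#'
#' @param name short panel name.
#' @param genes character vector of gene identifiers (nonempty).
#' @param role one of `"rgc_marker"`, `"contaminant_marker"`, `"tf"`,
#'   `"sex"`.
#' @return An object of class `gene_panel`.
#' @export
gene_panel <- function(name, genes,
                       role = c("rgc_marker", "contaminant_marker",
                                "tf", "sex")) {
  role <- match.arg(role)
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("gene panel '", name, "' is empty")
  structure(list(name = name, genes = genes, role = role),
            class = "gene_panel")
}

#' Read a gene panel from a one-gene-per-line text file
#'
#' @param path file with one gene identifier per line; blank lines and lines
#'   starting with `#` are ignored.
#' @inheritParams gene_panel
#' @return A [gene_panel].
#' @export
read_panel <- function(path, name = basename(path), role = "rgc_marker") {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  gene_panel(name, lines, role)
}

#' Resolve a panel against the genes of a matrix
#'
#' @param panel a [gene_panel].
#' @param gene_ids gene identifiers to resolve against.
#' @param min_found minimum number of resolvable genes required.
#' @return character vector of panel genes present in `gene_ids`; attribute
#'   `missing` lists the unresolvable ones.
#' @export
resolve_panel <- function(panel, gene_ids, min_found = 1L) {
  stopifnot(inherits(panel, "gene_panel"))
  found <- intersect(panel$genes, gene_ids)
  if (length(found) < min_found)
    stop("panel '", panel$name, "' resolves to ", length(found),
         " gene(s); need >= ", min_found)
  attr(found, "missing") <- setdiff(panel$genes, gene_ids)
  found
}
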