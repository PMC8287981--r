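# Count-matrix container and 10x-style triplet I/O.

#' Count matrix container
#'
#' Bundles a sparse genes x cells integer count matrix with per-cell
#' metadata (sample id, tissue class) and an optional gene table.
#'
#' @param counts sparse (or dense) nonnegative integer matrix, genes in
#'   rows, cells in columns, with dimnames.
#' @param cell_meta data frame with columns \code{cell_id},
#'   \code{sample_id}, \code{tissue}; one row per column of \code{counts},
#'   same order.
#' @param gene_table optional data frame with a \code{gene_symbol} column
#'   matching \code{rownames(counts)}.
#' @return object of class \code{caf_counts}.
#' @export
new_caf_counts <- function(counts, cell_meta, gene_table = NULL) {
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- as(as(counts, "dMatrix"), "CsparseMatrix")
  counts <- as(counts, "generalMatrix")
  if (is.null(rownames(counts))) {
    if (nrow(counts) > 0) .stopf("counts must have gene dimnames")
    rownames(counts) <- character(0)
  }
  if (is.null(colnames(counts))) {
    if (ncol(counts) > 0) .stopf("counts must have cell dimnames")
    colnames(counts) <- character(0)
  }
  if (anyDuplicated(rownames(counts)))
    .stopf("duplicate gene identifiers")
  if (anyDuplicated(colnames(counts)))
    .stopf("duplicate cell barcodes")
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != floor(x))))
    .stopf("counts must be nonnegative integers")
  stopifnot(is.data.frame(cell_meta),
            all(c("cell_id", "sample_id", "tissue") %in% names(cell_meta)),
            nrow(cell_meta) == ncol(counts))
  if (!identical(cell_meta$cell_id, colnames(counts)))
    .stopf("cell_meta rows must match count matrix columns in order")
  if (is.null(gene_table))
    gene_table <- data.frame(gene_id = rownames(counts),
                             gene_symbol = rownames(counts),
                             stringsAsFactors = FALSE)
  structure(list(counts = counts, cell_meta = cell_meta,
                 gene_table = gene_table),
            class = "caf_counts")
}

#' @export
print.caf_counts <- function(x, ...) {
  cat(sprintf("caf_counts: %d genes x %d cells (%d samples; tissues: %s)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$sample_id)),
              paste(sort(unique(x$cell_meta$tissue)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.caf_counts <- function(x) dim(x$counts)

#' Subset a count object to a set of cells
#'
#' @param x a \code{caf_counts} object.
#' @param cells character vector of cell ids to keep (order preserved).
#' @return a \code{caf_counts} object.
#' @export
subset_cells <- function(x, cells) {
  stopifnot(inherits(x, "caf_counts"))
  idx <- match(cells, colnames(x$counts))
  if (anyNA(idx)) .stopf("unknown cell ids in 'cells'")
  new_caf_counts(x$counts[, idx, drop = FALSE],
                 x$cell_meta[idx, , drop = FALSE],
                 gene_table = x$gene_table)
}

#' Read a 10x-style Matrix Market triplet directory
#'
#' Expects \code{matrix.mtx} (genes x cells, integer), \code{features.tsv}
#' (gene_id, gene_symbol; no header), \code{barcodes.tsv} (one barcode per
#' line) and optionally \code{cell_meta.tsv} (header: cell_id, sample_id,
#' tissue). Without a metadata file all cells get sample "S1", tissue
#' "tumour".
#'
#' @param dir_path directory containing the triplet.
#' @return a \code{caf_counts} object.
#' @export
read_mtx_triplet <- function(dir_path) {
  need <- file.path(dir_path, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  if (!all(file.exists(need)))
    .stopf("directory '%s' must contain matrix.mtx, features.tsv, barcodes.tsv",
           dir_path)
  m <- Matrix::readMM(need[1])
  feats <- read.delim(need[2], header = FALSE, stringsAsFactors = FALSE)
  if (ncol(feats) < 2) feats$V2 <- feats$V1
  barcodes <- readLines(need[3])
  barcodes <- barcodes[nzchar(barcodes)]
  if (nrow(m) != nrow(feats))
    .stopf("matrix has %d rows but features.tsv has %d", nrow(m), nrow(feats))
  if (ncol(m) != length(barcodes))
    .stopf("matrix has %d columns but barcodes.tsv has %d", ncol(m),
           length(barcodes))
  if (anyDuplicated(barcodes)) .stopf("duplicate barcodes")
  if (length(m@x) && any(m@x != floor(m@x)))
    .stopf("non-integer entries in matrix.mtx")
  dimnames(m) <- list(feats[[2]], barcodes)
  meta_path <- file.path(dir_path, "cell_meta.tsv")
  meta <- if (file.exists(meta_path)) {
    mt <- read.delim(meta_path, stringsAsFactors = FALSE)
    mt[match(barcodes, mt$cell_id), , drop = FALSE]
  } else {
    data.frame(cell_id = barcodes, sample_id = "S1", tissue = "tumour",
               stringsAsFactors = FALSE)
  }
  new_caf_counts(m, meta,
                 gene_table = data.frame(gene_id = feats[[1]],
                                         gene_symbol = feats[[2]],
                                         stringsAsFactors = FALSE))
}

#' Write a count object as a Matrix Market triplet
#'
#' Inverse of [read_mtx_triplet()]; the round-trip is lossless. Also writes
#' \code{cell_meta.tsv} with the per-cell metadata.
#'
#' @param x a \code{caf_counts} object.
#' @param dir_path output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_mtx_triplet <- function(x, dir_path) {
  stopifnot(inherits(x, "caf_counts"))
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(x$counts, file.path(dir_path, "matrix.mtx"))
  write.table(x$gene_table[, c("gene_id", "gene_symbol")],
              file.path(dir_path, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(x$counts), file.path(dir_path, "barcodes.tsv"))
  write.table(x$cell_meta, file.path(dir_path, "cell_meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir_path)
}

#' Library-size normalization (CP10K, log1p)
#'
#' Scales each cell to 10,000 counts and applies \code{log1p}:
#' \code{value(g,j) = log(1 + 10000 * count(g,j) / T_j)} for cell total
#' \code{T_j > 0}. Cells with zero total counts pass through as all-zero
#' columns with a warning.
#'
#' @param x a \code{caf_counts} object.
#' @param scale_factor per-cell target total (default 10,000).
#' @return object of class \code{caf_norm}: sparse \code{values} matrix on
#'   the same axes plus the cell metadata.
#' @export
normalize_counts <- function(x, scale_factor = 1e4) {
  stopifnot(inherits(x, "caf_counts"))
  totals <- Matrix::colSums(x$counts)
  zero <- totals == 0
  if (any(zero))
    .warnf("%d cell(s) with zero total counts pass through as zeros",
           sum(zero))
  scl <- ifelse(zero, 0, scale_factor / pmax(totals, 1))
  v <- x$counts %*% Matrix::Diagonal(x = scl)
  v@x <- log1p(v@x)
  v <- as(v, "CsparseMatrix")
  dimnames(v) <- dimnames(x$counts)
  structure(list(values = v, cell_meta = x$cell_meta,
                 gene_table = x$gene_table),
            class = "caf_norm")
}

#' @export
print.caf_norm <- function(x, ...) {
  cat(sprintf("caf_norm: %d genes x %d cells (log1p CP10K)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Subset a normalized object to a set of cells
#' @param x a \code{caf_norm} object.
#' @param cells cell ids to keep (order preserved).
#' @return a \code{caf_norm} object.
#' @export
subset_norm <- function(x, cells) {
  stopifnot(inherits(x, "caf_norm"))
  idx <- match(cells, colnames(x$values))
  if (anyNA(idx)) .stopf("unknown cell ids in 'cells'")
  structure(list(values = x$values[, idx, drop = FALSE],
                 cell_meta = x$cell_meta[idx, , drop = FALSE],
                 gene_table = x$gene_table),
            class = "caf_norm")
}

#' Basic quality-control filter
#'
#' Keeps cells detecting at least \code{min_genes_per_cell} genes, then
#' genes detected in at least \code{min_cells_per_gene} of the retained
#' cells (cells are filtered first; the order matters and is fixed).
#'
#' @param x a \code{caf_counts} object.
#' @param min_genes_per_cell,min_cells_per_gene nonnegative thresholds.
#' @return filtered \code{caf_counts}; an empty result is returned with a
#'   warning, not an error.
#' @export
qc_filter <- function(x, min_genes_per_cell = 200L, min_cells_per_gene = 3L) {
  stopifnot(inherits(x, "caf_counts"),
            min_genes_per_cell >= 0, min_cells_per_gene >= 0)
  detected <- Matrix::colSums(x$counts > 0)
  keep_cells <- detected >= min_genes_per_cell
  m <- x$counts[, keep_cells, drop = FALSE]
  keep_genes <- Matrix::rowSums(m > 0) >= min_cells_per_gene
  m <- m[keep_genes, , drop = FALSE]
  if (nrow(m) == 0L || ncol(m) == 0L)
    .warnf("qc_filter removed all %s", if (ncol(m) == 0L) "cells" else "genes")
  new_caf_counts(m, x$cell_meta[keep_cells, , drop = FALSE],
                 gene_table = x$gene_table[
                   match(rownames(m), x$gene_table$gene_symbol), ,
                   drop = FALSE])
}
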