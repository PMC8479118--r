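#' Read a gene-by-cell count matrix from a MatrixMarket triplet
#'
#' Reads a CellRanger-style triplet: a MatrixMarket coordinate file plus one
#' gene identifier and one cell identifier per line in two companion TSVs
#' (first column used, no header). Counts mapped to duplicate gene symbols
#' are summed into a single row.
#'
#' @param mtx_path Path to the `.mtx` coordinate file (1-based indices).
#' @param genes_path Path to the gene id TSV (rows of the matrix).
#' @param cells_path Path to the cell id TSV (columns of the matrix).
#' @return A sparse `dgCMatrix` with gene row names and cell column names.
#' @export
read_counts <- function(mtx_path, genes_path, cells_path) {
  for (f in c(mtx_path, genes_path, cells_path)) {
    if (!file.exists(f)) stop("file not found: ", f)
  }
  m <- Matrix::readMM(mtx_path)
  genes <- utils::read.delim(genes_path, header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  cells <- utils::read.delim(cells_path, header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != length(genes)) {
    stop("matrix has ", nrow(m), " rows but ", length(genes), " gene ids")
  }
  if (ncol(m) != length(cells)) {
    stop("matrix has ", ncol(m), " columns but ", length(cells), " cell ids")
  }
  vals <- if (methods::is(m, "sparseMatrix")) m@x else as.vector(m)
  bad <- which(vals != round(vals) | vals < 0)
  if (length(bad)) {
    stop("non-integer or negative count value ", vals[bad[1]], " in ", mtx_path)
  }
  if (anyDuplicated(cells)) stop("duplicated cell ids in ", cells_path)
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(genes, cells)
  sum_duplicate_genes(m)
}

# Rows sharing a gene symbol are summed (first occurrence keeps its position).
sum_duplicate_genes <- function(m) {
  g <- rownames(m)
  if (is.null(g) || !anyDuplicated(g)) return(m)
  keep <- !duplicated(g)
  fac <- factor(g, levels = g[keep])
  agg <- Matrix::fac2sparse(fac)                     # unique genes x rows
  out <- agg %*% m
  rownames(out) <- levels(fac)
  methods::as(out, "CsparseMatrix")
}

#' Write a count matrix as a MatrixMarket triplet
#'
#' Writes `matrix.mtx` (integer general coordinate, 1-based, genes as rows),
#' `genes.tsv` and `cells.tsv` under `dir`. Round-trips bit-exactly with
#' [read_counts()] on integer data.
#'
#' @param counts Matrix (sparse or dense) with gene row names and cell
#'   column names.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the three file paths.
#' @export
write_counts <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "TsparseMatrix")
  mtx <- file.path(dir, "matrix.mtx")
  con <- file(mtx, "w")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               paste(nrow(counts), ncol(counts), length(counts@x))), con)
  ord <- order(counts@j, counts@i)
  writeLines(sprintf("%d %d %d", counts@i[ord] + 1L, counts@j[ord] + 1L,
                     as.integer(counts@x[ord])), con)
  close(con)
  gf <- file.path(dir, "genes.tsv")
  cf <- file.path(dir, "cells.tsv")
  writeLines(rownames(counts), gf)
  writeLines(colnames(counts), cf)
  invisible(c(mtx = mtx, genes = gf, cells = cf))
}

#' Read per-cell annotations from a TSV
#'
#' The file must be tab-delimited with a header containing at least
#' `cell_id`, `replicate` and `condition`; an optional `group` column (cell
#' type or spatial region) defaults to the single label `"all"`.
#'
#' @param tsv_path Path to the annotation TSV.
#' @return A data.frame with columns `cell_id`, `replicate`, `condition`,
#'   `group`, in file order.
#' @export
read_cell_annotations <- function(tsv_path) {
  ann <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  for (col in c("cell_id", "replicate", "condition")) {
    if (!col %in% names(ann)) stop("missing required column: ", col)
  }
  if (anyDuplicated(ann$cell_id)) {
    stop("duplicated cell_id: ", ann$cell_id[duplicated(ann$cell_id)][1])
  }
  if (!"group" %in% names(ann)) ann$group <- "all"
  ann[, c("cell_id", "replicate", "condition", "group")]
}

#' Write per-cell annotations to a TSV
#' @param annotations Annotation data.frame.
#' @param path Output path.
#' @export
write_cell_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Remove genes detected in too few cells
#'
#' A gene is "detected" in a cell when its count is > 0; genes detected in
#' fewer than `min_cells` cells are removed. Row order is preserved and the
#' operation is idempotent.
#'
#' @param counts Genes-by-cells count matrix.
#' @param min_cells Minimum number of cells with a nonzero count (default 3).
#' @return The filtered matrix (possibly with zero rows).
#' @export
filter_genes <- function(counts, min_cells = 3) {
  detected <- Matrix::rowSums(counts > 0)
  counts[detected >= min_cells, , drop = FALSE]
}

#' Keep only groups testable in both conditions
#'
#' Retains cell groups (cell types or spatial regions) with at least
#' `min_cells_per_condition` cells in *each* condition, dropping the cells
#' of all other groups from both the matrix and the annotations.
#'
#' @param counts Genes-by-cells count matrix.
#' @param annotations Annotation data.frame with `condition` and `group`.
#' @param min_cells_per_condition Minimum cells per (group, condition).
#' @return A list with the filtered `counts` and `annotations`.
#' @export
filter_groups <- function(counts, annotations, min_cells_per_condition = 3) {
  if (length(unique(annotations$condition)) < 2) {
    stop("no testable groups: fewer than two conditions present")
  }
  tab <- table(annotations$group, annotations$condition)
  ok <- rownames(tab)[apply(tab >= min_cells_per_condition, 1, all)]
  if (!length(ok)) stop("no testable groups")
  keep <- annotations$group %in% ok
  list(counts = counts[, keep, drop = FALSE],
       annotations = annotations[keep, , drop = FALSE])
}
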