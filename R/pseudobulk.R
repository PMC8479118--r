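#' Aggregate single-cell counts into pseudobulk samples
#'
#' Sums counts over all cells sharing a (replicate, condition) pair, turning
#' a genes-by-cells matrix into a genes-by-samples matrix -- the aggregation
#' step that lets bulk RNA-seq statistical machinery operate on single-cell
#' data. Columns are ordered by condition, then replicate (lexicographic).
#'
#' @param counts Genes-by-cells count matrix (sparse or dense).
#' @param annotations Data.frame with `cell_id`, `replicate`, `condition`;
#'   rows must match matrix columns (matched by `cell_id` when column names
#'   are present, by position otherwise).
#' @return A list of class `pseudobulk` with `counts` (dense genes-by-samples
#'   integer matrix) and `samples` (data.frame of `replicate`, `condition`).
#' @export
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 0, 1, 0, 2), 2, 4, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), paste0("c", 1:4)))
#' ann <- data.frame(cell_id = paste0("c", 1:4),
#'                   replicate = c("A", "A", "B", "B"), condition = "ctl")
#' aggregate_pseudobulk(m, ann)$counts
aggregate_pseudobulk <- function(counts, annotations) {
  if (!nrow(counts) || !ncol(counts)) stop("empty count matrix")
  ann <- align_annotations(counts, annotations)
  if (anyNA(ann$replicate) || anyNA(ann$condition)) {
    stop("every cell needs replicate and condition labels")
  }
  key <- paste(ann$condition, ann$replicate, sep = "\r")
  lev <- sort(unique(key))
  fac <- factor(key, levels = lev)
  memb <- Matrix::sparse.model.matrix(~ 0 + fac)        # cells x samples
  pb <- as.matrix(counts %*% memb)
  parts <- do.call(rbind, strsplit(lev, "\r", fixed = TRUE))
  samples <- data.frame(replicate = parts[, 2], condition = parts[, 1],
                        stringsAsFactors = FALSE)
  colnames(pb) <- paste(samples$condition, samples$replicate, sep = ":")
  rownames(pb) <- rownames(counts)
  structure(list(counts = pb, samples = samples), class = "pseudobulk")
}

align_annotations <- function(counts, annotations) {
  if (!is.null(colnames(counts)) && "cell_id" %in% names(annotations)) {
    idx <- match(colnames(counts), annotations$cell_id)
    if (anyNA(idx)) stop("annotations missing cells: ",
                         colnames(counts)[which(is.na(idx))[1]])
    annotations <- annotations[idx, , drop = FALSE]
  } else if (nrow(annotations) != ncol(counts)) {
    stop("annotation rows do not match matrix columns")
  }
  annotations
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat("pseudobulk:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  invisible(x)
}

#' Shuffle replicate labels to form pseudo-replicates
#'
#' Permutes the replicate label of every cell uniformly at random *within
#' each condition*, leaving condition and group labels untouched. The
#' multiset of replicate labels per condition is preserved exactly, so
#' downstream pseudobulk samples keep their sizes while the biological
#' between-replicate structure is destroyed.
#'
#' @param annotations Annotation data.frame.
#' @param seed Integer seed.
#' @return The annotations with permuted `replicate` column.
#' @export
shuffle_pseudoreplicates <- function(annotations, seed) {
  set.seed(seed)
  out <- annotations
  for (cond in unique(annotations$condition)) {
    idx <- which(annotations$condition %in% cond)
    out$replicate[idx] <- annotations$replicate[idx][sample(length(idx))]
  }
  out
}

#' Log-normalize single-cell counts to counts per 10,000
#'
#' The standard single-cell normalization: each cell's counts are scaled to
#' a library size of 10,000 and natural-log transformed with a pseudocount
#' of 1, `ln(1 + 1e4 * c / libsize)`. Doubling every count of a cell leaves
#' its column unchanged.
#'
#' @param counts Genes-by-cells count matrix (sparse or dense).
#' @return A matrix of the same shape and sparsity pattern.
#' @export
normalize_cp10k_log <- function(counts) {
  lib <- Matrix::colSums(counts)
  if (any(lib == 0)) {
    nm <- colnames(counts)[which(lib == 0)[1]]
    stop("cell with zero total count: ", if (is.null(nm)) which(lib == 0)[1] else nm)
  }
  if (methods::is(counts, "sparseMatrix")) {
    out <- methods::as(counts, "CsparseMatrix")
    scale <- rep.int(1e4 / lib, diff(out@p))
    out@x <- log1p(out@x * scale)
    out
  } else {
    log1p(sweep(counts, 2, lib, "/") * 1e4)
  }
}

#' Log2 counts-per-million for pseudobulk samples
#'
#' Computes `log2(CPM)` with a prior count scaled by relative library size
#' (sample `j` receives `prior_count * lib_j / mean(lib)`), which keeps the
#' transform finite at zero counts and scale-equivariant across samples:
#' `log2(1e6 * (count + pc_j) / (lib_j + 2 * pc_j))`.
#'
#' @param pb A `pseudobulk` object or a genes-by-samples count matrix.
#' @param prior_count Prior count before scaling (default 2).
#' @return A dense genes-by-samples matrix of log2-CPM values.
#' @export
log_cpm <- function(pb, prior_count = 2) {
  m <- if (inherits(pb, "pseudobulk")) pb$counts else as.matrix(pb)
  lib <- colSums(m)
  if (any(lib == 0)) stop("sample with zero library size")
  pc <- prior_count * lib / mean(lib)
  t(log2(t(m + rep(pc, each = nrow(m))) / (lib + 2 * pc) * 1e6))
}
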