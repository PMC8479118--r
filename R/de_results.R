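#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: the adjusted value of the i-th smallest p is
#' `min over j >= i of p_(j) * m / j`, capped at 1. `NaN`/`NA` inputs give
#' `NA` outputs and are excluded from `m`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values of the same length.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

# Uniform result table shared by all DE tests. Ranking key: |statistic|
# descending, then p ascending, then gene id -- the statistic dominates so
# that floating-point underflow of p (everything below ~2e-308 collapsing to
# 0) never scrambles the top of the ranking.
de_result_table <- function(gene, log2fc, statistic, p, method) {
  statistic[!is.finite(statistic) & !is.na(statistic)] <-
    sign(statistic[!is.finite(statistic) & !is.na(statistic)]) * .Machine$double.xmax
  p <- pmin(pmax(p, 0), 1)
  ord <- order(-abs(statistic), p, gene)
  rank <- integer(length(gene))
  rank[ord] <- seq_along(gene)
  out <- data.frame(gene = gene, log2fc = log2fc, statistic = statistic,
                    pval = p, qval = bh_adjust(p), rank = rank,
                    method = method, stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Genes ordered by differential-expression rank
#' @param res A DE result table.
#' @return Character vector of gene ids, most significant first.
#' @export
ranked_genes <- function(res) {
  res$gene[order(res$rank)]
}

#' Per-gene log2 fold changes between two conditions
#'
#' Two conventions: `"sc_mean_log"` is the difference in mean log-normalized
#' (CP10K) expression between conditions, rescaled to log2; `"pb_cpm_ratio"`
#' is `log2((mean CPM_treatment + prior) / (mean CPM_control + prior))`.
#' The sign is treatment minus control (second condition level vs first).
#'
#' @param counts Genes-by-cells counts (`sc_mean_log`) or a `pseudobulk`
#'   object / genes-by-samples matrix (`pb_cpm_ratio`).
#' @param annotations Cell annotations (`sc_mean_log`) or sample condition
#'   labels (`pb_cpm_ratio`; taken from the pseudobulk object if absent).
#' @param mode `"sc_mean_log"` or `"pb_cpm_ratio"`.
#' @param prior Pseudocount for the CPM ratio (default 1).
#' @return Numeric vector of per-gene log2 fold changes.
#' @export
compute_log2fc <- function(counts, annotations = NULL,
                           mode = c("sc_mean_log", "pb_cpm_ratio"),
                           prior = 1) {
  mode <- match.arg(mode)
  if (mode == "sc_mean_log") {
    ann <- align_annotations(counts, annotations)
    cond <- condition_levels(ann$condition)
    y <- normalize_cp10k_log(counts)
    a <- Matrix::rowMeans(y[, ann$condition == cond[1], drop = FALSE])
    b <- Matrix::rowMeans(y[, ann$condition == cond[2], drop = FALSE])
    (b - a) / log(2)
  } else {
    if (inherits(counts, "pseudobulk")) {
      condition <- counts$samples$condition
      m <- counts$counts
    } else {
      condition <- annotations
      m <- as.matrix(counts)
    }
    cond <- condition_levels(condition)
    cpm <- t(t(m) / colSums(m)) * 1e6
    a <- rowMeans(cpm[, condition == cond[1], drop = FALSE])
    b <- rowMeans(cpm[, condition == cond[2], drop = FALSE])
    log2((b + prior) / (a + prior))
  }
}

# Two condition levels, control first when recognizably named.
condition_levels <- function(condition) {
  lev <- sort(unique(as.character(condition)))
  if (length(lev) != 2) stop("exactly two condition levels are required")
  ctl <- c("control", "ctl", "ctrl", "unst", "unstim", "reference")
  if (any(tolower(lev) %in% ctl) && !tolower(lev[1]) %in% ctl) lev <- rev(lev)
  lev
}
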