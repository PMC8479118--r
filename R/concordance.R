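#' Area under the concordance curve between two gene rankings
#'
#' For each list depth j = 1..k, the size of the intersection of the top-j
#' genes of both rankings is computed; the AUCC is the sum of these
#' intersection sizes divided by its maximum possible value k(k+1)/2.
#' 1 means identical top-k behavior, 0 disjoint top-k sets. Symmetric in
#' its arguments.
#'
#' @param ranking_a,ranking_b Duplicate-free character vectors of gene ids,
#'   most significant first (see [ranked_genes()]).
#' @param k Depth of the concordance curve (default 500); lowered with a
#'   warning when a ranking is shorter.
#' @return AUCC in \[0, 1\].
#' @export
#' @examples
#' aucc(c("g1", "g2", "g3"), c("g2", "g1", "g4"), k = 3)  # 4/6
aucc <- function(ranking_a, ranking_b, k = 500) {
  if (!length(ranking_a) || !length(ranking_b)) stop("empty ranking")
  if (anyDuplicated(ranking_a) || anyDuplicated(ranking_b)) {
    stop("rankings must be duplicate-free")
  }
  if (k < 1) stop("k must be >= 1")
  kmax <- min(length(ranking_a), length(ranking_b))
  if (k > kmax) {
    warning("k lowered to ", kmax, " (length of shortest ranking)")
    k <- kmax
  }
  pa <- match(ranking_b[seq_len(k)], ranking_a[seq_len(k)])
  # depth at which each shared gene enters both prefixes
  depth <- pmax(pa[!is.na(pa)], which(!is.na(pa)))
  sum(k - depth + 1) / (k * (k + 1) / 2)
}

#' Signed Spearman correlation between two DE result tables
#'
#' Each gene's absolute test statistic is signed by its log fold change,
#' and the Spearman correlation of the signed scores is computed over the
#' shared gene universe (inner join; ties receive average ranks).
#'
#' @param res_a,res_b DE result tables.
#' @return Correlation in \[-1, 1\].
#' @export
signed_spearman <- function(res_a, res_b) {
  shared <- intersect(res_a$gene, res_b$gene)
  if (length(shared) < 3) stop("fewer than 3 shared genes")
  ia <- match(shared, res_a$gene)
  ib <- match(shared, res_b$gene)
  sa <- abs(res_a$statistic[ia]) * sign(res_a$log2fc[ia])
  sb <- abs(res_b$statistic[ib]) * sign(res_b$log2fc[ib])
  stats::cor(sa, sb, method = "spearman")
}

#' AUCC within expression terciles
#'
#' Splits the shared gene universe into three (near-)equally sized bins of
#' lowly, moderately and highly expressed genes by mean expression (ties
#' broken by gene id), and recomputes the AUCC within each bin, restricting
#' both rankings to the bin's genes and capping k at the bin size.
#'
#' @param res_sc,res_bulk DE result tables.
#' @param mean_expr Named per-gene mean expression covering the shared
#'   universe.
#' @param k AUCC depth (capped at the bin size).
#' @return Named numeric vector `c(low =, mid =, high =)`.
#' @export
aucc_by_expression_tercile <- function(res_sc, res_bulk, mean_expr, k = 500) {
  shared <- intersect(intersect(res_sc$gene, res_bulk$gene), names(mean_expr))
  n <- length(shared)
  if (n < 3) stop("fewer than 3 shared genes")
  ord <- shared[order(mean_expr[shared], shared)]
  base <- n %/% 3
  sizes <- base + (seq_len(3) <= n %% 3)
  bin <- rep(1:3, times = sizes)
  out <- numeric(3)
  for (b in 1:3) {
    genes <- ord[bin == b]
    ra <- ranked_genes(res_sc)
    rb <- ranked_genes(res_bulk)
    out[b] <- suppressWarnings(
      aucc(ra[ra %in% genes], rb[rb %in% genes], k = min(k, length(genes))))
  }
  names(out) <- c("low", "mid", "high")
  out
}

#' Putative false-positive genes of a single-cell DE analysis
#'
#' Genes called DE by the matched bulk analysis (q < `fdr`) are excluded;
#' the `n_top` top-ranked remaining genes of the single-cell analysis are
#' returned -- highly ranked single-cell genes with no bulk support.
#'
#' @param res_sc,res_bulk DE result tables on a shared universe.
#' @param fdr Bulk FDR threshold (default 0.10).
#' @param n_top Number of genes to return (default 100).
#' @return Character vector of gene ids (possibly fewer than `n_top`).
#' @export
false_positive_genes <- function(res_sc, res_bulk, fdr = 0.10, n_top = 100) {
  shared <- intersect(res_sc$gene, res_bulk$gene)
  bulk_de <- res_bulk$gene[res_bulk$qval < fdr]
  keep <- setdiff(shared, bulk_de)
  ranked <- ranked_genes(res_sc)
  utils::head(ranked[ranked %in% keep], n_top)
}

#' Putative false-negative genes of a single-cell DE analysis
#'
#' Genes called DE in bulk (q < `fdr`) whose single-cell q exceeds `fdr`,
#' ordered by bulk rank; the first `n_top` are returned.
#'
#' @inheritParams false_positive_genes
#' @return Character vector of gene ids (possibly fewer than `n_top`).
#' @export
false_negative_genes <- function(res_sc, res_bulk, fdr = 0.10, n_top = 100) {
  shared <- intersect(res_sc$gene, res_bulk$gene)
  bulk_de <- intersect(res_bulk$gene[res_bulk$qval < fdr], shared)
  sc_q <- res_sc$qval[match(bulk_de, res_sc$gene)]
  miss <- bulk_de[sc_q > fdr]
  ranked <- ranked_genes(res_bulk)
  utils::head(ranked[ranked %in% miss], n_top)
}

#' Mean expression quantile of a method's top-ranked genes
#'
#' Converts each gene's mean expression into its quantile via the empirical
#' cumulative distribution function (ties averaged), then averages the
#' quantile over the `n_top` top-ranked genes. Values near 1 indicate a
#' ranking biased toward highly expressed genes; an unbiased ranking gives
#' about 0.5.
#'
#' @param res A DE result table.
#' @param mean_expr Named per-gene mean expression.
#' @param n_top Number of top-ranked genes (default 200).
#' @return Mean expression quantile in \[0, 1\].
#' @export
expression_quantile_bias <- function(res, mean_expr, n_top = 200) {
  if (nrow(res) < n_top) stop("fewer genes than n_top")
  expr <- mean_expr[res$gene]
  quant <- rank(expr, ties.method = "average") / length(expr)
  top <- order(res$rank)[seq_len(n_top)]
  mean(quant[top])
}

#' Spike-in expression bias of a DE method
#'
#' Spearman correlation between the mean expression of equal-concentration
#' spike-ins and the -log10 p-value each was assigned. Under a correct
#' analysis no spike-in is differentially expressed, so any correlation
#' with abundance is an expression bias. P-values are floored at 1e-300
#' before the log; spike-ins detected in fewer than `min_cells` cells are
#' dropped when detection counts are supplied.
#'
#' @param res A DE result table over spike-ins.
#' @param spikein_mean_expr Named per-spike-in mean expression.
#' @param min_cells Detection threshold (default 3).
#' @param n_cells_detected Optional named vector of cells-detected counts.
#' @return Spearman correlation (0 when either input is constant).
#' @export
spikein_bias <- function(res, spikein_mean_expr, min_cells = 3,
                         n_cells_detected = NULL) {
  keep <- intersect(res$gene, names(spikein_mean_expr))
  if (!is.null(n_cells_detected)) {
    keep <- keep[n_cells_detected[keep] >= min_cells]
  }
  if (length(keep) < 3) stop("fewer than 3 retained spike-ins")
  p <- pmax(res$pval[match(keep, res$gene)], 1e-300)
  x <- spikein_mean_expr[keep]
  y <- -log10(p)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y, method = "spearman")
}
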