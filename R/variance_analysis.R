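#' Per-gene expression variance across pseudobulk samples
#'
#' Sample variance (n - 1 denominator) of normalized expression across
#' pseudobulk samples, computed within each condition and averaged across
#' conditions so that a genuine condition effect is never counted as
#' replicate variability.
#'
#' @param pb A `pseudobulk` object.
#' @param scale Normalization applied to the counts before the variance
#'   (a function of the matrix; default [log_cpm()]).
#' @param within_condition Compute within conditions and average (default);
#'   `FALSE` uses all samples at once.
#' @return Named per-gene variance vector.
#' @export
pseudobulk_variance <- function(pb, scale = log_cpm, within_condition = TRUE) {
  y <- scale(pb$counts)
  if (!within_condition) return(matrixRowVars(y))
  conds <- unique(pb$samples$condition)
  vs <- vapply(conds, function(cd) {
    cols <- pb$samples$condition == cd
    if (sum(cols) < 2) stop("a condition has a single sample")
    matrixRowVars(y[, cols, drop = FALSE])
  }, numeric(nrow(y)))
  if (!is.matrix(vs)) vs <- matrix(vs, nrow = nrow(y))
  stats::setNames(rowMeans(vs), rownames(y))
}

#' Delta-variance: what shuffling replicates does to pseudobulk variance
#'
#' Aggregates biological pseudobulks, then shuffles replicate labels within
#' conditions ([shuffle_pseudoreplicates()]) and re-aggregates, computing
#' the per-gene variance of log2-CPM expression in both. The difference
#' `delta = var_pseudo - var_bio` is negative when pseudo-replicates lose
#' the variance that biological replication carries -- the signature of DE
#' methods that ignore replicates.
#'
#' @param counts Genes-by-cells count matrix.
#' @param annotations Cell annotations with `replicate` and `condition`.
#' @param seed Seed for the single shuffle draw.
#' @return A data.frame of class `delta_variance` with columns `gene`,
#'   `var_bio`, `var_pseudo`, `delta`.
#' @export
delta_variance <- function(counts, annotations, seed) {
  pb_bio <- aggregate_pseudobulk(counts, annotations)
  shuffled <- shuffle_pseudoreplicates(align_annotations(counts, annotations),
                                       seed)
  pb_pseudo <- aggregate_pseudobulk(counts, shuffled)
  var_bio <- pseudobulk_variance(pb_bio)
  var_pseudo <- pseudobulk_variance(pb_pseudo)
  gene <- rownames(pb_bio$counts)
  if (is.null(gene)) gene <- sprintf("gene%d", seq_along(var_bio))
  out <- data.frame(gene = gene, var_bio = var_bio, var_pseudo = var_pseudo,
                    delta = var_pseudo - var_bio, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("delta_variance", "data.frame")
  out
}

#' Fraction of genes whose variance decreased in pseudo-replicates
#' @param dv A [delta_variance()] table.
#' @return Fraction of genes with `delta < 0` (strict).
#' @export
fraction_variance_decreased <- function(dv) {
  if (!nrow(dv)) stop("empty delta-variance table")
  mean(dv$delta < 0)
}

#' Correlates of the delta-variance
#'
#' Spearman correlations of delta-variance with mean expression and with
#' the biological variance, plus the partial correlation of each given the
#' other (computed on ranks with the standard two-variable partial-
#' correlation formula). Disentangles whether variance loss tracks
#' expression level per se or the expression variance that high-expression
#' genes tend to have.
#'
#' @param dv A [delta_variance()] table.
#' @param mean_expr Per-gene mean expression (aligned to `dv`).
#' @param var_bio Per-gene biological variance (defaults to `dv$var_bio`).
#' @return Named list `cor_mean`, `cor_var`, `pcor_mean`, `pcor_var`.
#' @export
delta_variance_correlations <- function(dv, mean_expr, var_bio = dv$var_bio) {
  if (nrow(dv) < 4) stop("at least 4 genes are required")
  rd <- rank(dv$delta)
  rm_ <- rank(mean_expr)
  rv <- rank(var_bio)
  if (stats::sd(rd) == 0 || stats::sd(rm_) == 0 || stats::sd(rv) == 0) {
    warning("zero-variance input: correlations undefined")
    return(list(cor_mean = NaN, cor_var = NaN, pcor_mean = NaN, pcor_var = NaN))
  }
  r_dm <- stats::cor(rd, rm_)
  r_dv <- stats::cor(rd, rv)
  r_mv <- stats::cor(rm_, rv)
  partial <- function(rxy, rxz, ryz) {
    (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  }
  list(cor_mean = r_dm, cor_var = r_dv,
       pcor_mean = partial(r_dm, r_dv, r_mv),
       pcor_var = partial(r_dv, r_dm, r_mv))
}

#' DE-gene counts per delta-variance decile
#'
#' Bins genes into `n_bins` equal-size bins by the magnitude of their
#' delta-variance (ascending |delta|; ties broken by gene id) and counts
#' the genes called DE (q < `fdr`) in each bin. A count that rises with the
#' bin index shows that false discoveries concentrate where shuffling
#' replicates destroys the most variance.
#'
#' @param dv A [delta_variance()] table.
#' @param de_results A DE result table on a shared universe.
#' @param fdr FDR threshold (default 0.05).
#' @param n_bins Number of bins (default 10).
#' @return Integer vector of DE-gene counts, lowest |delta| bin first.
#' @export
decile_de_counts <- function(dv, de_results, fdr = 0.05, n_bins = 10) {
  shared <- intersect(dv$gene, de_results$gene)
  ad <- abs(dv$delta[match(shared, dv$gene)])
  ord <- order(ad, shared)
  n <- length(shared)
  base <- n %/% n_bins
  sizes <- base + (seq_len(n_bins) <= n %% n_bins)
  bin <- integer(n)
  bin[ord] <- rep(seq_len(n_bins), times = sizes)
  sig <- de_results$gene[de_results$qval < fdr]
  vapply(seq_len(n_bins), function(b) sum(shared[bin == b] %in% sig),
         integer(1))
}
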