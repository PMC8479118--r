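#' Pseudobulk differential expression tests
#'
#' Runs one of five tests on a genes-by-samples pseudobulk matrix with a
#' two-group design. The count-based tests fit per-gene NB GLMs with log
#' library-size offsets on moderated dispersions from
#' [fit_nb_dispersion()]: `nb_lrt` (likelihood-ratio chi-square on 1 df,
#' shrunk dispersions), `nb_qlf` (quasi-likelihood F-test: trended
#' dispersions plus an empirical-Bayes-squeezed per-gene quasi-dispersion),
#' and `nb_wald` (coefficient over its standard error from the Fisher
#' information, normal reference, shrunk dispersions). The linear-model
#' tests operate on log2-CPM: `mod_t_trend` (moderated t with the
#' mean-variance trend folded into the prior variance) and `voom`
#' (mean-variance trend converted to per-observation precision weights,
#' weighted least squares, then moderated t).
#'
#' Genes with zero counts in every sample have no estimable dispersion and
#' are excluded from the result table.
#'
#' @param pb A `pseudobulk` object, or a genes-by-samples count matrix with
#'   `condition` supplied.
#' @param method One of `"nb_lrt"`, `"nb_qlf"`, `"nb_wald"`,
#'   `"mod_t_trend"`, `"voom"`.
#' @param condition Per-sample condition labels (taken from the pseudobulk
#'   object when omitted).
#' @param dispersion Optional precomputed [fit_nb_dispersion()] result,
#'   reused across the NB methods to avoid refitting.
#' @param prior_df Prior degrees of freedom for dispersion shrinkage.
#' @return A DE result table (see [de_single_cell()] for the schema).
#' @export
de_pseudobulk <- function(pb, method = c("nb_lrt", "nb_qlf", "nb_wald",
                                         "mod_t_trend", "voom"),
                          condition = NULL, dispersion = NULL,
                          prior_df = 10) {
  method <- match.arg(method)
  if (inherits(pb, "pseudobulk")) {
    m <- pb$counts
    if (is.null(condition)) condition <- pb$samples$condition
  } else {
    m <- as.matrix(pb)
  }
  lev <- condition_levels(condition)
  grp2 <- condition == lev[2]
  if (sum(grp2) < 2 || sum(!grp2) < 2) {
    stop("cannot estimate within-group variance: a condition has < 2 samples")
  }
  gene <- rownames(m)
  if (is.null(gene)) gene <- sprintf("gene%d", seq_len(nrow(m)))
  nonzero <- rowSums(m) > 0
  Y <- m[nonzero, , drop = FALSE]
  gene <- gene[nonzero]
  lib <- colSums(m)
  n <- ncol(Y)

  if (method %in% c("nb_lrt", "nb_qlf", "nb_wald")) {
    if (is.null(dispersion)) {
      dispersion <- fit_nb_dispersion(m, condition, prior_df = prior_df)
    }
    idx <- match(gene, dispersion$gene)
    phi <- if (method == "nb_qlf") {
      dispersion$trend_dispersion[idx]
    } else {
      dispersion$shrunk_dispersion[idx]
    }
    phi <- pmax(phi, 1e-8)
    fa <- nb_fit_group(Y[, !grp2, drop = FALSE], lib[!grp2], phi)
    fb <- nb_fit_group(Y[, grp2, drop = FALSE], lib[grp2], phi)
    f0 <- nb_fit_group(Y, lib, phi)
    log2fc <- (fb$beta - fa$beta) / log(2)
    dev <- pmax(2 * (fa$kernel + fb$kernel - f0$kernel), 0)

    if (method == "nb_lrt") {
      p <- stats::pchisq(dev, 1, lower.tail = FALSE)
      return(de_result_table(gene, log2fc, dev, p, method))
    }
    if (method == "nb_wald") {
      se <- sqrt(1 / pmax(fa$info, 1e-12) + 1 / pmax(fb$info, 1e-12))
      z <- (fb$beta - fa$beta) / se
      z[dev == 0 & abs(fb$beta - fa$beta) < 1e-12] <- 0
      p <- 2 * stats::pnorm(-abs(z))
      return(de_result_table(gene, log2fc, z, p, method))
    }
    # nb_qlf
    sat <- nb_kernel_saturated(Y, phi)
    resid_dev <- pmax(2 * (sat - fa$kernel - fb$kernel), 0)
    df_resid <- n - 2
    s2 <- resid_dev / df_resid
    ave <- rowMeans(log_cpm(Y))
    mod <- squeeze_variances(s2, df_resid, avg_expr = ave, trend = TRUE)
    Fstat <- dev / pmax(mod$posterior_s2, 1e-12)
    df2 <- min(mod$d0, 1e6) + df_resid
    p <- stats::pf(Fstat, 1, df2, lower.tail = FALSE)
    return(de_result_table(gene, log2fc, Fstat, p, method))
  }

  if (method == "mod_t_trend") {
    Y2 <- log_cpm(Y)
    fit <- two_group_lm(Y2, grp2)
    mod <- squeeze_variances(fit$s2, fit$df, avg_expr = rowMeans(Y2),
                             trend = TRUE)
    t <- fit$coef / sqrt(mod$posterior_s2 * fit$coef_unscaled_var)
    df_t <- min(mod$d0, 1e6) + fit$df
    p <- 2 * stats::pt(-abs(t), df_t)
    return(de_result_table(gene, fit$coef, t, p, method))
  }

  # voom
  Y2 <- log2(t(t(Y + 0.5) / (lib + 1)) * 1e6)
  fit0 <- two_group_lm(Y2, grp2)
  sx <- rowMeans(Y2) + mean(log2(lib + 1)) - log2(1e6)  # average log2 count
  sy <- sqrt(sqrt(fit0$s2))                             # sqrt residual SD
  lo <- stats::lowess(sx, sy, f = 0.5)
  pred <- function(x) stats::approx(lo$x, lo$y, xout = x, rule = 2,
                                    ties = mean)$y
  fitted_cpm <- matrix(0, nrow(Y2), n)
  fitted_cpm[, !grp2] <- fit0$mean1
  fitted_cpm[, grp2] <- fit0$mean2
  fitted_logcount <- t(t(fitted_cpm) + log2(lib + 1) - log2(1e6))
  w <- matrix(pmax(pred(fitted_logcount), 1e-6)^-4, nrow(Y2), n)
  fitw <- two_group_lm(Y2, grp2, w = w)
  mod <- squeeze_variances(fitw$s2, fitw$df, trend = FALSE)
  t <- fitw$coef / sqrt(mod$posterior_s2 * fitw$coef_unscaled_var)
  df_t <- min(mod$d0, 1e6) + fitw$df
  p <- 2 * stats::pt(-abs(t), df_t)
  de_result_table(gene, fitw$coef, t, p, "voom")
}

# Per-gene two-group linear model, optionally with observation weights.
# Returns the group means, the coefficient (group2 - group1), its unscaled
# variance multiplier, and the residual variance on n - 2 df.
two_group_lm <- function(Y, grp2, w = NULL) {
  n <- ncol(Y)
  if (is.null(w)) w <- matrix(1, nrow(Y), n)
  wa <- w[, !grp2, drop = FALSE]; wb <- w[, grp2, drop = FALSE]
  ya <- Y[, !grp2, drop = FALSE]; yb <- Y[, grp2, drop = FALSE]
  swa <- rowSums(wa); swb <- rowSums(wb)
  m1 <- rowSums(wa * ya) / swa
  m2 <- rowSums(wb * yb) / swb
  ss <- rowSums(wa * (ya - m1)^2) + rowSums(wb * (yb - m2)^2)
  df <- n - 2
  list(mean1 = m1, mean2 = m2, coef = m2 - m1,
       coef_unscaled_var = 1 / swa + 1 / swb,
       s2 = ss / df, df = df)
}

# Treat every cell as its own replicate, so pseudobulk machinery runs on
# individual cells (aggregation disabled).
#' Disable aggregation: present cells as pseudobulk samples
#'
#' Builds a `pseudobulk` object in which every cell is its own sample, so
#' that the pseudobulk statistical tests can be applied to individual cells
#' (the "aggregation disabled" experiment).
#'
#' @param counts Genes-by-cells count matrix.
#' @param annotations Cell annotations with `condition`.
#' @return A `pseudobulk` object with one sample per cell.
#' @export
cells_as_pseudobulk <- function(counts, annotations) {
  ann <- align_annotations(counts, annotations)
  structure(list(counts = as.matrix(counts),
                 samples = data.frame(replicate = ann$cell_id,
                                      condition = ann$condition,
                                      stringsAsFactors = FALSE)),
            class = "pseudobulk")
}
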