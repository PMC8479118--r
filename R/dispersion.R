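#' Estimate negative binomial dispersions with empirical-Bayes shrinkage
#'
#' Per-gene NB dispersions under a two-group model with log library-size
#' offsets, estimated by profile likelihood (the group rates are profiled
#' out at each candidate dispersion). A lowess trend of log-dispersion
#' against average log-CPM captures the mean-dispersion relationship, and
#' the raw estimates are shrunk toward the trend on the log scale with
#' weights `d / (d + prior_df)` where `d` is the residual degrees of
#' freedom -- the moderation that makes NB tests usable with a handful of
#' replicates.
#'
#' The profile likelihood is maximized over a dense grid in log10-dispersion
#' (floor 1e-8, ceiling 1e3, step 0.1) followed by parabolic interpolation
#' at the optimum.
#'
#' @param pb A `pseudobulk` object, or a genes-by-samples count matrix (a
#'   genes-by-cells matrix works too for the single-cell variant).
#' @param condition Two-level condition labels per column; taken from the
#'   pseudobulk object when omitted.
#' @param prior_df Prior degrees of freedom of the shrinkage (default 10;
#'   `Inf` forces shrunk = trend, 0 forces shrunk = raw).
#' @return A data.frame of class `dispersion_fit` with columns `gene`,
#'   `raw_dispersion`, `trend_dispersion`, `shrunk_dispersion`; all-zero
#'   genes get `NA` and are flagged in the `excluded` attribute.
#' @export
fit_nb_dispersion <- function(pb, condition = NULL, prior_df = 10) {
  if (inherits(pb, "pseudobulk")) {
    m <- pb$counts
    if (is.null(condition)) condition <- pb$samples$condition
  } else {
    m <- as.matrix(pb)
  }
  lev <- condition_levels(condition)
  grp2 <- condition == lev[2]
  if (sum(grp2) < 2 || sum(!grp2) < 2) {
    stop("at least 2 samples per condition are required")
  }
  lib <- colSums(m)
  nonzero <- rowSums(m) > 0
  Y <- m[nonzero, , drop = FALSE]

  lgrid <- seq(-8, 3, by = 0.1)                       # log10 dispersion
  ll <- matrix(-Inf, nrow(Y), length(lgrid))
  for (j in seq_along(lgrid)) {
    ll[, j] <- nb_two_group_profile_ll(Y, lib, grp2, 10^lgrid[j])
  }
  best <- max.col(ll, ties.method = "first")
  raw_l <- lgrid[best]
  interior <- best > 1 & best < length(lgrid)
  if (any(interior)) {
    i <- which(interior)
    y0 <- ll[cbind(i, best[i] - 1L)]
    y1 <- ll[cbind(i, best[i])]
    y2 <- ll[cbind(i, best[i] + 1L)]
    denom <- y0 - 2 * y1 + y2
    shift <- ifelse(denom < 0, 0.5 * (y0 - y2) / denom, 0)
    raw_l[i] <- lgrid[best[i]] + 0.1 * pmin(pmax(shift, -0.5), 0.5)
  }
  raw_nz <- 10^raw_l

  ave <- rowMeans(log_cpm(Y))
  # trend fitted on genes whose optimum is interior (not stuck at the
  # dispersion floor), so floor artifacts cannot drag the trend down
  interior_fit <- raw_l > min(lgrid) + 0.2
  if (sum(interior_fit) >= 20) {
    lo <- stats::lowess(ave[interior_fit], log(raw_nz[interior_fit]), f = 0.5)
    trend_nz <- exp(stats::approx(lo$x, lo$y, xout = ave, rule = 2,
                                  ties = mean)$y)
  } else {
    trend_nz <- rep(exp(stats::median(log(raw_nz))), length(raw_nz))
  }
  d <- ncol(Y) - 2
  shrunk_nz <- if (is.infinite(prior_df)) {
    trend_nz
  } else {
    exp((d * log(raw_nz) + prior_df * log(trend_nz)) / (d + prior_df))
  }

  fill <- function(x) {
    out <- rep(NA_real_, nrow(m))
    out[nonzero] <- x
    out
  }
  gene <- rownames(m)
  if (is.null(gene)) gene <- sprintf("gene%d", seq_len(nrow(m)))
  out <- data.frame(gene = gene, raw_dispersion = fill(raw_nz),
                    trend_dispersion = fill(trend_nz),
                    shrunk_dispersion = fill(shrunk_nz),
                    stringsAsFactors = FALSE)
  attr(out, "prior_df") <- prior_df
  attr(out, "excluded") <- gene[!nonzero]
  class(out) <- c("dispersion_fit", "data.frame")
  out
}

#' Empirical-Bayes squeezing of per-gene variances
#'
#' Moderates per-gene sample variances toward a pooled (or expression-
#' trended) prior by fitting the scaled F hierarchical model: observed
#' variances are assumed `s^2 ~ s0^2 * F(df, d0)`, and the prior degrees of
#' freedom `d0` and prior variance `s0^2` are estimated by matching the
#' moments of `log(s^2)` (a scaled log-F). The posterior variance is
#' `(d0 * s0^2 + df * s^2) / (d0 + df)`, and moderated t-statistics built on
#' it gain `d0` degrees of freedom.
#'
#' @param s2 Per-gene sample variances (length >= 3).
#' @param df Residual degrees of freedom of each `s2` (scalar).
#' @param avg_expr Per-gene average expression, required when `trend = TRUE`.
#' @param trend When `TRUE`, `s0^2` is a lowess function of `avg_expr`
#'   instead of a constant.
#' @return A list of class `moderation_state`: `d0` (prior df, capped at
#'   1e9 when infinite), `s0sq` (prior variance, scalar or per-gene), and
#'   `posterior_s2`.
#' @export
squeeze_variances <- function(s2, df, avg_expr = NULL, trend = FALSE) {
  if (length(s2) < 3) stop("at least 3 genes are required")
  if (length(df) != 1) stop("df must be a scalar")
  if (trend && is.null(avg_expr)) stop("avg_expr is required when trend = TRUE")
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 3) stop("fewer than 3 positive variances")
  e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)

  if (trend) {
    lo <- stats::lowess(avg_expr[ok], e, f = 0.5)
    efit <- stats::approx(lo$x, lo$y, xout = avg_expr, rule = 2,
                          ties = mean)$y
    resid <- e - efit[ok]
  } else {
    efit <- mean(e)
    resid <- e - efit
  }
  evar <- stats::var(resid)
  target <- evar - trigamma(df / 2)
  if (evar < 1e-12) {                 # all variances (locally) identical
    d0 <- 1e9
    s0sq <- if (trend) exp(efit) else mean(s2[ok])
  } else if (target <= 0) {           # less spread than sampling alone
    d0 <- 1e9
    s0sq <- exp(efit)
  } else {
    d0 <- 2 * trigamma_inverse(target)
    if (d0 > 1e9) d0 <- 1e9
    s0sq <- exp(efit + digamma(d0 / 2) - log(d0 / 2))
  }
  posterior <- posterior_variance(s2, df, d0, s0sq)
  structure(list(d0 = d0, s0sq = s0sq, posterior_s2 = posterior),
            class = "moderation_state")
}

# (d0 * s0^2 + df * s^2) / (d0 + df); exact limits at d0 = 0 and d0 >= cap.
posterior_variance <- function(s2, df, d0, s0sq) {
  if (d0 >= 1e9) return(rep_len(s0sq, length(s2)) + 0 * s2)
  if (d0 == 0) return(s2)
  (d0 * s0sq + df * s2) / (d0 + df)
}

# Solve trigamma(x) = y by Newton iteration on the inverse scale.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}
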