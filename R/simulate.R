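#' Simulation parameters for the null single-cell count generator
#'
#' Constructs the full parameter set of the gamma-Poisson (splatter-style)
#' simulator used throughout the package to generate single-cell count data
#' with controllable between-replicate heterogeneity and *no* condition
#' effect.
#'
#' The generative model draws a per-gene base mean from a Gamma distribution,
#' applies a multiplicative log-normal "DE factor" per (gene, replicate) pair
#' to a fraction `de_prob` of genes (this is the between-replicate
#' heterogeneity dial; `de_facLoc = de_facScale = 0` switches it off), draws
#' log-normal cell library sizes, and inflates Poisson noise to negative
#' binomial via a biological coefficient of variation (BCV) term.
#'
#' @param n_genes Number of genes.
#' @param n_cells Total number of cells, split evenly across the
#'   `2 * n_reps_per_group` replicates.
#' @param n_reps_per_group Number of replicates per (future) condition; the
#'   simulator itself assigns no conditions.
#' @param de_prob Probability that a gene receives a replicate DE factor.
#' @param de_facLoc Location (meanlog) of the log-normal DE factor; 0-1 is
#'   the range explored in heterogeneity sweeps.
#' @param de_facScale Scale (sdlog) of the log-normal DE factor.
#' @param de_downProb Probability that a drawn factor is inverted
#'   (reciprocal), making the perturbation a decrease.
#' @param mean_shape,mean_rate Gamma shape/rate of the per-gene base mean.
#' @param lib_loc,lib_scale Meanlog/sdlog of the log-normal cell library size.
#' @param bcv_common Common biological coefficient of variation.
#' @param bcv_df Degrees of freedom of the per-gene BCV inflation.
#' @param seed Integer seed; the simulator is fully deterministic given it.
#'
#' @return A list of class `sim_params`.
#' @export
#' @examples
#' p <- sim_params(n_genes = 200, n_cells = 60, seed = 1)
#' ds <- simulate_null_dataset(p)
#' dim(ds$counts)
sim_params <- function(n_genes = 10000,
                       n_cells = 500,
                       n_reps_per_group = 3,
                       de_prob = 0.5,
                       de_facLoc = 0.5,
                       de_facScale = 0.4,
                       de_downProb = 0.5,
                       mean_shape = 0.6,
                       mean_rate = 0.3,
                       lib_loc = log(2000),
                       lib_scale = 0.2,
                       bcv_common = 0.2,
                       bcv_df = 60,
                       seed = 1L) {
  p <- list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
            n_reps_per_group = as.integer(n_reps_per_group),
            de_prob = de_prob, de_facLoc = de_facLoc,
            de_facScale = de_facScale, de_downProb = de_downProb,
            mean_shape = mean_shape, mean_rate = mean_rate,
            lib_loc = lib_loc, lib_scale = lib_scale,
            bcv_common = bcv_common, bcv_df = bcv_df, seed = as.integer(seed))
  validate_sim_params(p)
  class(p) <- "sim_params"
  p
}

validate_sim_params <- function(p) {
  stopifnot(p$n_genes >= 1, p$n_cells >= 1, p$n_reps_per_group >= 1)
  for (nm in c("de_prob", "de_downProb")) {
    if (p[[nm]] < 0 || p[[nm]] > 1) stop(nm, " must be in [0, 1]")
  }
  for (nm in c("de_facScale", "bcv_common", "lib_scale")) {
    if (p[[nm]] < 0) stop(nm, " must be >= 0")
  }
  if (p$mean_shape <= 0 || p$mean_rate <= 0) stop("Gamma parameters must be > 0")
  if (p$bcv_df <= 0) stop("bcv_df must be > 0")
  invisible(p)
}

# Independent sub-seeds per generative stage, so that (for example) changing
# how many library sizes are drawn never shifts the gene-level draws.
stage_seeds <- function(seed, n = 6L) {
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

#' Simulate a null single-cell dataset with between-replicate heterogeneity
#'
#' Generates a genes-by-cells count matrix in which expected expression
#' depends on the *replicate* a cell belongs to -- never on any experimental
#' condition. Cells are split into `2 * n_reps_per_group` replicates in equal
#' contiguous blocks (remainder cells go to the last replicate); the
#' `condition` annotation column is left unset so that
#' [assign_null_conditions()] can create an artificial two-group design.
#'
#' The recipe: (1) per-gene base mean `lambda_g ~ Gamma(mean_shape,
#' mean_rate)`; (2) per replicate, each gene is selected with probability
#' `de_prob` and receives a factor `exp(N(de_facLoc, de_facScale))`, inverted
#' with probability `de_downProb` (unselected genes get factor 1); (3) cell
#' library size `L_c ~ LogNormal(lib_loc, lib_scale)`; (4) expected count
#' `mu_gc = L_c * lambda_g f_gr / sum_g lambda_g f_gr`; (5) per-gene BCV
#' `B_g = (bcv_common + 1/sqrt(mean mu_g)) * sqrt(bcv_df / chisq(bcv_df))`
#' and counts drawn NB with mean `mu_gc` and dispersion `B_g^2`.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `sim_dataset` with elements `counts` (sparse
#'   genes-by-cells integer matrix), `annotations` (data.frame with columns
#'   `cell_id`, `replicate`, `condition` (NA), `group`), `truth`
#'   (genes-by-replicates matrix of the multiplicative factors actually
#'   applied; 1 where none), and `params`.
#' @export
simulate_null_dataset <- function(params) {
  validate_sim_params(params)
  n_reps <- 2L * params$n_reps_per_group
  if (params$n_cells < n_reps) stop("too few cells")
  ss <- stage_seeds(params$seed)

  set.seed(ss[1])                                     # gene base means
  lambda <- stats::rgamma(params$n_genes, shape = params$mean_shape,
                          rate = params$mean_rate)

  rep_ids <- sprintf("rep%d", seq_len(n_reps))
  set.seed(ss[2])                                     # replicate DE factors
  fac <- matrix(1, params$n_genes, n_reps, dimnames = list(NULL, rep_ids))
  for (r in seq_len(n_reps)) {
    sel <- stats::runif(params$n_genes) < params$de_prob
    f <- exp(stats::rnorm(params$n_genes, params$de_facLoc, params$de_facScale))
    down <- stats::runif(params$n_genes) < params$de_downProb
    f[down] <- 1 / f[down]
    fac[sel, r] <- f[sel]
  }

  set.seed(ss[3])                                     # cell library sizes
  lib <- stats::rlnorm(params$n_cells, params$lib_loc, params$lib_scale)

  # contiguous equal blocks; remainder cells go to the last replicate
  block <- params$n_cells %/% n_reps
  rep_of_cell <- rep(seq_len(n_reps), times = c(rep(block, n_reps - 1L),
                                                params$n_cells - block * (n_reps - 1L)))

  lam_eff <- lambda * fac                             # genes x reps
  prop <- sweep(lam_eff, 2, colSums(lam_eff), "/")    # expression proportions
  mu <- prop[, rep_of_cell, drop = FALSE] *
    rep(lib, each = params$n_genes)                   # genes x cells

  set.seed(ss[4])                                     # BCV inflation
  gene_mean <- rowMeans(mu)
  infl <- sqrt(params$bcv_df / stats::rchisq(params$n_genes, params$bcv_df))
  bcv <- (params$bcv_common + 1 / sqrt(pmax(gene_mean, 1e-12))) * infl
  phi <- bcv^2

  set.seed(ss[5])                                     # NB count sampling
  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                  size = rep(1 / phi, times = params$n_cells)),
                   params$n_genes, params$n_cells)
  gene_ids <- sprintf("gene%d", seq_len(params$n_genes))
  cell_ids <- sprintf("cell%d", seq_len(params$n_cells))
  dimnames(counts) <- list(gene_ids, cell_ids)
  rownames(fac) <- gene_ids

  ann <- data.frame(cell_id = cell_ids,
                    replicate = rep_ids[rep_of_cell],
                    condition = NA_character_,
                    group = "all",
                    stringsAsFactors = FALSE)
  structure(list(counts = Matrix::Matrix(counts, sparse = TRUE),
                 annotations = ann, truth = fac, params = params),
            class = "sim_dataset")
}

#' Randomly assign replicates to artificial treatment/control conditions
#'
#' Half of the replicates (rounding down) are assigned to an artificial
#' "treatment" condition and the rest to "control", uniformly at random.
#' Used to create two-group designs in which no true condition effect exists.
#'
#' @param replicate_ids Character vector of (unique) replicate labels.
#' @param seed Integer seed; the assignment is deterministic given it.
#' @return Named character vector mapping each replicate to `"control"` or
#'   `"treatment"`.
#' @export
#' @examples
#' assign_null_conditions(paste0("rep", 1:6), seed = 1)
assign_null_conditions <- function(replicate_ids, seed) {
  replicate_ids <- as.character(replicate_ids)
  if (anyDuplicated(replicate_ids)) replicate_ids <- unique(replicate_ids)
  n <- length(replicate_ids)
  if (n < 2) stop("at least 2 replicates are required")
  if (n %% 2 == 1) {
    warning("odd number of replicates: assigning floor(n/2) to treatment")
  }
  set.seed(seed)
  treat <- sample(replicate_ids, n %/% 2)
  out <- stats::setNames(rep("control", n), replicate_ids)
  out[treat] <- "treatment"
  out
}

#' Simulate an equal-concentration spike-in panel inside a carrier library
#'
#' Emulates a panel of synthetic RNA species spiked into every cell at
#' fixed, known relative concentrations spanning four orders of magnitude
#' on a log-uniform grid, alongside a "carrier" endogenous transcriptome
#' that dominates each cell's library (as in real spike-in experiments,
#' where normalization is driven by cellular mRNA, not by the spike-ins).
#' Cells are split into two artificial conditions (`n_reps` replicate
#' wells/batches each) that follow the *identical* generative law, so the
#' true fold change is 1 for every spike-in and any inferred differential
#' expression is artifactual.
#'
#' The panel's relative concentrations are identical in every cell (one
#' master mix), but the *total* amount of spike-in RNA captured relative to
#' cellular mRNA varies between wells: each replicate batch receives a
#' log-normal dilution factor (`dilution_scale`) applied to all spike-ins
#' jointly. After library-size normalization against the carrier
#' transcriptome this batch-level variability survives -- the technical
#' analogue of biological replicate heterogeneity, and the reason
#' single-cell tests that pool cells across wells call abundant spike-ins
#' differentially expressed while replicate-aware pseudobulk tests do not.
#'
#' @param n_spikeins Number of spike-in species (>= 2; default 92, the
#'   size of the standard ERCC panel).
#' @param n_cells Total number of cells.
#' @param capture_scale sdlog of the per-cell log-normal capture factor
#'   (overall library-size variation).
#' @param dispersion NB dispersion of counts (default 0.05, the residual
#'   technical noise left once capture variation is modeled; 0 gives
#'   Poisson).
#' @param seed Integer seed.
#' @param n_reps Replicates (wells/batches) per artificial condition.
#' @param dilution_scale sdlog of the per-replicate log-normal dilution of
#'   the whole spike-in panel relative to cellular mRNA (default 0.3).
#' @param n_carrier Number of carrier transcriptome genes (default 500).
#' @param spike_fraction Expected fraction of each library coming from
#'   spike-ins (default 0.05).
#' @param ratio_scale sdlog of the residual per-(replicate, spike-in)
#'   log-normal ratio noise -- batch-specific capture/amplification
#'   efficiency of individual species (default 0.3).
#' @param carrier_het sdlog of the per-(replicate, carrier gene) biological
#'   heterogeneity factor (default 0.3), so the carrier transcriptome
#'   carries the replicate-to-replicate variability real tissues show.
#' @param lambda_range Range of expected per-cell spike-in counts; the
#'   panel is log-uniform across it (default 1e-2 to 1e3, so the least
#'   concentrated species sit at the detection limit).
#' @return A `sim_dataset` list: `counts` ((spike-ins + carriers) x cells),
#'   `annotations` (with both `replicate` and `condition` set), `truth`
#'   (per-spike-in condition-level factor, all 1), `spikein_ids`,
#'   `dilution` (realized per-replicate dilution factors), and
#'   `concentration` (the known per-cell expected spike-in counts at
#'   dilution 1 and capture 1).
#' @export
simulate_spikein_dataset <- function(n_spikeins = 92, n_cells = 500,
                                     capture_scale = 0.5, dispersion = 0.05,
                                     seed = 1L, n_reps = 3L,
                                     dilution_scale = 0.3, n_carrier = 500,
                                     spike_fraction = 0.05,
                                     ratio_scale = 0.3, carrier_het = 0.3,
                                     lambda_range = c(1e-2, 1e3)) {
  if (n_spikeins < 2) stop("n_spikeins must be >= 2")
  if (capture_scale < 0) stop("capture_scale must be >= 0")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (dilution_scale < 0) stop("dilution_scale must be >= 0")
  if (ratio_scale < 0) stop("ratio_scale must be >= 0")
  lambda <- 10^seq(log10(lambda_range[1]), log10(lambda_range[2]),
                   length.out = n_spikeins)
  ss <- stage_seeds(seed, 5L)
  n_reps <- as.integer(n_reps)
  n_grp <- 2L * n_reps
  block0 <- n_cells %/% n_grp
  rep_idx <- rep(seq_len(n_grp), times = c(rep(block0, n_grp - 1L),
                                           n_cells - block0 * (n_grp - 1L)))

  set.seed(ss[1])
  capture <- stats::rlnorm(n_cells, 0, capture_scale)
  set.seed(ss[3])
  carrier <- stats::rgamma(n_carrier, shape = 0.6, rate = 0.3)
  carrier <- carrier * sum(lambda) * (1 - spike_fraction) /
    (spike_fraction * sum(carrier))
  set.seed(ss[4])
  dilution <- stats::rlnorm(n_grp, 0, dilution_scale)
  set.seed(ss[5])
  ratio_fac <- matrix(exp(stats::rnorm(n_spikeins * n_grp, 0, ratio_scale)),
                      n_spikeins, n_grp)
  carrier_fac <- matrix(exp(stats::rnorm(n_carrier * n_grp, 0, carrier_het)),
                        n_carrier, n_grp)

  mu <- rbind(outer(lambda, capture) *
                rep(dilution[rep_idx], each = n_spikeins) *
                ratio_fac[, rep_idx, drop = FALSE],
              outer(carrier, capture) * carrier_fac[, rep_idx, drop = FALSE])

  set.seed(ss[2])
  if (dispersion == 0) {
    counts <- matrix(stats::rpois(length(mu), as.vector(mu)), nrow(mu))
  } else {
    counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                    size = 1 / dispersion), nrow(mu))
  }
  spike_ids <- sprintf("spikein%d", seq_len(n_spikeins))
  ids <- c(spike_ids, sprintf("carrier%d", seq_len(n_carrier)))
  cell_ids <- sprintf("cell%d", seq_len(n_cells))
  dimnames(counts) <- list(ids, cell_ids)

  ann <- data.frame(cell_id = cell_ids,
                    replicate = sprintf("rep%d", rep_idx),
                    condition = ifelse(rep_idx <= n_reps, "control", "treatment"),
                    group = "all",
                    stringsAsFactors = FALSE)
  truth <- matrix(1, n_spikeins, 1, dimnames = list(spike_ids, "factor"))
  structure(list(counts = Matrix::Matrix(counts, sparse = TRUE),
                 annotations = ann, truth = truth,
                 spikein_ids = spike_ids,
                 dilution = stats::setNames(dilution,
                                            sprintf("rep%d", seq_len(n_grp))),
                 concentration = stats::setNames(lambda, spike_ids)),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset:", nrow(x$counts), "genes x", ncol(x$counts), "cells;",
      length(unique(x$annotations$replicate)), "replicates\n")
  invisible(x)
}
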