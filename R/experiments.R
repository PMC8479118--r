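#' Run one DE method in a given analysis mode
#'
#' Dispatches a method descriptor of the form `"mode:method"` where mode is
#' `sc` (test individual cells), `pb` (aggregate to pseudobulk first), `pr`
#' (shuffle replicate labels into pseudo-replicates, then aggregate), or
#' `cells` (run a pseudobulk test on individual cells, aggregation
#' disabled). Examples: `"sc:wilcox"`, `"pb:nb_lrt"`, `"pr:nb_lrt"`,
#' `"cells:voom"`.
#'
#' @param counts Genes-by-cells count matrix.
#' @param annotations Cell annotations with `replicate` and a two-level
#'   `condition`.
#' @param method Method descriptor string.
#' @param seed Seed for the pseudo-replicate shuffle (ignored otherwise).
#' @param dispersion Optional precomputed dispersion fit forwarded to
#'   pseudobulk NB tests (`pb` mode only).
#' @return A DE result table.
#' @export
run_de <- function(counts, annotations, method, seed = 1L,
                   dispersion = NULL) {
  parts <- strsplit(method, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) {
    stop("method must be of the form 'mode:test', e.g. 'pb:nb_lrt'")
  }
  mode <- parts[1]
  test <- parts[2]
  switch(mode,
    sc = de_single_cell(counts, annotations, test),
    pb = de_pseudobulk(aggregate_pseudobulk(counts, annotations), test,
                       dispersion = dispersion),
    pr = {
      ann <- shuffle_pseudoreplicates(align_annotations(counts, annotations),
                                      seed)
      de_pseudobulk(aggregate_pseudobulk(counts, ann), test)
    },
    cells = de_pseudobulk(cells_as_pseudobulk(counts, annotations), test),
    stop("unknown mode: ", mode))
}

#' Null experiment: DE analysis with no true condition effect
#'
#' For each of `n_sims` simulations, generates a fresh null dataset (or a
#' fresh random split of the control replicates of a supplied dataset),
#' randomly assigns half of the replicates to an artificial treatment
#' condition, runs every requested DE method, and records the number of
#' genes called DE at BH q < `fdr` along with the fraction of raw p-values
#' below 0.05. Every reported discovery is by construction a false one.
#'
#' @param source A [sim_params()] object, or a list with `counts` and
#'   `annotations` (only cells of `control_condition` are used).
#' @param methods Character vector of method descriptors (see [run_de()]).
#' @param fdr BH q-value threshold for counting DE genes (default 0.05).
#' @param n_sims Number of independent simulations (default 10).
#' @param seed Master seed; all per-simulation seeds derive from it.
#' @param control_condition Condition label selecting the cells to split
#'   when `source` is a dataset (default `"control"`; ignored for
#'   simulations).
#' @return A data.frame of class `null_experiment` with one row per
#'   (simulation, method): `sim`, `seed`, `method`, `n_de`, `n_p05`,
#'   `n_genes`; the `summary` attribute holds mean and SD of `n_de` per
#'   method.
#' @export
run_null_experiment <- function(source, methods, fdr = 0.05, n_sims = 10,
                                seed = 1L, control_condition = "control") {
  set.seed(seed)
  sim_seeds <- sample.int(.Machine$integer.max, 3 * n_sims)
  rows <- vector("list", n_sims * length(methods))
  k <- 0L
  for (i in seq_len(n_sims)) {
    if (inherits(source, "sim_params")) {
      p <- source
      p$seed <- sim_seeds[3 * i - 2]
      ds <- simulate_null_dataset(p)
      units <- list(all = list(counts = ds$counts, ann = ds$annotations))
    } else {
      keep <- source$annotations$condition %in% control_condition
      ann0 <- source$annotations[keep, , drop = FALSE]
      counts0 <- source$counts[, match(ann0$cell_id, colnames(source$counts)),
                               drop = FALSE]
      grp <- if ("group" %in% names(ann0)) ann0$group else "all"
      units <- lapply(split(seq_len(nrow(ann0)), grp), function(idx) {
        list(counts = counts0[, idx, drop = FALSE],
             ann = ann0[idx, , drop = FALSE])
      })
    }
    for (u in seq_along(units)) {
      counts <- units[[u]]$counts
      ann <- units[[u]]$ann
      reps <- unique(ann$replicate)
      if (length(reps) < 4) stop("at least 4 replicates are required")
      assignment <- assign_null_conditions(reps, seed = sim_seeds[3 * i - 1])
      ann$condition <- unname(assignment[ann$replicate])
      disp <- NULL
      if (any(startsWith(methods, "pb:nb"))) {
        disp <- fit_nb_dispersion(aggregate_pseudobulk(counts, ann))
      }
      for (m in methods) {
        res <- run_de(counts, ann, m, seed = sim_seeds[3 * i],
                      dispersion = disp)
        k <- k + 1L
        rows[[k]] <- data.frame(sim = i, seed = sim_seeds[3 * i - 2],
                                group = names(units)[u], method = m,
                                n_de = sum(res$qval < fdr),
                                n_p05 = sum(res$pval < 0.05),
                                n_genes = nrow(res), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  agg <- stats::aggregate(n_de ~ method, out, function(x) c(mean = mean(x),
                                                            sd = stats::sd(x)))
  summary <- data.frame(method = agg$method, mean_n_de = agg$n_de[, "mean"],
                        sd_n_de = agg$n_de[, "sd"], stringsAsFactors = FALSE)
  attr(out, "summary") <- summary
  class(out) <- c("null_experiment", "data.frame")
  out
}

#' Sweep a simulation parameter and rerun the null experiment
#'
#' Runs [run_null_experiment()] at each value of a parameter grid --
#' typically `de_facLoc` between 0 and 1 (replicate heterogeneity), the
#' number of replicates per condition, or the number of cells -- and
#' returns a long-format table of DE-gene counts.
#'
#' @param base A [sim_params()] object used as the template.
#' @param grid Numeric vector of parameter values.
#' @param methods Character vector of method descriptors.
#' @param fdr BH q-value threshold.
#' @param n_sims Simulations per grid point.
#' @param seed Master seed.
#' @param vary Which parameter the grid applies to: `"de_facLoc"`,
#'   `"n_reps_per_group"` or `"n_cells"`.
#' @return Long data.frame: `value`, `method`, `sim`, `n_de`, `n_p05`,
#'   `n_genes`.
#' @export
heterogeneity_sweep <- function(base, grid, methods, fdr = 0.05, n_sims = 10,
                                seed = 1L,
                                vary = c("de_facLoc", "n_reps_per_group",
                                         "n_cells")) {
  vary <- match.arg(vary)
  if (!length(grid)) stop("empty grid")
  set.seed(seed)
  point_seeds <- sample.int(.Machine$integer.max, length(grid))
  out <- vector("list", length(grid))
  for (j in seq_along(grid)) {
    p <- base
    p[[vary]] <- if (vary == "de_facLoc") grid[j] else as.integer(grid[j])
    res <- run_null_experiment(p, methods, fdr = fdr, n_sims = n_sims,
                               seed = point_seeds[j])
    out[[j]] <- cbind(value = grid[j],
                      res[, c("method", "sim", "n_de", "n_p05", "n_genes")])
  }
  do.call(rbind, out)
}

#' AUCC benchmark of single-cell methods against bulk references
#'
#' Computes the AUCC between every (single-cell method, bulk method) pair
#' of DE result tables, plus the arithmetic mean over bulk methods for each
#' single-cell method.
#'
#' @param sc_results Named list of DE result tables (single-cell side).
#' @param bulk_results Named list of DE result tables (bulk side).
#' @param k AUCC depth (default 500, capped at the shortest ranking).
#' @return Matrix of AUCC values with a `mean` column appended.
#' @export
run_concordance_benchmark <- function(sc_results, bulk_results, k = 500) {
  if (!length(sc_results) || !length(bulk_results)) stop("empty result list")
  m <- matrix(NA_real_, length(sc_results), length(bulk_results),
              dimnames = list(names(sc_results), names(bulk_results)))
  for (i in seq_along(sc_results)) {
    for (j in seq_along(bulk_results)) {
      m[i, j] <- suppressWarnings(
        aucc(ranked_genes(sc_results[[i]]), ranked_genes(bulk_results[[j]]),
             k = k))
    }
  }
  cbind(m, mean = rowMeans(m))
}

#' Chi-square test of independence for a 2x2 table
#'
#' Pearson chi-square statistic `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`
#' with an optional Yates continuity correction (|ad - bc| reduced by n/2,
#' floored at 0), referred to the upper tail of chi-square on 1 df. Used,
#' for example, to compare how many DE calls of two methods an independent
#' validation corroborates.
#'
#' @param a,b,c,d Nonnegative integer cell counts, row-wise.
#' @param yates Apply the continuity correction (default `FALSE`).
#' @return List with `statistic` and `p`.
#' @export
#' @examples
#' chisq_2x2(5, 1, 3, 10)
chisq_2x2 <- function(a, b, c, d, yates = FALSE) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be nonnegative integers")
  }
  n <- sum(cells)
  if (n == 0) stop("empty table")
  if (any(c(a + b, c + d, a + c, b + d) == 0)) stop("degenerate table")
  num <- abs(a * d - b * c)
  if (yates) num <- max(num - n / 2, 0)
  stat <- n * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}
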