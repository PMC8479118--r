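test_that("simulator is deterministic and respects its dimensions", {
  p <- tiny_params()
  a <- simulate_null_dataset(p)
  b <- simulate_null_dataset(p)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$truth, b$truth)
  expect_equal(dim(a$counts), c(p$n_genes, p$n_cells))
  expect_equal(nrow(a$annotations), p$n_cells)
  expect_equal(ncol(a$truth), 2 * p$n_reps_per_group)
  expect_true(all(table(a$annotations$replicate) >= 1))
  expect_true(all(is.na(a$annotations$condition)))
})

test_that("switching heterogeneity off gives unit truth factors", {
  ds <- simulate_null_dataset(tiny_params(de_facLoc = 0, de_facScale = 0))
  expect_true(all(ds$truth == 1))
})

test_that("too few cells for the replicate design is an error", {
  expect_error(simulate_null_dataset(tiny_params(n_cells = 5)),
               "too few cells")
})

test_that("counts match the stated NB moments within one replicate", {
  # fixed library, one gene panel observed across many cells of a replicate:
  # mean ~ mu and var ~ mu (1 + phi mu) with phi = B^2 from the BCV recipe
  p <- tiny_params(n_genes = 60, n_cells = 6000, n_reps_per_group = 1,
                   de_facLoc = 0, de_facScale = 0, lib_scale = 0,
                   bcv_common = 1e-6, bcv_df = 1e8, seed = 11)
  ds <- simulate_null_dataset(p)
  rep1 <- ds$annotations$cell_id[ds$annotations$replicate == "rep1"]
  m <- as.matrix(ds$counts[, rep1])
  emp_mean <- rowMeans(m)
  emp_var <- apply(m, 1, var)
  # reconstruct the model mean and dispersion for this degenerate setting
  mu <- emp_mean
  phi <- (1e-6 + 1 / sqrt(pmax(mu, 1e-12)))^2
  expected_var <- mu * (1 + phi * mu)
  keep <- mu > 0.5
  expect_gt(sum(keep), 20)
  ratio <- emp_var[keep] / expected_var[keep]
  expect_lt(abs(median(ratio) - 1), 0.1)
})

test_that("per-cell totals concentrate around the drawn library size", {
  p <- tiny_params(n_genes = 2000, n_cells = 200, lib_scale = 0,
                   seed = 3)
  ds <- simulate_null_dataset(p)
  totals <- Matrix::colSums(ds$counts)
  expect_lt(abs(mean(totals) / 2000 - 1), 0.05)
})

test_that("pseudobulk profiles of replicates converge without heterogeneity", {
  # mean absolute log-ratio of replicate pseudobulk CPM shrinks with cells
  ratio_at <- function(n_cells) {
    p <- tiny_params(n_genes = 400, n_cells = n_cells, n_reps_per_group = 1,
                     de_facLoc = 0, de_facScale = 0, seed = 5)
    ds <- simulate_null_dataset(p)
    ann <- ds$annotations
    ann$condition <- "ctl"
    pb <- aggregate_pseudobulk(ds$counts, ann)
    cpm <- t(t(pb$counts) / colSums(pb$counts)) * 1e6
    keep <- rowSums(cpm > 0) == 2
    mean(abs(log(cpm[keep, 1] / cpm[keep, 2])))
  }
  expect_lt(ratio_at(2000), ratio_at(100))
})

test_that("null condition assignment splits replicates in half uniformly", {
  ids <- paste0("rep", 1:6)
  a <- assign_null_conditions(ids, seed = 1)
  expect_equal(sum(a == "treatment"), 3)
  expect_equal(sum(a == "control"), 3)
  expect_identical(a, assign_null_conditions(ids, seed = 1))
  expect_warning(assign_null_conditions(paste0("r", 1:5), seed = 1), "odd")
  expect_error(assign_null_conditions("r1", seed = 1))

  # all C(6,3) = 20 splits occur with frequency consistent with uniformity
  splits <- vapply(1:10000, function(s) {
    paste(sort(names(which(assign_null_conditions(ids, s) == "treatment"))),
          collapse = ",")
  }, character(1))
  tab <- table(splits)
  expect_equal(length(tab), 20)
  expect_gt(chisq.test(tab)$p.value, 0.001)
})

test_that("spike-in panel obeys its generative moments and null truth", {
  ds <- simulate_spikein_dataset(n_spikeins = 10, n_cells = 20000,
                                 capture_scale = 0.4, dispersion = 0,
                                 dilution_scale = 0, ratio_scale = 0,
                                 carrier_het = 0, seed = 9,
                                 lambda_range = c(1, 100))
  expect_true(all(ds$truth == 1))
  emp <- Matrix::rowMeans(ds$counts[ds$spikein_ids, ])
  expected <- ds$concentration * exp(0.4^2 / 2)   # log-normal capture moment
  expect_lt(max(abs(emp / expected - 1)), 0.1)

  expect_error(simulate_spikein_dataset(n_spikeins = 1), "n_spikeins")
  expect_error(simulate_spikein_dataset(capture_scale = -1), "capture_scale")
})

test_that("spike-in conditions follow an identical generative law", {
  ds <- simulate_spikein_dataset(n_cells = 4000, dilution_scale = 0,
                                 ratio_scale = 0, carrier_het = 0, seed = 2)
  m <- ds$counts[ds$spikein_ids, ]
  ctl <- ds$annotations$condition == "control"
  hi <- which(ds$concentration > 10)
  lfc <- log2(Matrix::rowMeans(m[hi, ctl]) / Matrix::rowMeans(m[hi, !ctl]))
  expect_lt(max(abs(lfc)), 0.25)
})
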