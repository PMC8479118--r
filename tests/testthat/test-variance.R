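test_that("pseudobulk variance on an injected scale is exact", {
  m <- matrix(c(2, 4, 3, 3), 1, 4,
              dimnames = list("g1", sprintf("s%d", 1:4)))
  pb <- structure(list(counts = m,
                       samples = data.frame(
                         replicate = sprintf("s%d", 1:4),
                         condition = rep(c("ctl", "stim"), each = 2))),
                  class = "pseudobulk")
  v <- pseudobulk_variance(pb, scale = identity)
  expect_equal(unname(v), ((4 - 2)^2 / 2 + 0) / 2)  # var 2 and 0, averaged
  # permuting sample order leaves the result unchanged
  perm <- c(2, 1, 4, 3)
  pb2 <- pb
  pb2$counts <- pb$counts[, perm, drop = FALSE]
  pb2$samples <- pb$samples[perm, ]
  expect_equal(pseudobulk_variance(pb2, scale = identity), v)
  # identical columns give zero variance
  pb3 <- pb
  pb3$counts[] <- 5
  expect_equal(unname(pseudobulk_variance(pb3, scale = identity)), 0)
  # single-sample condition is an error
  pb4 <- pb
  pb4$samples$condition <- c("a", "b", "b", "b")
  expect_error(pseudobulk_variance(pb4), "single sample")
})

test_that("delta variance is exactly var_pseudo minus var_bio", {
  ds <- null_dataset_with_conditions(tiny_params(n_genes = 200, seed = 6))
  dv <- delta_variance(ds$counts, ds$annotations, seed = 11)
  expect_equal(dv$delta, dv$var_pseudo - dv$var_bio)
  expect_true(all(dv$var_bio >= 0 & dv$var_pseudo >= 0))
  expect_equal(nrow(dv), 200)
})

test_that("an identity shuffle gives zero delta for every gene", {
  ann <- toy_annotations(8, replicate = rep(c("r1", "r2"), each = 4),
                         condition = rep(c("control", "treatment"),
                                         times = 4))
  counts <- toy_counts(rpois(80, 8) + 1, 10, 8)
  # find a seed whose within-condition permutation is the identity
  id_seed <- NULL
  for (s in 1:200) {
    if (identical(shuffle_pseudoreplicates(ann, s)$replicate,
                  ann$replicate)) { id_seed <- s; break }
  }
  expect_false(is.null(id_seed))
  dv <- delta_variance(counts, ann, seed = id_seed)
  expect_equal(unname(dv$delta), rep(0, 10))
})

test_that("fraction of decreased-variance genes counts strictly", {
  dv <- data.frame(gene = paste0("g", 1:4), var_bio = 1, var_pseudo = 1,
                   delta = c(-1, -2, 3, 0))
  class(dv) <- c("delta_variance", "data.frame")
  expect_equal(fraction_variance_decreased(dv), 0.5)
  dv$delta <- rep(0, 4)
  expect_equal(fraction_variance_decreased(dv), 0)
  dv$delta <- c(-1, -2, 3, 0)
  expect_equal(fraction_variance_decreased(dv) + mean(dv$delta >= 0), 1)
})

test_that("partial correlations follow the closed form", {
  set.seed(44)
  n <- 50000
  z <- rnorm(n)
  x <- 0.6 * z + sqrt(1 - 0.36) * rnorm(n)   # delta proxy
  y <- 0.5 * z + sqrt(1 - 0.25) * rnorm(n)   # var proxy
  w <- 0.5 * z + sqrt(1 - 0.25) * rnorm(n)   # mean proxy
  dv <- data.frame(gene = sprintf("g%d", 1:n), var_bio = y,
                   var_pseudo = y + x, delta = x)
  out <- delta_variance_correlations(dv, mean_expr = w, var_bio = y)
  # pearson partial of the latent gaussian: (r_xy - r_xz r_yz)/(...)
  # with r_xy ~ 0.30, r_xz ~ 0.30, r_yz ~ 0.25 on ranks; use sample values
  rd <- rank(x); rv <- rank(y); rm_ <- rank(w)
  r_dv <- cor(rd, rv); r_dm <- cor(rd, rm_); r_mv <- cor(rv, rm_)
  expect_equal(out$cor_var, r_dv, tolerance = 1e-12)
  expect_equal(out$pcor_var,
               (r_dv - r_dm * r_mv) / sqrt((1 - r_dm^2) * (1 - r_mv^2)),
               tolerance = 1e-12)
  # independence: all four correlations near zero
  dv2 <- dv
  dv2$delta <- rnorm(n)
  out2 <- delta_variance_correlations(dv2, mean_expr = w, var_bio = y)
  expect_lt(max(abs(unlist(out2))), 0.05)
  # perfect monotone dependence on variance alone
  small <- data.frame(gene = paste0("g", 1:100), var_bio = 1:100,
                      var_pseudo = 0, delta = -(1:100))
  out3 <- delta_variance_correlations(small, mean_expr = rnorm(100),
                                      var_bio = small$var_bio)
  expect_equal(out3$cor_var, -1)
  expect_equal(out3$pcor_var, -1, tolerance = 1e-6)
  expect_warning(
    delta_variance_correlations(small, mean_expr = rep(1, 100)),
    "zero-variance")
})

test_that("decile binning is equal-sized and counts significant genes", {
  dv <- data.frame(gene = sprintf("g%02d", 1:25), var_bio = 0,
                   var_pseudo = 0, delta = seq(-12, 12))
  res <- data.frame(gene = dv$gene, qval = rep(1, 25))
  expect_equal(decile_de_counts(dv, res), rep(0, 10))
  res$qval <- ifelse(abs(dv$delta) >= 10, 0.01, 1)   # 6 big-|delta| genes
  counts <- decile_de_counts(dv, res)
  expect_equal(sum(counts), 6)
  expect_true(all(which(counts > 0) >= 8))
  # bin sizes differ by at most one
  sizes <- table(cut(rank(abs(dv$delta), ties.method = "first"),
                     breaks = 10))
  expect_lte(diff(range(sizes)), 1)
})
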