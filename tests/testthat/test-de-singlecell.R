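# A 1-gene matrix whose cp10k-log values keep the order of raw values is
# enough to address the rank-based and value-based tests directly; for
# count models we build counts explicitly.

two_group_ann <- function(n1, n2) {
  toy_annotations(n1 + n2, replicate = rep(c("r1", "r2"), c(n1, n2)),
                  condition = rep(c("control", "treatment"), c(n1, n2)))
}

test_that("wilcoxon matches exact enumeration for small untied groups", {
  # textbook case: [1,2,3] vs [4,5,6] has exact two-sided p = 0.1
  Y <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6)
  r <- pseudobulkDE:::wilcox_vec(Y, grp2 = rep(c(FALSE, TRUE), each = 3))
  expect_equal(r$p, 0.1)

  set.seed(99)
  for (i in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    vals <- sample(1000, n1 + n2)   # distinct -> no ties
    grp2 <- rep(c(FALSE, TRUE), c(n1, n2))
    r <- pseudobulkDE:::wilcox_vec(matrix(vals, 1), grp2)
    expect_equal(r$p, wilcox_exact_enum(vals[!grp2], vals[grp2]),
                 tolerance = 1e-12)
  }
})

test_that("wilcoxon approximation agrees with stats::wilcox.test on ties", {
  set.seed(7)
  vals <- rpois(120, 2)
  grp2 <- rep(c(FALSE, TRUE), 60)
  r <- pseudobulkDE:::wilcox_vec(matrix(vals, 1), grp2)
  ref <- suppressWarnings(wilcox.test(vals[grp2], vals[!grp2]))
  expect_equal(r$p, ref$p.value, tolerance = 1e-10)
})

test_that("degenerate genes get statistic 0 and p 1 in every method", {
  m <- rbind(g1 = rep(3, 12), g2 = rpois(12, 4))
  colnames(m) <- sprintf("c%d", 1:12)
  ann <- two_group_ann(6, 6)
  for (meth in c("wilcox", "t", "logistic_lrt", "poisson_lrt",
                 "negbinom_lrt", "bimod_lrt", "hurdle_lrt")) {
    res <- de_single_cell(m, ann, meth)
    expect_equal(res$statistic[res$gene == "g1"], 0, info = meth)
    expect_equal(res$pval[res$gene == "g1"], 1, info = meth)
  }
})

test_that("poisson LRT reproduces the closed-form deviance", {
  # groups [1,2] vs [5,6] without offsets: dev = 2[3 ln(1.5/3.5) + 11 ln(5.5/3.5)]
  r <- pseudobulkDE:::poisson_lrt_vec(matrix(c(1, 2, 5, 6), 1), grp2 = c(F, F, T, T),
                                      lib = rep(1, 4))
  dev <- 2 * (3 * log(1.5 / 3.5) + 11 * log(5.5 / 3.5))
  expect_equal(r$statistic, dev, tolerance = 1e-12)
  expect_equal(r$p, pchisq(dev, 1, lower.tail = FALSE))
  expect_equal(round(dev, 3), 4.86)
})

test_that("poisson LRT with offsets matches glm()", {
  set.seed(12)
  y <- rpois(40, 3)
  lib <- rpois(40, 2000)
  grp <- rep(c(0, 1), 20)
  fit1 <- glm(y ~ grp + offset(log(lib)), family = poisson)
  fit0 <- glm(y ~ 1 + offset(log(lib)), family = poisson)
  ref <- fit0$deviance - fit1$deviance
  r <- pseudobulkDE:::poisson_lrt_vec(matrix(y, 1), grp2 = grp == 1, lib = lib)
  expect_equal(r$statistic, ref, tolerance = 1e-8)
})

test_that("logistic regression LRT matches glm()", {
  set.seed(13)
  x <- rnorm(60)
  y <- rbinom(60, 1, plogis(0.5 * x))
  fit1 <- glm(y ~ x, family = binomial)
  ref <- fit1$null.deviance - fit1$deviance
  r <- pseudobulkDE:::logistic_lrt_vec(matrix(x, 1), y)
  expect_equal(r$statistic, ref, tolerance = 1e-6)
})

test_that("welch t matches t.test", {
  set.seed(14)
  x <- rnorm(25); y <- rnorm(30, 0.4, 1.6)
  ref <- t.test(y, x)
  r <- pseudobulkDE:::welch_t_vec(matrix(c(x, y), 1),
                                  grp2 = rep(c(FALSE, TRUE), c(25, 30)))
  expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(r$p, ref$p.value, tolerance = 1e-10)
})

test_that("result tables are well-formed and statistic-first ranked", {
  ds <- null_dataset_with_conditions(tiny_params(n_genes = 150, seed = 2))
  res <- de_single_cell(ds$counts, ds$annotations, "t")
  expect_setequal(res$rank, seq_len(nrow(res)))
  expect_true(all(res$qval >= res$pval - 1e-12))
  ord <- order(res$rank)
  expect_true(all(diff(abs(res$statistic[ord])) <= 1e-12))
  # ranking must not depend on p underflow: statistic dominates
  fake <- res
  fake$pval[1:5] <- 0
  tab <- pseudobulkDE:::de_result_table(fake$gene, fake$log2fc,
                                        fake$statistic, fake$pval, "t")
  expect_equal(order(-abs(tab$statistic))[1], which(tab$rank == 1))
})

test_that("log2fc signs flip when condition labels swap", {
  ds <- null_dataset_with_conditions(tiny_params(n_genes = 80, seed = 4))
  fc <- compute_log2fc(ds$counts, ds$annotations, "sc_mean_log")
  ann2 <- ds$annotations
  ann2$condition <- ifelse(ann2$condition == "control", "treatment", "control")
  fc2 <- compute_log2fc(ds$counts, ann2, "sc_mean_log")
  expect_equal(fc, -fc2)
  # pb ratio arithmetic: mean CPM 100 vs 25 with prior 1
  pbm <- cbind(s1 = c(100, 1e6 - 100), s2 = c(25, 1e6 - 25))
  rownames(pbm) <- c("g", "rest")
  fc3 <- compute_log2fc(pbm, c("treatment", "control"), "pb_cpm_ratio")
  expect_equal(unname(fc3["g"]), log2(101 / 26), tolerance = 1e-6)
})

test_that("bh adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.2, NA, 0.01)
  q <- bh_adjust(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], p.adjust(p[c(1, 3)], "BH"))
  set.seed(8)
  for (i in 1:20) {
    p <- round(runif(sample(3:12, 1)), 3)
    expect_equal(bh_adjust(p), bh_bruteforce(p), tolerance = 1e-9)
  }
})
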