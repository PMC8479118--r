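# Small deterministic fixtures shared across test files.

tiny_params <- function(...) {
  defaults <- list(n_genes = 300, n_cells = 120, n_reps_per_group = 3,
                   seed = 42L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_params, args)
}

# A simulated dataset with artificial conditions already assigned.
null_dataset_with_conditions <- function(params = tiny_params(),
                                         split_seed = 7L) {
  ds <- simulate_null_dataset(params)
  assignment <- assign_null_conditions(unique(ds$annotations$replicate),
                                       seed = split_seed)
  ds$annotations$condition <- unname(assignment[ds$annotations$replicate])
  ds
}

# Dense toy count matrix with named dimensions.
toy_counts <- function(values, n_genes, n_cells) {
  matrix(values, n_genes, n_cells,
         dimnames = list(sprintf("g%d", seq_len(n_genes)),
                         sprintf("c%d", seq_len(n_cells))))
}

toy_annotations <- function(n_cells, replicate, condition = "ctl",
                            group = "all") {
  data.frame(cell_id = sprintf("c%d", seq_len(n_cells)),
             replicate = replicate, condition = condition, group = group,
             stringsAsFactors = FALSE)
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# assignments of the pooled values to the first group.
wilcox_exact_enum <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  ws <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- mean(ws)
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# Brute-force BH: smallest alpha at which each p is rejected by step-up.
bh_bruteforce <- function(p) {
  m <- length(p)
  vapply(seq_along(p), function(i) {
    alphas <- sort(unique(c(as.vector(outer(p, seq_len(m),
                                            function(pp, j) pp * m / j)), 1)))
    alphas <- alphas[alphas <= 1]
    for (a in alphas) {
      ok <- which(sort(p) <= seq_len(m) / m * a + 1e-12)
      rej <- if (length(ok)) sort(p)[seq_len(max(ok))] else numeric(0)
      if (p[i] <= max(c(rej, -1)) + 1e-12) return(a)
    }
    1
  }, numeric(1))
}

# Brute-force AUCC: explicit double loop over prefixes.
aucc_bruteforce <- function(a, b, k) {
  s <- 0
  for (j in seq_len(k)) {
    s <- s + length(intersect(a[seq_len(j)], b[seq_len(j)]))
  }
  s / (k * (k + 1) / 2)
}
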