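# Negative binomial GLM machinery shared by the single-cell NB test, the
# pseudobulk NB tests and the profile-likelihood dispersion estimator.
#
# All fits are one-parameter-per-group log-link models with a log
# library-size offset: mu_gc = exp(beta_g) * L_c. The log-likelihood is
# concave in beta, so a handful of Fisher-scoring steps from the Poisson
# closed form converges for every gene simultaneously (matrix-vectorized).

# Fit a single rate per gene over the given columns at fixed per-gene
# dispersion phi. Returns beta (log rate), the likelihood kernel (terms of
# the maximized log-likelihood that depend on the fitted mean), and the
# Fisher information of beta. With `poisson_limit = TRUE`, dispersions below
# 1e-6 use the exact Poisson kernel so that the NB likelihood-ratio test
# reproduces the Poisson one as phi -> 0; profiling over phi needs a formula
# continuous in phi and sets it to FALSE.
nb_fit_group <- function(Y, lib, phi, iters = 12L, poisson_limit = TRUE) {
  G <- nrow(Y)
  s <- rowSums(Y)
  L <- sum(lib)
  beta <- log(pmax(s / L, 1e-12))
  libm <- matrix(lib, G, ncol(Y), byrow = TRUE)
  phi <- rep_len(phi, G)
  for (i in seq_len(iters)) {
    mu <- exp(beta) * libm
    score <- rowSums((Y - mu) / (1 + phi * mu))
    info <- rowSums(mu / (1 + phi * mu))
    beta <- beta + pmin(pmax(ifelse(info > 0, score / info, 0), -5), 5)
  }
  mu <- pmax(exp(beta) * libm, 1e-12)
  info <- rowSums(mu / (1 + phi * mu))
  kernel <- nb_kernel(Y, mu, phi, poisson_limit)
  list(beta = beta, kernel = kernel, info = info)
}

# Mean-dependent part of the NB log-likelihood at given mu.
nb_kernel <- function(Y, mu, phi, poisson_limit = TRUE) {
  G <- nrow(Y)
  phi <- rep_len(phi, G)
  out <- numeric(G)
  pois <- poisson_limit & phi < 1e-6
  if (any(pois)) {
    Yp <- Y[pois, , drop = FALSE]
    mup <- mu[pois, , drop = FALSE]
    out[pois] <- rowSums(ifelse(Yp > 0, Yp * log(mup), 0) - mup)
  }
  if (any(!pois)) {
    Yn <- Y[!pois, , drop = FALSE]
    mun <- mu[!pois, , drop = FALSE]
    k <- 1 / phi[!pois]
    out[!pois] <- rowSums(ifelse(Yn > 0, Yn * log(mun), 0) -
                            (Yn + k) * log(mun + k))
  }
  out
}

# Saturated-model kernel (mu = y), used for residual deviances.
nb_kernel_saturated <- function(Y, phi, poisson_limit = TRUE) {
  nb_kernel(Y, pmax(Y, 1e-12), phi, poisson_limit)
}

# Dispersion-dependent terms of the full NB log-likelihood (needed when
# profiling over phi; constant in mu). Uses the exact NB form everywhere.
nb_ll_phi_terms <- function(Y, phi) {
  G <- nrow(Y)
  k <- 1 / rep_len(phi, G)
  rowSums(lgamma(Y + k)) + ncol(Y) * (k * log(k) - lgamma(k))
}

# Cox-Reid adjusted profile log-likelihood of the two-group NB model at
# fixed phi (up to the phi-independent -sum lgamma(y+1) constant). The
# adjustment -0.5 log det(I) corrects the downward bias of plain profile
# likelihood when the group means are estimated from few samples; with one
# rate per group the information matrix is diagonal.
nb_two_group_profile_ll <- function(Y, lib, grp2, phi) {
  fa <- nb_fit_group(Y[, !grp2, drop = FALSE], lib[!grp2], phi,
                     poisson_limit = FALSE)
  fb <- nb_fit_group(Y[, grp2, drop = FALSE], lib[grp2], phi,
                     poisson_limit = FALSE)
  fa$kernel + fb$kernel + nb_ll_phi_terms(Y, phi) -
    0.5 * (log(pmax(fa$info, 1e-12)) + log(pmax(fb$info, 1e-12)))
}
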