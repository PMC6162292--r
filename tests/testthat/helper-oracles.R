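# Independent oracles used across the suite. These deliberately take the
# dense-matrix route so they share no code with the package's closed forms.

# U' R(rho)^-1 V by explicit inversion of the AR(1) correlation matrix.
dense_quadform <- function(rho, U, V) {
  drop(U %*% solve(ar1_cor(rho, length(U))) %*% V)
}

# Multivariate-normal log-density of a fitted polynomial/AR(1) model, summed
# over strains, via dense covariance matrices.
dense_mvn_loglik <- function(fit, trait, genotype) {
  m <- ncol(trait)
  S <- fit$sigma2 * ar1_cor(fit$rho, m)
  Si <- solve(S)
  ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  basis <- outer(fit$times, 0:3, "^")
  grp <- if (is.null(genotype)) rep(fit$groups[1], nrow(trait)) else genotype
  tot <- 0
  for (i in seq_len(nrow(trait))) {
    mu <- drop(basis %*% fit$beta[, as.character(grp[i])])
    r <- trait[i, ] - mu
    tot <- tot - 0.5 * (m * log(2 * pi) + ld + drop(r %*% Si %*% r))
  }
  tot
}

# Balanced 0/1 genotype vector.
balanced_geno <- function(n) rep(0:1, length.out = n)

# A dataset pair of distinct patterns with a given noise scale.
effect_dataset <- function(N, rho_mean = 0.9, noise_sd = 1,
                           pats = pattern_library()[c("increase", "peak")]) {
  g <- balanced_geno(N)
  y <- simulate_trait(sim_design(N, 6, rho_mean, 0.02, pats, noise_sd), g)
  list(trait = y, genotype = g)
}
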