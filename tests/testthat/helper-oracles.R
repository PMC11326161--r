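# Independent oracles used to validate the fast implementations.

# Dense brute-force restricted log-likelihood of the random-intercept model
# at given variance components: builds the full N x N covariance and
# evaluates the textbook REML expression directly.
reml_loglik_dense <- function(y, X, cluster, sigma2_b, sigma2_e) {
  cluster <- factor(cluster)
  Z <- stats::model.matrix(~ cluster - 1)
  V <- sigma2_e * diag(length(y)) + sigma2_b * tcrossprod(Z)
  Vi <- solve(V)
  XtVi <- crossprod(X, Vi)
  B <- XtVi %*% X
  beta <- solve(B, XtVi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * ((length(y) - ncol(X)) * log(2 * pi) +
                       determinant(V)$modulus +
                       determinant(B)$modulus +
                       t(r) %*% Vi %*% r))
}

# Brute-force pairwise moment correlation: enumerate all within-cage pairs
# of residuals from the grand mean, scale by the bias-corrected variance.
pairwise_moment_icc <- function(y, cluster) {
  e <- y - mean(y)
  phi <- sum(e^2) / (length(y) - 1)
  tot <- 0; np <- 0
  for (cl in split(e, cluster)) {
    k <- length(cl)
    if (k < 2) next
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      tot <- tot + cl[i] * cl[j]; np <- np + 1
    }
  }
  tot / (phi * np)
}

# Monte Carlo standard error of a mean
mc_se_mean <- function(x) stats::sd(x) / sqrt(length(x))

# quick balanced clustered gaussian cohort
make_test_cohort <- function(n_cages, k, icc, seed, n_arms = 2, effect = 0, ...) {
  st <- make_cage_structure(ceiling(n_cages / n_arms), k, n_arms = n_arms)
  sample_exchangeable_outcomes(st, icc = icc, effect = effect, seed = seed, ...)
}
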