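# Random-intercept REML by profiled likelihood. The exchangeable structure
# of cage blocks gives W_j^{-1} = I - lambda/(1+lambda k_j) J in closed form,
# so the whole restricted likelihood reduces to per-cage sums and one scalar
# search over the variance ratio lambda = sigma2_between / sigma2_within.

# drop right-censored rows (lifespan analyses exclude them)
.drop_censored <- function(data) {
  if ("censored" %in% names(data)) data[!data$censored, , drop = FALSE] else data
}

.icc_estimate <- function(method, estimate, ci_low = NA_real_, ci_high = NA_real_,
                          ci_method = "none", n_clusters = NA_integer_,
                          mean_cluster_size = NA_real_, ...) {
  structure(list(method = method, estimate = estimate,
                 ci_low = ci_low, ci_high = ci_high, ci_method = ci_method,
                 n_clusters = n_clusters, mean_cluster_size = mean_cluster_size,
                 ...),
            class = "icc_estimate")
}

#' @export
print.icc_estimate <- function(x, digits = 3, ...) {
  ci <- if (!is.na(x$ci_low)) sprintf(" (%s, %s)", format(round(x$ci_low, digits)),
                                      format(round(x$ci_high, digits))) else ""
  cat(sprintf("ICC [%s]: %s%s  [%d clusters, mean size %.2f]\n",
              x$method, format(round(x$estimate, digits)), ci,
              x$n_clusters, x$mean_cluster_size))
  invisible(x)
}

# Profiled restricted log-likelihood machinery on sufficient statistics.
.reml_suffstats <- function(y, X, cluster) {
  g <- as.integer(cluster)
  list(N = length(y), p = ncol(X),
       k = as.vector(table(cluster)),
       XtX = crossprod(X), Xty = crossprod(X, y), yty = sum(y^2),
       Sx = rowsum(X, g), Sy = as.vector(rowsum(y, g)))
}

# restricted log-likelihood at variance ratio lambda, with sigma2_e and the
# fixed effects profiled out; returns components needed by callers
.reml_eval <- function(lambda, ss) {
  a <- lambda / (1 + lambda * ss$k)
  yWy <- ss$yty - sum(a * ss$Sy^2)
  df <- ss$N - ss$p
  if (ss$p == 1) { # scalar fast path (intercept-only refits dominate bootstraps)
    A <- ss$XtX[1] - sum(a * ss$Sx[, 1]^2)
    b <- ss$Xty[1] - sum(a * ss$Sx[, 1] * ss$Sy)
    beta <- b / A
    sig2 <- (yWy - beta * b) / df
    ll <- -0.5 * (df * (log(2 * pi) + log(sig2) + 1) +
                    sum(log1p(lambda * ss$k)) + log(A))
    return(list(ll = ll, beta = beta, sigma2_within = sig2,
                vcov = matrix(sig2 / A), lambda = lambda))
  }
  A <- ss$XtX - crossprod(ss$Sx * sqrt(a))
  b <- ss$Xty - crossprod(ss$Sx, a * ss$Sy)
  R <- chol(A)
  beta <- backsolve(R, forwardsolve(t(R), b))
  rss <- yWy - sum(beta * b)
  sig2 <- rss / df
  ll <- -0.5 * (df * (log(2 * pi) + log(sig2) + 1) +
                  sum(log1p(lambda * ss$k)) + 2 * sum(log(diag(R))))
  list(ll = ll, beta = as.vector(beta), sigma2_within = sig2,
       vcov = sig2 * chol2inv(R), lambda = lambda)
}

# optimize the profiled likelihood over lambda given sufficient statistics
.reml_opt <- function(ss, tol = 1e-6) {
  # default x-tolerance 1e-6 on log(lambda): the profiled likelihood is flat
  # at its optimum, so the attained log-likelihood is accurate to ~1e-12
  f <- function(loglam) .reml_eval(exp(loglam), ss)$ll
  lo <- log(1e-8); hi <- log(1e3)
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = tol)
  # bounded bracket expansion if the optimum sits at the upper edge
  tries <- 0
  while (opt$maximum > hi - 0.01 && tries < 3) {
    lo <- hi; hi <- hi + log(1e3); tries <- tries + 1
    opt2 <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = tol)
    if (opt2$objective <= opt$objective) break
    opt <- opt2
  }
  fit0 <- .reml_eval(0, ss)
  if (opt$objective > fit0$ll + 1e-8) {
    fit <- .reml_eval(exp(opt$maximum), ss)
    fit$boundary <- FALSE
  } else {
    fit <- fit0
    fit$boundary <- TRUE
  }
  fit
}

# core fit: y, design matrix X, cluster factor -> variance components
.reml_profile <- function(y, X, cluster) {
  cluster <- droplevels(factor(cluster))
  ss <- .reml_suffstats(y, X, cluster)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient; drop aliased fixed-effect columns")
  fit <- .reml_opt(ss)
  boundary <- fit$boundary
  structure(list(
    sigma2_between = fit$lambda * fit$sigma2_within,
    sigma2_within = fit$sigma2_within,
    sigma2_animal = NULL,
    beta = setNames(fit$beta, colnames(X)),
    vcov_fixed = fit$vcov,
    reml_loglik = fit$ll,
    lambda = fit$lambda,
    boundary = boundary,
    n_clusters = nlevels(cluster),
    cluster_sizes = ss$k,
    X = X, y = y, cluster = cluster
  ), class = "variance_components")
}

#' @export
print.variance_components <- function(x, digits = 4, ...) {
  cat("Random-intercept variance components (REML)\n")
  if (!is.null(x$sigma2_animal))
    cat(sprintf("  sigma2_cage = %.*g, sigma2_animal = %.*g, sigma2_resid = %.*g\n",
                digits, x$sigma2_between, digits, x$sigma2_animal,
                digits, x$sigma2_within))
  else
    cat(sprintf("  sigma2_between = %.*g, sigma2_within = %.*g\n",
                digits, x$sigma2_between, digits, x$sigma2_within))
  if (isTRUE(x$boundary))
    cat("  (between-cluster variance at the zero boundary)\n")
  cat(sprintf("  REML log-likelihood %.6f over %d clusters\n",
              x$reml_loglik, x$n_clusters))
  invisible(x)
}

#' Random-intercept REML fit for clustered outcomes
#'
#' Fits `outcome ~ fixed effects + (1 | cage)` by restricted maximum
#' likelihood, maximizing the profiled likelihood over the variance ratio
#' `lambda = sigma2_between / sigma2_within` with the fixed effects and the
#' residual variance concentrated out in closed form (cost linear in the
#' number of animals). The between-cage variance is constrained to be
#' non-negative; when the profiled likelihood is maximal at `lambda = 0`
#' the fit is flagged as a boundary fit, which is how a mixed model reacts
#' to negatively correlated cage-mates.
#'
#' @param formula Model formula for the fixed effects, e.g.
#'   `lifespan_months ~ sex + arm`.
#' @param data A `clustered_cohort` data frame; censored rows are dropped.
#' @param cluster Name of the cage identifier column.
#' @return A `variance_components` object: `sigma2_between`,
#'   `sigma2_within`, GLS fixed effects and covariance, REML log-likelihood,
#'   boundary flag, and the model frame pieces needed for bootstrap refits.
#' @seealso [lmm_icc()], [parametric_bootstrap_ci()], [icc_fit()]
#' @export
reml_random_intercept <- function(formula, data, cluster = "cage_id") {
  data <- .drop_censored(data)
  if (!cluster %in% names(data)) stop(sprintf("column '%s' not found", cluster))
  vars <- all.vars(formula)
  cc <- stats::complete.cases(data[, c(vars, cluster), drop = FALSE])
  data <- data[cc, , drop = FALSE]
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  .reml_profile(y, X, droplevels(factor(data[[cluster]])))
}

#' ICC from fitted random-intercept variance components
#'
#' The model-based intra-class correlation
#' `sigma2_between / (sigma2_between + sigma2_within)`, which is 0 at the
#' boundary fit and can never be negative (the documented bias of the mixed
#' model under within-cage competition).
#'
#' @param vc A `variance_components` fit from [reml_random_intercept()].
#' @param ci `"none"` or `"parametric_bootstrap"`.
#' @param B,level,seed Bootstrap controls passed to
#'   [parametric_bootstrap_ci()].
#' @return An `icc_estimate` with method `"lmm_reml"`.
#' @export
lmm_icc <- function(vc, ci = c("none", "parametric_bootstrap"),
                    B = 500, level = 0.95, seed = NULL) {
  ci <- match.arg(ci)
  stopifnot(inherits(vc, "variance_components"))
  est <- vc$sigma2_between / (vc$sigma2_between + vc$sigma2_within)
  lo <- hi <- NA_real_
  if (ci == "parametric_bootstrap") {
    b <- parametric_bootstrap_ci(vc, B = B, level = level, seed = seed)
    lo <- b[1]; hi <- b[2]
  }
  .icc_estimate("lmm_reml", est, lo, hi, ci,
                n_clusters = vc$n_clusters,
                mean_cluster_size = mean(vc$cluster_sizes),
                boundary = vc$boundary,
                components = c(sigma2_between = vc$sigma2_between,
                               sigma2_within = vc$sigma2_within))
}

#' Parametric bootstrap percentile CI for the random-intercept ICC
#'
#' Simulates `B` datasets from the fitted model (GLS fixed effects + normal
#' cage intercepts + normal noise on the observed design), refits each by
#' REML, and returns the percentile interval of the bootstrap ICC
#' distribution. With a zero between-cage component the lower limit piles
#' up at 0.
#'
#' @param vc A `variance_components` fit.
#' @param B Number of bootstrap refits (>= 200).
#' @param level Interval coverage (default 0.95).
#' @param seed Optional integer seed.
#' @return Length-2 numeric vector `(ci_low, ci_high)`.
#' @export
parametric_bootstrap_ci <- function(vc, B = 500, level = 0.95, seed = NULL) {
  stopifnot(inherits(vc, "variance_components"), B >= 200)
  if (!is.null(seed)) set.seed(seed)
  mu <- as.vector(vc$X %*% vc$beta)
  m <- vc$n_clusters
  n <- length(vc$y)
  idx <- as.integer(vc$cluster)
  sd_b <- sqrt(vc$sigma2_between)
  sd_e <- sqrt(vc$sigma2_within)
  k <- vc$cluster_sizes
  fail <- 0L

  balanced_intercept <- ncol(vc$X) == 1 && length(unique(vc$X[, 1])) == 1 &&
    length(unique(k)) == 1
  if (balanced_intercept) {
    # balanced intercept-only refits have the REML solution in closed form
    # (between/within mean squares, between-cage variance truncated at 0),
    # so the whole bootstrap vectorizes across replicates
    kk <- k[1]
    Y <- mu + matrix(stats::rnorm(m * B, 0, sd_b), m, B)[idx, , drop = FALSE] +
      matrix(stats::rnorm(n * B, 0, sd_e), n, B)
    M <- rowsum(Y, idx) / kk
    cm2 <- colSums(M^2)
    g <- colMeans(Y)
    msb <- (kk * cm2 - n * g^2) / (m - 1)
    msw <- (colSums(Y^2) - kk * cm2) / (n - m)
    est <- pmax(0, (msb - msw) / (msb + (kk - 1) * msw))
  } else {
    # X-side sufficient statistics are fixed across refits
    ss <- .reml_suffstats(vc$y, vc$X, vc$cluster)
    est <- numeric(B)
    for (i in seq_len(B)) {
      ystar <- mu + stats::rnorm(m, 0, sd_b)[idx] + stats::rnorm(n, 0, sd_e)
      ss$Xty <- crossprod(vc$X, ystar)
      ss$yty <- sum(ystar^2)
      ss$Sy <- as.vector(rowsum(ystar, idx))
      fit <- tryCatch(.reml_opt(ss, tol = 1e-4), error = function(e) NULL)
      if (is.null(fit)) { fail <- fail + 1L; est[i] <- NA_real_; next }
      est[i] <- fit$lambda / (fit$lambda + 1)
    }
  }
  if (fail > 0.05 * B) stop(sprintf("bootstrap refit failure rate %.1f%% exceeds 5%%", 100 * fail / B))
  alpha <- 1 - level
  as.numeric(stats::quantile(est, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE, names = FALSE))
}

#' Two-level (cage + animal) random-intercept REML
#'
#' REML for longitudinal traits with animals nested in cages:
#' `value ~ fixed effects + (1 | cage) + (1 | animal)`. The residual
#' variance and fixed effects are profiled out and the restricted
#' likelihood is maximized over the two variance ratios
#' `(sigma2_cage, sigma2_animal) / sigma2_resid`, exploiting the
#' block-diagonal structure by cage. A cage component whose profiled
#' optimum sits at zero is reported as a boundary fit and flagged rather
#' than treated as a failure.
#'
#' @param formula Fixed-effect formula, e.g. `value ~ diet + age`.
#' @param data A `longitudinal_cohort` data frame.
#' @param cage,animal Names of the nesting identifier columns; each animal
#'   must belong to exactly one cage.
#' @return A `variance_components` object with `sigma2_between` (cage),
#'   `sigma2_animal`, and `sigma2_within` (residual).
#' @export
two_level_reml <- function(formula, data, cage = "cage_id", animal = "animal_id") {
  for (col in c(cage, animal)) if (!col %in% names(data)) stop(sprintf("column '%s' not found", col))
  an <- factor(data[[animal]])
  cg <- factor(data[[cage]])
  n_cage_per_animal <- tapply(as.character(cg), an, function(x) length(unique(x)))
  if (any(n_cage_per_animal > 1))
    stop("non-nested identifiers: some animal appears in more than one cage")
  obs_per_animal <- table(an)
  if (all(obs_per_animal <= 1))
    stop(paste("every animal has a single observation: sigma2_animal and the residual",
               "variance are not separately identifiable; collapse to the one-level",
               "model reml_random_intercept()"))

  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  N <- length(y); p <- ncol(X)
  cg <- droplevels(cg); an <- droplevels(an)

  # per-cage blocks: indices and same-animal indicator matrices
  idx_by_cage <- split(seq_len(N), cg)
  blocks <- lapply(idx_by_cage, function(ix) {
    aa <- as.integer(an[ix])
    list(ix = ix, same = outer(aa, aa, "=="))
  })

  eval2 <- function(lam_c, lam_a) {
    A <- matrix(0, p, p); b <- numeric(p); yWy <- 0; logdetW <- 0
    for (bl in blocks) {
      k <- length(bl$ix)
      W <- matrix(lam_c, k, k)
      W[bl$same] <- W[bl$same] + lam_a
      diag(W) <- diag(W) + 1
      R <- chol(W)
      logdetW <- logdetW + 2 * sum(log(diag(R)))
      M <- cbind(X[bl$ix, , drop = FALSE], y[bl$ix])
      WiM <- backsolve(R, forwardsolve(t(R), M))
      G <- crossprod(M, WiM)
      A <- A + G[1:p, 1:p, drop = FALSE]
      b <- b + G[1:p, p + 1]
      yWy <- yWy + G[p + 1, p + 1]
    }
    Ra <- chol(A)
    beta <- backsolve(Ra, forwardsolve(t(Ra), b))
    rss <- yWy - sum(beta * b)
    sig2 <- as.numeric(rss / (N - p))
    ll <- as.numeric(-0.5 * ((N - p) * (log(2 * pi) + log(sig2) + 1) +
                               logdetW + 2 * sum(log(diag(Ra)))))
    list(ll = ll, beta = as.vector(beta), sigma2 = sig2,
         vcov = sig2 * chol2inv(Ra))
  }

  # full 2-D optimum on the log-ratio scale
  obj <- function(par) eval2(exp(par[1]), exp(par[2]))$ll
  opt <- stats::optim(c(log(0.05), log(0.5)), obj, method = "Nelder-Mead",
                      control = list(fnscale = -1, reltol = 1e-12, maxit = 2000))
  # cage component at the zero boundary
  obj_c0 <- function(loglam_a) eval2(0, exp(loglam_a))$ll
  opt_c0 <- stats::optimize(obj_c0, c(log(1e-8), log(1e3)), maximum = TRUE, tol = 1e-10)

  if (opt$value > opt_c0$objective + 1e-8 && exp(opt$par[1]) > 1e-7) {
    lam_c <- exp(opt$par[1]); lam_a <- exp(opt$par[2]); boundary <- FALSE
  } else {
    lam_c <- 0; lam_a <- exp(opt_c0$maximum); boundary <- TRUE
  }
  fit <- eval2(lam_c, lam_a)
  structure(list(
    sigma2_between = lam_c * fit$sigma2,
    sigma2_within = fit$sigma2,
    sigma2_animal = lam_a * fit$sigma2,
    beta = setNames(fit$beta, colnames(X)),
    vcov_fixed = fit$vcov,
    reml_loglik = fit$ll,
    lambda = c(cage = lam_c, animal = lam_a),
    boundary = boundary,
    n_clusters = nlevels(cg),
    cluster_sizes = as.vector(table(cg)),
    X = X, y = y, cluster = cg, animal = an
  ), class = "variance_components")
}

#' Proportion-of-variance ICC from a two-level fit
#'
#' Cage-level variance share
#' `sigma2_cage / (sigma2_cage + sigma2_animal + sigma2_resid)` of a
#' two-level fit, bounded below by 0 by construction.
#'
#' @param vc A `variance_components` fit from [two_level_reml()].
#' @return An `icc_estimate` with method `"two_level_lmm"`.
#' @export
proportion_of_variance_icc <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  if (is.null(vc$sigma2_animal)) stop("vc must come from two_level_reml()")
  tot <- vc$sigma2_between + vc$sigma2_animal + vc$sigma2_within
  .icc_estimate("two_level_lmm", vc$sigma2_between / tot,
                n_clusters = vc$n_clusters,
                mean_cluster_size = mean(vc$cluster_sizes),
                boundary = vc$boundary,
                components = c(sigma2_cage = vc$sigma2_between,
                               sigma2_animal = vc$sigma2_animal,
                               sigma2_resid = vc$sigma2_within))
}
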