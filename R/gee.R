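# Gaussian identity-link GEE with an exchangeable working correlation.
# Alternates GLS coefficient updates with a moment update of the working
# correlation alpha from standardized residual cross-products; the inverse
# working correlation has the same closed form per cage as the mixed-model
# weights, so cost stays linear in the number of animals. Unlike the mixed
# model, alpha may be negative (down to the positive-semidefiniteness bound
# -1/(k_max - 1)), which is what makes GEE the unbiased route to the ICC.

#' Exchangeable working-correlation (GEE) estimate of the intra-cage correlation
#'
#' Fits the marginal mean model by iterating generalized least squares under
#' an exchangeable working correlation with a moment update
#' `alpha = sum of within-cage residual cross-products / (phi * n_pairs)`,
#' `phi = RSS / (N - p)`. During iteration `alpha` is clamped inside the
#' positive-semidefinite range `[-1/(k_max - 1) + eps, 1 - eps]`; the final
#' reported value is the unclamped interior fixed point when one exists.
#' Robust (sandwich) covariance for the coefficients is always attached;
#' the CI for `alpha` is a cage-level nonparametric bootstrap percentile
#' interval by default, or a leave-one-cage-out jackknife normal interval.
#'
#' @param formula Marginal mean model, e.g. `lifespan_months ~ sex + arm`.
#' @param data A `clustered_cohort` data frame (censored rows dropped).
#' @param cluster Cage identifier column name.
#' @param ci `"none"`, `"cluster_bootstrap"` (default when `B > 0`), or
#'   `"cluster_jackknife"`.
#' @param B Bootstrap resamples of cages (default 1000).
#' @param level CI coverage.
#' @param seed Optional integer seed for the bootstrap.
#' @param max_iter,tol Iteration controls.
#' @return An `icc_estimate` with method `"gee_exchangeable"`, plus
#'   `$beta`, `$vcov_sandwich`, `$phi`, and `$n_iter`. Fewer than 20 cages
#'   triggers a warning (the sandwich variance and the moment update both
#'   assume many clusters).
#' @export
gee_exchangeable <- function(formula, data, cluster = "cage_id",
                             ci = c("none", "cluster_bootstrap", "cluster_jackknife"),
                             B = 1000, level = 0.95, seed = NULL,
                             max_iter = 100, tol = 1e-10) {
  ci <- match.arg(ci)
  data <- .drop_censored(data)
  if (!cluster %in% names(data)) stop(sprintf("column '%s' not found", cluster))
  vars <- all.vars(formula)
  cc <- stats::complete.cases(data[, c(vars, cluster), drop = FALSE])
  data <- data[cc, , drop = FALSE]
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  cl <- droplevels(factor(data[[cluster]]))
  fit <- .gee_core(y, X, cl, max_iter = max_iter, tol = tol)

  lo <- hi <- NA_real_
  if (ci == "cluster_bootstrap") {
    if (!is.null(seed)) set.seed(seed)
    m <- nlevels(cl)
    idx_by_cage <- split(seq_along(y), cl)
    alphas <- numeric(B)
    for (b in seq_len(B)) {
      pick <- sample.int(m, m, replace = TRUE)
      ix <- unlist(idx_by_cage[pick], use.names = FALSE)
      newcl <- factor(rep.int(seq_len(m), lengths(idx_by_cage)[pick]))
      alphas[b] <- .gee_core(y[ix], X[ix, , drop = FALSE], newcl,
                             max_iter = max_iter, tol = tol)$alpha
    }
    qq <- stats::quantile(alphas, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
    lo <- qq[1]; hi <- qq[2]
  } else if (ci == "cluster_jackknife") {
    m <- nlevels(cl)
    idx_by_cage <- split(seq_along(y), cl)
    av <- numeric(m)
    for (j in seq_len(m)) {
      ix <- setdiff(seq_along(y), idx_by_cage[[j]])
      av[j] <- .gee_core(y[ix], X[ix, , drop = FALSE], droplevels(cl[ix]),
                         max_iter = max_iter, tol = tol)$alpha
    }
    se <- sqrt((m - 1) / m * sum((av - mean(av))^2))
    z <- stats::qnorm(1 - (1 - level) / 2)
    lo <- fit$alpha - z * se; hi <- fit$alpha + z * se
  }

  k <- as.vector(table(cl))
  out <- .icc_estimate("gee_exchangeable", fit$alpha, lo, hi, ci,
                       n_clusters = nlevels(cl), mean_cluster_size = mean(k),
                       beta = fit$beta, vcov_sandwich = fit$vcov_sandwich,
                       phi = fit$phi, n_iter = fit$n_iter)
  if (nlevels(cl) < 20)
    warning("fewer than 20 cages: GEE asymptotics are unreliable at this scale")
  out
}

# iteration engine on raw pieces; also used by the bootstrap and the trial
# analyzer
.gee_core <- function(y, X, cl, max_iter = 100, tol = 1e-10) {
  cl <- droplevels(factor(cl))
  g <- as.integer(cl)
  k <- as.vector(table(cl))
  kmax <- max(k)
  lb <- if (kmax > 1) -1 / (kmax - 1) else -1
  eps <- 1e-6
  N <- length(y); p <- ncol(X)
  n_pairs <- sum(k * (k - 1) / 2)
  if (n_pairs == 0) stop("no within-cage pairs: all cages are singletons")
  XtX <- crossprod(X)
  Sx <- rowsum(X, g)

  alpha <- 0
  beta <- as.vector(solve(XtX, crossprod(X, y)))
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    e <- y - as.vector(X %*% beta)
    phi <- sum(e^2) / (N - p)
    Se <- as.vector(rowsum(e, g))
    cross <- sum((Se^2 - as.vector(rowsum(e^2, g))) / 2)
    alpha_new <- cross / (phi * n_pairs)
    alpha_cl <- min(max(alpha_new, lb + eps), 1 - eps)
    cfac <- alpha_cl / (1 + alpha_cl * (k - 1))
    A1 <- XtX - t(Sx * cfac) %*% Sx
    Sy <- as.vector(rowsum(y, g))
    b1 <- crossprod(X, y) - crossprod(Sx, cfac * Sy)
    beta_new <- as.vector(solve(A1, b1))
    done <- abs(alpha_new - alpha) < tol && max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))
    alpha <- alpha_new; beta <- beta_new
    trace <- c(trace, alpha)
    if (done) break
    if (it == max_iter)
      stop(paste0("GEE failed to converge in ", max_iter, " iterations; alpha trace tail: ",
                  paste(signif(utils::tail(trace, 5), 6), collapse = ", ")))
  }

  # sandwich covariance at the final working correlation (clamped if needed)
  alpha_cl <- min(max(alpha, lb + eps), 1 - eps)
  cfac <- alpha_cl / (1 + alpha_cl * (k - 1))
  e <- y - as.vector(X %*% beta)
  Se <- as.vector(rowsum(e, g))
  Xe <- rowsum(X * e, g)                   # m x p: per-cage X_j' e_j
  G <- (Xe - Sx * (cfac * Se)) / (1 - alpha_cl)  # per-cage X_j' R_j^{-1} e_j
  A1 <- (XtX - t(Sx * cfac) %*% Sx) / (1 - alpha_cl)
  Ainv <- solve(A1)
  vcov_sand <- Ainv %*% crossprod(G) %*% Ainv

  list(alpha = alpha, beta = setNames(beta, colnames(X)),
       vcov_sandwich = vcov_sand, phi = sum(e^2) / (N - p), n_iter = it)
}
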