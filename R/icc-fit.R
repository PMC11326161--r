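# User-facing model interface: one fitting function returning a classed
# object, in the idiom of lm()/survfit(). Delegates to the ANOVA, REML and
# GEE engines.

#' Fit the intra-cage correlation of a clustered outcome
#'
#' Central fitting function of the package. Estimates the intra-class
#' (intra-cage) correlation of an outcome after adjusting for fixed-effect
#' covariates, by one of three routes:
#' \describe{
#'   \item{`"lmm"`}{random-intercept REML ([reml_random_intercept()]);
#'     ICC = `sigma2_between / (sigma2_between + sigma2_within)`, bounded
#'     below by 0. With `animal` supplied the two-level nested model
#'     ([two_level_reml()]) is fitted and the cage variance share reported.}
#'   \item{`"gee"`}{exchangeable working-correlation GEE
#'     ([gee_exchangeable()]); the working correlation `alpha` is the ICC
#'     and may be negative.}
#'   \item{`"anova"`}{one-way moment estimator ([anova_icc()]); may be
#'     negative.}
#' }
#'
#' @param formula Fixed-effect model formula, e.g.
#'   `lifespan_months ~ sex + arm`.
#' @param data A `clustered_cohort` (or, with `animal`, a
#'   `longitudinal_cohort`) data frame. Censored rows are dropped.
#' @param cluster Cage identifier column name.
#' @param animal Optional animal identifier column for two-level
#'   (repeated-measures) data; only valid with `method = "lmm"`.
#' @param method `"lmm"`, `"gee"`, or `"anova"`.
#' @param ci CI method: `"none"`, `"parametric_bootstrap"` (lmm),
#'   `"cluster_bootstrap"` or `"cluster_jackknife"` (gee).
#' @param B,level,seed CI controls.
#' @return An object of class `icc_fit`: the `icc_estimate`, the underlying
#'   engine fit, and the call. Methods: [print()], [summary()], [coef()],
#'   [confint()], [residuals()], [predict()], [simulate()], [plot()].
#' @examples
#' st <- make_cage_structure(50, 4)
#' coh <- sample_exchangeable_outcomes(st, icc = 0.05, seed = 1)
#' fit <- icc_fit(lifespan_months ~ arm, coh, method = "lmm")
#' fit
#' @export
icc_fit <- function(formula, data, cluster = "cage_id", animal = NULL,
                    method = c("lmm", "gee", "anova"),
                    ci = "none", B = 500, level = 0.95, seed = NULL) {
  method <- match.arg(method)
  if (!is.null(animal) && method != "lmm")
    stop("two-level (cage + animal) estimation is only available with method = \"lmm\"")

  if (method == "lmm") {
    if (is.null(animal)) {
      vc <- reml_random_intercept(formula, data, cluster)
      est <- lmm_icc(vc, ci = if (ci == "parametric_bootstrap") ci else "none",
                     B = B, level = level, seed = seed)
    } else {
      vc <- two_level_reml(formula, data, cage = cluster, animal = animal)
      est <- proportion_of_variance_icc(vc)
      if (ci == "parametric_bootstrap")
        warning("parametric bootstrap CI not implemented for the two-level model; returning point estimate")
    }
    fit <- vc
  } else if (method == "gee") {
    fit <- gee_exchangeable(formula, data, cluster,
                            ci = if (ci %in% c("cluster_bootstrap", "cluster_jackknife")) ci else "none",
                            B = B, level = level, seed = seed)
    est <- fit
  } else {
    ov <- all.vars(formula)[1]
    covs <- attr(stats::terms(formula), "term.labels")
    fit <- est <- anova_icc(data, residualize_on = covs, cluster = cluster, outcome = ov)
  }
  structure(list(estimate = est, engine = fit, method = method,
                 formula = formula, cluster = cluster, animal = animal,
                 call = match.call()),
            class = "icc_fit")
}

#' @export
print.icc_fit <- function(x, digits = 3, ...) {
  cat("Intra-cage correlation fit (method:", x$method, ")\n")
  cat("  model: ", deparse(x$formula), " + cage",
      if (!is.null(x$animal)) " + animal", " clustering\n", sep = "")
  print(x$estimate, digits = digits)
  invisible(x)
}

#' @export
summary.icc_fit <- function(object, ...) {
  est <- object$estimate
  out <- list(fit = object, estimate = est)
  if (inherits(object$engine, "variance_components")) {
    vc <- object$engine
    se <- sqrt(diag(vc$vcov_fixed))
    out$fixed <- data.frame(estimate = vc$beta, se = se,
                            z = vc$beta / se,
                            row.names = names(vc$beta))
    out$components <- c(sigma2_between = vc$sigma2_between,
                        sigma2_animal = if (!is.null(vc$sigma2_animal)) vc$sigma2_animal,
                        sigma2_within = vc$sigma2_within)
    out$boundary <- vc$boundary
  } else if (object$method == "gee") {
    se <- sqrt(diag(est$vcov_sandwich))
    out$fixed <- data.frame(estimate = est$beta, se = se, z = est$beta / se,
                            row.names = names(est$beta))
  }
  class(out) <- "summary.icc_fit"
  out
}

#' @export
print.summary.icc_fit <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  if (!is.null(x$components)) {
    cat("\nVariance components:\n")
    print(round(x$components, 5))
    if (isTRUE(x$boundary))
      cat("Note: between-cage variance fit at the zero boundary (possible negative ICC;\n",
          "compare the GEE or ANOVA estimate).\n", sep = "")
  }
  if (!is.null(x$fixed)) {
    cat("\nFixed effects", if (x$fit$method == "gee") " (robust/sandwich SE)", ":\n", sep = "")
    print(round(x$fixed, 4))
  }
  invisible(x)
}

#' @export
coef.icc_fit <- function(object, ...) {
  if (inherits(object$engine, "variance_components")) object$engine$beta
  else if (object$method == "gee") object$estimate$beta
  else stop("the ANOVA route has no fitted coefficients")
}

#' @export
confint.icc_fit <- function(object, parm = "icc", level = 0.95, B = 500, seed = NULL, ...) {
  est <- object$estimate
  if (!is.na(est$ci_low)) return(c(est$ci_low, est$ci_high))
  if (object$method == "lmm" && is.null(object$animal))
    return(parametric_bootstrap_ci(object$engine, B = max(B, 200), level = level, seed = seed))
  stop("no CI attached; refit with a ci= method")
}

#' @export
residuals.icc_fit <- function(object, ...) {
  if (inherits(object$engine, "variance_components"))
    as.vector(object$engine$y - object$engine$X %*% object$engine$beta)
  else stop("residuals available for REML fits only")
}

#' @export
predict.icc_fit <- function(object, newdata = NULL, ...) {
  if (!inherits(object$engine, "variance_components"))
    stop("predict available for REML fits only")
  vc <- object$engine
  if (is.null(newdata)) return(as.vector(vc$X %*% vc$beta))
  X <- stats::model.matrix(stats::delete.response(stats::terms(object$formula)), newdata)
  as.vector(X %*% vc$beta)
}

#' @export
simulate.icc_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!inherits(object$engine, "variance_components") || !is.null(object$animal))
    stop("simulate available for one-level REML fits only")
  vc <- object$engine
  if (!is.null(seed)) set.seed(seed)
  mu <- as.vector(vc$X %*% vc$beta)
  idx <- as.integer(vc$cluster)
  out <- replicate(nsim, mu + stats::rnorm(vc$n_clusters, 0, sqrt(vc$sigma2_between))[idx] +
                     stats::rnorm(length(mu), 0, sqrt(vc$sigma2_within)))
  as.data.frame(out)
}

#' @export
plot.icc_fit <- function(x, max_cages = 60, ...) {
  if (!inherits(x$engine, "variance_components"))
    stop("plot available for REML fits only")
  r <- residuals(x)
  cl <- x$engine$cluster
  med <- tapply(r, cl, stats::median)
  keep <- levels(cl)[order(med)]
  if (length(keep) > max_cages)
    keep <- keep[round(seq(1, length(keep), length.out = max_cages))]
  sel <- cl %in% keep
  graphics::boxplot(r[sel] ~ factor(cl[sel], levels = keep),
                    xlab = "cage (sorted by median residual)",
                    ylab = "residual outcome", xaxt = "n", ...)
  invisible(x)
}

#' Cage-permutation significance test for the intra-cage correlation
#'
#' Tests the observed ICC against its permutation null: animals are
#' shuffled across cages within permutation strata (cages, not animals, are
#' the randomized units, so strata default to the treatment arm), each
#' cage keeping its size, and the ICC is recomputed for each shuffle. The
#' add-one p-value `(1 + #{null >= observed}) / (1 + n_perm)` is one-sided
#' against the clustering (positive-correlation) alternative by default.
#'
#' @param data A `clustered_cohort` data frame.
#' @param estimator `"anova"` (fast moment estimator, default) or `"gee"`.
#' @param n_perm Number of permutations (default 1000; estimates are
#'   typically stable beyond a few hundred).
#' @param strata Optional column name whose levels are permuted within
#'   (e.g. `"arm"`); `NULL` permutes across the whole cohort.
#' @param residualize_on Covariates regressed out before estimating
#'   (passed to [anova_icc()]) or included in the GEE mean model.
#' @param sided `"upper"` (default) or `"two"`.
#' @param cluster,outcome Column names.
#' @param seed Integer seed.
#' @return A `permutation_icc` object: observed ICC, the vector of null
#'   draws, and the p-value.
#' @export
permutation_icc_test <- function(data, estimator = c("anova", "gee"),
                                 n_perm = 1000, strata = "arm",
                                 residualize_on = character(0),
                                 sided = c("upper", "two"),
                                 cluster = "cage_id", outcome = "lifespan_months",
                                 seed = NULL) {
  estimator <- match.arg(estimator)
  sided <- match.arg(sided)
  if (n_perm < 300) warning("fewer than 300 permutations: p-values may be unstable")
  data <- .drop_censored(data)
  cl <- droplevels(factor(data[[cluster]]))
  strat <- if (is.null(strata)) factor(rep(1, nrow(data))) else factor(data[[strata]])
  if (any(tapply(as.character(cl), strat, function(x) length(unique(x))) < 2))
    stop("each permutation stratum needs at least 2 cages")

  est_fun <- if (estimator == "anova") {
    function(y) anova_icc(y, cluster = cl)$estimate
  } else {
    X <- if (length(residualize_on) > 0) {
      stats::model.matrix(stats::as.formula(paste("~", paste(residualize_on, collapse = "+"))), data)
    } else matrix(1, nrow(data), 1)
    function(y) .gee_core(y, X, cl)$alpha
  }

  y0 <- data[[outcome]]
  if (estimator == "anova" && length(residualize_on) > 0) {
    fml <- stats::as.formula(paste(outcome, "~", paste(residualize_on, collapse = "+")))
    y0 <- stats::residuals(stats::lm(fml, data = data))
  }
  observed <- est_fun(y0)

  if (!is.null(seed)) set.seed(seed)
  idx_by_str <- split(seq_along(y0), strat)
  null_draws <- numeric(n_perm)
  yp <- y0
  for (b in seq_len(n_perm)) {
    for (ix in idx_by_str) yp[ix] <- y0[sample(ix)]
    null_draws[b] <- est_fun(yp)
  }
  p <- if (sided == "upper") (1 + sum(null_draws >= observed)) / (1 + n_perm)
  else (1 + sum(abs(null_draws - mean(null_draws)) >= abs(observed - mean(null_draws)))) / (1 + n_perm)

  structure(list(observed_icc = observed, null_draws = null_draws,
                 p_value = p, n_permutations = n_perm, estimator = estimator,
                 sided = sided, seed = seed),
            class = "permutation_icc")
}

#' @export
print.permutation_icc <- function(x, digits = 3, ...) {
  cat(sprintf("Cage-permutation test (%s estimator, %s-sided)\n", x$estimator, x$sided))
  cat(sprintf("  observed ICC = %s, p = %s (%d permutations)\n",
              format(round(x$observed_icc, digits)),
              format(round(x$p_value, max(digits, ceiling(log10(x$n_permutations))))),
              x$n_permutations))
  invisible(x)
}

#' Joint Wald F-test for a fixed-effect term, with or without cage effects
#'
#' Tests a (possibly multi-level) categorical term by a Wald F-statistic on
#' the model's coefficient covariance: with `with_cage_effect = TRUE` the
#' REML/GLS covariance from the random-intercept fit and a between-cage
#' denominator df (number of cages minus the rank of the cage-level
#' design); with `FALSE` ordinary least squares with residual df. Running
#' both exposes the anti-conservative p-values that ignoring co-housing
#' produces under positive intra-cage correlation.
#'
#' @param formula Full fixed-effect model formula.
#' @param data A `clustered_cohort` data frame.
#' @param term Name of the term to test (must appear in the formula).
#' @param with_cage_effect Logical; include the cage random intercept?
#' @param cluster Cage identifier column.
#' @return A list with `F`, `df1`, `df2`, `p_value`, and `method`.
#' @export
joint_fixed_effect_test <- function(formula, data, term,
                                    with_cage_effect = TRUE,
                                    cluster = "cage_id") {
  data <- .drop_censored(data)
  tl <- attr(stats::terms(formula), "term.labels")
  if (!term %in% tl) stop(sprintf("term '%s' is not in the model formula", term))
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  asgn <- attr(X, "assign")
  cols <- which(asgn == which(tl == term))
  if (length(cols) == 0) stop(sprintf("term '%s' contributes no columns (aliased?)", term))
  cl <- droplevels(factor(data[[cluster]]))[seq_along(y)]

  if (with_cage_effect) {
    fit <- .reml_profile(y, X, cl)
    beta <- fit$beta; V <- fit$vcov_fixed
    Xc <- rowsum(X, as.integer(cl)) / as.vector(table(cl))  # cage-level design
    df2 <- nlevels(cl) - qr(Xc)$rank
  } else {
    A <- crossprod(X)
    beta <- as.vector(solve(A, crossprod(X, y)))
    r <- y - as.vector(X %*% beta)
    df2 <- length(y) - ncol(X)
    V <- sum(r^2) / df2 * solve(A)
  }
  b <- beta[cols]
  Vb <- V[cols, cols, drop = FALSE]
  q <- length(cols)
  Fstat <- as.numeric(crossprod(b, solve(Vb, b))) / q
  list(F = Fstat, df1 = q, df2 = df2,
       p_value = stats::pf(Fstat, q, df2, lower.tail = FALSE),
       method = if (with_cage_effect) "reml_gls" else "ols")
}
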