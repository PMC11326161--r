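# Moment (one-way ANOVA) estimator of the intra-class correlation, with the
# unbalanced-design average cluster size k0. Unlike the mixed model it can
# go negative, down to -1/(k_max - 1).

#' ANOVA (moment) estimator of the intra-cage correlation
#'
#' After optionally regressing covariates out of the outcome, computes the
#' one-way between/within mean squares over cages and returns
#' `(MSB - MSW) / (MSB + (k0 - 1) MSW)`, where for unbalanced designs
#' `k0 = (N - sum(k_j^2)/N) / (m - 1)`. The estimate can be negative, which
#' is how competition for shared resources within a cage shows up.
#'
#' @param data A `clustered_cohort` data frame (censored rows are dropped),
#'   or a numeric outcome vector when `cluster` is given as a factor.
#' @param residualize_on Character vector of covariate column names whose
#'   linear effect is removed (OLS) before the variance decomposition.
#' @param cluster Cage identifier column name (or a factor parallel to a
#'   numeric `data` vector).
#' @param outcome Outcome column name.
#' @return An `icc_estimate` with method `"anova"` and the mean squares in
#'   `$components`.
#' @examples
#' # perfect within-cage agreement
#' anova_icc(c(1, 1, -1, -1), cluster = factor(c("a", "a", "b", "b")))
#' @export
anova_icc <- function(data, residualize_on = character(0),
                      cluster = "cage_id", outcome = "lifespan_months") {
  if (is.numeric(data)) {
    y <- data
    cl <- droplevels(factor(cluster))
    stopifnot(length(y) == length(cl))
  } else {
    data <- .drop_censored(data)
    y <- data[[outcome]]
    cl <- droplevels(factor(data[[cluster]]))
    if (length(residualize_on) > 0) {
      fml <- stats::as.formula(paste(outcome, "~", paste(residualize_on, collapse = "+")))
      y <- stats::residuals(stats::lm(fml, data = data))
    }
  }
  m <- nlevels(cl)
  if (m < 2) stop("need at least 2 cages")
  k <- as.vector(table(cl))
  if (all(k < 2)) stop("all cages are singletons: within-cage mean square is undefined")
  N <- length(y)

  cage_mean <- as.vector(rowsum(y, as.integer(cl))) / k
  grand <- mean(y)
  ssb <- sum(k * (cage_mean - grand)^2)
  ssw <- sum((y - cage_mean[as.integer(cl)])^2)
  msb <- ssb / (m - 1)
  msw <- ssw / (N - m)
  k0 <- (N - sum(k^2) / N) / (m - 1)
  est <- (msb - msw) / (msb + (k0 - 1) * msw)
  .icc_estimate("anova", est,
                n_clusters = m, mean_cluster_size = mean(k),
                components = c(msb = msb, msw = msw, k0 = k0))
}
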