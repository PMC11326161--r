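# Monte Carlo engine for two-arm cage-randomized trials: simulate cohorts
# over ICC x size grids, analyze each replicate with methods that do or do
# not account for clustering, and summarize empirical rejection rates.

#' Analyze one two-arm trial by a chosen method
#'
#' Returns the two-sided p-value for the arm effect under one of:
#' \describe{
#'   \item{`"LM"`}{ordinary regression t-test, ignoring cages (censored
#'     rows dropped).}
#'   \item{`"LMM"`}{Wald F from the cage random-intercept REML fit with
#'     between-cage denominator df.}
#'   \item{`"GEE"`}{sandwich-variance Wald z from the exchangeable GEE fit.}
#'   \item{`"LOGRANK"`}{two-group log-rank test (the score-test equivalent
#'     of a proportional-hazards fit) honoring censor flags but naive to
#'     clustering.}
#' }
#'
#' @param cohort A `clustered_cohort` with exactly two arms.
#' @param method One of `"LM"`, `"LMM"`, `"GEE"`, `"LOGRANK"`.
#' @param cluster,outcome Column names.
#' @return A single p-value.
#' @export
analyze_trial <- function(cohort, method = c("LM", "LMM", "GEE", "LOGRANK"),
                          cluster = "cage_id", outcome = "lifespan_months") {
  method <- match.arg(method)
  arms <- droplevels(factor(cohort$arm))
  if (nlevels(arms) != 2) stop("analyze_trial needs exactly two arms")
  fml <- stats::as.formula(paste(outcome, "~ arm"))

  if (method == "LM") {
    d <- .drop_censored(cohort)
    fit <- stats::lm(fml, data = d)
    return(summary(fit)$coefficients[2, 4])
  }
  if (method == "LMM") {
    jt <- joint_fixed_effect_test(fml, cohort, term = "arm",
                                  with_cage_effect = TRUE, cluster = cluster)
    return(jt$p_value)
  }
  if (method == "GEE") {
    fit <- gee_exchangeable(fml, cohort, cluster = cluster, ci = "none")
    z <- fit$beta[2] / sqrt(fit$vcov_sandwich[2, 2])
    return(as.numeric(2 * stats::pnorm(-abs(z))))
  }
  # LOGRANK
  event <- if ("censored" %in% names(cohort)) !cohort$censored else rep(TRUE, nrow(cohort))
  sd <- survival::survdiff(survival::Surv(cohort[[outcome]], event) ~ arms)
  as.numeric(stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Define a simulated trial scenario
#'
#' Bundles the design of one simulated two-arm cage-randomized trial. When
#' `n_per_group` is not divisible by `cluster_size` the last cage of each
#' arm is partial.
#'
#' @param n_per_group Animals per arm.
#' @param cluster_size Animals per cage.
#' @param icc Ground-truth intra-cage correlation.
#' @param effect_frac Fractional shift of the treated-arm mean (0 = null).
#' @param marginal_mean,marginal_sd,marginal_family,censor_rate Passed to
#'   [sample_exchangeable_outcomes()].
#' @param n_reps Monte Carlo replicates (>= 100).
#' @param alpha Nominal test level.
#' @param seed Integer seed; replicate streams are derived from it.
#' @return A `trial_scenario` list.
#' @export
trial_scenario <- function(n_per_group, cluster_size, icc = 0, effect_frac = 0,
                           marginal_mean = 30, marginal_sd = 5,
                           marginal_family = "gaussian", censor_rate = 0,
                           n_reps = 1000, alpha = 0.05, seed = 1) {
  stopifnot(n_per_group >= cluster_size, cluster_size >= 1, n_reps >= 100)
  if (cluster_size > 1 && icc < -1 / (cluster_size - 1))
    stop("icc below the exchangeable positive-semidefiniteness bound")
  structure(list(n_per_group = as.integer(n_per_group),
                 cluster_size = as.integer(cluster_size), icc = icc,
                 effect_frac = effect_frac, marginal_mean = marginal_mean,
                 marginal_sd = marginal_sd, marginal_family = marginal_family,
                 censor_rate = censor_rate, n_reps = as.integer(n_reps),
                 alpha = alpha, seed = as.integer(seed)),
            class = "trial_scenario")
}

# cage sizes for one arm, allowing a partial last cage
.arm_sizes <- function(n_per_group, k) {
  full <- n_per_group %/% k
  rem <- n_per_group %% k
  c(rep(k, full), if (rem > 0) rem)
}

# generate one replicate cohort for a scenario
.simulate_trial <- function(sc, rep_seed) {
  sizes <- .arm_sizes(sc$n_per_group, sc$cluster_size)
  st <- make_cage_structure(length(sizes), rep(sizes, 2), n_arms = 2)
  sample_exchangeable_outcomes(
    st, icc = sc$icc, marginal_mean = sc$marginal_mean,
    marginal_sd = sc$marginal_sd,
    effect = sc$effect_frac * sc$marginal_mean,
    family = sc$marginal_family, censor_rate = sc$censor_rate,
    seed = rep_seed)
}

#' Run a grid of simulated trial scenarios
#'
#' For each scenario and analysis method, simulates `n_reps` trials,
#' analyzes each replicate, and reports the empirical rejection rate at
#' the scenario's nominal level with its Monte Carlo standard error
#' `sqrt(r (1 - r) / n_reps)`. Replicate seeds are derived from the
#' scenario seed by counter-based substreams, so results do not depend on
#' execution order. Scenarios with fewer than 20 cages per arm are flagged
#' (`small_sample = TRUE`): sandwich/REML asymptotics assume many cages.
#'
#' @param scenarios A `trial_scenario` or list of them.
#' @param methods Subset of `c("LM", "LMM", "GEE", "LOGRANK")`.
#' @param keep_pvalues Return the raw p-value matrix per scenario
#'   (for distribution diagnostics)?
#' @return A data frame of class `power_result`, one row per scenario x
#'   method: `icc`, `n_per_group`, `cluster_size`, `effect_frac`, `method`,
#'   `rejection_rate`, `mc_se`, `n_reps`, `seed`, `small_sample`. With
#'   `keep_pvalues = TRUE`, the matrices are in `attr(, "pvalues")`.
#' @export
run_power_grid <- function(scenarios, methods = c("LM", "LMM", "GEE"),
                           keep_pvalues = FALSE) {
  if (inherits(scenarios, "trial_scenario")) scenarios <- list(scenarios)
  methods <- match.arg(methods, c("LM", "LMM", "GEE", "LOGRANK"), several.ok = TRUE)
  rows <- list(); pstore <- list()
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    stopifnot(inherits(sc, "trial_scenario"))
    P <- matrix(NA_real_, sc$n_reps, length(methods),
                dimnames = list(NULL, methods))
    failures <- 0L
    for (r in seq_len(sc$n_reps)) {
      coh <- .simulate_trial(sc, substream_seed(sc$seed, r))
      for (mth in methods) {
        pv <- tryCatch(analyze_trial(coh, mth), error = function(e) NA_real_)
        if (is.na(pv)) failures <- failures + 1L
        P[r, mth] <- pv
      }
    }
    if (failures > 0.02 * sc$n_reps * length(methods))
      stop(sprintf("scenario %d: %d replicate analyses failed (> 2%%)", si, failures))
    n_cages_arm <- length(.arm_sizes(sc$n_per_group, sc$cluster_size))
    for (mth in methods) {
      rate <- mean(P[, mth] < sc$alpha, na.rm = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        icc = sc$icc, n_per_group = sc$n_per_group,
        cluster_size = sc$cluster_size, effect_frac = sc$effect_frac,
        method = mth, rejection_rate = rate,
        mc_se = sqrt(rate * (1 - rate) / sc$n_reps),
        n_reps = sc$n_reps, seed = sc$seed,
        small_sample = n_cages_arm < 20)
    }
    if (keep_pvalues) pstore[[si]] <- P
  }
  out <- do.call(rbind, rows)
  class(out) <- c("power_result", "data.frame")
  if (keep_pvalues) attr(out, "pvalues") <- pstore
  out
}

#' Diagnostics for skew of a null p-value distribution
#'
#' Under a correctly calibrated test, null p-values are uniform on (0, 1).
#' Ignoring positive intra-cage correlation skews them toward 0
#' (anti-conservative); negative correlation skews them toward 1
#' (conservative). Reports the one-sample Kolmogorov-Smirnov distance from
#' U(0,1), the mean shift from 0.5 as skew direction, and decile counts.
#'
#' @param pvals Numeric vector of at least 100 p-values in `[0, 1]`.
#' @return A list: `ks_distance`, `ks_p_value`, `skew` (mean - 0.5;
#'   negative = skewed toward 0), `decile_counts`, `n`.
#' @export
pvalue_skew_diagnostics <- function(pvals) {
  pvals <- pvals[!is.na(pvals)]
  if (length(pvals) < 100) stop("need at least 100 p-values")
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  list(ks_distance = as.numeric(ks$statistic),
       ks_p_value = ks$p.value,
       skew = mean(pvals) - 0.5,
       decile_counts = as.vector(table(cut(pvals, seq(0, 1, 0.1), include.lowest = TRUE))),
       n = length(pvals))
}
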