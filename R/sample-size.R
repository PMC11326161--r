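# Closed-form cluster-randomized sample sizes: the independent-data
# two-sample n inflated by the design effect DE = 1 + (k - 1) * ICC.

#' Cluster design effect
#'
#' Variance inflation factor `1 + (cluster_size - 1) * icc` that multiplies
#' the independent-data sample size of a comparison of means when treatment
#' is randomized by cage.
#'
#' @param cluster_size Animals per cage (>= 1).
#' @param icc Intra-cage correlation; must be at least
#'   `-1/(cluster_size - 1)` for `cluster_size > 1`.
#' @return The design effect (1 for singleton cages, any `icc`).
#' @examples
#' design_effect(4, 0.05) # 1.15
#' @export
design_effect <- function(cluster_size, icc) {
  stopifnot(cluster_size >= 1)
  if (any(cluster_size > 1 & icc < -1 / (pmax(cluster_size, 2) - 1)))
    stop("icc below the exchangeable positive-semidefiniteness bound -1/(k-1)")
  1 + (cluster_size - 1) * icc
}

#' Unrounded two-sample n per group for a fractional mean shift
#'
#' Normal-approximation sample size for a two-arm comparison of means with
#' equal allocation:
#' `n = (1 + 1/ratio) * (z_{1-alpha/2} + z_{power})^2 * sd^2 / (effect_frac * mean)^2`
#' per (first) group. A t-quantile variant iterates the df until stable.
#'
#' @param mean,sd Outcome mean and SD (any units; the paper-style worked
#'   example uses days).
#' @param effect_frac Fractional mean shift to detect (e.g. 0.10).
#' @param alpha Two-sided type-I level.
#' @param power Target power `1 - beta`.
#' @param quantiles `"z"` (default, normal) or `"t"`.
#' @param allocation_ratio `n2 / n1` (default 1, equal allocation).
#' @return Unrounded n per group (first group under unequal allocation).
#' @examples
#' base_n_two_sample(912, 143, 0.10) # about 38.6
#' @export
base_n_two_sample <- function(mean, sd, effect_frac, alpha = 0.05, power = 0.8,
                              quantiles = c("z", "t"), allocation_ratio = 1) {
  quantiles <- match.arg(quantiles)
  stopifnot(effect_frac > 0, alpha > 0, alpha < 1, power > 0, power < 1,
            sd >= 0, mean > 0, allocation_ratio > 0)
  delta <- effect_frac * mean
  mult <- 1 + 1 / allocation_ratio
  zq <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  n <- mult * zq^2 * sd^2 / delta^2
  if (quantiles == "t") {
    for (i in 1:25) {
      df <- max(mult * n - 2, 2)
      tq <- stats::qt(1 - alpha / 2, df) + stats::qt(power, df)
      n_new <- mult * tq^2 * sd^2 / delta^2
      if (abs(n_new - n) < 1e-10) break
      n <- n_new
    }
  }
  n
}

#' Required n per group for a cage-randomized trial
#'
#' Ceiling of the unrounded two-sample n per group after inflation by the
#' design effect: `ceiling(base_n * (1 + (cluster_size - 1) * icc))`.
#' Rounding is applied once, after inflation.
#'
#' @inheritParams base_n_two_sample
#' @param icc Intra-cage correlation (>= 0 for design purposes).
#' @param cluster_size Animals per cage.
#' @return Integer n per group.
#' @examples
#' # the worked example: mean 912 d, SD 143, 10% effect, power 0.8, cages of 4
#' sapply(c(0, 0.01, 0.05, 0.1), function(icc)
#'   n_per_group(912, 143, 0.10, icc = icc, cluster_size = 4))
#' @export
n_per_group <- function(mean, sd, effect_frac = 0.10, alpha = 0.05, power = 0.8,
                        icc = 0, cluster_size = 1,
                        quantiles = c("z", "t"), allocation_ratio = 1) {
  stopifnot(icc >= 0, icc < 1, cluster_size >= 1)
  base <- base_n_two_sample(mean, sd, effect_frac, alpha, power,
                            quantiles = match.arg(quantiles),
                            allocation_ratio = allocation_ratio)
  as.integer(ceiling(base * design_effect(cluster_size, icc)))
}

#' Sample-size grid over strata, ICC, and cluster size
#'
#' Full factorial grid of [n_per_group()] over user-supplied strata (each
#' with its own mean and SD, e.g. strain-by-sex cells) by ICC values and
#' cluster sizes.
#'
#' @param strata Data frame with columns `stratum`, `mean`, `sd`.
#' @param icc_list,k_list Grid axes (nonempty).
#' @inheritParams base_n_two_sample
#' @return Long data frame: `stratum`, `mean`, `sd`, `icc`, `cluster_size`,
#'   `n_per_group`; nondecreasing in `icc` and (for positive `icc`) in
#'   `cluster_size`.
#' @export
sample_size_grid <- function(strata, icc_list = c(0, 0.01, 0.05, 0.1),
                             k_list = c(4, 6, 8),
                             effect_frac = 0.10, alpha = 0.05, power = 0.8) {
  stopifnot(is.data.frame(strata), all(c("stratum", "mean", "sd") %in% names(strata)),
            length(icc_list) > 0, length(k_list) > 0,
            all(strata$mean > 0), all(strata$sd > 0))
  grid <- expand.grid(si = seq_len(nrow(strata)), icc = icc_list,
                      cluster_size = k_list, KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(
    stratum = strata$stratum[grid$si],
    mean = strata$mean[grid$si],
    sd = strata$sd[grid$si],
    icc = grid$icc,
    cluster_size = grid$cluster_size)
  out$n_per_group <- mapply(function(m, s, icc, k)
    n_per_group(m, s, effect_frac, alpha, power, icc = icc, cluster_size = k),
    out$mean, out$sd, out$icc, out$cluster_size)
  out[order(out$stratum, out$cluster_size, out$icc), , drop = FALSE]
}
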