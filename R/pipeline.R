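# End-to-end pipeline: config-driven generate/ingest -> batch adjustment ->
# ICC estimation by all methods -> permutation test -> optional power grid
# and sample-size table, with CSV outputs and a JSON run manifest.

.validate_config <- function(config) {
  known <- c("seed", "data", "generate", "batch_adjust", "icc", "permutation",
             "power_grid", "sample_size", "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0)
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  if (is.null(config$data) && is.null(config$generate))
    stop("config needs either a 'data' path or a 'generate' block")
  if (!is.null(config$generate)) {
    gknown <- c("n_cages_per_arm", "cluster_size", "n_arms", "icc", "marginal_mean",
                "marginal_sd", "effect", "family", "censor_rate",
                "batch_labels", "batch_shifts")
    gunknown <- setdiff(names(config$generate), gknown)
    if (length(gunknown) > 0)
      stop(sprintf("unknown generate field(s): %s", paste(gunknown, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Run the full co-housing analysis pipeline from a config
#'
#' Executes generate-or-ingest, optional batch adjustment, ICC estimation
#' by ANOVA, REML-LMM and GEE, a cage-permutation test, and (if configured)
#' a power grid and a sample-size table. Writes result CSVs plus a JSON
#' manifest recording seeds, row counts, and every dropped row's reason.
#' Rerunning the same config and seed reproduces the outputs byte for byte.
#'
#' @param config Path to a YAML/JSON config file, or an equivalent named
#'   list. Fields: `seed`; either `data` (cohort CSV path) or `generate`
#'   (arguments for [make_cage_structure()]/[sample_exchangeable_outcomes()]);
#'   optional `batch_adjust` (`batch`, `fixed_terms`), `icc`
#'   (`fixed_terms`), `permutation` (`n_perm`, `estimator`, `strata`),
#'   `power_grid` (scenario fields, vectors crossed), `sample_size`
#'   (`strata` data frame or CSV path, `icc_list`, `k_list`), `out_dir`.
#' @param out_dir Output directory (overrides the config field).
#' @return Invisibly, a list with the cohort, the `icc_estimate`s, the
#'   permutation result, optional power/sample-size tables, and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  t0 <- Sys.time()
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  .validate_config(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- if (!is.null(out_dir)) out_dir else config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_stage <- function(fmt, ...) message(sprintf(paste0("[cagecor] ", fmt), ...))

  manifest <- list(config = config, seed = seed,
                   package_version = as.character(utils::packageVersion("cagecor")),
                   started = format(t0, "%Y-%m-%dT%H:%M:%S"))

  # --- stage 1: generate or ingest -----------------------------------------
  if (!is.null(config$data)) {
    cohort <- read_cohort_csv(config$data)
    log_stage("read %d rows from %s", nrow(cohort), config$data)
  } else {
    g <- config$generate
    st <- make_cage_structure(g$n_cages_per_arm, g$cluster_size,
                              n_arms = if (is.null(g$n_arms)) 2 else g$n_arms,
                              seed = seed)
    cohort <- sample_exchangeable_outcomes(
      st, icc = if (is.null(g$icc)) 0 else g$icc,
      marginal_mean = if (is.null(g$marginal_mean)) 30 else g$marginal_mean,
      marginal_sd = if (is.null(g$marginal_sd)) 5 else g$marginal_sd,
      effect = if (is.null(g$effect)) 0 else g$effect,
      family = if (is.null(g$family)) "gaussian" else g$family,
      censor_rate = if (is.null(g$censor_rate)) 0 else g$censor_rate,
      batch_labels = g$batch_labels, batch_shifts = g$batch_shifts,
      seed = substream_seed(seed, 10))
    log_stage("generated %d animals in %d cages", nrow(cohort), nrow(st))
  }
  rows_in <- nrow(cohort)

  # --- stage 2: batch adjustment -------------------------------------------
  n_outliers <- 0L; n_dropped_neg <- 0L
  if (!is.null(config$batch_adjust)) {
    ba <- config$batch_adjust
    cohort <- remove_batch_effects(
      cohort,
      batch = if (is.null(ba$batch)) "batch" else ba$batch,
      fixed_terms = if (is.null(ba$fixed_terms)) character(0) else ba$fixed_terms)
    rep <- attr(cohort, "batch_report")
    n_outliers <- rep$n_outliers
    n_dropped_neg <- rep$n_dropped_nonpositive
    manifest$batch_coefficients <- as.list(rep$batch_coefficients)
    log_stage("batch adjustment: %d outliers trimmed from fit, %d non-positive rows dropped",
              n_outliers, n_dropped_neg)
  }

  # --- stage 3: ICC estimates, all methods ---------------------------------
  fixed <- if (!is.null(config$icc)) config$icc$fixed_terms else "arm"
  fixed <- intersect(fixed, names(cohort))
  fixed <- fixed[vapply(fixed, function(cn) length(unique(cohort[[cn]])) > 1, logical(1))]
  fml <- stats::as.formula(paste("lifespan_months ~",
                                 if (length(fixed) > 0) paste(fixed, collapse = "+") else "1"))
  estimates <- list(
    anova = anova_icc(cohort, residualize_on = fixed),
    lmm_reml = lmm_icc(reml_random_intercept(fml, cohort),
                       ci = "parametric_bootstrap", B = 500,
                       seed = substream_seed(seed, 20)),
    gee_exchangeable = gee_exchangeable(fml, cohort, ci = "cluster_bootstrap",
                                        B = 500, seed = substream_seed(seed, 21)))
  log_stage("ICC estimates: anova %.4f, lmm %.4f, gee %.4f",
            estimates$anova$estimate, estimates$lmm_reml$estimate,
            estimates$gee_exchangeable$estimate)
  icc_table <- summarize_icc_table(estimates)

  # --- stage 4: permutation test -------------------------------------------
  pm <- config$permutation
  perm <- permutation_icc_test(
    cohort,
    estimator = if (is.null(pm$estimator)) "anova" else pm$estimator,
    n_perm = if (is.null(pm$n_perm)) 1000 else pm$n_perm,
    strata = if (is.null(pm$strata)) "arm" else pm$strata,
    residualize_on = fixed,
    seed = substream_seed(seed, 30))
  log_stage("permutation test: observed %.4f, p = %.4f", perm$observed_icc, perm$p_value)

  # --- optional stages ------------------------------------------------------
  power_table <- NULL
  if (!is.null(config$power_grid)) {
    pg <- config$power_grid
    grid <- expand.grid(icc = pg$icc, n_per_group = pg$n_per_group,
                        KEEP.OUT.ATTRS = FALSE)
    scenarios <- lapply(seq_len(nrow(grid)), function(i)
      trial_scenario(grid$n_per_group[i],
                     cluster_size = if (is.null(pg$cluster_size)) 4 else pg$cluster_size,
                     icc = grid$icc[i],
                     effect_frac = if (is.null(pg$effect_frac)) 0 else pg$effect_frac,
                     n_reps = if (is.null(pg$n_reps)) 500 else pg$n_reps,
                     seed = substream_seed(seed, 40 + i)))
    power_table <- run_power_grid(scenarios,
                                  methods = if (is.null(pg$methods)) c("LM", "LMM", "GEE") else pg$methods)
    log_stage("power grid: %d scenario x method cells", nrow(power_table))
  }
  ss_table <- NULL
  if (!is.null(config$sample_size)) {
    sscfg <- config$sample_size
    strata <- if (is.character(sscfg$strata)) utils::read.csv(sscfg$strata) else
      as.data.frame(sscfg$strata)
    ss_table <- sample_size_grid(strata,
                                 icc_list = if (is.null(sscfg$icc_list)) c(0, 0.01, 0.05, 0.1) else sscfg$icc_list,
                                 k_list = if (is.null(sscfg$k_list)) c(4, 6, 8) else sscfg$k_list)
    log_stage("sample-size grid: %d cells", nrow(ss_table))
  }

  # each dropped row is attributed to exactly one rule: the negative-adjusted
  # drop happens inside remove_batch_effects; censored rows are counted among
  # the survivors of that stage
  n_censored <- sum(cohort$censored)
  manifest$rows <- list(read = rows_in, analyzed = nrow(.drop_censored(cohort)),
                        dropped_censored = n_censored,
                        dropped_negative_adjusted = n_dropped_neg,
                        outliers_flagged_for_fit = n_outliers)
  manifest$seeds <- list(global = seed,
                         generate = substream_seed(seed, 10),
                         lmm_bootstrap = substream_seed(seed, 20),
                         gee_bootstrap = substream_seed(seed, 21),
                         permutation = substream_seed(seed, 30))
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  if (!is.null(out_dir)) {
    utils::write.csv(icc_table, file.path(out_dir, "icc_estimates.csv"), row.names = FALSE)
    utils::write.csv(data.frame(observed_icc = perm$observed_icc,
                                p_value = perm$p_value,
                                n_permutations = perm$n_permutations),
                     file.path(out_dir, "permutation_test.csv"), row.names = FALSE)
    if (!is.null(power_table))
      utils::write.csv(power_table, file.path(out_dir, "power_grid.csv"), row.names = FALSE)
    if (!is.null(ss_table))
      utils::write.csv(ss_table, file.path(out_dir, "sample_size_grid.csv"), row.names = FALSE)
    man <- manifest
    # keep written outputs reproducible across runs and locations
    man$finished <- NULL; man$elapsed_s <- NULL; man$started <- NULL
    man$config$out_dir <- NULL
    jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  invisible(list(cohort = cohort, estimates = estimates, icc_table = icc_table,
                 permutation = perm, power = power_table, sample_size = ss_table,
                 manifest = manifest))
}

#' Format ICC estimates as a summary table
#'
#' One row per estimate with `est (lo, hi)` formatting to three decimals,
#' the layout used for side-by-side method comparisons.
#'
#' @param estimates A single `icc_estimate`, or a (possibly named) list of
#'   them; empty entries are omitted.
#' @return A data frame: `label`, `method`, `estimate`, `ci_low`,
#'   `ci_high`, `formatted`.
#' @export
summarize_icc_table <- function(estimates) {
  if (inherits(estimates, "icc_estimate")) estimates <- list(estimates)
  estimates <- Filter(Negate(is.null), estimates)
  if (length(estimates) == 0) stop("no estimates supplied")
  labels <- names(estimates)
  if (is.null(labels)) labels <- vapply(estimates, function(e) e$method, character(1))
  fmt1 <- function(v) ifelse(is.na(v), "NA", formatC(round(v, 3), format = "g"))
  rows <- lapply(seq_along(estimates), function(i) {
    e <- estimates[[i]]
    data.frame(label = labels[i], method = e$method, estimate = e$estimate,
               ci_low = e$ci_low, ci_high = e$ci_high,
               formatted = sprintf("%s (%s, %s)", fmt1(e$estimate),
                                   fmt1(e$ci_low), fmt1(e$ci_high)))
  })
  do.call(rbind, rows)
}
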