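# Pre-analysis batch-effect removal: fit a mixed model with sum-to-zero
# batch coefficients on outlier-trimmed rows, subtract each row's batch
# coefficient, and sanitize the adjusted outcome.

#' Convert lifespans from days to months
#'
#' Uses the 30.4-day month convention of colony lifespan databases.
#'
#' @param days Numeric vector of durations in days.
#' @return `days / 30.4`.
#' @examples
#' days_to_months(912) # 30 months
#' @export
days_to_months <- function(days) {
  stopifnot(is.numeric(days))
  days / 30.4
}

#' Flag far outliers by the median +/- 3 IQR rule
#'
#' Marks values strictly beyond `median(x) +/- 3 * IQR(x)`. Used to trim the
#' fitting subset of the batch model so extreme lifespans do not drive the
#' batch coefficients; all rows are still adjusted.
#'
#' @param values Numeric vector with at least 4 finite entries.
#' @return Logical mask, `TRUE` for far outliers (all `FALSE` for constant
#'   input).
#' @examples
#' flag_far_outliers(c(10, 11, 12, 13, 100))
#' @export
flag_far_outliers <- function(values) {
  stopifnot(is.numeric(values))
  finite <- is.finite(values)
  if (sum(finite) < 4) stop("need at least 4 finite values")
  med <- stats::median(values[finite])
  iqr <- stats::IQR(values[finite])
  out <- rep(FALSE, length(values))
  out[finite] <- values[finite] < med - 3 * iqr | values[finite] > med + 3 * iqr
  out
}

# Names of columns aliased with earlier columns in the design matrix.
.aliased_columns <- function(X) {
  q <- qr(X)
  if (q$rank == ncol(X)) return(character(0))
  colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
}

#' Remove batch effects from a clustered cohort
#'
#' Fits a random-intercept model (cage intercepts) for the outcome with
#' sum-to-zero-coded batch coefficients plus any further fixed covariates,
#' on rows with far outliers removed, then subtracts each row's estimated
#' batch coefficient from the raw outcome. Because the coefficients are
#' sum-to-zero coded, the adjusted grand mean equals the raw grand mean up
#' to sampling balance. Rows whose adjusted outcome is non-positive are
#' dropped and counted.
#'
#' @param cohort A `clustered_cohort` data frame.
#' @param batch Name of the batch column (>= 2 levels for any adjustment;
#'   a single-level batch returns the cohort unchanged).
#' @param fixed_terms Character vector of additional fixed-effect covariate
#'   names (e.g. `c("sex", "arm")`); may be empty.
#' @param cluster Name of the cage identifier column.
#' @param outcome Name of the outcome column.
#' @return The cohort with the outcome column replaced by its adjusted
#'   value, an added `<outcome>_raw` column, and a `batch_report` attribute
#'   listing batch coefficients, outlier count, and dropped-row count.
#' @export
remove_batch_effects <- function(cohort, batch = "batch",
                                 fixed_terms = character(0),
                                 cluster = "cage_id",
                                 outcome = "lifespan_months") {
  for (col in c(batch, fixed_terms, cluster, outcome))
    if (!col %in% names(cohort)) stop(sprintf("column '%s' not found in cohort", col))
  if (batch == cluster) stop("batch and cluster must be distinct columns")

  y <- cohort[[outcome]]
  bf <- factor(cohort[[batch]])
  if (nlevels(bf) < 2) {
    report <- list(batch_levels = levels(bf), batch_coefficients = setNames(0, levels(bf)),
                   n_outliers = 0L, n_dropped_nonpositive = 0L, adjusted = FALSE)
    attr(cohort, "batch_report") <- report
    return(cohort)
  }

  # sum-to-zero batch coding; fixed covariates with default treatment coding
  terms_rhs <- paste(c(fixed_terms, batch), collapse = " + ")
  fml <- stats::as.formula(paste("~", terms_rhs))
  dat <- cohort
  dat[[batch]] <- bf
  mf <- stats::model.frame(fml, dat, na.action = stats::na.pass)
  contr <- list()
  contr[[batch]] <- "contr.sum"
  X <- stats::model.matrix(fml, mf, contrasts.arg = contr)

  aliased <- .aliased_columns(X)
  if (length(aliased) > 0)
    stop(sprintf("singular design: column(s) %s aliased with earlier terms; batch is confounded",
                 paste(aliased, collapse = ", ")))

  keep <- !flag_far_outliers(y)
  fit <- .reml_profile(y[keep], X[keep, , drop = FALSE], droplevels(factor(cohort[[cluster]][keep])))

  # batch coefficients on all levels (sum-to-zero: last level = -sum(others))
  bcols <- grep(paste0("^", batch), colnames(X))
  bco <- fit$beta[bcols]
  coefs <- c(bco, -sum(bco))
  names(coefs) <- levels(bf)
  adjusted <- y - coefs[as.character(bf)]

  drop_mask <- adjusted <= 0
  out <- cohort
  out[[paste0(outcome, "_raw")]] <- y
  out[[outcome]] <- as.numeric(adjusted)
  out <- out[!drop_mask, , drop = FALSE]
  attr(out, "batch_report") <- list(
    batch_levels = levels(bf),
    batch_coefficients = coefs,
    n_outliers = sum(!keep),
    n_dropped_nonpositive = sum(drop_mask),
    adjusted = TRUE
  )
  class(out) <- class(cohort)
  out
}
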