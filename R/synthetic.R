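# Synthetic clustered cohorts with known ground-truth intra-cage correlation.
# Treatments are assigned to whole cages (cluster-randomized design), so the
# generator builds a cage frame first and then draws animal outcomes from an
# exchangeable within-cage covariance.

#' Build a cage structure for a cluster-randomized design
#'
#' Creates the cage-level frame of a cluster-randomized study: cage
#' identifiers, cage sizes, and arm labels, with treatment constant within
#' cage. Arms are filled in balanced blocks (`n_cages_per_arm` cages each).
#'
#' @param n_cages_per_arm Number of cages in each arm.
#' @param cluster_size Animals per cage; a scalar, or a vector of length
#'   `n_cages_per_arm * n_arms` giving each cage's size.
#' @param n_arms Number of treatment arms (default 2).
#' @param arm_labels Optional character labels, length `n_arms`.
#' @param seed Optional integer; recorded in the result so downstream draws
#'   can derive substreams from it.
#' @return A data frame of class `cage_structure` with columns `cage_id`
#'   (factor), `size` (integer) and `arm` (factor).
#' @examples
#' make_cage_structure(3, cluster_size = 4, n_arms = 2)
#' @export
make_cage_structure <- function(n_cages_per_arm, cluster_size, n_arms = 2,
                                arm_labels = NULL, seed = NULL) {
  stopifnot(n_cages_per_arm >= 1, n_arms >= 1)
  m <- as.integer(n_cages_per_arm) * as.integer(n_arms)
  sizes <- as.integer(rep_len(cluster_size, m))
  if (any(sizes < 1)) stop("all cluster sizes must be >= 1")
  if (is.null(arm_labels)) arm_labels <- paste0("arm", seq_len(n_arms))
  stopifnot(length(arm_labels) == n_arms)
  out <- data.frame(
    cage_id = factor(sprintf("C%05d", seq_len(m))),
    size = sizes,
    arm = factor(rep(arm_labels, each = n_cages_per_arm), levels = arm_labels)
  )
  attr(out, "seed") <- seed
  class(out) <- c("cage_structure", "data.frame")
  out
}

# Lower PSD bound of the exchangeable correlation for the largest cage.
.icc_lower_bound <- function(sizes) {
  kmax <- max(sizes)
  if (kmax <= 1) -1 else -1 / (kmax - 1)
}

# One exchangeable N(0, (1-rho) I + rho J) draw per cage, any rho above the
# PSD bound. Spectral form: sqrt(1-rho) on the centered part, sqrt(1+(k-1)rho)
# on the cage-mean direction.
.rexchangeable <- function(sizes, rho) {
  n <- sum(sizes)
  z <- stats::rnorm(n)
  g <- rep.int(seq_along(sizes), sizes)
  zbar <- rep.int(as.vector(rowsum(z, g)) / sizes, sizes)
  sqrt(1 - rho) * (z - zbar) + sqrt(1 + (rep.int(sizes, sizes) - 1) * rho) * zbar
}

# Weibull (shape, scale) matching a target mean and sd.
.weibull_from_moments <- function(mean, sd) {
  stopifnot(mean > 0, sd > 0)
  cv2 <- (sd / mean)^2
  f <- function(logk) {
    k <- exp(logk)
    gamma(1 + 2 / k) / gamma(1 + 1 / k)^2 - 1 - cv2
  }
  logk <- stats::uniroot(f, c(log(0.08), log(100)), tol = 1e-12)$root
  shape <- exp(logk)
  list(shape = shape, scale = mean / gamma(1 + 1 / shape))
}

#' Sample clustered outcomes with exchangeable within-cage correlation
#'
#' Draws one outcome per animal from a cage structure so that any two
#' cage-mates have correlation `icc` (the ground-truth intra-class
#' correlation). Non-negative `icc` is realised as a shared cage intercept
#' plus independent noise; negative `icc` uses a direct factorization of the
#' exchangeable covariance, which a shared intercept cannot produce. For the
#' `"gaussian-copula-weibull"` family, exchangeable standard-normal scores
#' are pushed through the probability-integral transform onto a Weibull
#' marginal with the requested mean and SD; the ground-truth `icc` then
#' refers to the latent normal scale (the outcome-scale correlation is
#' slightly attenuated), which is recorded in the attributes.
#'
#' @param structure A [make_cage_structure()] result.
#' @param icc Target pairwise within-cage correlation; must be at least
#'   `-1/(k_max - 1)` and below 1.
#' @param marginal_mean,marginal_sd Marginal mean and SD of the outcome
#'   (months of life under the defaults).
#' @param effect Additive arm shifts in outcome units: a scalar applied to
#'   the second arm (first arm is reference) or a vector with one shift per
#'   arm.
#' @param family `"gaussian"` (default) or `"gaussian-copula-weibull"`.
#' @param censor_rate Probability an animal is right-censored; applied via
#'   [apply_censoring()]. Kept below 0.04 by default settings to mirror
#'   typical colony records.
#' @param batch_labels,batch_shifts Optional batch structure: cages are
#'   assigned round-robin to `batch_labels` and each batch adds its
#'   `batch_shifts` entry to the outcome.
#' @param seed Integer seed (substreams are derived internally).
#' @return A data frame of class `clustered_cohort` with columns
#'   `animal_id`, `cage_id`, `arm`, `batch`, `lifespan_months`, `censored`.
#'   Attributes record the generating parameters.
#' @examples
#' st <- make_cage_structure(10, 4)
#' coh <- sample_exchangeable_outcomes(st, icc = 0.05, seed = 1)
#' head(coh)
#' @export
sample_exchangeable_outcomes <- function(structure, icc = 0,
                                         marginal_mean = 30, marginal_sd = 5,
                                         effect = 0,
                                         family = c("gaussian", "gaussian-copula-weibull"),
                                         censor_rate = 0,
                                         batch_labels = NULL, batch_shifts = NULL,
                                         seed = NULL) {
  family <- match.arg(family)
  stopifnot(inherits(structure, "cage_structure"))
  if (marginal_sd <= 0) stop("marginal_sd must be positive")
  lb <- .icc_lower_bound(structure$size)
  if (icc < lb - 1e-12 || icc >= 1)
    stop(sprintf("icc must lie in [%.4f, 1) for the largest cage size", lb))
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")

  sizes <- structure$size
  m <- nrow(structure)
  n <- sum(sizes)
  arms <- levels(structure$arm)
  shift <- if (length(effect) == 1 && length(arms) >= 2) {
    c(0, rep_len(effect, length(arms) - 1))
  } else rep_len(effect, length(arms))
  names(shift) <- arms

  .seed_substream(seed, 1)
  if (icc >= 0 && family == "gaussian") {
    b <- stats::rnorm(m, 0, sqrt(icc) * marginal_sd)
    e <- stats::rnorm(n, 0, sqrt(1 - icc) * marginal_sd)
    dev <- rep.int(b, sizes) + e
  } else {
    z <- .rexchangeable(sizes, icc)
    dev <- if (family == "gaussian") marginal_sd * z else z
  }

  arm_row <- rep.int(as.character(structure$arm), sizes)
  mu_row <- marginal_mean + shift[arm_row]
  if (family == "gaussian") {
    y <- mu_row + dev
  } else {
    u <- stats::pnorm(dev)
    y <- numeric(n)
    for (a in arms) {
      idx <- arm_row == a
      wb <- .weibull_from_moments(marginal_mean + shift[[a]], marginal_sd)
      y[idx] <- stats::qweibull(u[idx], shape = wb$shape, scale = wb$scale)
    }
  }

  batch_row <- NA_character_
  if (!is.null(batch_labels)) {
    if (is.null(batch_shifts)) batch_shifts <- rep(0, length(batch_labels))
    stopifnot(length(batch_shifts) == length(batch_labels))
    cage_batch <- rep_len(batch_labels, m)
    batch_row <- rep.int(as.character(cage_batch), sizes)
    y <- y + rep.int(batch_shifts[match(cage_batch, batch_labels)], sizes)
  }

  out <- data.frame(
    animal_id = sprintf("A%06d", seq_len(n)),
    cage_id = factor(rep.int(as.character(structure$cage_id), sizes)),
    arm = factor(arm_row, levels = arms),
    batch = factor(batch_row),
    lifespan_months = y,
    censored = FALSE
  )
  attr(out, "icc") <- icc
  attr(out, "icc_scale") <- if (family == "gaussian") "outcome" else "latent-normal"
  attr(out, "family") <- family
  attr(out, "marginal_mean") <- marginal_mean
  attr(out, "marginal_sd") <- marginal_sd
  class(out) <- c("clustered_cohort", "data.frame")
  if (censor_rate > 0) {
    out <- apply_censoring(out, censor_rate,
                           seed = if (is.null(seed)) NULL else substream_seed(seed, 2))
  }
  out
}

#' Right-censor a fraction of a clustered cohort
#'
#' Flags each animal independently with probability `censor_rate`; flagged
#' animals get a censoring time drawn uniformly below their event time and
#' `censored = TRUE`. Lifespan analyses that require complete outcomes drop
#' these rows.
#'
#' @param cohort A `clustered_cohort` data frame.
#' @param censor_rate Probability in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return The cohort with `lifespan_months` shortened and `censored` set on
#'   flagged rows.
#' @export
apply_censoring <- function(cohort, censor_rate, seed = NULL) {
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")
  if (censor_rate == 0) return(cohort)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)
  flag <- stats::runif(n) < censor_rate
  if (any(flag)) {
    cohort$lifespan_months[flag] <-
      stats::runif(sum(flag), 0, cohort$lifespan_months[flag])
    cohort$censored[flag] <- TRUE
  }
  cohort
}

#' Sample two-level longitudinal trait trajectories
#'
#' Generates repeated trait measurements nested animal-within-cage, the
#' structure of longitudinal phenotyping in dietary-intervention colonies:
#' trait value = diet (arm) effect + linear age trend + cage intercept +
#' animal intercept + noise. The three random components carry variance
#' shares `icc_cage`, `icc_animal` and `1 - icc_cage - icc_animal` of the
#' total random variance `residual_sd^2`.
#'
#' @param structure A [make_cage_structure()] result; arms play the role of
#'   diet groups.
#' @param icc_cage,icc_animal Non-negative variance shares with
#'   `icc_cage + icc_animal < 1`.
#' @param ages Vector of measurement ages (every animal is measured at each).
#' @param diet_effects Per-arm additive shifts (scalar recycled; first arm
#'   reference when scalar).
#' @param residual_sd Total SD of the random part (cage + animal + noise).
#' @param age_slope Fixed linear age trend in trait units per age unit.
#' @param trait_name Label stored in the `trait` column.
#' @param seed Integer seed.
#' @return A data frame of class `longitudinal_cohort` with columns
#'   `animal_id`, `cage_id`, `diet`, `age`, `trait`, `value`.
#' @examples
#' st <- make_cage_structure(5, 4, n_arms = 2)
#' traj <- sample_longitudinal(st, icc_cage = 0.05, icc_animal = 0.3,
#'                             ages = c(6, 12, 18), seed = 1)
#' @export
sample_longitudinal <- function(structure, icc_cage, icc_animal,
                                ages = c(6, 12, 18, 24, 30, 36),
                                diet_effects = 0, residual_sd = 1,
                                age_slope = 0.1, trait_name = "trait",
                                seed = NULL) {
  stopifnot(inherits(structure, "cage_structure"))
  if (icc_cage < 0 || icc_animal < 0 || icc_cage + icc_animal >= 1)
    stop("variance shares must satisfy icc_cage >= 0, icc_animal >= 0, icc_cage + icc_animal < 1")
  if (residual_sd <= 0) stop("residual_sd must be positive")

  sizes <- structure$size
  m <- nrow(structure)
  n_animal <- sum(sizes)
  t <- length(ages)
  arms <- levels(structure$arm)
  shift <- if (length(diet_effects) == 1 && length(arms) >= 2) {
    c(0, rep_len(diet_effects, length(arms) - 1))
  } else rep_len(diet_effects, length(arms))
  names(shift) <- arms

  .seed_substream(seed, 3)
  v <- residual_sd^2
  cage_int <- stats::rnorm(m, 0, sqrt(icc_cage * v))
  animal_int <- stats::rnorm(n_animal, 0, sqrt(icc_animal * v))
  noise <- stats::rnorm(n_animal * t, 0, sqrt((1 - icc_cage - icc_animal) * v))

  animal_id <- sprintf("A%06d", seq_len(n_animal))
  cage_row <- rep.int(as.character(structure$cage_id), sizes)
  arm_row <- rep.int(as.character(structure$arm), sizes)

  idx <- rep(seq_len(n_animal), each = t)
  out <- data.frame(
    animal_id = animal_id[idx],
    cage_id = factor(cage_row[idx]),
    diet = factor(arm_row[idx], levels = arms),
    age = rep(ages, times = n_animal),
    trait = trait_name,
    value = shift[arm_row[idx]] + age_slope * rep(ages, times = n_animal) +
      rep.int(cage_int, sizes * t) + animal_int[idx] + noise
  )
  attr(out, "icc_cage") <- icc_cage
  attr(out, "icc_animal") <- icc_animal
  attr(out, "residual_sd") <- residual_sd
  class(out) <- c("longitudinal_cohort", "data.frame")
  out
}

#' Read or write cohort tables as CSV
#'
#' Plain-CSV persistence for the cohort containers, with the header layout
#' used throughout the package.
#'
#' @param cohort A `clustered_cohort` or `longitudinal_cohort` data frame.
#' @param path File path.
#' @return `read_cohort_csv` returns the data frame with `cage_id` (and
#'   `arm`/`diet`) as factors; `write_cohort_csv` returns `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"cage_id" %in% names(df)) stop("cohort CSV must contain a cage_id column")
  df$cage_id <- factor(df$cage_id)
  for (col in c("arm", "diet", "batch", "sex", "strain"))
    if (col %in% names(df)) df[[col]] <- factor(df[[col]])
  cls <- if (all(c("age", "value") %in% names(df))) "longitudinal_cohort" else "clustered_cohort"
  class(df) <- c(cls, "data.frame")
  df
}
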