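test_that("cage structures have the requested counts and balanced arms", {
  st <- make_cage_structure(1, cluster_size = 4, n_arms = 2)
  expect_equal(nrow(st), 2)
  expect_equal(sum(st$size), 8)
  expect_true(all(st$size == 4))
  expect_equal(as.vector(table(st$arm)), c(1, 1))

  # one-arm survey housed 5 per cage
  st5 <- make_cage_structure(50, cluster_size = 5, n_arms = 1)
  expect_equal(sum(st5$size), 250)

  # five-arm dietary design housed 8 per cage
  st8 <- make_cage_structure(120, cluster_size = 8, n_arms = 5)
  expect_equal(nrow(st8), 600)
  expect_equal(sum(st8$size), 4800)
  expect_true(all(tapply(st8$arm, st8$cage_id, function(a) length(unique(a))) == 1))

  expect_error(make_cage_structure(0, 4), "n_cages_per_arm")
  expect_error(make_cage_structure(2, 0), "sizes")
})

test_that("generation is deterministic for a fixed seed and refuses bad parameters", {
  st <- make_cage_structure(10, 4)
  a <- sample_exchangeable_outcomes(st, icc = 0.05, seed = 11)
  b <- sample_exchangeable_outcomes(st, icc = 0.05, seed = 11)
  expect_identical(a, b)
  c <- sample_exchangeable_outcomes(st, icc = 0.05, seed = 12)
  expect_false(identical(a$lifespan_months, c$lifespan_months))

  # exchangeable PSD bound: k = 4 allows icc >= -1/3
  expect_error(sample_exchangeable_outcomes(st, icc = -0.34), "icc")
  expect_error(sample_exchangeable_outcomes(st, icc = 1), "icc")
  expect_error(sample_exchangeable_outcomes(st, icc = 0, marginal_sd = 0), "marginal_sd")
})

test_that("at the PSD bound (k=2, icc=-1) cage pairs sum to a constant", {
  st <- make_cage_structure(200, 2, n_arms = 1)
  coh <- sample_exchangeable_outcomes(st, icc = -1, marginal_mean = 30,
                                      marginal_sd = 5, seed = 4)
  sums <- tapply(coh$lifespan_months, coh$cage_id, sum)
  expect_lt(stats::var(sums), 1e-20)
  expect_equal(unname(sums[1]), 60, tolerance = 1e-12)
})

test_that("the moment estimator recovers ground-truth icc, positive and negative", {
  # 50 replicates x 300 cages per setting keeps this fast; the full
  # database-scale recovery grid runs in the acceptance suite
  for (icc in c(-0.1, 0, 0.05)) {
    est <- vapply(1:50, function(r) {
      coh <- make_test_cohort(300, 4, icc, seed = substream_seed(500 + icc * 100, r))
      anova_icc(coh)$estimate
    }, numeric(1))
    expect_lt(abs(mean(est) - icc), 3 * mc_se_mean(est))
  }
})

test_that("negative icc induces negative mean off-diagonal covariance within cages", {
  st <- make_cage_structure(800, 4, n_arms = 1)
  coh <- sample_exchangeable_outcomes(st, icc = -0.1, seed = 21)
  Y <- matrix(coh$lifespan_months, nrow = 4)  # animals x cage (balanced, in order)
  S <- stats::cov(t(Y))
  off <- S[upper.tri(S)]
  expect_lt(mean(off), 0)
})

test_that("copula-weibull outcomes match the requested marginal moments", {
  st <- make_cage_structure(25000, 4, n_arms = 1)
  coh <- sample_exchangeable_outcomes(st, icc = 0.05, marginal_mean = 30,
                                      marginal_sd = 5,
                                      family = "gaussian-copula-weibull",
                                      seed = 31)
  expect_equal(mean(coh$lifespan_months), 30, tolerance = 0.02 * 30)
  expect_equal(stats::sd(coh$lifespan_months), 5, tolerance = 0.02 * 5)
  expect_true(all(coh$lifespan_months > 0))
  expect_identical(attr(coh, "icc_scale"), "latent-normal")
})

test_that("censoring flags the expected fraction, below event times, deterministically", {
  st <- make_cage_structure(2500, 4, n_arms = 1)
  coh <- sample_exchangeable_outcomes(st, icc = 0, seed = 41)

  expect_identical(apply_censoring(coh, 0), coh)

  cen <- apply_censoring(coh, 0.04, seed = 42)
  n_flag <- sum(cen$censored)
  # binomial 99% interval around 400 of 10000
  expect_gte(n_flag, qbinom(0.005, 10000, 0.04))
  expect_lte(n_flag, qbinom(0.995, 10000, 0.04))
  expect_true(all(cen$lifespan_months[cen$censored] <
                    coh$lifespan_months[cen$censored]))

  small <- coh[1:4, ]
  f1 <- apply_censoring(small, 0.5, seed = 7)
  f2 <- apply_censoring(small, 0.5, seed = 7)
  expect_identical(f1, f2)
  expect_error(apply_censoring(coh, 1), "censor_rate")
})

test_that("longitudinal generator honors nesting, shares, and the degenerate cases", {
  st <- make_cage_structure(20, 4, n_arms = 2)
  tr <- sample_longitudinal(st, icc_cage = 0.05, icc_animal = 0.3,
                            ages = c(6, 12), seed = 51)
  expect_equal(nrow(tr), 160 * 2)
  # each (animal, trait, age) appears once; each animal in exactly one cage
  expect_false(any(duplicated(tr[, c("animal_id", "trait", "age")])))
  expect_true(all(tapply(as.character(tr$cage_id), tr$animal_id,
                         function(x) length(unique(x))) == 1))

  # iid case: no cage or animal clustering beyond noise
  st2 <- make_cage_structure(150, 4, n_arms = 1)
  tr0 <- sample_longitudinal(st2, 0, 0, ages = c(6, 12, 18), residual_sd = 2,
                             age_slope = 0, seed = 52)
  expect_equal(stats::sd(tr0$value), 2, tolerance = 0.1)
  expect_lt(abs(anova_icc(tr0$value, cluster = tr0$cage_id)$estimate), 0.05)

  # single age: collapses to a one-level exchangeable cohort
  tr1 <- sample_longitudinal(st2, icc_cage = 0.05, icc_animal = 0.3,
                             ages = 12, seed = 53)
  expect_equal(nrow(tr1), 600)

  expect_error(sample_longitudinal(st, -0.1, 0.3, ages = 1:2), "shares")
  expect_error(sample_longitudinal(st, 0.6, 0.5, ages = 1:2), "shares")
})

test_that("cohort CSV round-trips", {
  coh <- make_test_cohort(10, 4, 0.05, seed = 61)
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(coh, path)
  back <- read_cohort_csv(path)
  expect_equal(back$lifespan_months, coh$lifespan_months)
  expect_s3_class(back, "clustered_cohort")
  expect_identical(levels(back$cage_id), levels(coh$cage_id))
})

test_that("substream seeds are deterministic, distinct, and 32-bit safe", {
  s <- vapply(0:200, function(i) substream_seed(7, i), integer(1))
  expect_identical(s, vapply(0:200, function(i) substream_seed(7, i), integer(1)))
  expect_gt(length(unique(s)), 195)
  expect_true(all(s > 0 & s < 2^31))
  expect_false(substream_seed(7, 1) == substream_seed(8, 1))
})
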