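test_that("ANOVA ICC reproduces hand-computed degenerate cases", {
  # perfect within-cage agreement: MSW = 0 -> ICC = 1
  est1 <- anova_icc(c(1, 1, -1, -1), cluster = factor(c("a", "a", "b", "b")))
  expect_equal(est1$estimate, 1)

  # cage means all zero: MSB = 0, MSW = 5, k0 = 2 -> ICC = -1/(k-1) = -1
  est2 <- anova_icc(c(1, -1, 2, -2), cluster = factor(c("a", "a", "b", "b")))
  expect_equal(est2$estimate, -1)
  expect_equal(unname(est2$components["msw"]), 5)
  expect_equal(unname(est2$components["msb"]), 0)

  expect_error(anova_icc(c(1, 2), cluster = factor(c("a", "b"))), "singleton")
  expect_error(anova_icc(c(1, 2), cluster = factor(c("a", "a"))), "2 cages")
})

test_that("profiled REML matches the dense brute-force restricted likelihood", {
  # unbalanced cages, a covariate, 180 animals
  st <- make_cage_structure(25, c(rep(3, 20), rep(4, 15), rep(5, 15)), n_arms = 2)
  coh <- sample_exchangeable_outcomes(st, icc = 0.08, seed = 101)
  vc <- reml_random_intercept(lifespan_months ~ arm, coh)
  mf <- stats::model.frame(lifespan_months ~ arm, coh)
  X <- stats::model.matrix(lifespan_months ~ arm, mf)
  ll_dense <- reml_loglik_dense(coh$lifespan_months, X, coh$cage_id,
                                vc$sigma2_between, vc$sigma2_within)
  expect_equal(vc$reml_loglik, ll_dense, tolerance = 1e-6)

  # and at an off-optimum point the profiled evaluator still agrees
  ss <- cagecor:::.reml_suffstats(coh$lifespan_months, X, coh$cage_id)
  lam <- 0.0371
  fit <- cagecor:::.reml_eval(lam, ss)
  ll_dense2 <- reml_loglik_dense(coh$lifespan_months, X, coh$cage_id,
                                 lam * fit$sigma2_within, fit$sigma2_within)
  expect_equal(fit$ll, ll_dense2, tolerance = 1e-6)
})

test_that("REML agrees with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  coh <- make_test_cohort(120, 4, icc = 0.06, seed = 102)
  vc <- reml_random_intercept(lifespan_months ~ arm, coh)
  fm <- lme4::lmer(lifespan_months ~ arm + (1 | cage_id), coh, REML = TRUE)
  vcs <- as.data.frame(lme4::VarCorr(fm))
  expect_equal(vc$sigma2_between, vcs$vcov[1], tolerance = 1e-5)
  expect_equal(vc$sigma2_within, vcs$vcov[2], tolerance = 1e-5)
  expect_equal(vc$reml_loglik, as.numeric(stats::logLik(fm)), tolerance = 1e-6)
  expect_equal(unname(vc$beta), unname(lme4::fixef(fm)), tolerance = 1e-6)
})

test_that("on balanced data REML ICC equals the ANOVA estimator when non-negative", {
  coh <- make_test_cohort(200, 4, icc = 0.07, seed = 103, n_arms = 1)
  a <- anova_icc(coh)$estimate
  vc <- reml_random_intercept(lifespan_months ~ 1, coh)
  expect_gt(a, 0)
  expect_equal(lmm_icc(vc)$estimate, a, tolerance = 1e-6)
})

test_that("the mixed model truncates at zero where ANOVA and GEE go negative", {
  coh <- make_test_cohort(400, 4, icc = -0.1, seed = 104)
  a <- anova_icc(coh, residualize_on = "arm")
  vc <- reml_random_intercept(lifespan_months ~ arm, coh)
  g <- gee_exchangeable(lifespan_months ~ arm, coh)
  expect_lt(a$estimate, 0)
  expect_lt(g$estimate, 0)
  expect_identical(vc$sigma2_between, 0)
  expect_true(vc$boundary)
  expect_identical(lmm_icc(vc)$estimate, 0)

  # independence truth: all three near zero
  coh0 <- make_test_cohort(500, 4, icc = 0, seed = 105)
  g0 <- gee_exchangeable(lifespan_months ~ arm, coh0)
  expect_lt(abs(g0$estimate), 3 / sqrt(1000 * 6))  # ~3 SE with 6000 pairs
})

test_that("lmm_icc arithmetic follows the variance-ratio definition", {
  fake <- function(b, e) structure(list(sigma2_between = b, sigma2_within = e,
                                        n_clusters = 10L, cluster_sizes = rep(4, 10),
                                        boundary = b == 0),
                                   class = "variance_components")
  expect_equal(lmm_icc(fake(1, 19))$estimate, 0.05)
  expect_equal(lmm_icc(fake(0, 5))$estimate, 0)
  expect_equal(lmm_icc(fake(2, 2))$estimate, 0.5)
})

test_that("GEE working correlation equals the brute-force pairwise moment oracle", {
  coh <- make_test_cohort(60, 4, icc = 0.1, seed = 106, n_arms = 1)
  g <- gee_exchangeable(lifespan_months ~ 1, coh)
  oracle <- pairwise_moment_icc(coh$lifespan_months, coh$cage_id)
  expect_equal(g$estimate, oracle, tolerance = 1e-6)

  # also on negative-correlation data
  cohn <- make_test_cohort(60, 4, icc = -0.15, seed = 107, n_arms = 1)
  gn <- gee_exchangeable(lifespan_months ~ 1, cohn)
  expect_equal(gn$estimate, pairwise_moment_icc(cohn$lifespan_months, cohn$cage_id),
               tolerance = 1e-6)
})

test_that("GEE warns below 20 cages and bootstraps CIs over cages", {
  cohs <- make_test_cohort(16, 4, icc = 0.05, seed = 108)
  expect_warning(gee_exchangeable(lifespan_months ~ arm, cohs), "20 cages")

  coh <- make_test_cohort(150, 4, icc = 0.05, seed = 109)
  g <- gee_exchangeable(lifespan_months ~ arm, coh, ci = "cluster_bootstrap",
                        B = 300, seed = 110)
  expect_lt(g$ci_low, g$estimate)
  expect_gt(g$ci_high, g$estimate)
  gj <- gee_exchangeable(lifespan_months ~ arm, coh, ci = "cluster_jackknife")
  expect_lt(gj$ci_low, g$estimate)
  expect_gt(gj$ci_high, g$estimate)
})

test_that("parametric bootstrap lower limit piles up at zero under a boundary fit", {
  coh <- make_test_cohort(150, 4, icc = -0.05, seed = 111)
  vc <- reml_random_intercept(lifespan_months ~ arm, coh)
  expect_true(vc$boundary)
  ci <- parametric_bootstrap_ci(vc, B = 200, seed = 112)
  expect_identical(ci[1], 0)
})

test_that("two-level REML matches the independent implementation and flags misuse", {
  skip_if_not_installed("lme4")
  st <- make_cage_structure(30, 4, n_arms = 2)
  tr <- sample_longitudinal(st, icc_cage = 0.1, icc_animal = 0.3,
                            ages = c(6, 12, 18), diet_effects = 0.5, seed = 113)
  vc <- two_level_reml(value ~ diet + age, tr)
  fm <- lme4::lmer(value ~ diet + age + (1 | cage_id) + (1 | animal_id),
                   tr, REML = TRUE)
  vcs <- as.data.frame(lme4::VarCorr(fm))
  comp <- setNames(vcs$vcov, vcs$grp)
  expect_equal(vc$reml_loglik, as.numeric(stats::logLik(fm)), tolerance = 1e-4)
  expect_equal(vc$sigma2_between, unname(comp["cage_id"]), tolerance = 1e-3)
  expect_equal(vc$sigma2_animal, unname(comp["animal_id"]), tolerance = 1e-3)

  # zero cage share -> boundary
  tr0 <- sample_longitudinal(st, icc_cage = 0, icc_animal = 0.4,
                             ages = c(6, 12, 18), seed = 114)
  vc0 <- two_level_reml(value ~ diet + age, tr0)
  expect_true(vc0$boundary || vc0$sigma2_between < 0.01)

  # animal appearing in two cages
  bad <- tr
  bad$cage_id[bad$animal_id == bad$animal_id[1]] <-
    c(as.character(bad$cage_id[1]), rep(as.character(bad$cage_id[nrow(bad)]), 2))
  expect_error(two_level_reml(value ~ diet + age, bad), "non-nested")

  # one observation per animal: not identifiable
  tr1 <- sample_longitudinal(st, icc_cage = 0.05, icc_animal = 0.3,
                             ages = 12, seed = 115)
  expect_error(two_level_reml(value ~ diet, tr1), "single observation|collapse")
})

test_that("proportion-of-variance ICC is the cage share of total variance", {
  fake <- structure(list(sigma2_between = 1, sigma2_animal = 9, sigma2_within = 10,
                         n_clusters = 10L, cluster_sizes = rep(4, 10),
                         boundary = FALSE),
                    class = "variance_components")
  expect_equal(proportion_of_variance_icc(fake)$estimate, 0.05)
  fake$sigma2_between <- 0
  expect_equal(proportion_of_variance_icc(fake)$estimate, 0)
  fake$sigma2_animal <- NULL
  expect_error(proportion_of_variance_icc(fake), "two_level")
})

test_that("permutation test saturates under strong clustering and is seed-stable", {
  coh <- make_test_cohort(200, 4, icc = 0.3, seed = 116)
  pt <- permutation_icc_test(coh, n_perm = 500, seed = 117)
  expect_equal(pt$p_value, 1 / 501)
  pt2 <- permutation_icc_test(coh, n_perm = 500, seed = 117)
  expect_identical(pt$null_draws, pt2$null_draws)
  expect_identical(eval(formals(permutation_icc_test)$n_perm), 1000)
  expect_warning(permutation_icc_test(coh, n_perm = 100, seed = 1), "300")
})

test_that("joint F-test reduces to the squared t for a two-level term without cage effects", {
  coh <- make_test_cohort(40, 4, icc = 0, effect = 1, seed = 118)
  jt <- joint_fixed_effect_test(lifespan_months ~ arm, coh, term = "arm",
                                with_cage_effect = FALSE)
  lmfit <- summary(stats::lm(lifespan_months ~ arm, coh))
  expect_equal(jt$F, lmfit$coefficients[2, 3]^2, tolerance = 1e-10)
  expect_equal(jt$p_value, lmfit$coefficients[2, 4], tolerance = 1e-10)
  expect_equal(jt$df2, 158)

  jt2 <- joint_fixed_effect_test(lifespan_months ~ arm, coh, term = "arm",
                                 with_cage_effect = TRUE)
  expect_equal(jt2$df2, 40 - 2)  # 40 cages, cage-level design of rank 2
  expect_error(joint_fixed_effect_test(lifespan_months ~ arm, coh, term = "sex"),
               "not in the model")
})

test_that("icc_fit front end dispatches to all three engines with methods", {
  coh <- make_test_cohort(150, 4, icc = 0.08, seed = 119)
  fl <- icc_fit(lifespan_months ~ arm, coh, method = "lmm")
  fg <- icc_fit(lifespan_months ~ arm, coh, method = "gee")
  fa <- icc_fit(lifespan_months ~ arm, coh, method = "anova")
  expect_s3_class(fl, "icc_fit")
  expect_equal(fl$estimate$method, "lmm_reml")
  expect_equal(fg$estimate$method, "gee_exchangeable")
  expect_equal(fa$estimate$method, "anova")
  # the three routes agree loosely on a positive-ICC balanced cohort
  ests <- c(fl$estimate$estimate, fg$estimate$estimate, fa$estimate$estimate)
  expect_lt(max(ests) - min(ests), 0.02)

  expect_output(print(fl), "lmm")
  s <- summary(fl)
  expect_s3_class(s, "summary.icc_fit")
  expect_named(coef(fl), c("(Intercept)", "armarm2"))
  expect_length(residuals(fl), nrow(coh))
  expect_equal(predict(fl), as.vector(fl$engine$X %*% fl$engine$beta))
  sim <- simulate(fl, nsim = 2, seed = 120)
  expect_equal(dim(sim), c(nrow(coh), 2))
  ci <- confint(fl, B = 200, seed = 121)
  expect_lt(ci[1], fl$estimate$estimate)
  expect_gt(ci[2], fl$estimate$estimate)

  # two-level dispatch
  st <- make_cage_structure(30, 4)
  tr <- sample_longitudinal(st, 0.1, 0.3, ages = c(6, 12), seed = 122)
  f2 <- icc_fit(value ~ diet + age, tr, animal = "animal_id", method = "lmm")
  expect_equal(f2$estimate$method, "two_level_lmm")
  expect_error(icc_fit(value ~ diet, tr, animal = "animal_id", method = "gee"),
               "two-level")
})
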