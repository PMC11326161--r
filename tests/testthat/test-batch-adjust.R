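test_that("day-to-month conversion uses the 30.4-day month", {
  expect_equal(days_to_months(912), 30)
  expect_equal(days_to_months(0), 0)
  expect_equal(days_to_months(30.4), 1)
  expect_equal(days_to_months(c(304, 608)), c(10, 20))
})

test_that("far-outlier rule flags beyond median +/- 3 IQR and nothing else", {
  expect_identical(flag_far_outliers(c(10, 11, 12, 13, 100)),
                   c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(flag_far_outliers(rep(5, 10)), rep(FALSE, 10))
  set.seed(81)
  x <- rnorm(1000)
  expect_lt(mean(flag_far_outliers(x)), 0.01)
  expect_error(flag_far_outliers(c(1, 2, 3)), "4 finite")
})

test_that("injected batch shifts are removed and single-batch input is untouched", {
  st <- make_cage_structure(150, 4)
  coh <- sample_exchangeable_outcomes(st, icc = 0.05, marginal_mean = 30,
                                      marginal_sd = 5, seed = 91,
                                      batch_labels = c("g1", "g2"),
                                      batch_shifts = c(5, -5))
  adj <- remove_batch_effects(coh, batch = "batch", fixed_terms = "arm")
  bm <- tapply(adj$lifespan_months, adj$batch, mean)
  expect_lt(abs(diff(bm)), 0.2)
  rep <- attr(adj, "batch_report")
  expect_equal(unname(rep$batch_coefficients["g1"]), 5, tolerance = 0.5)
  expect_equal(sum(rep$batch_coefficients), 0, tolerance = 1e-10)

  one <- sample_exchangeable_outcomes(st, icc = 0.05, seed = 92,
                                      batch_labels = "only", batch_shifts = 0)
  same <- remove_batch_effects(one, batch = "batch")
  expect_identical(same$lifespan_months, one$lifespan_months)
})

test_that("zero true shifts leave the outcome nearly unchanged", {
  st <- make_cage_structure(200, 4)
  coh <- sample_exchangeable_outcomes(st, icc = 0.05, seed = 93,
                                      batch_labels = c("g1", "g2"),
                                      batch_shifts = c(0, 0))
  adj <- remove_batch_effects(coh, batch = "batch", fixed_terms = "arm")
  # estimated batch coefficients are noise of order sd/sqrt(n): small
  expect_lt(max(abs(adj$lifespan_months - coh$lifespan_months)), 0.6)
})

test_that("adjustment is idempotent and preserves within-batch ranks", {
  st <- make_cage_structure(100, 4)
  coh <- sample_exchangeable_outcomes(st, icc = 0.05, marginal_mean = 30,
                                      marginal_sd = 3, seed = 94,
                                      batch_labels = c("g1", "g2", "g3"),
                                      batch_shifts = c(4, 0, -4))
  a1 <- remove_batch_effects(coh, batch = "batch", fixed_terms = "arm")
  a2 <- remove_batch_effects(a1, batch = "batch", fixed_terms = "arm")
  expect_lt(max(abs(a2$lifespan_months - a1$lifespan_months)),
            1e-6 * stats::sd(a1$lifespan_months))

  for (b in levels(coh$batch)) {
    raw <- coh$lifespan_months[coh$batch == b]
    new <- a1$lifespan_months[a1$batch == b]
    expect_identical(order(raw), order(new))
  }
})

test_that("adjustment reduces the between-batch variance component", {
  st <- make_cage_structure(150, 4)
  coh <- sample_exchangeable_outcomes(st, icc = 0.05, seed = 95,
                                      batch_labels = c("g1", "g2"),
                                      batch_shifts = c(3, -3))
  adj <- remove_batch_effects(coh, batch = "batch", fixed_terms = "arm")
  vb_raw <- anova_icc(coh, cluster = "batch")$components["msb"]
  vb_adj <- anova_icc(adj, cluster = "batch")$components["msb"]
  expect_lt(vb_adj, vb_raw)
})

test_that("batch confounded with a fixed term raises a named aliasing error", {
  st <- make_cage_structure(20, 4)
  coh <- sample_exchangeable_outcomes(st, icc = 0, seed = 96)
  coh$batch <- coh$arm  # perfectly aliased
  expect_error(remove_batch_effects(coh, batch = "batch", fixed_terms = "arm"),
               "aliased|confounded")
  expect_error(remove_batch_effects(coh, batch = "cage_id"), "distinct")
})
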