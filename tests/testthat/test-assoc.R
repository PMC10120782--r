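test_that("Kruskal-Wallis handles total ties and matches the rank formula", {
  d <- tibble::tibble(y = rep(7, 12), g = rep(c("a", "b", "c"), 4))
  res <- kruskal_wallis(d, y, g)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # hand rank-sum oracle on 6 points, no ties:
  # ranks 1..6, R1 = 6, R2 = 15 -> H = 12/(6*7) * (36/3 + 225/3) - 3*7
  d2 <- tibble::tibble(y = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
  H <- kruskal_wallis(d2, y, g)$statistic
  expect_equal(H, 12 / 42 * (36 / 3 + 225 / 3) - 21)
  expect_error(kruskal_wallis(d2[d2$g == "a", ], y, g), "two non-empty")
})

test_that("two-group H equals the squared standardized rank-sum statistic", {
  set.seed(90)
  y <- sample(seq(1, 200), 40)  # ties-free
  g <- rep(c("a", "b"), c(17, 23))
  H <- kruskal_wallis(tibble::tibble(y = y, g = g), y, g)$statistic
  r <- rank(y)
  W <- sum(r[g == "a"])
  n <- 40; n1 <- 17; n2 <- 23
  z2 <- (W - n1 * (n + 1) / 2)^2 / (n1 * n2 * (n + 1) / 12)
  expect_equal(H, z2, tolerance = 1e-12)
})

test_that("Kruskal-Wallis holds its size under label permutation", {
  set.seed(91)
  y <- rnorm(60)
  g <- rep(c("a", "b", "c"), each = 20)
  p <- replicate(2000, {
    kruskal_wallis(tibble::tibble(y = y, g = sample(g)), y, g)$p_value
  })
  expect_gte(mean(p < 0.05), 0.035)
  expect_lte(mean(p < 0.05), 0.065)
})

test_that("fit_linear matches a normal-equations solve on a small cohort", {
  coh <- generate_cohort(50, seed = 92)
  spec <- model_spec("tascd_percent", "parity", "partial")
  ft <- fit_linear(coh, spec)
  X <- stats::model.matrix(
    ~ parity + age_group + site + tissue_area_mm2,
    data = within(as.data.frame(coh), {
      parity <- factor(parity, ordered = FALSE)
      age_group <- factor(age_group, ordered = FALSE)
    }))
  beta <- solve(t(X) %*% X, t(X) %*% coh$tascd_percent)
  expect_equal(ft$beta, unname(beta["parityparous", 1]), tolerance = 1e-8)
})

test_that("null data yield exposure effects within 3 SE of zero", {
  coh <- generate_cohort(5000, null_effect_spec(), seed = 93)
  for (expo in c("parity", "body_size", "fhbc")) {
    ft <- fit_linear(coh, model_spec("tascd_percent", expo, "partial"))
    expect_true(all(abs(ft$beta) <= 3 * ft$se))
  }
})

test_that("a single-level exposure fits covariates only, collinearity errors", {
  coh <- generate_cohort(200, seed = 94)
  coh$parity <- factor("parous", levels = levels(coh$parity))
  ft <- fit_linear(coh, model_spec("tascd_percent", "parity", "partial"))
  expect_identical(nrow(ft), 0L)
  coh2 <- generate_cohort(200, seed = 95)
  coh2$dup <- coh2$parity
  spec <- model_spec("tascd_percent", "parity", "mutual",
                     mutual_set = c("dup"))
  expect_error(fit_linear(coh2, spec), "aliased")
})

test_that("the trend test recovers an injected per-level increment", {
  eff <- effect_spec(
    tascd_effects = list(body_size = c(moderate = -1.5, heavy = -3.0)),
    missingness = numeric(0))
  coh <- generate_cohort(4000, eff, seed = 96)
  tr <- trend_test(coh, model_spec("tascd_percent", "body_size", "partial"))
  expect_lt(abs(tr$score_beta - (-1.5)), 3 * tr$se)
  expect_lt(tr$p_trend, 0.001)
})

test_that("reversing category order negates the trend slope, p unchanged", {
  coh <- generate_cohort(1000, seed = 97)
  spec <- model_spec("tascd_percent", "body_size", "partial")
  tr1 <- trend_test(coh, spec)
  coh2 <- coh
  coh2$body_size <- factor(coh2$body_size,
                           levels = rev(levels(coh2$body_size)),
                           ordered = TRUE)
  tr2 <- trend_test(coh2, spec)
  expect_equal(tr2$score_beta, -tr1$score_beta)
  expect_equal(tr2$p_trend, tr1$p_trend)
})

test_that("non-ordinal exposures are refused by the trend test", {
  coh <- generate_cohort(500, seed = 98)
  expect_error(trend_test(coh, model_spec("tascd_percent", "site", "partial")),
               "not ordinal")
  spec2 <- model_spec("tascd_percent", "parity", "partial",
                      trend_scores = c(nulliparous = 0, parous = 1))
  expect_error(trend_test(coh, spec2), "3 levels")
})

test_that("trend p-values are uniform under the null", {
  spec <- model_spec("tascd_percent", "body_size", "partial")
  null_eff <- null_effect_spec()
  set.seed(99)
  p <- replicate(500, {
    coh <- generate_cohort(200, null_eff, seed = sample.int(2^31 - 1, 1))
    trend_test(coh, spec)$p_trend
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("an injected qualitative interaction is detected with high power", {
  ints <- list(data.frame(
    var1 = "body_size", var2 = "grade",
    level1 = c("moderate", "heavy", "moderate", "heavy"),
    level2 = c("1", "1", "3", "3"),
    delta = c(2.5, 5, -2.5, -5)))
  eff <- effect_spec(tascd_effects = list(), tascd_interactions = ints,
                     missingness = numeric(0))
  spec <- model_spec("tascd_percent", "body_size", "partial",
                     modifier = "grade")
  set.seed(100)
  hits <- replicate(200, {
    coh <- generate_cohort(2000, eff, seed = sample.int(2^31 - 1, 1))
    heterogeneity_test(coh, spec)$p_heterogeneity < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("heterogeneity p is calibrated under the null", {
  spec <- model_spec("tascd_percent", "body_size", "partial",
                     modifier = "grade")
  null_eff <- null_effect_spec()
  set.seed(101)
  rej <- replicate(600, {
    coh <- generate_cohort(1000, null_eff, seed = sample.int(2^31 - 1, 1))
    heterogeneity_test(coh, spec)$p_heterogeneity < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("degenerate modifiers and empty cells are refused", {
  coh <- generate_cohort(300, seed = 102)
  coh$grade <- factor("3", levels = levels(coh$grade))
  spec <- model_spec("tascd_percent", "body_size", "partial",
                     modifier = "grade")
  expect_error(heterogeneity_test(coh, spec), "single level")
  coh2 <- generate_cohort(300, seed = 103)
  coh2$grade[coh2$body_size == "slight"] <- "2"
  expect_error(heterogeneity_test(coh2, spec), "empty")
})

test_that("stratum-specific effects recombine main and product terms", {
  coh <- generate_cohort(3000, seed = 104)
  spec <- model_spec("tascd_percent", "fhbc", "partial", modifier = "er")
  h <- heterogeneity_test(coh, spec)
  expect_identical(nrow(h$strata), 2L)  # yes-vs-no in each ER stratum
  expect_true(all(is.finite(h$strata$beta)))
  expect_true(h$p_heterogeneity >= 0 && h$p_heterogeneity <= 1)
})
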