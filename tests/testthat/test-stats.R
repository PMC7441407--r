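test_that("identically distributed groups are not flagged", {
  set.seed(41)
  v <- rnorm(100)
  g <- rep(0:1, each = 50)
  res <- compare_groups(v, g, "binary")
  expect_false(res$significant)
  expect_equal(res$threshold, 0.05 / 16)
})

test_that("a 2-SD shift is detected and matches a permutation oracle", {
  set.seed(52)
  a <- rnorm(50)
  b <- rnorm(50) + 2
  res <- compare_groups(c(a, b), rep(0:1, each = 50), "binary")
  expect_lt(res$p_value, 0.001)
  expect_true(res$significant)
  # permutation oracle on the rank-sum statistic
  v <- c(a, b)
  obs <- sum(rank(v)[51:100])
  perm <- replicate(4000, {
    idx <- sample(100, 50)
    sum(rank(v)[idx])
  })
  p_perm <- mean(abs(perm - mean(perm)) >= abs(obs - mean(perm)))
  expect_lt(abs(res$p_value - p_perm), 0.01 + 3 * sqrt(p_perm * (1 - p_perm) / 4000))
})

test_that("polychotomous comparisons use Kruskal-Wallis", {
  set.seed(61)
  g <- rep(0:3, each = 40)
  v <- rnorm(160) + 0.8 * g
  res <- compare_groups(v, g, "polychotomous", m_tests = 16)
  expect_equal(res$p_value,
               kruskal.test(v, factor(g))$p.value)
  expect_true(res$significant)
})

test_that("the Bonferroni threshold follows the battery size", {
  set.seed(62)
  v <- rnorm(40); g <- rep(0:1, 20)
  expect_equal(compare_groups(v, g, "binary", m_tests = 16)$threshold,
               0.003125)
  expect_equal(compare_groups(v, g, "binary", m_tests = 20)$threshold,
               0.0025)
})

test_that("undersized groups are rejected", {
  expect_error(compare_groups(rnorm(5), c(0, 0, 0, 0, 1), "binary"),
               "insufficient group")
})

test_that("residualization removes all correlation with prior covariates", {
  set.seed(71)
  co <- simulate_cohort(cohort_effect_params(), n_nights = 200, seed = 5,
                        keep_hypnograms = FALSE)
  d <- co$table
  fit <- lm(rem_fraction ~ age_class + gender, data = d)
  r <- residuals(fit)
  expect_lt(abs(cor(r, d$age_class)), 1e-10)
  expect_lt(abs(cor(r, d$gender)), 1e-10)
})

test_that("an injected apnea effect on REM fraction is recovered", {
  eff <- cohort_effect_params(preset = "null", apnea_rem = -0.02)
  co <- simulate_cohort(eff, n_nights = 400, seed = 77,
                        keep_hypnograms = FALSE)
  rep <- adjusted_regression(co$table)
  apnea <- rep[rep$metric == "rem_fraction" & rep$covariate == "apnea", ]
  expect_lt(apnea$coefficient, 0)
  expect_true(apnea$significant)
  expect_equal(apnea$coefficient, -0.02, tolerance = 0.25)
  # covariates with no injected effect must not be flagged; light fraction
  # is excluded from this check because fractions are compositional (a REM
  # decrease necessarily raises the light share)
  others <- rep[rep$covariate != "apnea" & rep$metric != "light_fraction", ]
  expect_false(any(others$significant))
  # apnea leaves deep fraction and efficiency untouched
  expect_false(any(rep$significant[rep$covariate == "apnea" &
                                     rep$metric %in% c("deep_fraction",
                                                       "sleep_efficiency")]))
})

test_that("a null cohort yields no significant flags", {
  co <- simulate_cohort(cohort_effect_params(preset = "null"),
                        n_nights = 400, seed = 88, keep_hypnograms = FALSE)
  rep <- adjusted_regression(co$table)
  expect_false(any(rep$significant))
})

test_that("the report covers every metric-covariate pair once", {
  co <- simulate_cohort(cohort_effect_params(), n_nights = 100, seed = 3,
                        keep_hypnograms = FALSE)
  rep <- adjusted_regression(co$table)
  expect_equal(nrow(rep), 16)
  expect_setequal(unique(rep$covariate),
                  c("age", "gender", "apnea", "hypertension"))
  expect_true(all(rep$r2_pct >= 0 & rep$r2_pct <= 100))
  expect_true(all(rep$ci_low <= rep$coefficient &
                  rep$coefficient <= rep$ci_high))
})

test_that("cohort encodings are validated", {
  co <- simulate_cohort(cohort_effect_params(), n_nights = 50, seed = 4,
                        keep_hypnograms = FALSE)
  bad <- co$table
  bad$gender[1] <- 2
  expect_error(adjusted_regression(bad))
  expect_error(adjusted_regression(co$table[1:10, ]), "at least 30")
})

test_that("REM-bout fragmentation by apnea yields a negative coefficient", {
  eff <- cohort_effect_params(preset = "null", apnea_rem_frag = 0.8)
  co <- simulate_cohort(eff, n_nights = 400, seed = 78,
                        keep_hypnograms = FALSE)
  res <- rem_bout_regression(co$table)
  expect_lt(res$coefficient, 0)
  expect_true(res$significant)
  # age has no injected effect here, so it is dropped from the adjustment
  expect_false(res$age_retained)
})
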