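#' Rank-based group comparison of a sleep metric across a covariate
#'
#' Binary covariates (gender, hypertension) are compared with a two-sided
#' Wilcoxon rank-sum test (normal approximation with tie correction);
#' polychotomous covariates (age class, apnea class) with a Kruskal-Wallis
#' test.  Significance is declared at `alpha / m_tests` (Bonferroni over
#' the battery of metric-covariate tests).
#'
#' @param values Numeric metric, one value per night.
#' @param groups Group membership, one value per night.
#' @param kind `"binary"` or `"polychotomous"`.
#' @param alpha Family-wise significance level (default 0.05).
#' @param m_tests Number of tests in the battery (default 16: 4 metrics x
#'   4 covariates).
#' @return List with `p_value`, `statistic`, `threshold` and `significant`.
#' @export
compare_groups <- function(values, groups, kind = c("binary", "polychotomous"),
                           alpha = 0.05, m_tests = 16L) {
  kind <- match.arg(kind)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]
  groups <- groups[ok]
  cnt <- table(groups)
  if (length(cnt) < 2 || any(cnt < 2))
    stop("insufficient group: need at least 2 groups with 2 observations each")
  if (kind == "binary") {
    if (length(cnt) != 2) stop("binary covariate must have exactly 2 levels")
    g <- factor(groups)
    ht <- stats::wilcox.test(values[g == levels(g)[1]],
                             values[g == levels(g)[2]],
                             alternative = "two.sided", exact = FALSE,
                             correct = TRUE)
  } else {
    ht <- stats::kruskal.test(values, factor(groups))
  }
  thr <- alpha / m_tests
  list(p_value = unname(ht$p.value), statistic = unname(ht$statistic),
       threshold = thr, significant = ht$p.value < thr)
}

# covariate encodings used throughout: gender female 0 / male 1; age class
# 0 (<55), 1 (55-60), 2 (61-70), 3 (>70); apnea class 0 (AHI<5), 1 (5-15),
# 2 (15-30), 3 (>30); hypertension absent 0 / present 1
check_cohort <- function(table) {
  need <- c("night_id", "gender", "age_class", "apnea_class", "hypertension",
            "light_fraction", "deep_fraction", "rem_fraction",
            "sleep_efficiency", "mean_rem_bout")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0)
    stop("cohort table is missing column(s): ", paste(miss, collapse = ", "))
  stopifnot(all(table$gender %in% 0:1), all(table$age_class %in% 0:3),
            all(table$apnea_class %in% 0:3), all(table$hypertension %in% 0:1))
  invisible(table)
}

cohort_metrics <- function() {
  c("light_fraction", "deep_fraction", "rem_fraction", "sleep_efficiency")
}

# one step of the sequential procedure: regress `y` on a single covariate,
# returning the coefficient with its 95% CI, p-value and 100 * R^2
step_fit <- function(y, x) {
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  ci <- stats::confint(fit, "x", level = 0.95)
  list(coefficient = unname(coef(fit)["x"]),
       ci_low = ci[1], ci_high = ci[2],
       p_value = sm$coefficients["x", "Pr(>|t|)"],
       r2_pct = 100 * sm$r.squared,
       residuals = unname(stats::residuals(fit)))
}

#' Sequentially adjusted least-squares regression of sleep metrics on
#' clinical covariates
#'
#' Implements the sequential procedure used for the covariate analysis:
#' (1) each metric is regressed on age class and gender jointly and their
#' coefficients recorded; (2) the metric is adjusted for age and gender
#' (residualized) and regressed on apnea class; (3) the metric is further
#' adjusted for apnea and regressed on the presence of hypertension.
#' Age and apnea enter as single ordinal integers, not dummy expanded.
#' For every metric-covariate pair the coefficient, 95% CI, regression
#' p-value and percent variance explained (100 R^2, from the
#' single-covariate fit at that pair's adjustment stage) are reported,
#' together with the companion rank-test p-value on the raw metric; a pair
#' is flagged significant only when both p-values cross the
#' Bonferroni-corrected threshold.
#'
#' @param table Cohort data frame (see [simulate_cohort()] or
#'   [read_cohort()] for the column encodings).
#' @param alpha Family-wise level (default 0.05).
#' @param m_tests Bonferroni divisor (default 16).
#' @return A data frame of class `"regression_report"`, one row per
#'   metric-covariate pair.
#' @export
adjusted_regression <- function(table, alpha = 0.05, m_tests = 16L) {
  check_cohort(table)
  if (nrow(table) < 30) stop("need at least 30 nights")
  thr <- alpha / m_tests
  rows <- list()
  for (metric in cohort_metrics()) {
    y <- table[[metric]]
    ok <- is.finite(y)
    d <- table[ok, ]
    y <- y[ok]
    X <- cbind(age = d$age_class, gender = d$gender)
    if (qr(cbind(1, X, d$apnea_class, d$hypertension))$rank < 5)
      stop("collinearity error: singular design for metric ", metric)
    # step 1: metric ~ age + gender (joint), coefficients recorded; the
    # per-pair R^2 comes from the corresponding single-covariate fit
    fit1 <- stats::lm(y ~ d$age_class + d$gender)
    sm1 <- summary(fit1)
    ci1 <- stats::confint(fit1, level = 0.95)
    for (cov in c("age", "gender")) {
      v <- if (cov == "age") d$age_class else d$gender
      term <- if (cov == "age") "d$age_class" else "d$gender"
      rank_p <- if (cov == "age")
        stats::kruskal.test(y, factor(v))$p.value
      else
        stats::wilcox.test(y[v == 0], y[v == 1], exact = FALSE)$p.value
      reg_p <- sm1$coefficients[term, "Pr(>|t|)"]
      rows[[length(rows) + 1]] <- data.frame(
        metric = metric, covariate = cov,
        coefficient = unname(coef(fit1)[term]),
        ci_low = ci1[term, 1], ci_high = ci1[term, 2],
        p_regression = reg_p, p_ranktest = rank_p,
        r2_pct = 100 * summary(stats::lm(y ~ v))$r.squared,
        significant = reg_p < thr && rank_p < thr)
    }
    # step 2: residualize on age + gender, regress on apnea class
    r1 <- unname(stats::residuals(fit1))
    s2 <- step_fit(r1, d$apnea_class)
    rank_p <- stats::kruskal.test(y, factor(d$apnea_class))$p.value
    rows[[length(rows) + 1]] <- data.frame(
      metric = metric, covariate = "apnea",
      coefficient = s2$coefficient, ci_low = s2$ci_low, ci_high = s2$ci_high,
      p_regression = s2$p_value, p_ranktest = rank_p, r2_pct = s2$r2_pct,
      significant = s2$p_value < thr && rank_p < thr)
    # step 3: residualize on age + gender + apnea, regress on hypertension
    s3 <- step_fit(s2$residuals, d$hypertension)
    rank_p <- stats::wilcox.test(y[d$hypertension == 0],
                                 y[d$hypertension == 1],
                                 exact = FALSE)$p.value
    rows[[length(rows) + 1]] <- data.frame(
      metric = metric, covariate = "hypertension",
      coefficient = s3$coefficient, ci_low = s3$ci_low, ci_high = s3$ci_high,
      p_regression = s3$p_value, p_ranktest = rank_p, r2_pct = s3$r2_pct,
      significant = s3$p_value < thr && rank_p < thr)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "m_tests") <- m_tests
  class(out) <- c("regression_report", "data.frame")
  out
}

#' REM-bout-duration regression on apnea severity
#'
#' Restricts to the healthy, mild and severe apnea cohorts (classes 0, 1
#' and 3, coded by their class integers so the severe class keeps code 3),
#' tests whether age contributes alongside gender, drops age when it is
#' not significant, adjusts the mean REM bout duration for the retained
#' covariates, and regresses the adjusted durations on apnea severity.
#'
#' @param table Cohort data frame.
#' @param alpha Significance level for retaining age and for the final
#'   apnea coefficient (default 0.05).
#' @return List with the apnea `coefficient`, `ci_low`, `ci_high`,
#'   `p_value`, `significant`, plus `age_p`, `age_retained` and `gender_p`
#'   from the adjustment stage.
#' @export
rem_bout_regression <- function(table, alpha = 0.05) {
  check_cohort(table)
  d <- table[table$apnea_class %in% c(0, 1, 3) & is.finite(table$mean_rem_bout), ]
  if (nrow(d) < 30) stop("need at least 30 nights in the three apnea cohorts")
  y <- d$mean_rem_bout
  pre <- stats::lm(y ~ d$age_class + d$gender)
  smp <- summary(pre)$coefficients
  age_p <- smp["d$age_class", "Pr(>|t|)"]
  gender_p <- smp["d$gender", "Pr(>|t|)"]
  age_keep <- age_p < alpha
  adj <- if (age_keep) unname(stats::residuals(pre))
         else unname(stats::residuals(stats::lm(y ~ d$gender)))
  s <- step_fit(adj, d$apnea_class)
  list(coefficient = s$coefficient, ci_low = s$ci_low, ci_high = s$ci_high,
       p_value = s$p_value, significant = s$p_value < alpha,
       age_p = age_p, age_retained = age_keep, gender_p = gender_p,
       n = nrow(d))
}
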