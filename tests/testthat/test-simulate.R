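test_that("generators are pure functions of (params, seed)", {
  arch <- sleep_architecture_params()
  expect_identical(simulate_hypnogram(arch, 8, seed = 3),
                   simulate_hypnogram(arch, 8, seed = 3))
  h <- simulate_hypnogram(arch, 6, seed = 4)
  em <- cardiac_emission_params()
  a <- simulate_night_ibi(h, em, seed = 5)
  b <- simulate_night_ibi(h, em, seed = 5)
  expect_identical(a$intervals, b$intervals)
  eff <- cohort_effect_params()
  expect_identical(simulate_cohort(eff, 25, seed = 6, keep_hypnograms = FALSE),
                   simulate_cohort(eff, 25, seed = 6, keep_hypnograms = FALSE))
})

test_that("stage occupancy matches the analytic targets", {
  arch <- sleep_architecture_params()
  ms <- lapply(1:150, function(i)
    compute_sleep_metrics(simulate_hypnogram(arch, 8, seed = 100 + i)))
  get <- function(f) mean(vapply(ms, `[[`, numeric(1), f))
  # absolute Monte-Carlo tolerance: ~3 SE of the per-night spread plus the
  # small ratio nonlinearity of per-night fractions
  expect_lt(abs(get("light_fraction") - arch$frac_light), 0.015)
  expect_lt(abs(get("deep_fraction") - arch$frac_deep), 0.015)
  expect_lt(abs(get("rem_fraction") - arch$frac_rem), 0.015)
  expect_lt(abs(get("sleep_efficiency") - arch$efficiency), 0.015)
})

test_that("deep sleep is front-loaded and REM back-loaded", {
  arch <- sleep_architecture_params()
  res <- vapply(1:100, function(i) {
    s <- as.character(simulate_hypnogram(arch, 8, seed = 300 + i))
    half <- length(s) %/% 2
    c(deep = sum(s[1:half] == "deep") > sum(s[-(1:half)] == "deep"),
      rem = sum(s[1:half] == "rem") < sum(s[-(1:half)] == "rem"))
  }, logical(2))
  expect_gte(mean(res["deep", ]), 0.95)
  expect_gte(mean(res["rem", ]), 0.95)
})

test_that("hypnograms consist of cycle-scale bouts, not epoch noise", {
  h <- simulate_hypnogram(sleep_architecture_params(), 8, seed = 9)
  r <- rle(as.character(h))
  # mean bout length well above 1 epoch (a semi-Markov signature)
  expect_gt(mean(r$lengths), 4)
})

test_that("zero-noise single-stage emission gives constant intervals", {
  em <- cardiac_emission_params(
    sd_hr = c(wake = 0, light = 0, deep = 0, rem = 0),
    osc_amp = c(wake = 0, light = 0, deep = 0, rem = 0),
    noise_bpm = 0, outlier_rate = 0)
  h <- hypnogram(rep("deep", 10))
  ibi <- simulate_night_ibi(h, em, seed = 2)
  expect_lt(max(abs(ibi$intervals - 60 / em$mean_hr[["deep"]])), 1e-9)
})

test_that("stage-conditioned rates are recovered from the intervals", {
  em <- cardiac_emission_params(preset = "easy")
  h <- hypnogram(rep(c("deep", "wake"), each = 120)) # 1 h each
  ibi <- simulate_night_ibi(h, em, seed = 3)
  hr <- 60 / ibi$intervals
  in_deep <- ibi$anchor_times <= 120 * 30
  expect_equal(mean(hr[in_deep]), em$mean_hr[["deep"]], tolerance = 0.02)
  expect_equal(mean(hr[!in_deep]), em$mean_hr[["wake"]], tolerance = 0.02)
  # canonical ordering of the default stage means
  d <- cardiac_emission_params()
  expect_true(d$mean_hr[["wake"]] > d$mean_hr[["rem"]])
  expect_true(d$mean_hr[["rem"]] > d$mean_hr[["light"]])
  expect_true(d$mean_hr[["light"]] > d$mean_hr[["deep"]])
})

test_that("injected outlier beats are removed at the configured rate", {
  em <- cardiac_emission_params(outlier_rate = 0.01)
  h <- simulate_hypnogram(sleep_architecture_params(), 8, seed = 11)
  ibi <- simulate_night_ibi(h, em, seed = 12)
  filtered <- beats_to_ibi(c(0, ibi$anchor_times))
  removed <- length(ibi$intervals) - length(filtered$intervals)
  rate <- removed / length(ibi$intervals)
  se <- sqrt(0.01 * 0.99 / length(ibi$intervals))
  expect_lt(abs(rate - 0.01), 4 * se)
})

test_that("noise-free ECG round trips every beat within one sample", {
  set.seed(13)
  intervals <- runif(60, 0.8, 1.1)
  ibi <- ibi_series(cumsum(intervals), intervals)
  sim <- simulate_ecg(ibi, 250, noise = 0, seed = 14)
  peaks <- detect_r_peaks(sim$signal, 250)
  expect_length(peaks, length(sim$beat_times))
  expect_lte(max(abs(peaks - sim$beat_times)), 1 / 250 + 1e-9)
})

test_that("an empty interval series yields a flat baseline", {
  sim <- simulate_ecg(ibi_series(numeric(0), numeric(0)), 250, noise = 0,
                      seed = 15)
  expect_lt(diff(range(sim$signal)), 0.5)
  expect_length(sim$beat_times, 0)
})

test_that("the realized noise level tracks the request", {
  set.seed(16)
  intervals <- rep(1, 120)
  ibi <- ibi_series(cumsum(intervals), intervals)
  clean <- simulate_ecg(ibi, 250, noise = 0, seed = 17)
  noisy <- simulate_ecg(ibi, 250, noise = 0.2, seed = 17)
  realized <- sd(noisy$signal - clean$signal) / sd(clean$signal)
  expect_equal(realized, 0.2, tolerance = 0.1)
})

test_that("infeasible covariate effects are rejected", {
  eff <- cohort_effect_params(apnea_deep = -0.2)
  expect_error(simulate_cohort(eff, 50, seed = 18), "infeasible")
  expect_error(sleep_architecture_params(frac_deep = -0.1), "parameter")
  expect_error(sleep_architecture_params(frac_deep = 0.5), "sum to 1")
})

test_that("null cohorts rarely produce significant batteries", {
  flags <- vapply(1:25, function(r) {
    co <- simulate_cohort(cohort_effect_params(preset = "null"), 80,
                          seed = 900 + r, keep_hypnograms = FALSE)
    any(adjusted_regression(co$table)$significant)
  }, logical(1))
  expect_lte(mean(flags), 0.12) # Bonferroni keeps the family-wise rate low
})
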