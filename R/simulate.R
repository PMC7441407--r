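# All generators are pure functions of (params, seed): when a seed is given
# the global RNG state is saved and restored; when seed = NULL they consume
# the current RNG stream (so a caller that seeds once gets a deterministic
# composite).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# randomized rounding: unbiased integerisation of non-negative targets
rround <- function(x) {
  f <- floor(x)
  as.integer(f + (runif(length(x)) < (x - f)))
}

#' Sleep-architecture parameters for the hypnogram simulator
#'
#' The simulator produces nights as sequences of 60--90-min sleep cycles.
#' Within each cycle, stage bout durations are drawn from gamma
#' distributions whose means follow night-level stage-occupancy targets, so
#' the expected fraction of sleep spent in each stage equals the
#' corresponding `frac_*` parameter analytically.  Deep sleep is
#' front-loaded (its share decays geometrically across cycles) and REM is
#' back-loaded, reproducing the canonical overnight architecture; the
#' weights are normalised so front/back loading redistributes stages across
#' the night without changing night-level expectations.
#'
#' @param cycle_mean_min,cycle_sd_min Mean and SD of the cycle length in
#'   minutes; draws are clamped to `cycle_range_min`.
#' @param cycle_range_min Allowed cycle-length band (default 60--90 min).
#' @param frac_light,frac_deep,frac_rem Target stage fractions of total
#'   sleep; must sum to 1.
#' @param efficiency Target fraction of the night spent asleep.
#' @param front_loading Geometric decay rate of the deep-sleep share across
#'   cycles (0 = uniform).
#' @param back_loading Geometric growth rate of the REM share across cycles.
#' @param bout_shape Gamma shape parameter of bout-duration noise (larger =
#'   more regular nights).
#' @param wake_bout_rate Poisson rate of additional wake bouts per cycle.
#' @param rem_frag Poisson rate of REM-bout interruptions per cycle
#'   (fragmentation; interruption epochs are light sleep drawn from the
#'   cycle's light budget so stage fractions are unchanged).
#' @return A list of class `"sleep_architecture_params"`.
#' @export
sleep_architecture_params <- function(cycle_mean_min = 80, cycle_sd_min = 10,
                                      cycle_range_min = c(60, 90),
                                      frac_light = 0.55, frac_deep = 0.20,
                                      frac_rem = 0.25, efficiency = 0.88,
                                      front_loading = 0.7, back_loading = 0.35,
                                      bout_shape = 8, wake_bout_rate = 1,
                                      rem_frag = 0) {
  p <- list(cycle_mean_min = cycle_mean_min, cycle_sd_min = cycle_sd_min,
            cycle_range_min = cycle_range_min, frac_light = frac_light,
            frac_deep = frac_deep, frac_rem = frac_rem,
            efficiency = efficiency, front_loading = front_loading,
            back_loading = back_loading, bout_shape = bout_shape,
            wake_bout_rate = wake_bout_rate, rem_frag = rem_frag)
  validate_architecture(p)
  structure(p, class = "sleep_architecture_params")
}

validate_architecture <- function(p) {
  fr <- c(p$frac_light, p$frac_deep, p$frac_rem)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
    stop("parameter error: stage fractions must lie in [0, 1]")
  if (abs(sum(fr) - 1) > 1e-8)
    stop("parameter error: stage fractions must sum to 1")
  if (p$efficiency <= 0 || p$efficiency > 1)
    stop("parameter error: efficiency must lie in (0, 1]")
  if (p$cycle_mean_min <= 0 || p$bout_shape <= 0)
    stop("parameter error: dwell parameters must be positive")
  if (p$rem_frag < 0 || p$wake_bout_rate < 0)
    stop("parameter error: rates must be non-negative")
  invisible(p)
}

#' Simulate an overnight hypnogram
#'
#' @param params A [sleep_architecture_params()].
#' @param duration_h Night duration in hours (at most 10).
#' @param seed Integer seed, or `NULL` to consume the current RNG stream.
#' @return A [hypnogram()] of `duration_h * 120` 30-s epochs.
#' @examples
#' h <- simulate_hypnogram(sleep_architecture_params(), 8, seed = 1)
#' compute_sleep_metrics(h)
#' @export
simulate_hypnogram <- function(params = sleep_architecture_params(),
                               duration_h = 8, seed = NULL) {
  validate_architecture(params)
  stopifnot(duration_h > 0, duration_h <= 10)
  with_seed(seed, {
    total <- as.integer(round(duration_h * 120))
    # cycle lengths in epochs
    lens <- integer(0)
    while (sum(lens) < total) {
      l <- stats::rnorm(1, params$cycle_mean_min, params$cycle_sd_min)
      l <- min(max(l, params$cycle_range_min[1]), params$cycle_range_min[2])
      lens <- c(lens, as.integer(round(l * 2)))
    }
    lens[length(lens)] <- lens[length(lens)] - (sum(lens) - total)
    if (lens[length(lens)] < 10) {  # fold a stub cycle into its predecessor
      if (length(lens) > 1) {
        lens[length(lens) - 1] <- lens[length(lens) - 1] + lens[length(lens)]
        lens <- lens[-length(lens)]
      }
    }
    nc <- length(lens)
    # front/back loading weights, normalised so that the length-weighted
    # mean is 1 (night-level expectations are preserved)
    dc <- exp(-params$front_loading * (seq_len(nc) - 1))
    dc <- dc * sum(lens) / sum(dc * lens)
    rc <- exp(params$back_loading * (seq_len(nc) - 1))
    rc <- rc * sum(lens) / sum(rc * lens)
    k <- params$bout_shape
    stages <- character(0)
    for (ci in seq_len(nc)) {
      Lc <- lens[ci]
      sleep_t <- Lc * params$efficiency
      wake_t <- Lc - sleep_t
      deep_t <- params$frac_deep * dc[ci] * sleep_t
      rem_t <- params$frac_rem * rc[ci] * sleep_t
      budget <- 0.92 * Lc
      if (deep_t + rem_t + wake_t > budget) {
        sc <- budget / (deep_t + rem_t + wake_t)
        deep_t <- deep_t * sc; rem_t <- rem_t * sc; wake_t <- wake_t * sc
      }
      draw <- function(target) {
        if (target <= 0) return(0L)
        rround(stats::rgamma(1, shape = k, scale = target / k))
      }
      deep_e <- draw(deep_t)
      rem_e <- draw(rem_t)
      wake_e <- draw(wake_t)
      light_e <- Lc - deep_e - rem_e - wake_e
      while (light_e < 0) { # trim the largest bout when noise overshoots
        big <- which.max(c(deep_e, rem_e, wake_e))
        if (big == 1) deep_e <- deep_e - 1L
        else if (big == 2) rem_e <- rem_e - 1L
        else wake_e <- wake_e - 1L
        light_e <- light_e + 1L
      }
      # wake is split across up to three slots (cycle start, mid-cycle, end)
      nw <- 1L + stats::rpois(1, params$wake_bout_rate)
      wsplit <- if (wake_e > 0)
        as.integer(stats::rmultinom(1, wake_e, rep(1, min(nw, 3L))))
      else integer(0)
      wsplit <- c(wsplit, integer(3 - length(wsplit)))
      l1 <- rround(0.6 * light_e)
      l2 <- light_e - l1
      # REM fragmentation: interruptions are single light epochs moved out
      # of the late-light budget, so fractions are unchanged
      m <- stats::rpois(1, params$rem_frag)
      m <- min(m, max(0L, as.integer(l2) - 1L), max(0L, rem_e - 1L))
      rem_parts <- if (rem_e > 0 && m > 0) {
        as.integer(stats::rmultinom(1, rem_e - (m + 1L), rep(1, m + 1L))) + 1L
      } else if (rem_e > 0) rem_e else integer(0)
      l2 <- l2 - m
      rem_seq <- character(0)
      if (length(rem_parts) > 0) {
        for (j in seq_along(rem_parts)) {
          rem_seq <- c(rem_seq, rep("rem", rem_parts[j]))
          if (j < length(rem_parts)) rem_seq <- c(rem_seq, "light")
        }
      }
      stages <- c(stages,
                  rep("wake", wsplit[1]), rep("light", l1),
                  rep("deep", deep_e), rep("wake", wsplit[2]),
                  rep("light", l2), rem_seq, rep("wake", wsplit[3]))
    }
    hypnogram(stages[seq_len(min(length(stages), total))])
  })
}

#' Stage-conditioned cardiac emission parameters
#'
#' Per-stage mean heart rate and short-term variability, a slow
#' within-stage oscillation, broadband measurement noise and a rate of
#' outlier (missed/spurious) beats.  Defaults follow the canonical ordering
#' wake > REM > light > deep for mean rate.  The `"easy"` preset widens the
#' stage separation (used for learnability experiments); `"hard"` narrows
#' it.
#'
#' @param mean_hr Named numeric (wake, light, deep, rem), beats per minute.
#' @param sd_hr Beat-to-beat variability per stage, bpm.
#' @param osc_amp Amplitude of the slow oscillation per stage, bpm.
#' @param osc_period_s Period of the slow oscillation, seconds.
#' @param noise_bpm Stage-independent measurement noise, bpm.
#' @param outlier_rate Probability that a beat interval is an outlier
#'   (simulating a missed detection: the interval is stretched 2--3x).
#' @param preset `"default"`, `"easy"` or `"hard"`.
#' @return A list of class `"cardiac_emission_params"`.
#' @export
cardiac_emission_params <- function(mean_hr = c(wake = 72, light = 61,
                                                deep = 55, rem = 66),
                                    sd_hr = c(wake = 3, light = 2.5,
                                              deep = 1.5, rem = 3.5),
                                    osc_amp = c(wake = 1, light = 1,
                                                deep = 0.5, rem = 2),
                                    osc_period_s = 90, noise_bpm = 1,
                                    outlier_rate = 0.002,
                                    preset = c("default", "easy", "hard")) {
  preset <- match.arg(preset)
  if (preset == "easy") {
    if (missing(mean_hr)) mean_hr <- c(wake = 76, light = 62, deep = 51,
                                       rem = 69)
    if (missing(sd_hr)) sd_hr <- c(wake = 1.5, light = 1.5, deep = 1,
                                   rem = 1.5)
    if (missing(osc_amp)) osc_amp <- c(wake = 0.5, light = 0.5, deep = 0.3,
                                       rem = 1)
    if (missing(noise_bpm)) noise_bpm <- 0.5
    if (missing(outlier_rate)) outlier_rate <- 0.001
  } else if (preset == "hard") {
    if (missing(mean_hr)) mean_hr <- c(wake = 68, light = 62, deep = 58,
                                       rem = 65)
    if (missing(sd_hr)) sd_hr <- c(wake = 4.5, light = 3.5, deep = 2.5,
                                   rem = 5)
    if (missing(noise_bpm)) noise_bpm <- 2
    if (missing(outlier_rate)) outlier_rate <- 0.01
  }
  st <- stage_levels()
  stopifnot(all(st %in% names(mean_hr)), all(st %in% names(sd_hr)),
            all(st %in% names(osc_amp)), all(mean_hr > 0),
            osc_period_s > 0, outlier_rate >= 0, outlier_rate < 1)
  structure(list(mean_hr = mean_hr[st], sd_hr = sd_hr[st],
                 osc_amp = osc_amp[st], osc_period_s = osc_period_s,
                 noise_bpm = noise_bpm, outlier_rate = outlier_rate,
                 preset = preset),
            class = "cardiac_emission_params")
}

#' Simulate a night of inter-beat intervals from a hypnogram
#'
#' Beat-by-beat intervals whose local mean and variability follow the
#' current epoch's stage parameters, with a slow sinusoidal oscillation,
#' broadband noise and occasional outlier (stretched) intervals emulating
#' missed beats.
#'
#' @param h A [hypnogram()].
#' @param params A [cardiac_emission_params()].
#' @param seed Integer seed, or `NULL`.
#' @return An [ibi_series()].
#' @export
simulate_night_ibi <- function(h, params = cardiac_emission_params(),
                               seed = NULL) {
  stopifnot(inherits(params, "cardiac_emission_params"))
  epoch_s <- attr(h, "epoch_length") %||% 30
  with_seed(seed, {
    phase <- runif(1, 0, 2 * pi)
    stages <- as.character(h)
    stages[stages == "unscored"] <- "light"
    t <- 0
    beats <- numeric(0)
    for (i in seq_along(stages)) {
      e_end <- i * epoch_s
      mu <- params$mean_hr[[stages[i]]]
      svar <- params$sd_hr[[stages[i]]]
      amp <- params$osc_amp[[stages[i]]]
      while (t < e_end) {
        # generate a chunk of candidate beats at the epoch's rate
        need <- ceiling((e_end - t) / (60 / (mu + 3 * svar + 3))) + 2L
        approx_t <- t + cumsum(rep(60 / mu, need))
        hr <- mu + amp * sin(2 * pi * approx_t / params$osc_period_s + phase) +
          stats::rnorm(need, 0, svar) + stats::rnorm(need, 0, params$noise_bpm)
        hr <- pmax(hr, 25)
        ibi <- 60 / hr
        out <- runif(need) < params$outlier_rate
        ibi[out] <- ibi[out] * runif(sum(out), 2.2, 3.2)
        tt <- t + cumsum(ibi)
        keep <- tt <= e_end
        if (!any(keep)) { t <- tt[1]; beats <- c(beats, tt[1]); next }
        beats <- c(beats, tt[keep])
        t <- tt[max(which(keep))]
        if (t >= e_end) break
        if (!all(keep)) { t <- tt[sum(keep) + 1]; beats <- c(beats, t) }
      }
    }
    beats <- beats[beats <= length(stages) * epoch_s]
    ibis <- diff(c(0, beats))
    ibi_series(beats, ibis)
  })
}

#' Simulate an ECG waveform from an inter-beat-interval series
#'
#' Places a template QRS-T complex (Gaussian Q, R, S and T waves) at each
#' cumulative beat time, adds low-frequency baseline wander and white
#' measurement noise, and returns the ground-truth beat times alongside.
#'
#' @param ibi An [ibi_series()].
#' @param sampling_rate Output rate in Hz (at least 100).
#' @param noise Noise standard deviation relative to the standard deviation
#'   of the clean signal.
#' @param seed Integer seed, or `NULL`.
#' @return List with `signal`, `sampling_rate`, `beat_times` (ground
#'   truth, seconds) and `noise`.
#' @export
simulate_ecg <- function(ibi, sampling_rate = 250, noise = 0.05,
                         seed = NULL) {
  if (sampling_rate < 100) stop("sampling_rate must be at least 100 Hz")
  with_seed(seed, {
    beats <- if (length(ibi$intervals) > 0)
      c(ibi$anchor_times[1] - ibi$intervals[1], ibi$anchor_times)
    else numeric(0)
    dur <- if (length(beats) > 0) max(beats) + 0.6 else 30
    n <- as.integer(ceiling(dur * sampling_rate)) + 1L
    tg <- (seq_len(n) - 1) / sampling_rate
    sig <- numeric(n)
    g <- function(dt, amp, mu, s) amp * exp(-((dt - mu)^2) / (2 * s^2))
    half <- as.integer(round(0.45 * sampling_rate))
    for (b in beats) {
      ib <- as.integer(round(b * sampling_rate)) + 1L
      lo <- max(1L, ib - half)
      hi <- min(n, ib + half)
      dt <- tg[lo:hi] - b
      sig[lo:hi] <- sig[lo:hi] +
        g(dt, 1.0, 0, 0.008) +      # R
        g(dt, -0.15, -0.028, 0.009) + # Q
        g(dt, -0.2, 0.028, 0.009) +  # S
        g(dt, 0.3, 0.28, 0.045)      # T
    }
    ph <- runif(2, 0, 2 * pi)
    sig <- sig + 0.1 * sin(2 * pi * 0.25 * tg + ph[1]) +
      0.05 * sin(2 * pi * 0.05 * tg + ph[2])
    if (noise > 0) sig <- sig + stats::rnorm(n, 0, noise * stats::sd(sig))
    list(signal = sig, sampling_rate = sampling_rate, beat_times = beats,
         noise = noise)
  })
}

#' Cohort-level covariate effect parameters
#'
#' Effect sizes are expressed in metric units (fraction of sleep per
#' covariate class, or fraction of scored epochs for efficiency); they
#' shift the architecture parameters of each simulated night linearly, so
#' the expected metric of a night is linear in its covariates with exactly
#' these coefficients.  Covariate class frequencies default to the
#' composition of a large community test cohort (gender 45% male, age
#' classes 20/21/25/34%, apnea classes 46/39/8/7%, hypertension 45%).
#'
#' @param age_deep,age_rem,age_efficiency Effect per age class.
#' @param gender_deep,gender_rem Effect of male gender.
#' @param apnea_deep,apnea_rem Effect per apnea class.
#' @param apnea_rem_frag Additional REM interruptions per cycle per apnea
#'   class (REM fragmentation).
#' @param htn_efficiency Effect of hypertension on sleep efficiency.
#' @param gender_p,age_probs,apnea_probs,htn_p Covariate sampling
#'   frequencies.
#' @param architecture Baseline [sleep_architecture_params()].
#' @param preset `"default"` (effects as listed) or `"null"` (all zero).
#' @return A list of class `"cohort_effect_params"`.
#' @export
cohort_effect_params <- function(age_deep = -0.015, age_rem = -0.008,
                                 age_efficiency = -0.02,
                                 gender_deep = -0.02, gender_rem = -0.01,
                                 apnea_deep = -0.012, apnea_rem = -0.015,
                                 apnea_rem_frag = 0.7,
                                 htn_efficiency = -0.02,
                                 gender_p = 0.45,
                                 age_probs = c(164, 168, 198, 270) / 800,
                                 apnea_probs = c(364, 314, 65, 57) / 800,
                                 htn_p = 364 / 800,
                                 architecture = sleep_architecture_params(),
                                 preset = c("default", "null")) {
  preset <- match.arg(preset)
  if (preset == "null") {
    if (missing(age_deep)) age_deep <- 0
    if (missing(age_rem)) age_rem <- 0
    if (missing(age_efficiency)) age_efficiency <- 0
    if (missing(gender_deep)) gender_deep <- 0
    if (missing(gender_rem)) gender_rem <- 0
    if (missing(apnea_deep)) apnea_deep <- 0
    if (missing(apnea_rem)) apnea_rem <- 0
    if (missing(apnea_rem_frag)) apnea_rem_frag <- 0
    if (missing(htn_efficiency)) htn_efficiency <- 0
  }
  structure(list(age_deep = age_deep, age_rem = age_rem,
                 age_efficiency = age_efficiency, gender_deep = gender_deep,
                 gender_rem = gender_rem, apnea_deep = apnea_deep,
                 apnea_rem = apnea_rem, apnea_rem_frag = apnea_rem_frag,
                 htn_efficiency = htn_efficiency, gender_p = gender_p,
                 age_probs = age_probs, apnea_probs = apnea_probs,
                 htn_p = htn_p, architecture = architecture, preset = preset),
            class = "cohort_effect_params")
}

#' Simulate a covariate-structured cohort of nights
#'
#' Samples covariates independently per night, applies the configured
#' effects to the night's architecture parameters, simulates each
#' hypnogram, and computes its sleep metrics.
#'
#' @param effects A [cohort_effect_params()].
#' @param n_nights Number of nights (at least 20).
#' @param duration_h Night duration in hours.
#' @param seed Integer seed, or `NULL`.
#' @param keep_hypnograms Return the simulated hypnograms alongside the
#'   table (default TRUE).
#' @return List with `table` (the cohort data frame: covariate encodings
#'   gender female 0/male 1, age and apnea classes 0--3, hypertension 0/1,
#'   plus the sleep metrics) and `hypnograms`.
#' @export
simulate_cohort <- function(effects = cohort_effect_params(), n_nights = 100,
                            duration_h = 8, seed = NULL,
                            keep_hypnograms = TRUE) {
  stopifnot(inherits(effects, "cohort_effect_params"))
  if (n_nights < 20) stop("n_nights must be at least 20")
  with_seed(seed, {
    arch <- effects$architecture
    gender <- stats::rbinom(n_nights, 1, effects$gender_p)
    age <- sample(0:3, n_nights, replace = TRUE, prob = effects$age_probs)
    apnea <- sample(0:3, n_nights, replace = TRUE, prob = effects$apnea_probs)
    htn <- stats::rbinom(n_nights, 1, effects$htn_p)
    hyps <- vector("list", n_nights)
    rows <- vector("list", n_nights)
    for (i in seq_len(n_nights)) {
      fd <- arch$frac_deep + effects$age_deep * age[i] +
        effects$gender_deep * gender[i] + effects$apnea_deep * apnea[i]
      fr <- arch$frac_rem + effects$age_rem * age[i] +
        effects$gender_rem * gender[i] + effects$apnea_rem * apnea[i]
      fl <- 1 - fd - fr
      eff <- arch$efficiency + effects$age_efficiency * age[i] +
        effects$htn_efficiency * htn[i]
      if (fd <= 0 || fr <= 0 || fl <= 0 || eff <= 0 || eff > 1)
        stop("parameter error: infeasible effect (negative stage target)")
      ai <- arch
      ai$frac_deep <- fd; ai$frac_rem <- fr; ai$frac_light <- fl
      ai$efficiency <- eff
      ai$rem_frag <- arch$rem_frag + effects$apnea_rem_frag * apnea[i]
      h <- simulate_hypnogram(ai, duration_h, seed = NULL)
      m <- compute_sleep_metrics(h)
      if (keep_hypnograms) hyps[[i]] <- h
      rows[[i]] <- data.frame(
        night_id = sprintf("night%04d", i), gender = gender[i],
        age_class = age[i], apnea_class = apnea[i], hypertension = htn[i],
        light_fraction = m$light_fraction, deep_fraction = m$deep_fraction,
        rem_fraction = m$rem_fraction, sleep_efficiency = m$sleep_efficiency,
        mean_rem_bout = m$mean_rem_bout)
    }
    list(table = do.call(rbind, rows),
         hypnograms = if (keep_hypnograms) hyps else NULL)
  })
}
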