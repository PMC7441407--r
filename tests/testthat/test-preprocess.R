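test_that("consecutive beat differences form the IBI series", {
  ibi <- beats_to_ibi(c(0, 1, 2, 3))
  expect_equal(ibi$intervals, c(1, 1, 1))
  expect_equal(ibi$anchor_times, c(1, 2, 3))
})

test_that("a gross interval outlier is removed by the 5-SD filter", {
  # 1000 intervals of 1.0 s plus a single 3.0-s interval (a missed beat)
  intervals <- c(rep(1, 500), 3, rep(1, 500))
  beats <- cumsum(c(0, intervals))
  # direct mean/SD arithmetic oracle on the raw intervals
  z <- abs(intervals - mean(intervals)) / sd(intervals)
  expect_gt(max(z), 30)           # the outlier is unmistakable
  expect_equal(sum(z <= 5), 1000) # and it is the only removal
  ibi <- beats_to_ibi(beats)
  expect_length(ibi$intervals, 1000)
  expect_true(all(ibi$intervals == 1))
  expect_false(any(ibi$anchor_times == beats[502]))
})

test_that("degenerate beat inputs are rejected", {
  expect_error(beats_to_ibi(numeric(0)), "insufficient")
  expect_error(beats_to_ibi(5), "insufficient")
  expect_error(beats_to_ibi(c(1, 1)), "increasing")
  expect_error(beats_to_ibi(c(-1, 1)), "non-negative")
})

test_that("outlier filtering is idempotent on already-clean series", {
  set.seed(31)
  for (rep in 1:5) {
    beats <- cumsum(c(0, runif(500, 0.8, 1.2)))
    once <- beats_to_ibi(beats)
    again <- beats_to_ibi(c(0, once$anchor_times))
    # re-filtering a series with no > 5 SD values changes nothing
    if (length(once$intervals) == length(again$intervals))
      expect_equal(again$intervals, once$intervals)
  }
})

test_that("network input is always exactly 72,000 samples", {
  for (hours in c(2, 6, 9.5)) {
    beats <- seq(0, hours * 3600, by = 0.9)
    inp <- ibi_to_ihr_input(beats_to_ibi(beats))
    expect_length(inp$samples, 72000)
    expect_length(inp$valid_epochs, 1200)
    # padded region is exactly zero
    n_grid <- floor(hours * 3600 * 2) + 1
    expect_true(all(inp$samples[(n_grid + 1):72000] == 0))
    expect_equal(sum(inp$valid_epochs), floor(hours * 3600 / 30))
  }
})

test_that("constant rhythm triggers the zero-variance guard", {
  beats <- seq(0, 8 * 3600, by = 1)
  expect_warning(inp <- ibi_to_ihr_input(beats_to_ibi(beats)),
                 "zero-variance")
  expect_true(all(inp$samples == 0))
})

test_that("resampling matches an independent linear-interpolation oracle", {
  set.seed(7)
  # irregular anchors with a slow sinusoidal IHR
  anchors <- cumsum(runif(4000, 0.7, 1.3))
  intervals <- diff(c(0, anchors))
  ihr <- 1 / intervals
  ibi <- ibi_series(anchors, intervals)
  inp <- ibi_to_ihr_input(ibi)
  # oracle: z-normalize the beat-anchored values, then interpolate each
  # 2 Hz grid point by hand with the two bracketing anchors
  z <- (ihr - mean(ihr)) / sd(ihr)
  n_grid <- floor(max(anchors) * 2) + 1
  grid <- (seq_len(n_grid) - 1) / 2
  oracle <- vapply(grid, function(t) {
    if (t <= anchors[1]) return(z[1])
    if (t >= anchors[length(anchors)]) return(z[length(z)])
    j <- findInterval(t, anchors)
    w <- (t - anchors[j]) / (anchors[j + 1] - anchors[j])
    (1 - w) * z[j] + w * z[j + 1]
  }, numeric(1))
  expect_lt(max(abs(inp$samples[seq_len(n_grid)] - oracle)), 1e-9)
})

test_that("valid-region moments are near 0/1 for smooth rate modulation", {
  # normalization happens on the beat-anchored series before resampling;
  # for a slowly modulated rhythm the 2 Hz series keeps those moments
  t_apx <- cumsum(rep(0.9, 25000))
  hr <- 65 + 4 * sin(2 * pi * t_apx / 300)
  beats <- cumsum(c(0, 60 / hr[-1]))
  inp <- ibi_to_ihr_input(beats_to_ibi(beats))
  n_valid <- sum(inp$valid_epochs) * 60
  v <- inp$samples[seq_len(n_valid)]
  expect_lt(abs(mean(v)), 0.05)
  expect_lt(abs(sd(v) - 1), 0.05)
})

test_that("recordings longer than 10 h are truncated with a warning", {
  set.seed(44)
  beats <- cumsum(c(0, runif(50000, 0.7, 0.9)))
  expect_warning(inp <- ibi_to_ihr_input(beats_to_ibi(beats)), "truncated")
  expect_length(inp$samples, 72000)
  # everything up to the 10-h horizon is covered (the final epoch may lose
  # its last beat to the truncation)
  expect_gte(sum(inp$valid_epochs), 1199)
})

test_that("ihr input requires at least two surviving intervals", {
  expect_error(ibi_to_ihr_input(ibi_series(1, 1)), "insufficient")
})
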