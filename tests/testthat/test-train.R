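test_that("raw expert symbols map onto the four classes", {
  expect_equal(as.character(map_raw_stages(c("W", "N1", "N2", "REM"))),
               c("wake", "light", "light", "rem"))
  expect_equal(as.character(map_raw_stages(c("N3", "N4"))), c("deep", "deep"))
  expect_length(map_raw_stages(character(0)), 0)
  expect_error(map_raw_stages(c("W", "N5")), "N5")
})

test_that("masked cross-entropy matches hand arithmetic", {
  # perfect one-hot predictions
  p <- diag(4)
  expect_equal(masked_cross_entropy(p, hypnogram(stage_levels())), 0)
  # uniform predictions: -log(1/4) per valid epoch
  u <- matrix(0.25, 5, 4)
  expect_equal(masked_cross_entropy(u, hypnogram(rep("deep", 5))), log(4))
  # 3-epoch toy with one masked epoch, against manual arithmetic
  probs <- rbind(c(0.7, 0.1, 0.1, 0.1),
                 c(0.2, 0.5, 0.2, 0.1),
                 c(0.1, 0.1, 0.1, 0.7))
  ref <- hypnogram(c("wake", "light", "wake"))
  manual <- mean(c(-log(0.7), -log(0.5)))
  expect_equal(masked_cross_entropy(probs, ref, c(TRUE, TRUE, FALSE)), manual)
  # unscored reference epochs are excluded like masked ones
  ref2 <- hypnogram(c("wake", "light", "unscored"))
  expect_equal(masked_cross_entropy(probs, ref2), manual)
  expect_error(masked_cross_entropy(probs, ref, rep(FALSE, 3)), "masked")
})

test_that("training configuration echoes the published recipe", {
  tc <- train_config()
  expect_equal(tc$steps, 1e6)
  expect_equal(tc$batch_size, 2L)
  expect_equal(tc$learning_rate, 1e-4)
  expect_equal(tc$l1_decay, 0.25)
  expect_equal(tc$dropout_rate, 0.2)
})

test_that("a short run reduces the loss on separable synthetic nights", {
  cfg <- tiny_config(dropout_rate = 0.1)
  set.seed(21)
  n_ep <- cfg$epochs_per_night
  nights <- lapply(1:20, function(i) {
    stages <- sample(stage_levels(), n_ep, replace = TRUE)
    # strongly stage-separated input: each epoch's samples sit at a
    # stage-specific level plus noise
    lev <- c(wake = 3, light = -1, deep = -3, rem = 1)
    x <- rep(lev[stages], each = cfg$samples_per_epoch) +
      rnorm(n_ep * cfg$samples_per_epoch, 0, 0.3)
    list(input = as.numeric(x), stages = hypnogram(stages))
  })
  m <- stager_model(cfg, seed = 4)
  tc <- train_config(steps = 400, batch_size = 2, learning_rate = 3e-3,
                     l1_decay = 0.25, dropout_rate = 0.1, seed = 9)
  fit <- train_stager(m, nights, tc)
  first <- mean(head(fit$loss_log$data_loss, 10))
  last <- mean(tail(fit$loss_log$data_loss, 10))
  expect_lt(last, first)
  expect_lt(last, log(4)) # better than chance
})

test_that("training is reproducible given the seed", {
  cfg <- tiny_config(dropout_rate = 0.2)
  set.seed(33)
  n_ep <- cfg$epochs_per_night
  nights <- lapply(1:4, function(i) {
    stages <- sample(stage_levels(), n_ep, replace = TRUE)
    x <- rnorm(n_ep * cfg$samples_per_epoch)
    list(input = x, stages = hypnogram(stages))
  })
  run <- function() {
    m <- stager_model(cfg, seed = 7)
    train_stager(m, nights, train_config(steps = 50, batch_size = 2,
                                         learning_rate = 1e-3,
                                         dropout_rate = 0.2,
                                         seed = 11))$loss_log$data_loss
  }
  expect_identical(run(), run())
})

test_that("nights shorter than the padded grid only contribute valid epochs", {
  cfg <- tiny_config()
  m <- stager_model(cfg, seed = 2)
  n_ep <- cfg$epochs_per_night
  x <- rnorm(n_ep * cfg$samples_per_epoch)
  # an ihr_input-like night with only the first half valid
  input <- structure(list(samples = x,
                          valid_epochs = seq_len(n_ep) <= n_ep / 2,
                          night_id = "n1"), class = "ihr_input")
  stages <- hypnogram(rep("light", n_ep))
  s <- cardiostager:::night_to_sample(list(input = input, stages = stages),
                                      n_ep)
  expect_equal(sum(s$labels >= 0), n_ep / 2)
})
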