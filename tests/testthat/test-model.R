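test_that("patch extraction yields 1200 x 256 with zero-padded boundaries", {
  cfg <- model_config()
  x <- rnorm(72000)
  P <- extract_patches(x, cfg)
  expect_equal(dim(P), c(1200L, 256L))
  # patch 0 is centred at sample 30 (0-based): its first 98 positions fall
  # before the recording and are zero
  expect_true(all(P[1, 1:98] == 0))
  expect_equal(P[1, 99:256], x[1:158])
  # adjacent patches overlap by 256 - 60 = 196 samples
  expect_equal(P[2, 1:196], P[1, 61:256])
  expect_equal(P[601, 1:196], P[600, 61:256])
  expect_error(extract_patches(rnorm(100), cfg), "length")
})

test_that("R and compiled patch extraction agree", {
  cfg <- tiny_config()
  x <- rnorm(cfg$epochs_per_night * cfg$samples_per_epoch)
  m <- stager_model(cfg, seed = 3)
  expect_equal(extract_patches(x, cfg),
               cardiostager:::.net_extract_patches(m$ptr, x))
})

test_that("embedding output has the configured width and respects zeros", {
  cfg <- model_config()
  m <- stager_model(cfg, seed = 1)
  P <- extract_patches(rnorm(72000), cfg)
  E <- embed_patches(m, P)
  expect_equal(dim(E), c(1200L, 128L))
  # all-zero patches with zero biases (the initial state) embed to zero
  E0 <- embed_patches(m, matrix(0, 4, 256))
  expect_true(all(E0 == 0))
  expect_error(embed_patches(m, matrix(0, 4, 100)), "configuration|columns")
})

test_that("trainable parameter counts match the closed form", {
  for (cfg in list(tiny_config(), reduced_config(), model_config())) {
    m <- stager_model(cfg, seed = 2)
    got <- n_parameters(m)
    want <- expected_param_count(cfg)
    expect_equal(got$local, want$local)
    expect_equal(got$embedding, want$embedding)
    expect_equal(got$dilated, want$dilated)
    expect_equal(got$output, want$output)
    expect_equal(got$total, want$total)
  }
})

test_that("dilated-stack parameter count is independent of night length", {
  a <- expected_param_count(model_config(epochs_per_night = 1200L))
  b <- expected_param_count(model_config(epochs_per_night = 600L))
  expect_equal(a$dilated, b$dilated)
  ma <- stager_model(model_config(preset = "reduced"), 1)
  mb <- stager_model(model_config(preset = "reduced", epochs_per_night = 300L), 1)
  expect_equal(n_parameters(ma)$dilated, n_parameters(mb)$dilated)
})

test_that("forward output is row-stochastic for arbitrary weights", {
  cfg <- tiny_config()
  m <- stager_model(cfg, seed = 8)
  for (rep in 1:3) {
    x <- rnorm(cfg$epochs_per_night * cfg$samples_per_epoch, sd = rep)
    p <- predict(m, x)
    expect_equal(dim(p), c(cfg$epochs_per_night, 4L))
    expect_true(all(p >= 0))
    expect_lt(max(abs(rowSums(p) - 1)), 1e-6)
  }
})

test_that("inference is deterministic (dropout off)", {
  cfg <- reduced_config()
  m <- stager_model(cfg, seed = 5)
  x <- rnorm(72000)
  expect_identical(predict(m, x), predict(m, x))
})

test_that("analytic gradients match finite differences", {
  cfg <- tiny_config()
  m <- stager_model(cfg, seed = 42)
  set.seed(1)
  x <- rnorm(cfg$epochs_per_night * cfg$samples_per_epoch) * 0.5
  y <- c(sample(0:3, cfg$epochs_per_night - 2, TRUE), -1L, -1L)
  g <- cardiostager:::.net_grad(m$ptr, x, as.integer(y))
  rel <- c()
  for (pi in seq_along(g$grad)) {
    G <- g$grad[[pi]]
    for (ei in sample(length(G), min(6, length(G)))) {
      d <- 1e-5
      lp <- cardiostager:::.net_perturb_check(m$ptr, x, as.integer(y),
                                              pi - 1L, ei - 1L, d)
      lm <- cardiostager:::.net_perturb_check(m$ptr, x, as.integer(y),
                                              pi - 1L, ei - 1L, -d)
      fd <- (lp - lm) / (2 * d)
      rel <- c(rel, abs(fd - G[ei]) / max(1e-6, abs(fd) + abs(G[ei])))
    }
  }
  # the bulk of elements must agree tightly; a few may straddle a
  # leaky-ReLU kink or a max-pool tie where finite differences are invalid
  expect_lt(median(rel), 1e-8)
  expect_lt(quantile(rel, 0.9), 1e-4)
})

test_that("receptive-field spans follow the closed form", {
  expect_equal(receptive_field_span(7, 2), 13)   # 6.5 min of epochs
  expect_equal(receptive_field_span(7, 32), 193) # 96.5 min of epochs
  spans <- receptive_field_span(7, c(2, 4, 8, 16, 32))
  expect_equal(spans, (7 - 1) * c(2, 4, 8, 16, 32) + 1)
})

test_that("argmax decoding honours the mask and the tie rule", {
  probs <- rbind(c(1, 0, 0, 0), c(0, 0, 0, 1), c(0.1, 0.2, 0.3, 0.4),
                 c(0.25, 0.25, 0.25, 0.25), c(0.1, 0.4, 0.4, 0.1))
  h <- probabilities_to_hypnogram(probs)
  expect_equal(as.character(h), c("wake", "rem", "rem", "wake", "light"))
  h2 <- probabilities_to_hypnogram(probs, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(as.character(h2)[3], "unscored")
})

test_that("checkpoints round trip and refuse mismatched architectures", {
  cfg <- tiny_config()
  m <- stager_model(cfg, seed = 10)
  x <- rnorm(cfg$epochs_per_night * cfg$samples_per_epoch)
  p1 <- predict(m, x)
  path <- tempfile(fileext = ".rds")
  save_stager_model(m, path)
  m2 <- load_stager_model(path)
  expect_equal(predict(m2, x), p1)
  # a checkpoint from a different architecture must be refused
  other <- stager_model(tiny_config(embedding_dim = 8L), seed = 1)
  ck <- readRDS(path)
  ck$config <- other$config
  path2 <- tempfile(fileext = ".rds")
  saveRDS(ck, path2)
  expect_error(load_stager_model(path2), "mismatch")
})

test_that("batch normalization is rejected as configured off", {
  expect_error(model_config(batch_norm = TRUE), "batch normalization")
})

test_that("invalid dilation plans are rejected", {
  expect_error(model_config(dilation_rates = c(2L, 3L)), "powers of 2")
  expect_error(model_config(dilation_rates = c(4L, 2L)), "increasing")
  expect_error(model_config(patch_length = 100L), "divisible")
})
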