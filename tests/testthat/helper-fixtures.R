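# Shared fixtures: tiny network configurations and small synthetic inputs
# built in code at test time.

tiny_config <- function(...) {
  # a miniature architecture that exercises every layer type quickly
  args <- utils::modifyList(
    list(patch_length = 16L, epochs_per_night = 24L,
         samples_per_epoch = 4L, local_channels = c(2L, 3L, 4L),
         embedding_dim = 6L, dilated_blocks = 2L,
         dilation_rates = c(2L, 4L), dropout_rate = 0),
    list(...))
  do.call(model_config, args)
}

reduced_config <- function(...) model_config(preset = "reduced", ...)

# closed-form trainable parameter count for the architecture
expected_param_count <- function(cfg) {
  k <- cfg$local_kernel
  cin <- 1L
  local <- 0
  for (co in cfg$local_channels) {
    local <- local + (cin * k * co + co) + (co * k * co + co) + cin * co
    cin <- co
  }
  L3 <- cfg$patch_length / 2^length(cfg$local_channels)
  embed <- cin * L3 * cfg$embedding_dim + cfg$embedding_dim
  D <- cfg$embedding_dim
  dil <- cfg$dilated_blocks * length(cfg$dilation_rates) *
    (D * cfg$dilated_kernel * D + D)
  out <- D * cfg$n_classes + cfg$n_classes
  list(local = local, embedding = embed, dilated = dil, output = out,
       total = local + embed + dil + out)
}

# brute-force accuracy / kappa by enumerating epochs one at a time
brute_force_agreement <- function(pred, ref) {
  stopifnot(length(pred) == length(ref))
  n <- length(pred)
  hits <- 0
  for (i in seq_len(n)) if (pred[i] == ref[i]) hits <- hits + 1
  po <- hits / n
  pe <- 0
  for (s in stage_levels()) {
    pr <- 0; rr <- 0
    for (i in seq_len(n)) {
      if (pred[i] == s) pr <- pr + 1
      if (ref[i] == s) rr <- rr + 1
    }
    pe <- pe + (pr / n) * (rr / n)
  }
  list(accuracy = po, kappa = (po - pe) / (1 - pe))
}

# beat times for a perfectly regular rhythm
regular_beats <- function(n, interval = 1) seq(0, by = interval, length.out = n)
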