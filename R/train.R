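#' Training configuration
#'
#' Defaults are the published training recipe: 1 million optimisation steps
#' at batch size 2, learning rate 1e-4, an L1 weight-decay rate of 0.25 on
#' the convolutional weights, and dropout 0.2.  The decay rate multiplies
#' the mean absolute convolutional weight, which keeps the penalty on the
#' same scale as the cross-entropy term.  The optimizer is Adam.
#'
#' @param steps Number of optimisation steps.
#' @param batch_size Nights per step.
#' @param learning_rate Adam learning rate.
#' @param l1_decay L1 weight-decay coefficient.
#' @param dropout_rate Dropout probability applied after each dilated block
#'   during training.
#' @param seed Integer seed controlling batch sampling, weight
#'   initialisation noise and dropout.
#' @param beta1,beta2,epsilon Adam moment parameters.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(steps = 1e6, batch_size = 2L, learning_rate = 1e-4,
                         l1_decay = 0.25, dropout_rate = 0.2, seed = 1L,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8) {
  stopifnot(steps >= 1, batch_size >= 1, learning_rate > 0, l1_decay >= 0,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(steps = steps, batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, l1_decay = l1_decay,
                 dropout_rate = dropout_rate, seed = as.integer(seed),
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon),
            class = "train_config")
}

# one night of training data -> the C++ sample format: labels are 0-based
# class indices with -1 marking epochs excluded from the loss (padding or
# unscored reference epochs)
night_to_sample <- function(night, n_epochs) {
  input <- night$input
  stages <- night$stages
  x <- if (inherits(input, "ihr_input")) input$samples else as.numeric(input)
  lab <- rep(-1L, n_epochs)
  idx <- stage_to_index(stages)
  k <- min(length(idx), n_epochs)
  lab[seq_len(k)] <- ifelse(is.na(idx[seq_len(k)]), -1L, idx[seq_len(k)])
  if (inherits(input, "ihr_input"))
    lab[!input$valid_epochs] <- -1L
  list(samples = x, labels = lab)
}

#' Train a staging network
#'
#' Minimises the masked cross-entropy (mean over valid epochs of the
#' negative log probability of the reference class) plus the L1 penalty on
#' the convolutional weights, with dropout active, using Adam.  Epochs in
#' the zero-padded region of the input, and unscored reference epochs,
#' are excluded from the loss.  The run is deterministic given
#' `config$seed`.
#'
#' @param model A [stager_model()]; updated in place and also returned.
#' @param nights List of nights, each a list with elements `input` (an
#'   `ihr_input` or numeric vector) and `stages` (a [hypnogram()]).
#' @param config A [train_config()].
#' @param log_every Record the loss every this many steps (default 1).
#' @return List with elements `model`, `loss_log` (data frame of step,
#'   data loss and L1 penalty) and `weights` (final weights).
#' @export
train_stager <- function(model, nights, config = train_config(),
                         log_every = 1L) {
  stopifnot(inherits(model, "stager_model"), length(nights) >= 1)
  n_ep <- model$config$epochs_per_night
  samples <- lapply(nights, night_to_sample, n_epochs = n_ep)
  .net_set_dropout(model$ptr, config$dropout_rate)
  .net_set_seed(model$ptr, config$seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  steps <- as.integer(config$steps)
  keep <- seq(1L, steps, by = as.integer(log_every))
  log_step <- integer(0); log_loss <- numeric(0); log_pen <- numeric(0)
  for (step in seq_len(steps)) {
    pick <- sample.int(length(samples), config$batch_size, replace = TRUE)
    res <- .net_train_step(model$ptr, samples[pick], config$learning_rate,
                           config$l1_decay, config$beta1, config$beta2,
                           config$epsilon)
    if (!is.finite(res$data_loss))
      stop(sprintf("training failure: non-finite loss at step %d", step))
    if (step %in% keep || step == steps) {
      log_step <- c(log_step, step)
      log_loss <- c(log_loss, res$data_loss)
      log_pen <- c(log_pen, res$penalty)
    }
  }
  list(model = model,
       loss_log = data.frame(step = log_step, data_loss = log_loss,
                             l1_penalty = log_pen),
       weights = model_weights(model))
}

#' Masked cross-entropy loss
#'
#' Mean over valid epochs of the negative log probability assigned to the
#' reference class; epochs that are masked out (zero-padded input region)
#' or unscored in the reference contribute nothing.
#'
#' @param probs Row-stochastic matrix of per-epoch class probabilities.
#' @param reference A [hypnogram()] (or character vector of stage labels).
#' @param valid_epochs Logical mask (default: all valid).
#' @return The scalar loss.
#' @examples
#' p <- matrix(0.25, 4, 4)
#' masked_cross_entropy(p, hypnogram(rep("wake", 4)))  # log(4)
#' @export
masked_cross_entropy <- function(probs, reference,
                                 valid_epochs = rep(TRUE, nrow(probs))) {
  stopifnot(nrow(probs) == length(reference),
            nrow(probs) == length(valid_epochs))
  idx <- stage_to_index(reference)
  use <- valid_epochs & !is.na(idx)
  if (!any(use)) stop("undefined loss: all epochs are masked")
  i <- which(use)
  p <- probs[cbind(i, idx[i] + 1L)]
  mean(-log(p))
}
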