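#' Staging network configuration
#'
#' Architecture of the fully convolutional staging network.  The default
#' values are the published configuration: 256-sample patches centred on
#' each of the 1200 30-s epochs of a 10-h input; three local blocks of two
#' kernel-3 convolutions with leaky-ReLU activations, stride-2 max pooling
#' and a downsampled residual connection; a 128-unit embedding; two dilated
#' blocks of five kernel-7 convolutions at dilation rates 2, 4, 8, 16 and
#' 32 with dropout and a block-level residual; and a kernel-1 output
#' convolution with 4 filters followed by a per-epoch softmax.
#'
#' `preset = "reduced"` selects a deliberately small variant (128-sample
#' patches, channel plan 2/4/8, width-16 embedding, one dilated block) used
#' for CPU-scale training experiments on synthetic cohorts.
#'
#' @param patch_length Samples per patch (default 256).
#' @param epochs_per_night Number of 30-s label epochs (default 1200).
#' @param samples_per_epoch Input samples per epoch at 2 Hz (default 60).
#' @param local_channels Channel widths of the three local blocks.
#' @param local_kernel Kernel size of the local convolutions (default 3).
#' @param embedding_dim Embedding width; also the channel width of the
#'   dilated stack so residuals add without projection (default 128).
#' @param dilated_blocks Number of dilated blocks (default 2).
#' @param dilation_rates Dilation plan within a block (default 2,4,8,16,32).
#' @param dilated_kernel Kernel size of the dilated convolutions (default 7).
#' @param dropout_rate Dropout probability after each dilated block.
#' @param leaky_slope Negative-side slope of the leaky ReLU.
#' @param n_classes Output classes (4: wake, light, deep, REM).
#' @param batch_norm Accepted for completeness; the final model
#'   configuration does not use batch normalization and `TRUE` is rejected.
#' @param preset `"default"` or `"reduced"`.
#' @return A list of class `"model_config"`.
#' @export
model_config <- function(patch_length = 256L, epochs_per_night = 1200L,
                         samples_per_epoch = 60L,
                         local_channels = c(16L, 32L, 64L), local_kernel = 3L,
                         embedding_dim = 128L, dilated_blocks = 2L,
                         dilation_rates = c(2L, 4L, 8L, 16L, 32L),
                         dilated_kernel = 7L, dropout_rate = 0.2,
                         leaky_slope = 0.01, n_classes = 4L,
                         batch_norm = FALSE,
                         preset = c("default", "reduced")) {
  preset <- match.arg(preset)
  if (preset == "reduced") {
    if (missing(patch_length)) patch_length <- 128L
    if (missing(local_channels)) local_channels <- c(2L, 4L, 8L)
    if (missing(embedding_dim)) embedding_dim <- 16L
    if (missing(dilated_blocks)) dilated_blocks <- 1L
  }
  if (isTRUE(batch_norm))
    stop("batch normalization is not part of the final model configuration")
  dr <- as.integer(dilation_rates)
  if (any(diff(dr) <= 0) || any(bitwAnd(dr, dr - 1L) != 0L))
    stop("dilation_rates must be strictly increasing powers of 2")
  if (patch_length %% (2L^length(local_channels)) != 0L)
    stop("patch_length must be divisible by pool_stride^local_blocks")
  structure(list(patch_length = as.integer(patch_length),
                 epochs_per_night = as.integer(epochs_per_night),
                 samples_per_epoch = as.integer(samples_per_epoch),
                 local_channels = as.integer(local_channels),
                 local_kernel = as.integer(local_kernel),
                 embedding_dim = as.integer(embedding_dim),
                 dilated_blocks = as.integer(dilated_blocks),
                 dilation_rates = dr,
                 dilated_kernel = as.integer(dilated_kernel),
                 dropout_rate = dropout_rate, leaky_slope = leaky_slope,
                 n_classes = as.integer(n_classes), preset = preset),
            class = "model_config")
}

#' Create a staging network with freshly initialised weights
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialisation (and dropout during
#'   training).
#' @return An object of class `"stager_model"`.
#' @export
stager_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  ptr <- .net_create(config, as.integer(seed))
  structure(list(ptr = ptr, config = config, seed = as.integer(seed)),
            class = "stager_model")
}

#' @export
print.stager_model <- function(x, ...) {
  pc <- .net_param_count(x$ptr)
  cat(sprintf(paste0("<stager_model (%s): %d epochs x %d-sample patches, ",
                     "embedding %d, %d dilated block(s); %s parameters>\n"),
              x$config$preset, x$config$epochs_per_night,
              x$config$patch_length, x$config$embedding_dim,
              x$config$dilated_blocks, format(pc$total, big.mark = ",")))
  invisible(x)
}

#' Break a network input into per-epoch patches
#'
#' Patch `i` (0-based) is the `patch_length`-sample window centred on the
#' centre of epoch `i`; epoch `i` covers samples `[60i, 60i + 60)` of the
#' 2 Hz grid.  Windows extending past the array bounds are zero padded.
#'
#' @param input An `ihr_input` or a numeric vector of length
#'   `epochs_per_night * samples_per_epoch`.
#' @param config A [model_config()].
#' @return Matrix with `epochs_per_night` rows and `patch_length` columns.
#' @export
extract_patches <- function(input, config = model_config()) {
  x <- if (inherits(input, "ihr_input")) input$samples else as.numeric(input)
  n <- config$epochs_per_night * config$samples_per_epoch
  if (length(x) != n)
    stop(sprintf("input must have length %d (got %d)", n, length(x)))
  spe <- config$samples_per_epoch
  P <- config$patch_length
  # 1-based sample index of position t of patch i: centre of epoch i is at
  # 0-based sample i*spe + spe/2; the window starts half a patch earlier
  starts <- (seq_len(config$epochs_per_night) - 1L) * spe + spe %/% 2L - P %/% 2L
  idx <- outer(starts, 0:(P - 1L), `+`) + 1L
  out <- matrix(0, config$epochs_per_night, P)
  ok <- idx >= 1L & idx <= n
  out[ok] <- x[idx[ok]]
  out
}

#' Embed patches with the local feature extractor
#'
#' Runs only the first part of the network: three convolutional blocks and
#' the embedding layer, producing one fixed-length feature vector per
#' epoch.
#'
#' @param model A [stager_model()].
#' @param patches Matrix of patches (rows = epochs).
#' @return Matrix `epochs x embedding_dim`.
#' @export
embed_patches <- function(model, patches) {
  stopifnot(inherits(model, "stager_model"))
  if (!is.matrix(patches) || ncol(patches) != model$config$patch_length)
    stop(sprintf("configuration error: patches must have %d columns",
                 model$config$patch_length))
  .net_embed(model$ptr, patches)
}

#' Per-epoch stage probabilities for one night
#'
#' Full forward pass in inference mode (dropout disabled): local feature
#' extraction, dilated temporal context, kernel-1 output convolution and a
#' per-epoch softmax.
#'
#' @param object A [stager_model()].
#' @param input An `ihr_input` (or bare numeric vector of the right length).
#' @param ... Unused.
#' @return Matrix `epochs_per_night x 4` of row-stochastic class
#'   probabilities (columns wake, light, deep, rem), with the input's
#'   `valid_epochs` attached as an attribute when available.
#' @export
predict.stager_model <- function(object, input, ...) {
  x <- if (inherits(input, "ihr_input")) input$samples else as.numeric(input)
  probs <- .net_forward(object$ptr, x)
  colnames(probs) <- stage_levels()
  if (inherits(input, "ihr_input"))
    attr(probs, "valid_epochs") <- input$valid_epochs
  probs
}

#' Stage probabilities to a predicted hypnogram
#'
#' Takes the per-epoch argmax over the four classes; ties are broken
#' towards the lowest class index.  Epochs outside the validity mask are
#' labelled `unscored`.
#'
#' @param probs Row-stochastic matrix of per-epoch class probabilities.
#' @param valid_epochs Logical mask; defaults to the attribute attached by
#'   [predict.stager_model()], else all valid.
#' @return A [hypnogram()].
#' @export
probabilities_to_hypnogram <- function(probs,
                                       valid_epochs = attr(probs, "valid_epochs")) {
  if (is.null(valid_epochs)) valid_epochs <- rep(TRUE, nrow(probs))
  stopifnot(length(valid_epochs) == nrow(probs))
  idx <- max.col(probs, ties.method = "first") - 1L
  idx[!valid_epochs] <- NA_integer_
  hypnogram(index_to_stage(idx))
}

#' Receptive-field span of a dilated convolution layer
#'
#' A kernel of size `k` at dilation `d` spans `(k - 1) * d + 1` sequence
#' positions; at the 30-s epoch resolution this is the temporal field of
#' view of a single layer.
#'
#' @param kernel Kernel size.
#' @param dilation Dilation rate.
#' @return Span in sequence positions (epochs).
#' @export
receptive_field_span <- function(kernel, dilation) {
  (kernel - 1) * dilation + 1
}

#' Trainable parameter counts
#'
#' @param model A [stager_model()].
#' @return List with counts for the local extractor, embedding layer,
#'   dilated stack, output head, and the total.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "stager_model"))
  .net_param_count(model$ptr)
}

#' Extract or replace network weights
#'
#' @param model A [stager_model()].
#' @return Named list of weight matrices.
#' @export
model_weights <- function(model) {
  stopifnot(inherits(model, "stager_model"))
  .net_weights(model$ptr)
}

#' @rdname model_weights
#' @param weights Named list as returned by [model_weights()].
#' @export
set_model_weights <- function(model, weights) {
  stopifnot(inherits(model, "stager_model"))
  .net_set_weights(model$ptr, weights)
  invisible(model)
}

#' Save or load a model checkpoint
#'
#' The checkpoint stores the configuration alongside the weights;
#' [load_stager_model()] refuses to restore weights into a mismatched
#' architecture.
#'
#' @param model A [stager_model()].
#' @param path File path.
#' @export
save_stager_model <- function(model, path) {
  stopifnot(inherits(model, "stager_model"))
  saveRDS(list(config = model$config, weights = model_weights(model),
               seed = model$seed), path)
  invisible(path)
}

#' @rdname save_stager_model
#' @return For `load_stager_model`, a restored [stager_model()].
#' @export
load_stager_model <- function(path) {
  ck <- readRDS(path)
  if (!is.list(ck) || !all(c("config", "weights") %in% names(ck)))
    stop("not a stager model checkpoint")
  model <- stager_model(ck$config, seed = ck$seed %||% 1L)
  tryCatch(set_model_weights(model, ck$weights),
           error = function(e) stop("checkpoint/config mismatch: ",
                                    conditionMessage(e)))
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
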