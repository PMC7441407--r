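#' End-to-end learnability experiment on synthetic nights
#'
#' The central integration check of the pipeline: simulate a cohort of
#' nights (hypnogram, stage-conditioned inter-beat intervals, IHR network
#' input), train a reduced staging network on the training nights, predict
#' the held-out nights and report pooled epoch-wise agreement.  With the
#' well-separated `"easy"` emission preset the network should comfortably
#' exceed the 0.25 four-class chance level on held-out nights.
#'
#' @param n_train,n_test Simulated nights for training and held-out
#'   evaluation.
#' @param steps Optimisation steps.
#' @param seed Integer seed controlling every source of randomness.
#' @param emission A [cardiac_emission_params()]; default the easy preset.
#' @param architecture A [sleep_architecture_params()].
#' @param config A [model_config()]; default the reduced preset.
#' @param duration_h Night duration in hours.
#' @param learning_rate,batch_size,l1_decay Training settings for the
#'   reduced run.
#' @return List with `report` (an `eval_report` on the held-out nights),
#'   `train_report`, `loss_log` and `model`.
#' @export
run_learnability_experiment <- function(n_train = 60, n_test = 20,
                                        steps = 10000, seed = 1,
                                        emission = cardiac_emission_params(preset = "easy"),
                                        architecture = sleep_architecture_params(),
                                        config = model_config(preset = "reduced"),
                                        duration_h = 8,
                                        learning_rate = 1e-3,
                                        batch_size = 1L, l1_decay = 0.25) {
  n_all <- n_train + n_test
  nights <- with_seed(seed, lapply(seq_len(n_all), function(i) {
    h <- simulate_hypnogram(architecture, duration_h, seed = NULL)
    ibi_raw <- simulate_night_ibi(h, emission, seed = NULL)
    ibi <- beats_to_ibi(c(0, ibi_raw$anchor_times))
    input <- ibi_to_ihr_input(ibi, night_id = sprintf("night%03d", i))
    list(input = input, stages = h)
  }))
  train_nights <- nights[seq_len(n_train)]
  test_nights <- nights[n_train + seq_len(n_test)]
  model <- stager_model(config, seed = seed)
  tc <- train_config(steps = steps, batch_size = batch_size,
                     learning_rate = learning_rate, l1_decay = l1_decay,
                     dropout_rate = config$dropout_rate, seed = seed)
  fit <- train_stager(model, train_nights, tc, log_every = 50L)
  predict_pairs <- function(set) {
    lapply(set, function(nt) {
      probs <- predict(model, nt$input)
      list(predicted = probabilities_to_hypnogram(probs),
           reference = nt$stages, night_id = nt$input$night_id)
    })
  }
  list(report = evaluate_hypnograms(predict_pairs(test_nights)),
       train_report = evaluate_hypnograms(predict_pairs(train_nights)),
       loss_log = fit$loss_log, model = model)
}
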