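#' Epoch-wise agreement between predicted and reference hypnograms
#'
#' Treats every scored 30-s epoch as an independent prediction.  Epochs
#' unscored in either sequence are excluded.  Reports the pooled 4-class
#' accuracy, Cohen's kappa and confusion matrix over all nights, plus
#' per-night accuracy and kappa.
#'
#' @param pairs List of nights, each a list with elements `predicted` and
#'   `reference` ([hypnogram()]s aligned on epochs) and optionally
#'   `night_id`.
#' @return A list of class `"eval_report"` with `overall_accuracy`,
#'   `cohen_kappa`, `confusion_matrix` (rows = reference, columns =
#'   predicted) and `per_night` (data frame).
#' @export
evaluate_hypnograms <- function(pairs) {
  if (length(pairs) == 0) stop("empty evaluation: no nights supplied")
  conf <- matrix(0L, 4, 4, dimnames = list(reference = stage_levels(),
                                           predicted = stage_levels()))
  per <- data.frame(night_id = character(0), n_epochs = integer(0),
                    accuracy = numeric(0), kappa = numeric(0))
  for (k in seq_along(pairs)) {
    pr <- pairs[[k]]$predicted
    rf <- pairs[[k]]$reference
    n <- min(length(pr), length(rf))
    pi <- stage_to_index(pr[seq_len(n)])
    ri <- stage_to_index(rf[seq_len(n)])
    use <- !is.na(pi) & !is.na(ri)
    if (!any(use)) next
    ck <- table(factor(ri[use], levels = 0:3), factor(pi[use], levels = 0:3))
    conf <- conf + as.integer(ck)
    st <- agreement_stats(matrix(as.integer(ck), 4, 4))
    per <- rbind(per, data.frame(
      night_id = pairs[[k]]$night_id %||% as.character(k),
      n_epochs = sum(use), accuracy = st$accuracy, kappa = st$kappa))
  }
  if (sum(conf) == 0) stop("empty evaluation: zero comparable epochs")
  st <- agreement_stats(conf)
  structure(list(overall_accuracy = st$accuracy, cohen_kappa = st$kappa,
                 confusion_matrix = conf, per_night = per),
            class = "eval_report")
}

# accuracy and Cohen's kappa from a square confusion matrix
# (rows reference, columns predicted); kappa = (p_o - p_e) / (1 - p_e)
# with the chance agreement p_e computed from the marginals
agreement_stats <- function(conf) {
  n <- sum(conf)
  po <- sum(diag(conf)) / n
  pe <- sum(rowSums(conf) * colSums(conf)) / n^2
  kappa <- if (pe >= 1) {
    if (po >= 1) 1 else 0
  } else {
    (po - pe) / (1 - pe)
  }
  list(accuracy = po, kappa = kappa)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %d epochs over %d nights>\n",
              sum(x$confusion_matrix), nrow(x$per_night)))
  cat(sprintf("  overall accuracy %.3f, Cohen's kappa %.3f\n",
              x$overall_accuracy, x$cohen_kappa))
  print(x$confusion_matrix)
  invisible(x)
}
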