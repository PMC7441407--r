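#' Hypnogram-derived sleep metrics
#'
#' Computes the stage fractions (light, deep, REM as fractions of all sleep
#' epochs), sleep efficiency (fraction of scored epochs that are
#' non-wake) and the mean REM bout duration (mean length of maximal runs of
#' consecutive REM epochs, in minutes).  Unscored epochs are excluded from
#' every denominator.  A metric whose denominator is empty is returned as
#' `NA`.
#'
#' @param h A [hypnogram()].
#' @return A list of class `"sleep_metrics"` with elements
#'   `light_fraction`, `deep_fraction`, `rem_fraction`, `sleep_efficiency`
#'   and `mean_rem_bout` (minutes).
#' @examples
#' compute_sleep_metrics(hypnogram(
#'   c("wake", "light", "light", "deep", "rem", "rem", "wake", "rem")))
#' @export
compute_sleep_metrics <- function(h) {
  s <- as.character(h)
  scored <- s[s != "unscored"]
  if (length(scored) == 0) stop("undefined metrics: zero scored epochs")
  epoch_min <- (attr(h, "epoch_length") %||% 30) / 60
  sleep <- scored[scored != "wake"]
  eff <- length(sleep) / length(scored)
  if (length(sleep) > 0) {
    lf <- sum(sleep == "light") / length(sleep)
    df <- sum(sleep == "deep") / length(sleep)
    rf <- sum(sleep == "rem") / length(sleep)
  } else {
    lf <- df <- rf <- NA_real_
  }
  r <- rle(scored)
  rem_runs <- r$lengths[r$values == "rem"]
  mrb <- if (length(rem_runs) > 0) mean(rem_runs) * epoch_min else NA_real_
  structure(list(light_fraction = lf, deep_fraction = df, rem_fraction = rf,
                 sleep_efficiency = eff, mean_rem_bout = mrb),
            class = "sleep_metrics")
}

#' @export
print.sleep_metrics <- function(x, ...) {
  cat(sprintf(paste0("<sleep_metrics: light %.3f deep %.3f rem %.3f ",
                     "efficiency %.3f mean REM bout %.2f min>\n"),
              x$light_fraction, x$deep_fraction, x$rem_fraction,
              x$sleep_efficiency, x$mean_rem_bout))
  invisible(x)
}
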