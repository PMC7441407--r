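#' Sleep stage vocabulary
#'
#' Four-class stages in canonical index order (wake = 0, light = 1,
#' deep = 2, REM = 3), as used throughout the package.
#'
#' @return Character vector of the four stage labels.
#' @export
stage_levels <- function() c("wake", "light", "deep", "rem")

#' Construct a hypnogram
#'
#' A hypnogram is the sequence of sleep stages assigned to consecutive 30-s
#' epochs of a night.  Labels are drawn from the closed vocabulary
#' `wake`, `light`, `deep`, `rem`, plus `unscored` for epochs without a
#' valid stage (e.g. beyond the recorded night).
#'
#' @param stages Character vector of stage labels.
#' @param epoch_length Epoch duration in seconds (default 30).
#' @return A character vector of class `"hypnogram"` with an
#'   `epoch_length` attribute.
#' @examples
#' hypnogram(c("wake", "light", "light", "deep", "rem"))
#' @export
hypnogram <- function(stages, epoch_length = 30) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), c(stage_levels(), "unscored"))
  if (length(bad) > 0)
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  structure(stages, class = "hypnogram", epoch_length = epoch_length)
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram: %d epochs of %gs>\n", length(x),
              attr(x, "epoch_length")))
  tab <- table(factor(unclass(x), levels = c(stage_levels(), "unscored")))
  print(tab)
  invisible(x)
}

#' @export
`[.hypnogram` <- function(x, i) {
  hypnogram(unclass(x)[i], attr(x, "epoch_length"))
}

# stage label <-> 0-based class index (wake=0, light=1, deep=2, rem=3);
# unscored maps to NA
stage_to_index <- function(stages) {
  match(as.character(stages), stage_levels()) - 1L
}

index_to_stage <- function(idx) {
  out <- rep("unscored", length(idx))
  ok <- !is.na(idx) & idx >= 0 & idx <= 3
  out[ok] <- stage_levels()[idx[ok] + 1L]
  out
}

#' Map raw sleep-study stage symbols to the four-class vocabulary
#'
#' Expert-scored nights label every 30-s epoch with one of the symbols
#' `W`, `N1`, `N2`, `N3`, `N4`, `REM`.  N1 and N2 are grouped into a single
#' light-sleep class; N4 (used by Rechtschaffen--Kales scoring) is combined
#' with N3 into deep sleep.
#'
#' @param labels Character vector over the raw six-symbol vocabulary.
#' @return A [hypnogram()] over `wake`/`light`/`deep`/`rem`.
#' @examples
#' map_raw_stages(c("W", "N1", "N2", "N3", "N4", "REM"))
#' @export
map_raw_stages <- function(labels) {
  labels <- as.character(labels)
  map <- c(W = "wake", N1 = "light", N2 = "light",
           N3 = "deep", N4 = "deep", REM = "rem")
  bad <- setdiff(unique(labels), names(map))
  if (length(bad) > 0)
    stop("unknown stage symbol(s): ", paste(bad, collapse = ", "))
  hypnogram(unname(map[labels]))
}
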