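#' Construct a dominance-time series
#'
#' Container for one subject/condition run of perceptual dominance times,
#' together with the presentation timing. Dominance times are the intervals
#' (in seconds) between successive reported percept changes.
#'
#' @param durations numeric vector of dominance times (s, all > 0).
#' @param percepts optional character vector of percept labels ("L"/"R"),
#'   one per dominance time, strictly alternating.
#' @param condition "continuous" or "intermittent".
#' @param l_p presentation length (s); used for intermittent runs.
#' @param l_b blank-display length (s); 0 encodes continuous viewing.
#' @param duration_total total run length T (s). Defaults to the sum of the
#'   durations.
#' @param truncated logical: was a final truncated interval removed at T?
#'   Kept as metadata; the fitters never see the truncated tail.
#' @param subject optional subject identifier.
#' @return an object of class `dominance_series`.
#' @examples
#' dominance_series(c(5.2, 3.1, 8.4), condition = "continuous")
#' @export
dominance_series <- function(durations, percepts = NULL,
                             condition = c("continuous", "intermittent"),
                             l_p = 0.6, l_b = 0.8, duration_total = NULL,
                             truncated = FALSE, subject = NA_character_) {
  condition <- match.arg(condition)
  durations <- as.numeric(durations)
  if (length(durations) < 1 || any(!is.finite(durations)) || any(durations <= 0))
    stop("durations must be a non-empty vector of positive times")
  if (condition == "continuous") l_b <- 0
  if (condition == "intermittent" && (l_p <= 0 || l_b <= 0))
    stop("intermittent series need positive presentation and blank lengths")
  if (!is.null(percepts)) {
    if (length(percepts) != length(durations))
      stop("percepts must have one label per dominance time")
    if (length(percepts) > 1 && any(percepts[-1] == percepts[-length(percepts)]))
      stop("percept labels must strictly alternate")
  }
  if (is.null(duration_total)) duration_total <- sum(durations)
  if (duration_total + 1e-9 < sum(durations))
    stop("run length T is shorter than the summed dominance times")
  structure(list(durations = durations, percepts = percepts,
                 condition = condition, l_p = l_p, l_b = l_b,
                 duration_total = duration_total, truncated = truncated,
                 subject = subject),
            class = "dominance_series")
}

#' @export
print.dominance_series <- function(x, ...) {
  cat(sprintf("Dominance series (%s): n = %d, T = %.1f s", x$condition,
              length(x$durations), x$duration_total))
  if (!is.na(x$subject)) cat(sprintf(", subject %s", x$subject))
  cat(sprintf("\n  mean = %.2f s, sd = %.2f s, CV = %.2f\n",
              mean(x$durations), sd(x$durations),
              sd(x$durations) / mean(x$durations)))
  invisible(x)
}

as_durations <- function(x) {
  if (inherits(x, "dominance_series")) x$durations else as.numeric(x)
}
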