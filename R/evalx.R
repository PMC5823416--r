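#' Confusion-matrix metrics
#'
#' Computes accuracy, sensitivity and specificity from the four confusion
#' counts: `p_t` positives predicted positive, `n_t` negatives predicted
#' negative, `p_f` positives predicted negative, `n_f` negatives predicted
#' positive. The default `"printed"` convention reproduces the formula set
#' used in the capsule-endoscopy boundary literature this package follows,
#' where sensitivity is `n_t / (p_f + n_t)` and specificity
#' `p_t / (n_f + p_t)`; `"standard"` gives the textbook definitions
#' (sensitivity `p_t / (p_t + p_f)`, specificity `n_t / (n_t + n_f)`).
#' Zero denominators yield `NaN` with a warning.
#'
#' @param p_t,n_t,p_f,n_f non-negative integer counts.
#' @param convention `"printed"` (default) or `"standard"`.
#' @return named numeric vector `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(p_t, n_t, p_f, n_f,
                              convention = c("printed", "standard")) {
  convention <- match.arg(convention)
  stopifnot(p_t >= 0, n_t >= 0, p_f >= 0, n_f >= 0)
  total <- p_t + n_t + p_f + n_f
  if (total == 0) stop("no evaluated frames", call. = FALSE)
  div <- function(num, den) {
    if (den == 0) {
      warning("zero denominator in a confusion metric", call. = FALSE)
      return(NaN)
    }
    num / den
  }
  if (convention == "printed") {
    c(accuracy = (p_t + n_t) / total,
      sensitivity = div(n_t, p_f + n_t),
      specificity = div(p_t, n_f + p_t))
  } else {
    c(accuracy = (p_t + n_t) / total,
      sensitivity = div(p_t, p_t + p_f),
      specificity = div(n_t, n_t + n_f))
  }
}

#' Boundary-location error summary
#'
#' Absolute frame error per video between estimated and true boundary
#' frames, with mean and median. The median is the robust summary: a
#' single badly located video inflates the mean but not the median.
#'
#' @param estimates numeric vector of estimated boundary frames.
#' @param truths numeric vector of true boundary frames, same length.
#' @return a `location_error`: list `per_video_errors`, `mean_error`,
#'   `median_error`.
#' @export
location_error <- function(estimates, truths) {
  if (length(estimates) != length(truths))
    stop("estimates and truths must have equal length", call. = FALSE)
  err <- abs(as.numeric(estimates) - as.numeric(truths))
  structure(list(per_video_errors = err, mean_error = mean(err),
                 median_error = stats::median(err)),
            class = "location_error")
}
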