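#' Monitor parameters
#'
#' The Monitor divides the sequence into consecutive non-overlapping
#' windows of `window_size` frames and samples every `sample_interval`-th
#' frame inside a window (capsule cameras shoot a few frames per second,
#' so neighbors are near-duplicates). A window pair is handed to the Judge
#' when the ratio of its color dissimilarity to the running mean exceeds
#' `base_threshold + threshold_step * t`, where `t` counts prior Judge
#' rejections — each false alarm raises the bar.
#'
#' @param window_size frames per window (default 100).
#' @param sample_interval frame stride within a window (default 5).
#' @param base_threshold trigger ratio at `t = 0` (default 0.2).
#' @param threshold_step ratio increment per rejection (default 0.3).
#' @return a `monitor_params` list.
#' @export
monitor_params <- function(window_size = 100L, sample_interval = 5L,
                           base_threshold = 0.2, threshold_step = 0.3) {
  window_size <- as.integer(window_size)
  sample_interval <- as.integer(sample_interval)
  if (window_size < 2L * sample_interval)
    stop("window_size must be at least twice sample_interval", call. = FALSE)
  if (base_threshold <= 0 || threshold_step < 0)
    stop("base_threshold must be positive, threshold_step non-negative",
         call. = FALSE)
  structure(list(window_size = window_size, sample_interval = sample_interval,
                 base_threshold = base_threshold,
                 threshold_step = threshold_step),
            class = "monitor_params")
}

#' Mean color of a frame over its valid region
#'
#' Arithmetic mean of one Lab channel over the valid-region pixels.
#'
#' @param lab a `lab_image`.
#' @param mask a `vrof_mask` (fallback already applied, so never empty).
#' @param channel `"L"`, `"a"` or `"b"`.
#' @return scalar mean.
#' @export
frame_mean_color <- function(lab, mask, channel = c("a", "b", "L")) {
  channel <- match.arg(channel)
  m <- if (inherits(mask, "vrof_mask")) mask$mask else mask
  n <- sum(m)
  if (n == 0L) stop("empty valid region", call. = FALSE)
  sum(lab[[channel]][m]) / n
}

# masked (a, b) means of one frame
frame_ab_stats <- function(frame, sal_par) {
  v <- frame_vrof(frame, sal_par)
  c(a = frame_mean_color(v$lab, v$mask, "a"),
    b = frame_mean_color(v$lab, v$mask, "b"))
}

#' Color statistics of one window
#'
#' Means of the per-frame valid-region (a, b) means over the frames
#' sampled at the monitor stride. Only channels a and b enter: lightness
#' varies with capsule pose and illumination, chroma tracks the organ.
#'
#' @param frames a `frame_sequence`.
#' @param start 0-based index of the window's first frame.
#' @param params a `monitor_params`.
#' @param sal_par a `saliency_params`.
#' @return a `window_stats` list with `mean_a`, `mean_b`, `start`,
#'   `sampled_indices`.
#' @export
window_stats <- function(frames, start, params = monitor_params(),
                         sal_par = saliency_params()) {
  idx <- seq(start, start + params$window_size - 1L,
             by = params$sample_interval)
  idx <- idx[idx < length(frames)]
  if (length(idx) == 0L) stop("empty window", call. = FALSE)
  ab <- vapply(idx, function(i) frame_ab_stats(frames$get(i), sal_par),
               numeric(2L))
  structure(list(mean_a = mean(ab[1L, ]), mean_b = mean(ab[2L, ]),
                 start = as.integer(start), sampled_indices = as.integer(idx)),
            class = "window_stats")
}

#' Color dissimilarity of a window pair
#'
#' Euclidean distance between the (a, b) mean vectors of two windows.
#'
#' @param w1,w2 `window_stats` (or any list with `mean_a`, `mean_b`).
#' @return non-negative scalar.
#' @export
pair_dissimilarity <- function(w1, w2) {
  sqrt((w1$mean_a - w2$mean_a)^2 + (w1$mean_b - w2$mean_b)^2)
}

#' Initialize the Monitor state
#'
#' The running mean dissimilarity (MDC) starts equal to the first DC, so
#' the very first pair triggers the Judge (ratio 1 exceeds the base
#' threshold) — the Judge's rejection then calibrates `t` on the opening,
#' stationary stretch of the video.
#'
#' @return a `monitor_state` list: `dc_history`, `mdc`, `t`.
#' @export
monitor_init <- function() {
  structure(list(dc_history = numeric(0), mdc = NA_real_, t = 0L),
            class = "monitor_state")
}

#' One Monitor decision
#'
#' Applies the trigger rule `DC_k / MDC > base + step * t` to the current
#' pair's dissimilarity, then folds `dc_k` into the running mean for the
#' next pair. An MDC of exactly zero means the stream has been perfectly
#' constant, so any non-zero change triggers.
#'
#' @param state a `monitor_state`.
#' @param dc_k current pair dissimilarity.
#' @param params a `monitor_params`.
#' @return list `state` (updated), `trigger` (logical), `ratio`.
#' @export
monitor_step <- function(state, dc_k, params = monitor_params()) {
  mdc <- if (length(state$dc_history) == 0L) dc_k else state$mdc
  thresh <- params$base_threshold + params$threshold_step * state$t
  if (mdc == 0) {
    trigger <- dc_k > 0
    ratio <- if (dc_k > 0) Inf else 0
  } else {
    ratio <- dc_k / mdc
    trigger <- ratio > thresh
  }
  state$dc_history <- c(state$dc_history, dc_k)
  state$mdc <- mean(state$dc_history)
  list(state = state, trigger = trigger, ratio = ratio)
}

#' Run the Monitor over a frame sequence
#'
#' Walks window pairs `(W_1, W_2), (W_2, W_3), ...` in order, computing
#' each pair's color dissimilarity lazily (window statistics are cached,
#' so each window is measured once). On a trigger it calls `judge_fn(k)`
#' with the 1-based index of the pair's first window; if the Judge accepts,
#' the run stops immediately — frames past the accepted pair are never
#' decoded — otherwise `t` is incremented and monitoring continues.
#'
#' @param frames a `frame_sequence`.
#' @param params a `monitor_params`.
#' @param judge_fn function of the pair index returning a list with at
#'   least `accepted` (logical) and, when accepted, `boundary_frame`.
#' @param sal_par a `saliency_params`.
#' @return a `monitor_result`: `estimate` (the accepting Judge's return
#'   value, or NULL), `accepted`, `triggered_pair`, `n_judge_calls`,
#'   `t_final`, `dc_history`, `trigger_log`.
#' @export
run_monitor <- function(frames, params = monitor_params(), judge_fn,
                        sal_par = saliency_params()) {
  m <- params$window_size
  n_windows <- length(frames) %/% m
  if (n_windows < 2L) stop("need at least two full windows", call. = FALSE)
  stats_cache <- vector("list", n_windows)
  get_stats <- function(k) {
    if (is.null(stats_cache[[k]]))
      stats_cache[[k]] <<- window_stats(frames, (k - 1L) * m, params, sal_par)
    stats_cache[[k]]
  }
  state <- monitor_init()
  trigger_log <- list()
  n_judge <- 0L
  for (k in seq_len(n_windows - 1L)) {
    dc <- pair_dissimilarity(get_stats(k), get_stats(k + 1L))
    step <- monitor_step(state, dc, params)
    state <- step$state
    if (step$trigger) {
      n_judge <- n_judge + 1L
      verdict <- judge_fn(k)
      trigger_log[[length(trigger_log) + 1L]] <-
        list(pair = k, ratio = step$ratio, accepted = isTRUE(verdict$accepted))
      if (isTRUE(verdict$accepted)) {
        return(structure(list(estimate = verdict, accepted = TRUE,
                              triggered_pair = k, n_judge_calls = n_judge,
                              t_final = state$t, dc_history = state$dc_history,
                              trigger_log = trigger_log),
                         class = "monitor_result"))
      }
      state$t <- state$t + 1L
    }
  }
  structure(list(estimate = NULL, accepted = FALSE, triggered_pair = NA_integer_,
                 n_judge_calls = n_judge, t_final = state$t,
                 dc_history = state$dc_history, trigger_log = trigger_log),
            class = "monitor_result")
}
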