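#' Train the Judge's organ classifier
#'
#' Fits a support-vector classifier with radial-basis kernel on fused
#' color-texture descriptors. Features are standardized to zero mean and
#' unit variance with training-set statistics (the kernel is
#' scale-sensitive); the statistics travel with the model so prediction
#' applies the same transform. Labels follow the convention 0 = stomach
#' (before the pylorus), 1 = intestine (after).
#'
#' @param features numeric matrix, one row per frame.
#' @param labels integer/numeric vector of 0/1 labels.
#' @param cost soft-margin cost (default 1).
#' @param gamma kernel width; default `1 / ncol(features)`.
#' @return a `ctvp_model`.
#' @export
train_judge <- function(features, labels, cost = 1, gamma = NULL) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  if (nrow(features) != length(labels))
    stop("features and labels disagree in length", call. = FALSE)
  ctr <- colMeans(features)
  scl <- apply(features, 2L, stats::sd)
  scl[scl == 0] <- 1
  x <- scale(features, center = ctr, scale = scl)
  if (is.null(gamma)) gamma <- 1 / ncol(features)
  fit <- e1071::svm(x = x, y = factor(labels, levels = c(0L, 1L)),
                    kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  structure(list(fit = fit, center = ctr, scale = scl,
                 n_features = ncol(features)),
            class = "ctvp_model")
}

#' Predict organ labels for descriptor rows
#'
#' @param object a `ctvp_model`.
#' @param newdata numeric matrix (or single vector) of descriptors.
#' @param ... unused.
#' @return integer vector of 0/1 labels.
#' @export
predict.ctvp_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  x <- scale(as.matrix(newdata), center = object$center,
             scale = object$scale)
  as.integer(as.character(stats::predict(object$fit, x)))
}

#' Best step split of a 0/1 label sequence
#'
#' Finds the split position `s` (1-based, meaning labels `1..s-1` are the
#' stomach side and `s..n` the intestine side) minimizing the number of
#' misclassified labels: ones before the split plus zeros at or after it.
#' Ties go to the earliest split. Splits are restricted to `2..n`, so both
#' sides are non-empty as index sets.
#'
#' @param labels integer vector of 0/1.
#' @return list `split` (1-based index of the first intestine-side
#'   position), `cost`.
#' @export
best_split <- function(labels) {
  n <- length(labels)
  if (n < 2L) stop("need at least two labels", call. = FALSE)
  ones_before <- c(0, cumsum(labels))          # ones strictly before s
  zeros_after <- rev(c(0, cumsum(rev(1 - labels)))) # zeros at/after s
  s_cand <- 2:n
  cost <- ones_before[s_cand] + zeros_after[s_cand]
  best <- which.min(cost) # which.min takes the earliest minimum
  list(split = s_cand[best], cost = as.integer(cost[best]))
}

#' Judge a triggered window pair
#'
#' Classifies the sampled frames of the three target windows around a
#' triggered pair `(W_k, W_{k+1})` — the preceding window `W_{k-1}` is
#' included for context when it exists — and converts the 0/1 label
#' sequence into a boundary estimate via the minimum-misclassification
#' step split. The verdict is accepted only if the split cost stays within
#' `acceptance_fraction` of the judged frames and both organ labels are
#' actually present on their respective sides; otherwise the trigger is
#' treated as a false alarm.
#'
#' @param frames a `frame_sequence`.
#' @param pair_k 1-based index of the pair's first window.
#' @param model a `ctvp_model`.
#' @param params a `monitor_params` (window geometry and stride).
#' @param sal_par a `saliency_params`.
#' @param pc_par a `pc_params`.
#' @param glcm_par a `glcm_params`.
#' @param acceptance_fraction maximum tolerated split-cost fraction
#'   (default 0.2).
#' @param bank optional precomputed [log_gabor_bank()].
#' @param label_cache optional environment memoizing per-frame predicted
#'   labels across Judge calls with overlapping spans.
#' @return a `boundary_estimate`: `accepted`, `boundary_frame`, `labels`,
#'   `frame_indices`, `split_cost`.
#' @export
judge_pair <- function(frames, pair_k, model, params = monitor_params(),
                       sal_par = saliency_params(), pc_par = pc_params(),
                       glcm_par = glcm_params(), acceptance_fraction = 0.2,
                       bank = NULL, label_cache = NULL) {
  m <- params$window_size
  first_win <- max(1L, pair_k - 1L)
  span_start <- (first_win - 1L) * m
  span_end <- min((pair_k + 1L) * m, length(frames)) - 1L
  idx <- seq(span_start, span_end, by = params$sample_interval)
  if (length(idx) < 2L) stop("judged span too short", call. = FALSE)
  label_one <- function(i) {
    key <- as.character(i)
    if (!is.null(label_cache) && !is.null(label_cache[[key]]))
      return(label_cache[[key]])
    fr <- frames$get(i)
    v <- frame_vrof(fr, sal_par)
    lab <- predict(model, ctvp(fr, v$mask, pc_par, glcm_par, bank))
    if (!is.null(label_cache)) label_cache[[key]] <- lab
    lab
  }
  labels <- vapply(idx, label_one, integer(1L))
  sp <- best_split(labels)
  n <- length(labels)
  has_step <- any(labels[seq_len(sp$split - 1L)] == 0L) &&
    any(labels[sp$split:n] == 1L)
  accepted <- has_step && sp$cost <= acceptance_fraction * n
  structure(list(accepted = accepted,
                 boundary_frame = if (accepted) idx[sp$split] else NA_integer_,
                 labels = labels, frame_indices = idx,
                 split_cost = sp$cost),
            class = "boundary_estimate")
}
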