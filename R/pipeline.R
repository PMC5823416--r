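#' Build a labelled descriptor set from synthetic frames
#'
#' Generates `n_per_class` stomach and intestine frames from `cfg`
#' (varying only the per-frame seed) and computes each frame's fused
#' color-texture descriptor. Used to train and cross-validate the Judge
#' without clinical video.
#'
#' @param n_per_class frames per organ class.
#' @param cfg a `synthetic_config` (its `n_frames`/`boundary_frame` are
#'   ignored here; only the appearance model matters).
#' @param seed integer seed for the frame draws.
#' @param sal_par,pc_par,glcm_par stage parameters.
#' @return list `features` (matrix, rows = frames), `labels` (0/1).
#' @export
ctvp_training_set <- function(n_per_class, cfg, seed = cfg$seed,
                              sal_par = saliency_params(),
                              pc_par = pc_params(),
                              glcm_par = glcm_params()) {
  bank <- log_gabor_bank(pc_par, c(cfg$frame_height, cfg$frame_width))
  one <- function(organ, i) {
    fr <- generate_frame(organ, cfg,
                         seed = frame_seed(seed, i + 1e6 * (organ == "intestine")))
    v <- frame_vrof(fr, sal_par)
    ctvp(fr, v$mask, pc_par, glcm_par, bank)
  }
  feats <- rbind(
    t(vapply(seq_len(n_per_class), function(i) one("stomach", i),
             numeric(36L))),
    t(vapply(seq_len(n_per_class), function(i) one("intestine", i),
             numeric(36L))))
  list(features = feats,
       labels = rep(c(0L, 1L), each = n_per_class))
}

#' Locate the pylorus in a frame sequence
#'
#' End-to-end run of the Monitor-Judge model: the Monitor walks window
#' pairs tracking valid-region color dissimilarity; on a trigger the Judge
#' classifies the sampled frames of the three target windows with the
#' trained descriptor model and either returns the minimum-error step
#' split as the boundary or rejects the trigger (raising the Monitor's
#' threshold). Frames beyond the accepted pair are never decoded.
#'
#' @param frames a `frame_sequence`.
#' @param model a `ctvp_model` from [train_judge()].
#' @param params a `monitor_params`.
#' @param sal_par,pc_par,glcm_par stage parameters.
#' @param acceptance_fraction Judge split-cost tolerance (default 0.2).
#' @return list `boundary_frame` (or NA), `accepted`, `triggered_pair`,
#'   `n_judge_calls`, `t_final`, `trigger_log`.
#' @export
locate_pylorus <- function(frames, model, params = monitor_params(),
                           sal_par = saliency_params(),
                           pc_par = pc_params(), glcm_par = glcm_params(),
                           acceptance_fraction = 0.2) {
  first <- frames$get(0L)
  bank <- log_gabor_bank(pc_par, dim(first)[1:2])
  label_cache <- new.env(parent = emptyenv())
  judge_fn <- function(k) {
    judge_pair(frames, k, model, params, sal_par, pc_par, glcm_par,
               acceptance_fraction, bank, label_cache)
  }
  res <- run_monitor(frames, params, judge_fn, sal_par)
  list(boundary_frame = if (res$accepted) res$estimate$boundary_frame
       else NA_integer_,
       accepted = res$accepted, triggered_pair = res$triggered_pair,
       n_judge_calls = res$n_judge_calls, t_final = res$t_final,
       trigger_log = res$trigger_log)
}
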