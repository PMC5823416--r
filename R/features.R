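#' Masked hue-saturation histogram
#'
#' Converts the frame to HSI, restricts to the valid-region mask, and bins
#' hue and saturation each into `n_bins` uniform bins over \[0, 1\].
#' Frequencies are normalized by the valid pixel count, so each histogram
#' sums to 1. Intensity is deliberately ignored: capsule illumination is
#' unstable, chroma is not.
#'
#' @param frame numeric array `c(H, W, 3)` in \[0, 255\].
#' @param mask a `vrof_mask` (or logical matrix) selecting valid pixels.
#' @param n_bins bins per channel (default 16).
#' @return a `hs_histogram`: list with `hist_h`, `hist_s` (length
#'   `n_bins`, each summing to 1) and `n_valid`.
#' @export
hs_histogram <- function(frame, mask, n_bins = 16L) {
  m <- if (inherits(mask, "vrof_mask")) mask$mask else mask
  stopifnot(is.logical(m))
  n_valid <- sum(m)
  if (n_valid == 0L) stop("empty mask", call. = FALSE)
  hsi <- rgb_to_hsi(frame)
  bin <- function(v) {
    idx <- pmin(floor(v * n_bins) + 1L, n_bins)
    tabulate(idx, nbins = n_bins) / length(v)
  }
  structure(list(hist_h = bin(hsi$H[m]), hist_s = bin(hsi$S[m]),
                 n_valid = as.integer(n_valid)),
            class = "hs_histogram")
}

#' Fused color-texture frame descriptor
#'
#' The 36-value descriptor used to tell stomach from intestine frames:
#' four orientation-averaged co-occurrence statistics (contrast,
#' correlation, energy, homogeneity) of the phase-congruency
#' maximum-moment map — the intestinal villi leave a strong texture
#' imprint there — concatenated with the 16-bin masked hue and saturation
#' histograms. Texture is computed on the full-frame moment map (texture
#' needs spatial continuity); color only on the valid region.
#'
#' @param frame numeric array `c(H, W, 3)` in \[0, 255\].
#' @param mask a `vrof_mask` for the color histograms.
#' @param pc_par a `pc_params`.
#' @param glcm_par a `glcm_params`.
#' @param bank optional precomputed [log_gabor_bank()] for `dim(frame)`.
#' @return named numeric vector of length `4 + 2 * 16`.
#' @export
ctvp <- function(frame, mask, pc_par = pc_params(),
                 glcm_par = glcm_params(), bank = NULL) {
  gray <- rgb_to_gray(frame)
  pc <- phase_congruency(gray, pc_par, bank)
  m <- max_moment(pc)
  tex <- glcm_features_integrated(m, glcm_par)
  hs <- hs_histogram(frame, mask)
  out <- c(tex,
           stats::setNames(hs$hist_h, paste0("h", seq_along(hs$hist_h))),
           stats::setNames(hs$hist_s, paste0("s", seq_along(hs$hist_s))))
  out
}
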