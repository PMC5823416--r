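#' Parameters of the color-saliency detector
#'
#' `alpha` is the odd exponent applied to the signed deviation of channel a
#' from its image mean; tissue reflects more strongly in channel a than any
#' disturbance, so positive deviations mark tissue. `beta` is the fractional
#' exponent applied to the absolute deviation of channel b. `sigma1` is the
#' standard deviation of the Gaussian pre-filter; `sigma2 = 1.6 * sigma1`
#' parameterizes the optional difference-of-Gaussians variant (the classic
#' 1:1.6 band-pass ratio).
#'
#' @param alpha odd integer > 1 (default 3).
#' @param beta real in (1, alpha) (default 1.5).
#' @param sigma1 Gaussian std-dev in pixels (default 1).
#' @param sigma2 second std-dev for the DoG variant (default `1.6 * sigma1`).
#' @return a `saliency_params` list.
#' @export
saliency_params <- function(alpha = 3, beta = 1.5, sigma1 = 1,
                            sigma2 = 1.6 * sigma1) {
  if (alpha <= 1 || alpha %% 2 != 1)
    stop("alpha must be an odd integer greater than 1", call. = FALSE)
  if (beta <= 1 || beta >= alpha)
    stop("beta must satisfy 1 < beta < alpha", call. = FALSE)
  if (sigma1 <= 0 || sigma2 <= sigma1)
    stop("need 0 < sigma1 < sigma2", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, sigma1 = sigma1, sigma2 = sigma2),
            class = "saliency_params")
}

# 1-D Gaussian kernel, unit sum, radius 3*sigma
gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable 2-D convolution with reflective boundary handling. Reflection
# keeps the output mean equal to the input mean for a unit-sum kernel.
conv2_sep <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  pad_idx <- function(n) {
    # half-sample symmetric reflection: n=5,r=2 -> 2 1 |1..5| 5 4
    # (this padding redistributes boundary mass symmetrically, so a
    # unit-sum kernel preserves the image mean exactly)
    c(rev(seq_len(r)), seq_len(n), n + 1L - seq_len(r))
  }
  # rows
  mp <- m[pad_idx(nrow(m)), , drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k))
    out <- out + k[i] * mp[i:(i + nrow(m) - 1L), , drop = FALSE]
  # cols
  mp <- out[, pad_idx(ncol(m)), drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k))
    out <- out + k[i] * mp[, i:(i + ncol(m) - 1L), drop = FALSE]
  out
}

#' Pre-filter the chroma channels of a Lab image
#'
#' Smooths the a and b channels before the saliency test. The default is a
#' single Gaussian at `sigma1`, following the frequency-tuned saliency
#' lineage; `method = "dog"` instead applies the 1:1.6
#' difference-of-Gaussians band-pass. Lightness L is passed through
#' untouched since the saliency rule ignores it.
#'
#' @param lab a `lab_image`.
#' @param params a `saliency_params`.
#' @param method `"gaussian"` (default) or `"dog"`.
#' @return a `lab_image` with filtered `a`, `b`.
#' @export
csd_blur <- function(lab, params = saliency_params(),
                     method = c("gaussian", "dog")) {
  method <- match.arg(method)
  stopifnot(inherits(lab, "lab_image"))
  filt <- if (method == "gaussian") {
    k <- gaussian_kernel_1d(params$sigma1)
    function(m) conv2_sep(m, k)
  } else {
    k1 <- gaussian_kernel_1d(params$sigma1)
    k2 <- gaussian_kernel_1d(params$sigma2)
    n <- max(length(k1), length(k2))
    pad <- function(k) {
      d <- (n - length(k)) %/% 2L
      c(rep(0, d), k, rep(0, d))
    }
    function(m) conv2_sep(m, pad(k1)) - conv2_sep(m, pad(k2))
  }
  out <- list(L = lab$L, a = filt(lab$a), b = filt(lab$b))
  class(out) <- "lab_image"
  out
}

#' Color-saliency map of a Lab image
#'
#' Per pixel, `S = (a - a_u)^alpha + |b - b_u|^beta` where `a_u`, `b_u` are
#' the image-wide arithmetic means of the (pre-filtered) chroma channels.
#' The odd signed power on channel a makes pixels redder than the frame
#' average score positive — digestive-tract tissue — while disturbances
#' (overexposure, shadows, bubbles, fluid) fall at or below the chroma mean
#' and score negative. The absolute value on the b deviation keeps the
#' fractional power real.
#'
#' @param lab a `lab_image`, typically the output of [csd_blur()].
#' @param params a `saliency_params`.
#' @return a `saliency_map`: list with matrix `S` and scalars `mean_a`,
#'   `mean_b`.
#' @export
saliency <- function(lab, params = saliency_params()) {
  stopifnot(inherits(lab, "lab_image"))
  a_u <- mean(lab$a)
  b_u <- mean(lab$b)
  da <- lab$a - a_u
  s <- sign(da) * abs(da)^params$alpha + abs(lab$b - b_u)^params$beta
  structure(list(S = s, mean_a = a_u, mean_b = b_u), class = "saliency_map")
}

#' Valid region of the frame (VROF) from a saliency map
#'
#' The valid region is the positive set of the saliency map. When fewer
#' than `floor_frac` of the pixels survive (e.g. a featureless frame where
#' S is identically zero), downstream statistics that divide by the valid
#' pixel count would be meaningless, so the mask falls back to the full
#' frame and is flagged.
#'
#' @param sal a `saliency_map`.
#' @param floor_frac minimum valid fraction before the full-frame fallback
#'   (default 0.01).
#' @return a `vrof_mask`: list with logical matrix `mask`, integer
#'   `n_valid`, logical `fallback`.
#' @export
vrof <- function(sal, floor_frac = 0.01) {
  stopifnot(inherits(sal, "saliency_map"))
  mask <- sal$S > 0
  n <- sum(mask)
  fallback <- n < floor_frac * length(mask)
  if (fallback) {
    warning("valid region below floor; falling back to full-frame mask",
            call. = FALSE)
    mask[] <- TRUE
    n <- length(mask)
  }
  structure(list(mask = mask, n_valid = as.integer(n), fallback = fallback),
            class = "vrof_mask")
}

#' Frame to VROF mask in one call
#'
#' Convenience wrapper: Lab conversion, chroma pre-filter, saliency,
#' thresholding.
#'
#' @inheritParams rgb_to_lab
#' @inheritParams csd_blur
#' @inheritParams vrof
#' @return list with elements `lab` (pre-filtered `lab_image`), `sal`
#'   (`saliency_map`) and `mask` (`vrof_mask`).
#' @export
frame_vrof <- function(frame, params = saliency_params(), floor_frac = 0.01) {
  lab <- csd_blur(rgb_to_lab(frame), params)
  sal <- saliency(lab, params)
  list(lab = lab, sal = sal, mask = vrof(sal, floor_frac))
}
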