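#' Gray-level co-occurrence parameters
#'
#' @param distance inter-pixel distance in pixels (default 1).
#' @param angles orientations in degrees, subset of image-convention
#'   directions (default `c(0, 45, 90, 135)`).
#' @param levels number of quantized gray levels (default 16).
#' @param symmetric accumulate each pair in both directions (default TRUE).
#' @return a `glcm_params` list.
#' @export
glcm_params <- function(distance = 1L, angles = c(0, 45, 90, 135),
                        levels = 16L, symmetric = TRUE) {
  stopifnot(distance >= 1, levels >= 2, length(angles) >= 1,
            all(angles %in% c(0, 45, 90, 135)))
  structure(list(distance = as.integer(distance), angles = angles,
                 levels = as.integer(levels), symmetric = isTRUE(symmetric)),
            class = "glcm_params")
}

#' Quantize a real-valued map to discrete gray levels
#'
#' Uniform binning of the observed min-max range into `levels` bins; a
#' constant map collapses to level 1.
#'
#' @param map numeric matrix.
#' @param levels number of levels.
#' @return integer matrix with values in `1:levels`.
#' @export
quantize_map <- function(map, levels = 16L) {
  rng <- range(map)
  if (rng[1L] == rng[2L]) return(matrix(1L, nrow(map), ncol(map)))
  q <- floor((map - rng[1L]) / (rng[2L] - rng[1L]) * levels) + 1L
  q[q > levels] <- as.integer(levels)
  matrix(as.integer(q), nrow(map), ncol(map))
}

# row/col offset for one co-occurrence direction, image convention:
# rows grow downward, 45 degrees points up-right
glcm_offset <- function(angle, d) {
  switch(as.character(angle),
         "0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L), "135" = c(-d, -d),
         stop("unsupported angle", call. = FALSE))
}

#' Gray-level co-occurrence matrix at one displacement
#'
#' Counts ordered gray-level pairs `(i, j)` separated by `distance` pixels
#' along `angle`, optionally accumulated symmetrically, normalized to total
#' mass 1.
#'
#' @param qmap integer matrix of levels in `1:levels` (see [quantize_map()]).
#' @param angle one of 0, 45, 90, 135 degrees.
#' @param params a `glcm_params`.
#' @return `levels x levels` matrix summing to 1.
#' @export
glcm <- function(qmap, angle, params = glcm_params()) {
  d <- params$distance
  g <- params$levels
  off <- glcm_offset(angle, d)
  nr <- nrow(qmap); nc <- ncol(qmap)
  rs <- max(1L, 1L - off[1L]); re <- min(nr, nr - off[1L])
  cs <- max(1L, 1L - off[2L]); ce <- min(nc, nc - off[2L])
  if (rs > re || cs > ce)
    stop("map smaller than the displacement", call. = FALSE)
  r1 <- rs:re
  c1 <- cs:ce
  a <- qmap[r1, c1, drop = FALSE]
  b <- qmap[r1 + off[1L], c1 + off[2L], drop = FALSE]
  counts <- matrix(tabulate(a + g * (b - 1L), nbins = g * g), g, g)
  if (params$symmetric) counts <- counts + t(counts)
  tot <- sum(counts)
  if (tot == 0) stop("no valid pixel pairs", call. = FALSE)
  counts / tot
}

#' Haralick-style features of one co-occurrence matrix
#'
#' Contrast, correlation, energy and homogeneity of a normalized
#' co-occurrence matrix. Homogeneity defaults to the standard inverse
#' difference form `sum C / (1 + |i - j|)`; `variant = "moment"` instead
#' weights each term by the mean-centered level product, a non-standard
#' definition kept for comparison (it is not bounded by \[0, 1\]). A
#' degenerate matrix with zero marginal variance gets correlation 0 and a
#' `"degenerate_correlation"` attribute.
#'
#' @param C normalized co-occurrence matrix (sums to 1).
#' @param variant homogeneity form, `"standard"` or `"moment"`.
#' @return named numeric vector `contrast`, `correlation`, `energy`,
#'   `homogeneity`.
#' @export
glcm_features <- function(C, variant = c("standard", "moment")) {
  variant <- match.arg(variant)
  stopifnot(is.matrix(C), nrow(C) == ncol(C),
            abs(sum(C) - 1) < 1e-8)
  g <- nrow(C)
  i <- matrix(seq_len(g), g, g)
  j <- t(i)
  px <- rowSums(C)
  py <- colSums(C)
  ux <- sum(seq_len(g) * px)
  uy <- sum(seq_len(g) * py)
  sx <- sqrt(sum((seq_len(g) - ux)^2 * px))
  sy <- sqrt(sum((seq_len(g) - uy)^2 * py))
  contrast <- sum(C * (i - j)^2)
  degenerate <- sx == 0 || sy == 0
  correlation <- if (degenerate) 0 else
    sum((i - ux) * (j - uy) * C) / (sx * sy)
  energy <- sum(C^2)
  homogeneity <- if (variant == "standard") sum(C / (1 + abs(i - j))) else
    sum((i - ux) * (j - uy) * C / (1 + abs(i - j)))
  out <- c(contrast = contrast, correlation = correlation,
           energy = energy, homogeneity = homogeneity)
  if (degenerate) attr(out, "degenerate_correlation") <- TRUE
  out
}

#' Orientation-integrated co-occurrence features of a real-valued map
#'
#' Quantizes the map, computes the four co-occurrence statistics at each
#' orientation in `params$angles`, and averages them — the standard
#' rotation-robust treatment of co-occurrence texture.
#'
#' @param map numeric matrix (e.g. a phase-congruency maximum-moment map).
#' @param params a `glcm_params`.
#' @inheritParams glcm_features
#' @return named numeric vector as in [glcm_features()].
#' @export
glcm_features_integrated <- function(map, params = glcm_params(),
                                     variant = "standard") {
  qmap <- quantize_map(map, params$levels)
  feats <- vapply(params$angles,
                  function(th) glcm_features(glcm(qmap, th, params), variant),
                  numeric(4L))
  rowMeans(feats)
}
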