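#' Convert an RGB frame to CIE Lab
#'
#' Frames are numeric arrays of dimension height x width x 3 with channel
#' values in \[0, 255\]. The conversion assumes sRGB primaries under the D65
#' white point and returns L in \[0, 100\] with signed a and b channels, the
#' dominant convention for perceptual color work on endoscopic imagery.
#'
#' @param frame numeric array `c(H, W, 3)`, values in \[0, 255\].
#' @return A `lab_image`: list with numeric matrices `L`, `a`, `b`.
#' @export
rgb_to_lab <- function(frame) {
  check_frame(frame)
  d <- dim(frame)
  m <- matrix(as.numeric(frame), ncol = 3L) / 255
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  out <- list(
    L = matrix(lab[, 1L], d[1L], d[2L]),
    a = matrix(lab[, 2L], d[1L], d[2L]),
    b = matrix(lab[, 3L], d[1L], d[2L])
  )
  class(out) <- "lab_image"
  out
}

#' Convert an RGB frame to HSI
#'
#' Classical HSI decomposition: intensity is the channel mean, saturation
#' `1 - 3 min(R,G,B)/(R+G+B)`, and hue from the arccos form, returned
#' normalized to \[0, 1\] (hue divided by 2*pi). Black pixels get S = 0 and
#' H = 0 by convention.
#'
#' @param frame numeric array `c(H, W, 3)`, values in \[0, 255\].
#' @return list with matrices `H`, `S`, `I`, each in \[0, 1\].
#' @export
rgb_to_hsi <- function(frame) {
  check_frame(frame)
  r <- frame[, , 1L] / 255
  g <- frame[, , 2L] / 255
  b <- frame[, , 3L] / 255
  s <- r + g + b
  mn <- pmin(r, g, b)
  sat <- ifelse(s > 0, 1 - 3 * mn / s, 0)
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  ct <- ifelse(den > 0, pmin(pmax(num / den, -1), 1), 1)
  h <- acos(ct)
  h[b > g] <- 2 * pi - h[b > g]
  h[den == 0] <- 0
  list(H = h / (2 * pi), S = sat, I = s / 3)
}

#' Convert an RGB frame to gray scale
#'
#' Rec. 601 luma weights; output kept on the \[0, 255\] scale.
#'
#' @param frame numeric array `c(H, W, 3)`.
#' @return numeric matrix.
#' @export
rgb_to_gray <- function(frame) {
  check_frame(frame)
  0.299 * frame[, , 1L] + 0.587 * frame[, , 2L] + 0.114 * frame[, , 3L]
}

check_frame <- function(frame) {
  if (!is.numeric(frame) || length(dim(frame)) != 3L || dim(frame)[3L] != 3L)
    stop("frame must be a numeric H x W x 3 array", call. = FALSE)
  invisible(frame)
}
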