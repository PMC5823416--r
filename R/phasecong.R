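#' Phase-congruency filter-bank parameters
#'
#' Geometry and noise settings for the oriented 2-D log-Gabor bank used to
#' measure phase congruency. Defaults follow common practice for this
#' detector: 4 scales, 6 orientations, smallest wavelength 3 px, scale
#' multiplier 2.1, bandwidth parameter `sigma_onf = 0.55` (about two
#' octaves), and a noise threshold `k = 2` standard deviations above the
#' Rayleigh-estimated noise energy.
#'
#' @param n_scales number of filter scales.
#' @param n_orientations number of orientations (>= 2).
#' @param min_wavelength wavelength of the smallest-scale filter (pixels).
#' @param mult wavelength multiplier between scales.
#' @param sigma_onf log-Gabor bandwidth parameter (ratio of the Gaussian
#'   std-dev to the center frequency, on the log axis).
#' @param noise_comp_k std-devs above mean noise energy for the threshold.
#' @param cut_off,g parameters of the sigmoidal frequency-spread weight.
#' @param epsilon small positive constant guarding divisions.
#' @return a `pc_params` list.
#' @export
pc_params <- function(n_scales = 4L, n_orientations = 6L,
                      min_wavelength = 3, mult = 2.1, sigma_onf = 0.55,
                      noise_comp_k = 2, cut_off = 0.5, g = 10,
                      epsilon = 1e-8) {
  stopifnot(n_scales >= 1, n_orientations >= 2, min_wavelength >= 2,
            mult > 1, sigma_onf > 0, epsilon > 0)
  structure(list(n_scales = as.integer(n_scales),
                 n_orientations = as.integer(n_orientations),
                 min_wavelength = min_wavelength, mult = mult,
                 sigma_onf = sigma_onf, noise_comp_k = noise_comp_k,
                 cut_off = cut_off, g = g, epsilon = epsilon),
            class = "pc_params")
}

# normalized frequency radius and angle grids with DC at [1,1]
filter_grid <- function(nr, nc) {
  fy <- if (nr %% 2 == 0) c(0:(nr / 2 - 1), -(nr / 2):-1) / nr else
    c(0:((nr - 1) / 2), -((nr - 1) / 2):-1) / nr
  fx <- if (nc %% 2 == 0) c(0:(nc / 2 - 1), -(nc / 2):-1) / nc else
    c(0:((nc - 1) / 2), -((nc - 1) / 2):-1) / nc
  x <- matrix(fx, nr, nc, byrow = TRUE)
  y <- matrix(fy, nr, nc)
  radius <- sqrt(x^2 + y^2)
  radius[1L, 1L] <- 1 # avoid log(0); DC gain zeroed explicitly later
  list(radius = radius, theta = atan2(-y, x))
}

#' Oriented 2-D log-Gabor filter bank
#'
#' Frequency-domain bank of `n_scales * n_orientations` filters for an
#' image of the given size: a radial log-Gabor profile (zero DC gain by
#' construction) times an angular Gaussian spread, with a Butterworth
#' low-pass to suppress corner-frequency artifacts. Orientations are
#' spaced `180 / n_orientations` degrees apart.
#'
#' @param params a `pc_params`.
#' @param shape integer vector `c(rows, cols)`.
#' @return list with `filters[[o]][[s]]` real matrices, `angles` in
#'   radians, and the `shape`.
#' @export
log_gabor_bank <- function(params = pc_params(), shape) {
  nr <- as.integer(shape[1L]); nc <- as.integer(shape[2L])
  if (nr < 8L || nc < 8L) stop("image too small for the filter bank",
                               call. = FALSE)
  gr <- filter_grid(nr, nc)
  lp <- 1 / (1 + (gr$radius / 0.45)^30) # Butterworth low-pass, order 15
  radial <- vector("list", params$n_scales)
  for (s in seq_len(params$n_scales)) {
    wl <- params$min_wavelength * params$mult^(s - 1)
    f0 <- 1 / wl
    rf <- exp(-(log(gr$radius / f0))^2 / (2 * log(params$sigma_onf)^2)) * lp
    rf[1L, 1L] <- 0
    radial[[s]] <- rf
  }
  angles <- (seq_len(params$n_orientations) - 1) * pi / params$n_orientations
  theta_sigma <- pi / params$n_orientations / 1.3
  filters <- lapply(angles, function(ang) {
    ds <- sin(gr$theta) * cos(ang) - cos(gr$theta) * sin(ang)
    dc <- cos(gr$theta) * cos(ang) + sin(gr$theta) * sin(ang)
    dtheta <- abs(atan2(ds, dc))
    spread <- exp(-dtheta^2 / (2 * theta_sigma^2))
    lapply(radial, function(rf) rf * spread)
  })
  list(filters = filters, angles = angles, shape = c(nr, nc))
}

#' Per-orientation phase congruency of a gray-scale image
#'
#' Measures, at each pixel and orientation, how much the local log-Gabor
#' responses agree in phase: the weighted, noise-compensated local energy
#' divided by the total response amplitude over scales. Phase congruency
#' is contrast invariant — rescaling image intensity leaves it essentially
#' unchanged — and zero on structureless (constant) images. The noise
#' energy threshold per orientation is estimated from the median
#' smallest-scale amplitude under a Rayleigh model and subtracted with the
#' positive-part operator; a sigmoidal weight penalizes pixels whose energy
#' is concentrated in few scales.
#'
#' @param gray numeric matrix (any intensity scale).
#' @param params a `pc_params`.
#' @param bank optional precomputed [log_gabor_bank()] matching `dim(gray)`.
#' @return a `pc_result`: list with `pc_maps` (per-orientation matrices in
#'   \[0, 1\]), `angles`, and `params`.
#' @export
phase_congruency <- function(gray, params = pc_params(), bank = NULL) {
  stopifnot(is.matrix(gray))
  if (is.null(bank)) bank <- log_gabor_bank(params, dim(gray))
  stopifnot(all(bank$shape == dim(gray)))
  eps <- params$epsilon
  npix <- length(gray)
  imfft <- stats::fft(gray)
  pc_maps <- vector("list", params$n_orientations)
  for (o in seq_len(params$n_orientations)) {
    sumE <- sumO <- sumAn <- matrix(0, nrow(gray), ncol(gray))
    maxAn <- matrix(0, nrow(gray), ncol(gray))
    eo <- vector("list", params$n_scales)
    tau <- 0
    for (s in seq_len(params$n_scales)) {
      resp <- stats::fft(imfft * bank$filters[[o]][[s]],
                         inverse = TRUE) / npix
      e <- Re(resp); od <- Im(resp)
      an <- sqrt(e^2 + od^2)
      eo[[s]] <- list(e = e, o = od)
      sumE <- sumE + e
      sumO <- sumO + od
      sumAn <- sumAn + an
      maxAn <- pmax(maxAn, an)
      if (s == 1L) tau <- stats::median(an) / sqrt(log(4))
    }
    xEnergy <- sqrt(sumE^2 + sumO^2) + eps
    meanE <- sumE / xEnergy
    meanO <- sumO / xEnergy
    energy <- matrix(0, nrow(gray), ncol(gray))
    for (s in seq_len(params$n_scales)) {
      e <- eo[[s]]$e; od <- eo[[s]]$o
      energy <- energy + e * meanE + od * meanO - abs(e * meanO - od * meanE)
    }
    # Rayleigh noise model: total noise amplitude over a geometric scale
    # series, mean + k sigma threshold
    totalTau <- tau * (1 - (1 / params$mult)^params$n_scales) /
      (1 - 1 / params$mult)
    noiseMean <- totalTau * sqrt(pi / 2)
    noiseSigma <- totalTau * sqrt((4 - pi) / 2)
    T_o <- noiseMean + params$noise_comp_k * noiseSigma
    width <- (sumAn / (maxAn + eps)) / params$n_scales
    weight <- 1 / (1 + exp(params$g * (params$cut_off - width)))
    pc <- weight * pmax(energy - T_o, 0) / (sumAn + eps)
    pc_maps[[o]] <- pmin(pmax(pc, 0), 1)
  }
  structure(list(pc_maps = pc_maps, angles = bank$angles, params = params),
            class = "pc_result")
}

#' Maximum moment of the phase-congruency covariance
#'
#' Treats the per-orientation phase-congruency values at each pixel as a
#' set of oriented vectors and returns the larger principal value of their
#' covariance: with `a = sum (PC_o cos o)^2`, `b = 2 sum PC_o^2 sin o cos o`
#' and `c = sum (PC_o sin o)^2`, the map is
#' `M = (a + c + sqrt(b^2 + (a - c)^2)) / 2`. M highlights edge and
#' texture strength regardless of orientation; it is non-negative and zero
#' wherever every orientation's phase congruency is zero.
#'
#' @param pc a `pc_result`.
#' @return numeric matrix `M`.
#' @export
max_moment <- function(pc) {
  stopifnot(inherits(pc, "pc_result"))
  dims <- dim(pc$pc_maps[[1L]])
  a <- b <- cc <- matrix(0, dims[1L], dims[2L])
  for (o in seq_along(pc$pc_maps)) {
    p <- pc$pc_maps[[o]]
    ang <- pc$angles[o]
    a <- a + (p * cos(ang))^2
    b <- b + p^2 * sin(ang) * cos(ang)
    cc <- cc + (p * sin(ang))^2
  }
  b <- 2 * b
  (a + cc + sqrt(b^2 + (a - cc)^2)) / 2
}
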