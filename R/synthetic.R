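#' Configuration of the synthetic endoscopy sequence generator
#'
#' Describes a capsule-endoscopy-like sequence: reddish stomach tissue up to
#' a known boundary frame, then yellower small-intestine tissue carrying a
#' quasi-periodic villi texture, with optional injected disturbances
#' (overexposed blobs, shadows, bubble rings, low-chroma fluid patches).
#' Frame indices are 0-based; the boundary frame is the first intestine
#' frame. Identical config and seed give a bit-identical sequence.
#'
#' Default frame size is 128 x 120, a half-scale version of the 256 x 240
#' capsule sensor that keeps whole-sequence experiments fast while leaving
#' room for the disturbance primitives. Default colors put the stomach at a
#' clearly higher Lab channel-a chroma and the intestine at a higher
#' channel-b (yellow) chroma, mimicking the color shift at the pylorus.
#'
#' @param n_frames total frames (> 0).
#' @param boundary_frame 0-based index of the first intestine frame, in
#'   `[0, n_frames)`.
#' @param frame_width,frame_height frame size in pixels.
#' @param stomach_color,intestine_color mean RGB triples in \[0, 255\].
#' @param color_noise_sd per-pixel RGB Gaussian noise std-dev.
#' @param villi_amplitude contrast of the intestine villi texture
#'   (0 disables it).
#' @param disturbance_rate per-frame probability of injecting each
#'   disturbance kind independently.
#' @param seed integer seed controlling every random draw.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_frames,
                             boundary_frame,
                             frame_width = 128L,
                             frame_height = 120L,
                             stomach_color = c(170, 80, 70),
                             intestine_color = c(180, 140, 90),
                             color_noise_sd = 6,
                             villi_amplitude = 30,
                             disturbance_rate = 0.1,
                             seed = 1L) {
  n_frames <- as.integer(n_frames)
  boundary_frame <- as.integer(boundary_frame)
  if (n_frames < 1L) stop("n_frames must be positive", call. = FALSE)
  if (boundary_frame < 0L || boundary_frame >= n_frames)
    stop("boundary_frame must lie in [0, n_frames)", call. = FALSE)
  stopifnot(length(stomach_color) == 3L, length(intestine_color) == 3L,
            color_noise_sd >= 0, villi_amplitude >= 0,
            disturbance_rate >= 0, disturbance_rate <= 1)
  structure(list(
    n_frames = n_frames, boundary_frame = boundary_frame,
    frame_width = as.integer(frame_width),
    frame_height = as.integer(frame_height),
    stomach_color = as.numeric(stomach_color),
    intestine_color = as.numeric(intestine_color),
    color_noise_sd = color_noise_sd,
    villi_amplitude = villi_amplitude,
    disturbance_rate = disturbance_rate,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# evaluate expr under a local RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# deterministic per-frame seed below 2^31
frame_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + index) %% 2147483647)
}

disk_mask <- function(h, w, cy, cx, r) {
  outer(seq_len(h) - cy, seq_len(w) - cx, function(y, x) y^2 + x^2 <= r^2)
}

# thresholded band-pass noise bumps: white noise, Gaussian band-pass,
# positive part above threshold. Produces blob-like quasi-periodic texture
# whose co-occurrence contrast scales with `amp`.
villi_texture <- function(h, w, amp) {
  z <- matrix(stats::rnorm(h * w), h, w)
  bp <- conv2_sep(z, gaussian_kernel_1d(1.5)) -
    conv2_sep(z, gaussian_kernel_1d(3.5))
  bp <- bp / max(stats::sd(bp), 1e-12)
  amp * pmax(bp - 0.3, 0)
}

#' Generate one synthetic endoscopy frame
#'
#' Draws a frame from the stomach or intestine appearance model of `cfg`.
#' With zero noise, zero villi amplitude and zero disturbance rate the
#' frame is exactly uniform at the organ's configured color. Injected
#' disturbances are recorded in the `"disturbances"` attribute as a list of
#' `list(kind, mask)` entries so tests can assert exact exclusion regions.
#'
#' @param organ `"stomach"` or `"intestine"`.
#' @param cfg a `synthetic_config`.
#' @param seed integer seed for this frame (defaults to `cfg$seed`).
#' @return numeric array `c(frame_height, frame_width, 3)` in \[0, 255\]
#'   with attribute `"disturbances"`.
#' @export
generate_frame <- function(organ, cfg, seed = cfg$seed) {
  organ <- match.arg(organ, c("stomach", "intestine"))
  h <- cfg$frame_height
  w <- cfg$frame_width
  base <- if (organ == "stomach") cfg$stomach_color else cfg$intestine_color
  with_local_seed(seed, {
    frame <- array(rep(base, each = h * w), dim = c(h, w, 3L))
    if (cfg$color_noise_sd > 0)
      frame <- frame + array(stats::rnorm(h * w * 3L, sd = cfg$color_noise_sd),
                             dim = c(h, w, 3L))
    if (organ == "intestine" && cfg$villi_amplitude > 0) {
      tex <- villi_texture(h, w, cfg$villi_amplitude)
      for (ch in 1:3) frame[, , ch] <- frame[, , ch] + tex
    }
    disturbances <- list()
    if (cfg$disturbance_rate > 0) {
      kinds <- c("overexposure", "shadow", "bubble", "fluid")
      for (kind in kinds) {
        if (stats::runif(1) >= cfg$disturbance_rate) next
        cy <- stats::runif(1, 0.2 * h, 0.8 * h)
        cx <- stats::runif(1, 0.2 * w, 0.8 * w)
        r <- stats::runif(1, 0.08, 0.14) * min(h, w)
        mask <- switch(kind,
          overexposure = disk_mask(h, w, cy, cx, r),
          shadow = disk_mask(h, w, cy, cx, r),
          bubble = disk_mask(h, w, cy, cx, r) &
            !disk_mask(h, w, cy, cx, 0.6 * r),
          fluid = disk_mask(h, w, cy, cx, 1.3 * r)
        )
        col <- switch(kind,
          overexposure = c(252, 250, 248),
          shadow = c(6, 6, 6),
          bubble = c(205, 205, 205),
          fluid = c(150, 150, 143)
        )
        for (ch in 1:3) {
          m <- frame[, , ch]
          m[mask] <- col[ch]
          frame[, , ch] <- m
        }
        disturbances[[length(disturbances) + 1L]] <-
          list(kind = kind, mask = mask)
      }
    }
    frame <- pmin(pmax(frame, 0), 255)
    attr(frame, "disturbances") <- disturbances
    frame
  })
}

#' Generate a synthetic endoscopy sequence with known ground truth
#'
#' Frames before `cfg$boundary_frame` come from the stomach model, frames
#' at and after it from the intestine model. Frames are materialized
#' lazily: the returned `frame_sequence` holds a reader closure, so long
#' sequences cost nothing until a frame is actually decoded — mirroring how
#' the locator stops reading video once the boundary is found.
#'
#' @param cfg a `synthetic_config`.
#' @return list with `frames` (a [frame_sequence()]) and `truth` (list with
#'   `boundary_frame` and 0/1 `labels`, 0 = stomach, 1 = intestine).
#' @export
generate_video <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  reader <- function(i) {
    organ <- if (i < cfg$boundary_frame) "stomach" else "intestine"
    generate_frame(organ, cfg, seed = frame_seed(cfg$seed, i))
  }
  labels <- as.integer(seq_len(cfg$n_frames) - 1L >= cfg$boundary_frame)
  list(frames = frame_sequence(reader, cfg$n_frames),
       truth = list(boundary_frame = cfg$boundary_frame, labels = labels))
}

#' Lazy frame sequence
#'
#' Wraps a reader function `get(i)` (0-based frame index) and a frame
#' count. Decode calls are counted, which lets tests verify that the
#' locator never touches frames beyond the accepted window pair.
#'
#' @param get function taking a 0-based index and returning a frame.
#' @param n_frames number of frames available.
#' @return a `frame_sequence`.
#' @export
frame_sequence <- function(get, n_frames) {
  counter <- new.env(parent = emptyenv())
  counter$n_decoded <- 0L
  counter$max_index <- -1L
  fetch <- function(i) {
    if (i < 0L || i >= n_frames) stop("frame index out of range", call. = FALSE)
    counter$n_decoded <- counter$n_decoded + 1L
    counter$max_index <- max(counter$max_index, as.integer(i))
    get(i)
  }
  structure(list(get = fetch, n_frames = as.integer(n_frames),
                 counter = counter),
            class = "frame_sequence")
}

#' @export
length.frame_sequence <- function(x) x$n_frames

#' Wrap an in-memory list of frames as a frame sequence
#'
#' @param frames list of frame arrays, ordered by 0-based index.
#' @return a `frame_sequence`.
#' @export
as_frame_sequence <- function(frames) {
  frame_sequence(function(i) frames[[i + 1L]], length(frames))
}
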