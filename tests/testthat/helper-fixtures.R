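# shared fixtures, built in code at test time

# small, fast config variants
quiet_cfg <- function(n_frames = 10L, boundary_frame = 4L,
                      color_noise_sd = 0, villi_amplitude = 0,
                      disturbance_rate = 0, ...) {
  synthetic_config(n_frames, boundary_frame,
                   color_noise_sd = color_noise_sd,
                   villi_amplitude = villi_amplitude,
                   disturbance_rate = disturbance_rate, ...)
}

# one trained Judge model shared across test files (built on first use)
.fixture_cache <- new.env(parent = emptyenv())

shared_judge_model <- function() {
  if (is.null(.fixture_cache$model)) {
    cfg <- synthetic_config(n_frames = 10L, boundary_frame = 5L, seed = 404L)
    tr <- ctvp_training_set(50L, cfg, seed = 2024L)
    .fixture_cache$model <- train_judge(tr$features, tr$labels)
  }
  .fixture_cache$model
}

# independent sRGB (D65) -> Lab conversion, coded from the CIE definitions,
# used as an oracle against the package conversion
oracle_rgb_to_lab <- function(rgb255) {
  v <- rgb255 / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  m <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- as.numeric(m %*% lin)
  wp <- c(0.95047, 1, 1.08883) # D65
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3),
                          t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(xyz[1] / wp[1]); fy <- f(xyz[2] / wp[2]); fz <- f(xyz[3] / wp[3])
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

# exhaustive pair-enumeration co-occurrence oracle
oracle_glcm <- function(qmap, angle, d, levels, symmetric = TRUE) {
  off <- switch(as.character(angle),
                "0" = c(0L, d), "45" = c(-d, d),
                "90" = c(-d, 0L), "135" = c(-d, -d))
  counts <- matrix(0, levels, levels)
  for (r in seq_len(nrow(qmap))) {
    for (cc in seq_len(ncol(qmap))) {
      r2 <- r + off[1L]; c2 <- cc + off[2L]
      if (r2 >= 1 && r2 <= nrow(qmap) && c2 >= 1 && c2 <= ncol(qmap)) {
        counts[qmap[r, cc], qmap[r2, c2]] <- counts[qmap[r, cc], qmap[r2, c2]] + 1
      }
    }
  }
  if (symmetric) counts <- counts + t(counts)
  counts / sum(counts)
}

# brute-force minimum-misclassification step split, earliest tie-break
oracle_split <- function(labels) {
  n <- length(labels)
  best_s <- NA_integer_; best_cost <- Inf
  for (s in 2:n) {
    cost <- sum(labels[seq_len(s - 1L)] == 1L) + sum(labels[s:n] == 0L)
    if (cost < best_cost) {
      best_cost <- cost
      best_s <- s
    }
  }
  list(split = best_s, cost = best_cost)
}
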