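test_that("zero-noise frames are exactly uniform at the configured color", {
  cfg <- quiet_cfg()
  fr <- generate_frame("stomach", cfg)
  expect_equal(dim(fr), c(cfg$frame_height, cfg$frame_width, 3L))
  for (ch in 1:3) expect_true(all(fr[, , ch] == cfg$stomach_color[ch]))
})

test_that("frame generation is deterministic in (organ, cfg, seed)", {
  cfg <- synthetic_config(10L, 4L, seed = 77L)
  f1 <- generate_frame("intestine", cfg, seed = 5L)
  f2 <- generate_frame("intestine", cfg, seed = 5L)
  expect_identical(f1, f2)
  f3 <- generate_frame("intestine", cfg, seed = 6L)
  expect_false(identical(f1, f3))
  expect_error(generate_frame("colon", cfg), "arg")
})

test_that("frame generation restores the caller's RNG state", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_frame("stomach", synthetic_config(5L, 2L)))
  expect_identical(.Random.seed, before)
})

test_that("villi texture raises the co-occurrence contrast of the moment map", {
  cfg_v <- quiet_cfg(villi_amplitude = 30)
  cfg_0 <- quiet_cfg(villi_amplitude = 0)
  contrast_of <- function(cfg) {
    fr <- generate_frame("intestine", cfg, seed = 5L)
    m <- max_moment(phase_congruency(rgb_to_gray(fr)))
    glcm_features_integrated(m)[["contrast"]]
  }
  expect_gt(contrast_of(cfg_v), contrast_of(cfg_0))
})

test_that("ground-truth labels form the monotone step at the boundary", {
  v <- generate_video(quiet_cfg(n_frames = 10L, boundary_frame = 4L))
  expect_equal(v$truth$labels, c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L, 1L, 1L))
  v0 <- generate_video(quiet_cfg(n_frames = 5L, boundary_frame = 0L))
  expect_equal(v0$truth$labels, rep(1L, 5L))
  expect_error(synthetic_config(10L, 10L), "boundary_frame")
  expect_error(synthetic_config(10L, -1L), "boundary_frame")
})

test_that("identical config and seed give a bit-identical sequence", {
  cfg <- synthetic_config(6L, 3L, seed = 9L)
  va <- generate_video(cfg)
  vb <- generate_video(cfg)
  for (i in 0:5) expect_identical(va$frames$get(i), vb$frames$get(i))
})

test_that("stomach frames are redder than intestine frames in channel a", {
  cfg <- synthetic_config(20L, 10L, seed = 31L)
  v <- generate_video(cfg)
  mean_a <- function(i) mean(rgb_to_lab(v$frames$get(i))$a)
  a_stomach <- mean(vapply(0:4, mean_a, numeric(1)))
  a_intestine <- mean(vapply(15:19, mean_a, numeric(1)))
  # configured stomach color carries higher red chroma
  expect_gt(a_stomach, a_intestine)
})

test_that("disturbance primitives record their masks", {
  cfg <- synthetic_config(5L, 2L, disturbance_rate = 1)
  fr <- generate_frame("stomach", cfg, seed = 11L)
  d <- attr(fr, "disturbances")
  expect_setequal(vapply(d, `[[`, "", "kind"),
                  c("overexposure", "shadow", "bubble", "fluid"))
  for (dd in d) {
    expect_true(is.logical(dd$mask))
    expect_gt(sum(dd$mask), 0L)
  }
})

test_that("lazy frame sequences count decodes and bound indices", {
  v <- generate_video(quiet_cfg(n_frames = 8L, boundary_frame = 3L))
  expect_equal(length(v$frames), 8L)
  invisible(v$frames$get(2L))
  invisible(v$frames$get(6L))
  expect_equal(v$frames$counter$n_decoded, 2L)
  expect_equal(v$frames$counter$max_index, 6L)
  expect_error(v$frames$get(8L), "out of range")
})
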