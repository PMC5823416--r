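mk_lab <- function(a, b = a, L = a) {
  structure(list(L = L, a = a, b = b), class = "lab_image")
}
mk_mask <- function(mask) {
  structure(list(mask = mask, n_valid = sum(mask), fallback = FALSE),
            class = "vrof_mask")
}

test_that("masked frame means match brute-force pixel sums", {
  m <- matrix(TRUE, 6, 6)
  expect_equal(frame_mean_color(mk_lab(matrix(5, 6, 6)), mk_mask(m), "a"), 5)

  half <- matrix(FALSE, 6, 6); half[, 1:3] <- TRUE
  a <- matrix(0, 6, 6); a[, 1:3][1:9] <- 0; a[, 1:3][10:18] <- 10
  expect_equal(frame_mean_color(mk_lab(a), mk_mask(half), "a"), 5)

  set.seed(8)
  r <- matrix(rnorm(48), 6, 8)
  expect_equal(frame_mean_color(mk_lab(r), mk_mask(matrix(TRUE, 6, 8)), "a"),
               sum(r) / 48, tolerance = 1e-12)
  expect_error(frame_mean_color(mk_lab(r), mk_mask(matrix(FALSE, 6, 8))),
               "empty")
})

test_that("window statistics average the sampled frame means", {
  # identical zero-noise frames: window stats equal the frame stats,
  # and stride-5 sampling agrees with stride-1
  cfg <- quiet_cfg(n_frames = 40L, boundary_frame = 39L)
  v <- generate_video(cfg)
  p5 <- monitor_params(window_size = 20L, sample_interval = 5L)
  p1 <- monitor_params(window_size = 20L, sample_interval = 2L)
  # constant frames have an identically-zero saliency map, so every frame
  # takes the (warned) full-frame fallback mask
  w5 <- suppressWarnings(window_stats(v$frames, 0L, p5))
  w1 <- suppressWarnings(window_stats(v$frames, 0L, p1))
  single <- {
    fv <- suppressWarnings(frame_vrof(v$frames$get(0L)))
    c(frame_mean_color(fv$lab, fv$mask, "a"),
      frame_mean_color(fv$lab, fv$mask, "b"))
  }
  expect_equal(c(w5$mean_a, w5$mean_b), single, tolerance = 1e-10)
  expect_equal(c(w1$mean_a, w1$mean_b), single, tolerance = 1e-10)
  expect_error(monitor_params(window_size = 8L, sample_interval = 5L),
               "twice")
})

test_that("pair dissimilarity is the Euclidean distance on (a, b) means", {
  w <- function(a, b) list(mean_a = a, mean_b = b)
  expect_equal(pair_dissimilarity(w(2, 3), w(2, 3)), 0)
  expect_equal(pair_dissimilarity(w(0, 0), w(3, 4)), 5)
  expect_equal(pair_dissimilarity(w(1, 9), w(4, 5)),
               pair_dissimilarity(w(4, 5), w(1, 9)))
  # metric properties on random triples
  set.seed(14)
  for (i in 1:25) {
    ws <- replicate(3, w(rnorm(1), rnorm(1)), simplify = FALSE)
    d12 <- pair_dissimilarity(ws[[1]], ws[[2]])
    d13 <- pair_dissimilarity(ws[[1]], ws[[3]])
    d23 <- pair_dissimilarity(ws[[2]], ws[[3]])
    expect_gte(d12, 0)
    expect_lte(d13, d12 + d23 + 1e-12)
  }
})

test_that("the trigger rule compares the DC/MDC ratio to an escalating bar", {
  p <- monitor_params()
  st <- monitor_init()
  # first pair: MDC initialized to DC_1, ratio 1 > 0.2
  s1 <- monitor_step(st, 2, p)
  expect_true(s1$trigger)
  expect_equal(s1$state$mdc, 2)
  # same DC at t = 3: 1 <= 0.2 + 0.3*3 = 1.1, no trigger
  st3 <- s1$state; st3$t <- 3L
  expect_false(monitor_step(st3, 2, p)$trigger)
  # zero-MDC guard: any change from perfect constancy triggers
  stz <- monitor_init()
  sz <- monitor_step(stz, 0, p)
  expect_false(sz$trigger)
  expect_true(monitor_step(sz$state, 0.5, p)$trigger)
})

test_that("MDC is the running mean of all previous dissimilarities", {
  p <- monitor_params()
  st <- monitor_init()
  for (d in c(3, 3, 3, 3)) st <- monitor_step(st, d, p)$state
  expect_equal(st$mdc, 3)
  st <- monitor_step(st, 8, p)$state
  expect_equal(st$mdc, mean(c(3, 3, 3, 3, 8)))
})

test_that("a constant stream triggers only while the bar is below one", {
  # with a judge that always rejects, t escalates 0,1,2 then the
  # threshold passes 1 and a stationary ratio can no longer fire
  p <- monitor_params()
  st <- monitor_init()
  triggers <- integer(0)
  for (k in 1:30) {
    s <- monitor_step(st, 5, p)
    st <- s$state
    if (s$trigger) {
      triggers <- c(triggers, k)
      st$t <- st$t + 1L # judged and rejected
    }
  }
  expect_equal(triggers, 1:3)
  expect_equal(st$t, 3L)
})

test_that("after escalation a 10x spike is the first new trigger", {
  p <- monitor_params()
  st <- monitor_init()
  dcs <- c(rep(2, 14), 20, rep(2, 5)) # spike at pair 15
  triggers <- integer(0)
  for (k in seq_along(dcs)) {
    s <- monitor_step(st, dcs[k], p)
    st <- s$state
    if (s$trigger) {
      triggers <- c(triggers, k)
      st$t <- st$t + 1L
    }
  }
  expect_equal(triggers[triggers > 3], 15L)
})

test_that("run_monitor rejects forever on a changeless video and stays lazy", {
  cfg <- synthetic_config(200L, 199L, color_noise_sd = 2,
                          villi_amplitude = 0, disturbance_rate = 0,
                          frame_width = 32L, frame_height = 32L, seed = 6L)
  v <- generate_video(cfg)
  p <- monitor_params(window_size = 20L, sample_interval = 5L)
  rejecter <- function(k) list(accepted = FALSE)
  res <- run_monitor(v$frames, p, rejecter)
  expect_false(res$accepted)
  expect_null(res$estimate)
  expect_equal(res$t_final, res$n_judge_calls)
  expect_equal(res$t_final, length(res$trigger_log))

  # an accepting judge stops the walk: later frames are never decoded
  v2 <- generate_video(cfg)
  accepter <- function(k) list(accepted = TRUE, boundary_frame = k * 20L)
  res2 <- run_monitor(v2$frames, p, accepter)
  expect_true(res2$accepted)
  expect_equal(res2$triggered_pair, 1L)
  expect_lt(v2$frames$counter$max_index, 2L * 20L)
})
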