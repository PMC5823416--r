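test_that("Lab conversion matches the white point and an independent oracle", {
  white <- array(255, c(2, 2, 3))
  lab <- rgb_to_lab(white)
  expect_equal(lab$L[1, 1], 100, tolerance = 1e-3)
  expect_equal(lab$a[1, 1], 0, tolerance = 0.01)
  expect_equal(lab$b[1, 1], 0, tolerance = 0.01)
  black <- array(0, c(2, 2, 3))
  lab0 <- rgb_to_lab(black)
  expect_equal(c(lab0$L[1, 1], lab0$a[1, 1], lab0$b[1, 1]), c(0, 0, 0),
               tolerance = 1e-6)
  for (rgb in list(c(255, 0, 0), c(40, 200, 120), c(170, 80, 70))) {
    fr <- array(rep(rgb, each = 1L), c(1, 1, 3))
    got <- rgb_to_lab(fr)
    want <- oracle_rgb_to_lab(rgb)
    expect_equal(c(got$L[1], got$a[1], got$b[1]), unname(want),
                 tolerance = 0.5)
  }
  expect_error(rgb_to_lab(matrix(0, 2, 2)), "array")
})

test_that("chroma pre-filter preserves constants, impulses and the mean", {
  lab <- structure(list(L = matrix(50, 16, 16), a = matrix(3, 16, 16),
                        b = matrix(-7, 16, 16)), class = "lab_image")
  out <- csd_blur(lab)
  expect_equal(out$a, lab$a, tolerance = 1e-12)
  expect_equal(out$b, lab$b, tolerance = 1e-12)

  # impulse response reproduces the separable kernel
  p <- saliency_params(sigma1 = 1)
  k <- pyloruskit:::gaussian_kernel_1d(1)
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  lab_i <- structure(list(L = imp, a = imp, b = imp), class = "lab_image")
  got <- csd_blur(lab_i, p)$a
  r <- (length(k) - 1) / 2
  expect_equal(got[(11 - r):(11 + r), (11 - r):(11 + r)], outer(k, k),
               tolerance = 1e-9)

  # reflective boundaries keep the DC level
  set.seed(1)
  a <- matrix(runif(30 * 40), 30, 40)
  lab_r <- structure(list(L = a, a = a, b = a), class = "lab_image")
  expect_equal(mean(csd_blur(lab_r, p)$a), mean(a), tolerance = 1e-6)
})

test_that("saliency follows the signed-a / absolute-b deviation rule", {
  flat <- structure(list(L = matrix(0, 8, 8), a = matrix(4, 8, 8),
                         b = matrix(-2, 8, 8)), class = "lab_image")
  expect_true(all(saliency(flat)$S == 0))

  # direct evaluation of the decided formula on an arbitrary chroma field
  set.seed(42)
  a <- matrix(rnorm(64, 10, 4), 8, 8)
  b <- matrix(rnorm(64, 20, 4), 8, 8)
  lab <- structure(list(L = matrix(0, 8, 8), a = a, b = b),
                   class = "lab_image")
  s <- saliency(lab, saliency_params(alpha = 3, beta = 1.5))
  da <- a - mean(a); db <- b - mean(b)
  expect_equal(s$S, sign(da) * abs(da)^3 + abs(db)^1.5, tolerance = 1e-10)
  expect_equal(s$mean_a, mean(a))

  # an isolated +2 / -2 deviation in channel a scores +8 / -8
  a2 <- matrix(0, 100, 100); a2[5, 5] <- 2.0002 # mean of a2 makes da exactly 2
  da2 <- a2 - mean(a2)
  expect_equal(da2[5, 5], 2, tolerance = 1e-3)
  lab2 <- structure(list(L = a2 * 0, a = a2, b = a2 * 0), class = "lab_image")
  s2 <- saliency(lab2)$S
  expect_equal(s2[5, 5], 8, tolerance = 0.01)
  lab3 <- structure(list(L = a2 * 0, a = -a2, b = a2 * 0), class = "lab_image")
  expect_equal(saliency(lab3)$S[5, 5], -8, tolerance = 0.01)

  expect_error(saliency_params(alpha = 4), "odd")
  expect_error(saliency_params(alpha = 3, beta = 3.5), "beta")
})

test_that("saliency increases monotonically with the channel-a deviation", {
  a <- matrix(seq(-10, 10, length.out = 64), 8, 8) # gradient image
  b <- matrix(1, 8, 8)
  lab <- structure(list(L = b, a = a, b = b), class = "lab_image")
  s <- saliency(lab)$S
  ord <- order(a)
  expect_true(all(diff(s[ord]) > 0))
})

test_that("the valid-region mask is the positive saliency set with a floor", {
  s <- matrix(-1, 10, 10)
  s[1:3, 1:7] <- 2 # 21 positive pixels
  sal <- structure(list(S = s, mean_a = 0, mean_b = 0),
                   class = "saliency_map")
  m <- vrof(sal)
  expect_equal(m$n_valid, 21L)
  expect_false(m$fallback)
  expect_equal(m$mask, s > 0)

  zero <- structure(list(S = matrix(0, 10, 10), mean_a = 0, mean_b = 0),
                    class = "saliency_map")
  expect_warning(mz <- vrof(zero), "falling back")
  expect_true(mz$fallback)
  expect_true(all(mz$mask))
  expect_equal(mz$n_valid, 100L)
})

test_that("valid region ignores uniform lightness shifts", {
  cfg <- synthetic_config(5L, 2L, disturbance_rate = 1)
  fr <- generate_frame("stomach", cfg, seed = 3L)
  lab <- csd_blur(rgb_to_lab(fr))
  m1 <- vrof(saliency(lab))
  lab$L <- lab$L + 25
  m2 <- vrof(saliency(lab))
  expect_identical(m1$mask, m2$mask)
})

test_that("injected disturbances are excluded from the valid region", {
  cfg <- synthetic_config(5L, 2L, disturbance_rate = 1)
  for (seed in c(3L, 11L, 29L)) {
    fr <- generate_frame("stomach", cfg, seed = seed)
    v <- frame_vrof(fr)
    expect_false(v$mask$fallback)
    for (dd in attr(fr, "disturbances")) {
      excluded <- mean(!v$mask$mask[dd$mask])
      expect_gt(excluded, 0.9)
    }
  }
})
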