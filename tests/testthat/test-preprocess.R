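# enhancement pipeline: per-stage contracts, fixed points, derived examples

test_that("extract_green returns channel 2 unchanged", {
  px <- array(0L, dim = c(48, 48, 3))
  px[, , 1] <- 10L; px[, , 2] <- 200L; px[, , 3] <- 30L
  img <- fundus_image(px)
  expect_equal(extract_green(img), matrix(200, 48, 48))
  expect_equal(extract_green(fundus_image(px * 0L)), matrix(0, 48, 48))
})

test_that("clahe respects range, fixed points and contrast on a checkerboard", {
  withr::local_seed(1)
  g <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
  out <- clahe(g, 2, c(8, 8))
  expect_true(all(out >= 0 & out <= 255))
  expect_identical(dim(out), dim(g))

  # constant image: no contrast to amplify (up to integer rounding)
  cg <- clahe(matrix(120, 64, 64), 2, c(8, 8))
  expect_lte(diff(range(cg)), 1)
  expect_lte(max(abs(cg - 120)), 1)

  # checkerboard {40, 60}: equalization can only widen the spread
  cb <- matrix(40, 64, 64)
  cb[(row(cb) + col(cb)) %% 2 == 0] <- 60
  expect_gte(diff(range(clahe(cb, 4, c(4, 4)))), diff(range(cb)))

  expect_error(clahe(g, 2, c(100, 100)), "tile grid")
})

test_that("median filter removes impulses and only emits input values", {
  expect_equal(median_denoise(matrix(7, 20, 20), 3), matrix(7, 20, 20))

  flat <- matrix(50, 21, 21)
  flat[11, 11] <- 250
  expect_equal(median_denoise(flat, 3), matrix(50, 21, 21))

  withr::local_seed(2)
  g <- matrix(sample(0:255, 30 * 30, replace = TRUE), 30, 30)
  expect_true(all(median_denoise(g, 5) %in% g))

  expect_error(median_denoise(g, 4), "odd")
})

test_that("min-max normalization follows the printed formula", {
  expect_equal(minmax_normalize(matrix(c(0, 128, 255), 1, 3)),
               matrix(c(0, 128 / 255, 1), 1, 3))
  withr::local_seed(3)
  u <- minmax_normalize(matrix(runif(100, 10, 90), 10, 10))
  expect_equal(min(u), 0)
  expect_equal(max(u), 1)
  expect_warning(z <- minmax_normalize(matrix(5, 4, 4)), "constant")
  expect_equal(z, matrix(0, 4, 4))
})

test_that("adaptive gamma brightens dark images and is anchored at mean 0.5", {
  # mean exactly 0.5 -> gamma 1 -> identity
  u <- matrix(c(0.2, 0.8), 10, 10)
  expect_equal(adaptive_gamma(u), u)

  # closed form: uniform 0.25 with bounds [0.5, 2.5] -> gamma 0.5 -> 0.5
  expect_equal(adaptive_gamma(matrix(0.25, 6, 6), c(0.5, 2.5)),
               matrix(0.5, 6, 6))

  # 0 and 1 are fixed points of the power law
  withr::local_seed(4)
  u <- matrix(runif(64, 0, 0.4), 8, 8)
  u[1] <- 0; u[2] <- 1
  out <- adaptive_gamma(u)
  expect_equal(out[1], 0)
  expect_equal(out[2], 1)
  expect_gte(mean(out), mean(u))  # dark image brightened

  # clamping at the bounds
  dark <- matrix(0.01, 5, 5)
  expect_equal(adaptive_gamma(dark, c(0.9, 1.1)), dark^0.9)
  expect_warning(adaptive_gamma(matrix(0, 48, 48) + 0), "mean 0")
})

test_that("multi-scale top-hat enhancement matches hand-computed cases", {
  cfg <- preprocess_config()

  flat <- matrix(0.4, 24, 24)
  expect_equal(multiscale_enhance(flat, cfg), flat)

  cfg0 <- preprocess_config(enhance_k = 0)
  withr::local_seed(5)
  u <- matrix(runif(24 * 24), 24, 24)
  expect_equal(multiscale_enhance(u, cfg0), u)

  # single bright pixel 0.8 on 0.2: every white top-hat is 0.6 there,
  # black top-hats 0, so the output saturates at 0.2 + 0.6... clipped to 1
  imp <- matrix(0.2, 25, 25)
  imp[13, 13] <- 0.8
  out <- multiscale_enhance(imp, cfg)
  expect_equal(out[13, 13], 1.0)

  # linearity in k before clipping: f(2k) - I = 2 (f(k) - I)
  cfg1 <- preprocess_config(enhance_k = 1)
  cfg2 <- preprocess_config(enhance_k = 2)
  d1 <- multiscale_enhance(u, cfg1, clip = FALSE) - u
  d2 <- multiscale_enhance(u, cfg2, clip = FALSE) - u
  expect_equal(d2, 2 * d1)

  bad <- preprocess_config()
  bad$scales <- c(0L, 1L, 2L, 3L)
  expect_error(multiscale_enhance(u, bad), "radii")
})

test_that("the pipeline is pure, bounded, and raises vessel contrast", {
  s <- small_samples(1, seed = 320)[[1]]
  u1 <- preprocess_pipeline(s$image)
  u2 <- preprocess_pipeline(s$image)
  expect_identical(u1, u2)
  expect_true(all(u1 >= 0 & u1 <= 1))

  # enhancement intent: vessel/background separation grows through the
  # pipeline (vessels are darker, so contrast = background - vessel)
  v <- s$label$vessels == 1 & s$fov == 1
  b <- s$label$vessels == 0 & s$fov == 1
  g <- extract_green(s$image) / 255
  expect_gt(mean(u1[b]) - mean(u1[v]), mean(g[b]) - mean(g[v]))

  # stage errors carry the stage name
  cfg <- preprocess_config()
  cfg$median_kernel <- 4L
  expect_error(preprocess_pipeline(s$image, cfg), "stage 'median'")
})
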