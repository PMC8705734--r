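# random patch amplification: counts, determinism, conservation, uniformity

make_pair <- function(H, W, seed) {
  withr::with_seed(seed, {
    list(u = matrix(runif(H * W), H, W),
         lab = matrix(rbinom(H * W, 1, 0.2), H, W))
  })
}

test_that("single-center case: the patch is the whole image", {
  p <- make_pair(48, 48, 21)
  ps <- sample_patches(list(p$u), list(p$lab), n_total = 1, seed = 5)
  arr <- patch_arrays(ps)
  expect_equal(arr$x[, , 1], p$u)
  expect_equal(arr$y[, , 1], p$lab, ignore_attr = TRUE)
})

test_that("allocation, preconditions and seeded determinism", {
  p1 <- make_pair(64, 80, 22)
  p2 <- make_pair(64, 80, 23)
  imgs <- list(a = p1$u, b = p2$u)
  labs <- list(p1$lab, p2$lab)

  expect_error(sample_patches(imgs, labs, n_total = 5), "divisible")
  expect_error(sample_patches(imgs, labs, n_total = 2, patch_size = 100),
               "exceeds")

  ps <- sample_patches(imgs, labs, n_total = 40, seed = 7)
  expect_equal(n_patches(ps), 40)
  expect_equal(unname(table(ps$src)), c(20L, 20L), ignore_attr = TRUE)

  ps2 <- sample_patches(imgs, labs, n_total = 40, seed = 7)
  expect_identical(ps$corners, ps2$corners)
  ps3 <- sample_patches(imgs, labs, n_total = 40, seed = 8)
  expect_false(identical(ps$corners, ps3$corners))
})

test_that("conservation: label patches are bit-exact crops at image coords", {
  p <- make_pair(70, 60, 24)
  ps <- sample_patches(list(p$u), list(p$lab), n_total = 25, patch_size = 32,
                       seed = 9)
  arr <- patch_arrays(ps, 1:25)
  for (i in c(1, 7, 25)) {
    r <- ps$corners[i, 1]; c <- ps$corners[i, 2]
    expect_equal(arr$x[, , i], p$u[r:(r + 31), c:(c + 31)])
    expect_equal(arr$y[, , i], p$lab[r:(r + 31), c:(c + 31)],
                 ignore_attr = TRUE)
  }
  # patches always lie fully inside the image
  expect_true(all(ps$corners[, 1] >= 1 & ps$corners[, 1] <= 70 - 32 + 1))
  expect_true(all(ps$corners[, 2] >= 1 & ps$corners[, 2] <= 60 - 32 + 1))
})

test_that("centers are uniform over admissible positions (chi-square)", {
  # 20x20 image, patch 16 -> 5 x 5 admissible corners
  p <- make_pair(20, 20, 25)
  ps <- sample_patches(list(p$u), list(p$lab), n_total = 5000,
                       patch_size = 16, seed = 10)
  counts <- table(factor(ps$corners[, 1], levels = 1:5),
                  factor(ps$corners[, 2], levels = 1:5))
  stat <- sum((counts - 200)^2 / 200)
  expect_lt(stat, qchisq(1 - 1e-4, df = 24))
})

test_that("train/validation split is a seeded disjoint partition", {
  p <- make_pair(64, 64, 26)
  ps <- sample_patches(list(p$u), list(p$lab), n_total = 100, seed = 11)
  sp <- split_train_val(ps, 0.1, seed = 12)
  expect_equal(n_patches(sp$train), 90)
  expect_equal(n_patches(sp$val), 10)

  # the two parts together are exactly the original multiset of patches
  # (disjointness of the index partition is structural in subset_patchset)
  key <- function(s) paste(s$corners[, 1], s$corners[, 2])
  expect_identical(sort(c(key(sp$train), key(sp$val))), sort(key(ps)))

  sp2 <- split_train_val(ps, 0.1, seed = 12)
  expect_identical(sp$train$corners, sp2$train$corners)

  expect_error(split_train_val(ps, 1.2), "val_fraction")
  expect_error(split_train_val(ps, 0), "val_fraction")
})
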