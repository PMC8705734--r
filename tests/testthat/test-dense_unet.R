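# dense-block U-Net: channel algebra, construction, gradients, checkpoints

test_that("dense block plan follows the concatenation algebra", {
  pl <- dense_block_plan(16, 12, 4)
  expect_equal(pl$in_channels, c(16, 28, 40, 52))
  expect_equal(pl$out_channels, rep(12, 4))
  expect_equal(attr(pl, "block_out"), 64)

  pl1 <- dense_block_plan(10, 3, 1)
  expect_equal(pl1$in_channels, 10)
  expect_equal(attr(pl1, "block_out"), 13)

  expect_error(dense_block_plan(16, 0, 4), ">= 1")
  expect_error(network_spec(growth_rate = 0), "positive")
})

test_that("network_spec validates the divisibility constraint", {
  expect_error(network_spec(input_size = 50, n_blocks_down = 2),
               "not divisible")
  s <- network_spec(input_size = 48, n_blocks_down = 4)
  expect_s3_class(s, "network_spec")
})

test_that("layer plan and built parameters agree, module by module", {
  withr::local_seed(31)
  for (i in 1:5) {
    spec <- network_spec(growth_rate = sample(1:6, 1),
                         layers_per_block = sample(1:3, 1),
                         n_blocks_down = sample(1:2, 1),
                         initial_channels = sample(1:8, 1),
                         input_size = 16)
    plan <- layer_plan(spec)
    net <- build_network(spec, seed = i)
    for (r in seq_len(nrow(plan))) {
      W <- net$params[[plan$stage[r]]]$W
      expect_identical(dim(W)[3], plan$in_channels[r])
      expect_identical(dim(W)[4], plan$out_channels[r])
    }
    # dense rows match the block plan oracle
    for (b in seq_len(spec$n_blocks_down)) {
      rows <- plan[grepl(sprintf("^down%d_l", b), plan$stage), ]
      k0 <- rows$in_channels[1]
      ref <- dense_block_plan(k0, spec$growth_rate, spec$layers_per_block)
      expect_equal(rows$in_channels, ref$in_channels)
    }
  }
})

test_that("forward pass maps 48x48 inputs to probabilities and any /4 size", {
  spec <- tiny_spec()
  net <- build_network(spec, seed = 2)
  withr::local_seed(32)
  p <- predict_patches(net, array(runif(48 * 48 * 2), dim = c(48, 48, 2)))
  expect_identical(dim(p), c(48L, 48L, 2L))
  expect_true(all(p > 0 & p < 1))

  # fully convolutional: other divisible sizes are accepted
  p2 <- predict_patches(net, matrix(runif(64 * 96), 64, 96))
  expect_identical(dim(p2), c(64L, 96L, 1L))
  expect_error(predict_patches(net, matrix(runif(50 * 48), 50, 48)),
               "divisible")
})

test_that("doubling the growth rate strictly increases the parameter count", {
  n1 <- count_parameters(build_network(network_spec(growth_rate = 6,
    layers_per_block = 2, n_blocks_down = 2, initial_channels = 8)))
  n2 <- count_parameters(build_network(network_spec(growth_rate = 12,
    layers_per_block = 2, n_blocks_down = 2, initial_channels = 8)))
  expect_gt(n2, n1)
})

test_that("parameter count matches the hand-enumerated toy network", {
  # toy spec k0 = k = L = 1, one down block:
  #   stem 3x3 conv 1->1:            9 + 1 = 10
  #   down1_l1 BN(1) + 3x3 1->1:     2 + 10 = 12
  #   td1 BN(2) + 1x1 2->1:          4 + 3  = 7
  #   bott_l1 BN(1) + 3x3 1->1:      2 + 10 = 12
  #   tu1 2x2 convT 2->1:            8 + 1  = 9
  #   up1_l1 BN(3) + 3x3 3->1:       6 + 28 = 34
  #   head 1x1 4->1:                 4 + 1  = 5
  net <- build_network(toy_spec(), seed = 1)
  expect_identical(count_parameters(net), 89L)
  expect_identical(count_parameters(build_network(toy_spec(), seed = 9)), 89L)
})

test_that("builds are deterministic in the seed", {
  a <- build_network(tiny_spec(), seed = 5)
  b <- build_network(tiny_spec(), seed = 5)
  expect_identical(a$params, b$params)
  c <- build_network(tiny_spec(), seed = 6)
  expect_false(identical(a$params, c$params))
})

test_that("dense connectivity: ablating an inner layer reaches all later layers", {
  spec <- network_spec(growth_rate = 3, layers_per_block = 3,
                       n_blocks_down = 1, initial_channels = 4,
                       input_size = 16)
  net <- build_network(spec, seed = 3)
  withr::local_seed(33)
  x <- array(runif(16 * 16 * 1 * 1), dim = c(16, 16, 1, 1))
  fw0 <- retseg:::unet_forward(net, x, training = FALSE, keep_caches = TRUE)

  # zero layer 1's conv output in the first down block
  net$params$down1_l1$W[] <- 0
  net$params$down1_l1$b[] <- 0
  fw1 <- retseg:::unet_forward(net, x, training = FALSE, keep_caches = TRUE)

  idx <- function(nm) which(names(net$modules) == nm)
  for (l in 2:3) {
    nm <- sprintf("down1_l%d", l)
    expect_false(identical(fw0$caches[[idx(nm)]]$x, fw1$caches[[idx(nm)]]$x))
  }
})

test_that("analytic gradients match finite differences through the whole net", {
  net <- build_network(toy_spec(), seed = 4)
  withr::local_seed(34)
  x <- array(runif(8 * 8 * 1 * 2), dim = c(8, 8, 1, 2))
  g <- array(rbinom(8 * 8 * 2, 1, 0.3), dim = c(8, 8, 2))

  loss_fn <- function() {
    fw <- retseg:::unet_forward(net, x, training = TRUE)
    mean(vapply(1:2, function(i) {
      dice_loss(as.vector(fw$p[, , 1, i]), as.vector(g[, , i]), 1)
    }, 0))
  }
  fw <- retseg:::unet_forward(net, x, training = TRUE)
  lg <- retseg:::batch_loss_grad(fw$p, g, 1)
  grads <- retseg:::unet_backward(net, fw$caches, lg$gz)

  h <- 1e-5
  for (nm in names(grads)) {
    for (f in names(grads[[nm]])) {
      w <- net$params[[nm]][[f]]
      for (i in sample(length(w), min(2, length(w)))) {
        net$params[[nm]][[f]][i] <- w[i] + h
        lp <- loss_fn()
        net$params[[nm]][[f]][i] <- w[i] - h
        lm <- loss_fn()
        net$params[[nm]][[f]][i] <- w[i]
        num <- (lp - lm) / (2 * h)
        ana <- grads[[nm]][[f]][i]
        expect_lt(abs(num - ana) / max(1e-6, abs(num), abs(ana)), 1e-4)
      }
    }
  }
})

test_that("checkpoints round-trip exactly and validate the spec", {
  net <- build_network(tiny_spec(), seed = 7)
  withr::local_seed(35)
  x <- array(runif(48 * 48 * 3), dim = c(48, 48, 3))
  p0 <- predict_patches(net, x)

  f <- withr::local_tempfile(fileext = ".npz")
  save_checkpoint(net, f)
  net2 <- load_checkpoint(f)
  expect_identical(unclass(net2$spec), unclass(net$spec))
  expect_identical(predict_patches(net2, x), p0)

  expect_error(load_checkpoint(f, spec = toy_spec()), "mismatch")
  expect_error(load_checkpoint(file.path(tempdir(), "none.npz")),
               "does not exist")
})
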