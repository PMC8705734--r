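# Mini-batch SGD (with momentum) on the Dice loss.
#
# The loss for a batch is the mean over patches of 1 - D(p, g, eps); the
# gradient enters the network through the sigmoid head,
# dL/dz = dL/dp * p * (1 - p), with dL/dp the negated analytic Dice
# gradient. Everything is seeded: initialization, batch order and the loss
# trajectory are reproducible bit-for-bit.

#' Training configuration
#'
#' @param lr learning rate.
#' @param momentum SGD momentum in [0, 1).
#' @param batch_size patches per mini-batch.
#' @param epochs number of passes over the training set.
#' @param seed RNG seed (batch shuffling).
#' @param checkpoint_dir directory for the best-validation checkpoint, or
#'   `NULL` to keep the best weights only in memory.
#' @param eps Dice smoothing constant of the loss.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 0.01, momentum = 0.9, batch_size = 32L,
                         epochs = 20L, seed = 1L, checkpoint_dir = NULL,
                         eps = 1.0) {
  if (lr <= 0) stopf("train_config: lr must be > 0")
  if (momentum < 0 || momentum >= 1) {
    stopf("train_config: momentum must be in [0, 1)")
  }
  if (batch_size < 1 || epochs < 0) {
    stopf("train_config: batch_size >= 1 and epochs >= 0 required")
  }
  structure(list(lr = lr, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 checkpoint_dir = checkpoint_dir, eps = eps),
            class = "train_config")
}

batch_tensor <- function(arr) {
  d <- dim(arr$x)
  list(x = array(arr$x, dim = c(d[1], d[2], 1, d[3])), y = arr$y, n = d[3])
}

# loss and dL/dz for one batch; p is (H, W, 1, N)
batch_loss_grad <- function(p, y, eps) {
  d <- dim(p)
  n <- d[4]
  if (!all(is.finite(p))) {
    return(list(loss = NaN, gz = array(NaN, dim = d)))
  }
  gz <- array(0, dim = d)
  loss <- 0
  for (i in seq_len(n)) {
    pi <- as.vector(p[, , 1, i])
    gi <- as.vector(y[, , i])
    loss <- loss + dice_loss(pi, gi, eps)
    gp <- dice_loss_grad(pi, gi, eps) / n
    gz[, , 1, i] <- gp * pi * (1 - pi)
  }
  list(loss = loss / n, gz = gz)
}

eval_on_set <- function(model, ps, eps, batch_size = 64L) {
  n <- n_patches(ps)
  loss <- 0
  dice <- 0
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    bt <- batch_tensor(patch_arrays(ps, idx))
    p <- unet_forward(model, bt$x, training = FALSE, keep_caches = FALSE)$p
    for (i in seq_along(idx)) {
      pi <- as.vector(p[, , 1, i])
      gi <- as.vector(bt$y[, , i])
      loss <- loss + dice_loss(pi, gi, eps)
      dice <- dice + dice_coefficient(pi, gi, eps)
    }
  }
  c(loss = loss / n, dice = dice / n)
}

sgd_step <- function(net, grads, vel, lr, momentum) {
  for (nm in names(grads)) {
    for (f in names(grads[[nm]])) {
      key <- paste0(nm, ".", f)
      v <- vel[[key]]
      if (is.null(v)) v <- 0
      v <- momentum * v - lr * grads[[nm]][[f]]
      vel[[key]] <- v
      net$params[[nm]][[f]] <- net$params[[nm]][[f]] + v
    }
  }
  vel
}

#' Train a dense-block U-Net on a patch set
#'
#' Runs `cfg$epochs` epochs of mini-batch SGD with momentum on the Dice
#' loss, reshuffling batches each epoch from `cfg$seed`. After every epoch
#' the model is evaluated on `val_set`; the weights with the best
#' validation Dice are retained (and written to `cfg$checkpoint_dir` if
#' set). A NaN loss aborts with a diagnostic naming the epoch and batch.
#'
#' @param model a `dense_unet` (modified in place; also returned).
#' @param train_set,val_set `patch_set`s from [sample_patches()] /
#'   [split_train_val()].
#' @param cfg a [train_config].
#' @param verbose print one line per epoch.
#' @return List with `model` (best-validation weights) and `log` (data
#'   frame: epoch, train_loss, val_loss, val_dice).
#' @export
train_unet <- function(model, train_set, val_set, cfg = train_config(),
                       verbose = FALSE) {
  if (!inherits(model, "dense_unet")) stopf("train_unet: need dense_unet")
  n <- n_patches(train_set)
  if (n < 1 || n_patches(val_set) < 1) stopf("train_unet: empty patch set")
  log <- data.frame(epoch = integer(0), train_loss = double(0),
                    val_loss = double(0), val_dice = double(0))
  if (cfg$epochs == 0) {
    return(list(model = model, log = log))
  }
  vel <- new.env(parent = emptyenv())
  best_dice <- -Inf
  best_params <- NULL
  for (ep in seq_len(cfg$epochs)) {
    perm <- with_seed(derive_seed(cfg$seed, paste0("epoch/", ep)),
                      sample.int(n))
    ep_loss <- 0
    nb <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- perm[start:min(start + cfg$batch_size - 1, n)]
      bt <- batch_tensor(patch_arrays(train_set, idx))
      fw <- unet_forward(model, bt$x, training = TRUE)
      lg <- batch_loss_grad(fw$p, bt$y, cfg$eps)
      if (!is.finite(lg$loss)) {
        stopf("train_unet: non-finite loss at epoch %d, batch %d", ep, nb + 1)
      }
      grads <- unet_backward(model, fw$caches, lg$gz)
      vel <- sgd_step(model, grads, vel, cfg$lr, cfg$momentum)
      ep_loss <- ep_loss + lg$loss
      nb <- nb + 1
    }
    ev <- eval_on_set(model, val_set, cfg$eps)
    log <- rbind(log, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                 val_loss = ev[["loss"]],
                                 val_dice = ev[["dice"]]))
    if (verbose) {
      message(sprintf("epoch %d: train_loss %.4f val_loss %.4f val_dice %.4f",
                      ep, ep_loss / nb, ev[["loss"]], ev[["dice"]]))
    }
    if (ev[["dice"]] > best_dice) {
      best_dice <- ev[["dice"]]
      best_params <- model$params
      if (!is.null(cfg$checkpoint_dir)) {
        dir.create(cfg$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
        save_checkpoint(model, file.path(cfg$checkpoint_dir, "best.npz"))
      }
    }
  }
  model$params <- best_params
  list(model = model, log = log)
}
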