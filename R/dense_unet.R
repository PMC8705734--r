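# Dense-block U-Net.
#
# Encoder-decoder with dense blocks: the contraction path alternates dense
# blocks and transition-down layers (BN -> ReLU -> 1x1 conv halving the
# channels -> 2x2 average pooling), a bottleneck dense block sits at the
# lowest resolution, and the expansion path alternates transition-up layers
# (2x2 stride-2 transposed convolution, also halving channels), skip
# concatenation, and dense blocks. A 1x1 convolution plus sigmoid produces
# the per-pixel vessel probability.
#
# Inside a dense block every layer is the composite BN -> ReLU -> 3x3 conv
# emitting `k` (growth rate) channels; its input is the concatenation of
# the block input and all previous layer outputs, so layer l sees
# k0 + k*(l-1) channels and the block emits k0 + k*L.
#
# The network is fully convolutional: any input whose sides are divisible
# by 2^n_blocks_down is accepted, which enables whole-image inference.
#
# No deep-learning framework is available in this environment, so forward
# and backward passes are assembled here from the C++ primitives in
# src/nn_ops.cpp; correctness of the hand-derived backward pass is pinned
# by finite-difference tests.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

#' Dense-block U-Net hyperparameters
#'
#' @param growth_rate channels `k` added by each dense-block layer.
#' @param layers_per_block layers `L` in every dense block.
#' @param n_blocks_down number of down-sampling stages (the bottleneck
#'   block is extra).
#' @param initial_channels stem output channels `k0` (input to the first
#'   dense block).
#' @param input_size training patch side; must be divisible by
#'   `2^n_blocks_down`.
#' @param input_channels input image channels (1 for preprocessed fundus).
#' @return A `network_spec` object.
#' @export
network_spec <- function(growth_rate = 12L, layers_per_block = 4L,
                         n_blocks_down = 2L, initial_channels = 16L,
                         input_size = 48L, input_channels = 1L) {
  v <- c(growth_rate = growth_rate, layers_per_block = layers_per_block,
         n_blocks_down = n_blocks_down, initial_channels = initial_channels,
         input_size = input_size, input_channels = input_channels)
  if (any(v < 1) || any(v != round(v))) {
    stopf("network_spec: all fields must be positive integers")
  }
  if (input_size %% 2^n_blocks_down != 0) {
    stopf("network_spec: input_size %d not divisible by 2^%d",
          input_size, n_blocks_down)
  }
  structure(as.list(as.integer(v)) |> stats::setNames(names(v)),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf(
    "<network_spec: k=%d, L=%d, %d down-blocks, k0=%d, input %dx%dx%d>\n",
    x$growth_rate, x$layers_per_block, x$n_blocks_down, x$initial_channels,
    x$input_size, x$input_size, x$input_channels))
  invisible(x)
}

#' Channel plan of a single dense block
#'
#' Layer `l` (1-based) of a dense block receives `k0 + k*(l-1)` channels
#' (the concatenation of the block input and the `l-1` previous layer
#' outputs) and emits `k` new channels; the block output concatenates
#' everything, `k0 + k*L` channels. (The conventional printed channel-count
#' formula `k0 + k*(L-1)` is the input to the L-th layer.)
#'
#' @param k0 block input channels.
#' @param k growth rate.
#' @param L number of layers.
#' @return Data frame with columns `layer`, `in_channels`, `out_channels`;
#'   attribute `block_out` holds the block output channel count.
#' @export
dense_block_plan <- function(k0, k, L) {
  if (any(c(k0, k, L) < 1)) stopf("dense_block_plan: k0, k, L must be >= 1")
  out <- data.frame(layer = seq_len(L),
                    in_channels = k0 + k * (seq_len(L) - 1L),
                    out_channels = rep(as.integer(k), L))
  attr(out, "block_out") <- as.integer(k0 + k * L)
  out
}

# Ordered module descriptors; the single source of truth for the channel
# algebra, consumed by build, forward, backward and introspection alike.
build_modules <- function(spec) {
  k0 <- spec$initial_channels; k <- spec$growth_rate
  L <- spec$layers_per_block; d <- spec$n_blocks_down
  mods <- list()
  add <- function(name, type, K, cin, cout, size) {
    mods[[length(mods) + 1L]] <<- list(name = name, type = type, K = K,
                                       cin = as.integer(cin),
                                       cout = as.integer(cout),
                                       size = as.integer(size))
  }
  s <- spec$input_size
  add("stem", "conv", 3L, spec$input_channels, k0, s)
  c_cur <- k0
  skip_ch <- integer(d)
  for (b in seq_len(d)) {
    for (l in seq_len(L)) {
      add(sprintf("down%d_l%d", b, l), "bnreluconv", 3L,
          c_cur + k * (l - 1L), k, s)
    }
    c_cur <- c_cur + k * L
    skip_ch[b] <- c_cur
    add(sprintf("td%d", b), "transition_down", 1L, c_cur, c_cur %/% 2L, s)
    c_cur <- c_cur %/% 2L
    s <- s %/% 2L
  }
  for (l in seq_len(L)) {
    add(sprintf("bott_l%d", l), "bnreluconv", 3L, c_cur + k * (l - 1L), k, s)
  }
  c_cur <- c_cur + k * L
  for (b in rev(seq_len(d))) {
    add(sprintf("tu%d", b), "convt", 2L, c_cur, c_cur %/% 2L, s)
    c_cur <- c_cur %/% 2L
    s <- s * 2L
    c_cur <- c_cur + skip_ch[b]
    for (l in seq_len(L)) {
      add(sprintf("up%d_l%d", b, l), "bnreluconv", 3L,
          c_cur + k * (l - 1L), k, s)
    }
    c_cur <- c_cur + k * L
  }
  add("head", "conv", 1L, c_cur, 1L, s)
  names(mods) <- vapply(mods, `[[`, "", "name")
  list(mods = mods, skip_ch = skip_ch)
}

#' Stage-by-stage layer plan of a network
#'
#' Enumerates every parameterized stage with its input/output channel
#' counts and spatial size; dense-block rows follow [dense_block_plan()],
#' transitions halve (down) or double (up) the spatial size and halve the
#' channel count.
#'
#' @param spec a [network_spec].
#' @return Data frame with columns `stage`, `type`, `in_channels`,
#'   `out_channels`, `size`.
#' @export
layer_plan <- function(spec) {
  mods <- build_modules(spec)$mods
  data.frame(stage = vapply(mods, `[[`, "", "name"),
             type = vapply(mods, `[[`, "", "type"),
             in_channels = vapply(mods, `[[`, 0L, "cin"),
             out_channels = vapply(mods, `[[`, 0L, "cout"),
             size = vapply(mods, `[[`, 0L, "size"),
             row.names = NULL)
}

init_module_params <- function(m) {
  he <- function(K, cin, cout) {
    array(rnorm(K * K * cin * cout, sd = sqrt(2 / (K * K * cin))),
          dim = c(K, K, cin, cout))
  }
  p <- list()
  if (m$type %in% c("bnreluconv", "transition_down")) {
    p$gamma <- rep(1, m$cin)
    p$beta <- rep(0, m$cin)
    p$rmean <- rep(0, m$cin)
    p$rvar <- rep(1, m$cin)
  }
  p$W <- he(m$K, m$cin, m$cout)
  p$b <- rep(0, m$cout)
  p
}

#' Build a trainable dense-block U-Net
#'
#' Weights are He-initialized from `seed`; batch-norm scale/shift start at
#' 1/0 with unit running variance.
#'
#' @param spec a [network_spec].
#' @param seed integer seed for weight initialization.
#' @return A `dense_unet` model handle (an environment holding the spec,
#'   the module plan and the parameters).
#' @export
build_network <- function(spec, seed = 1L) {
  if (!inherits(spec, "network_spec")) stopf("build_network: need network_spec")
  bm <- build_modules(spec)
  net <- new.env(parent = emptyenv())
  net$spec <- spec
  net$modules <- bm$mods
  net$skip_ch <- bm$skip_ch
  net$params <- with_seed(derive_seed(seed, "init"),
                          lapply(bm$mods, init_module_params))
  class(net) <- "dense_unet"
  net
}

#' @export
print.dense_unet <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  %d modules, %d trainable parameters\n",
              length(x$modules), count_parameters(x)))
  invisible(x)
}

#' Count trainable parameters
#'
#' Convolution weights/biases and batch-norm scale/shift; running statistics
#' are buffers, not parameters.
#'
#' @param model a `dense_unet`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, function(p) {
    length(p$W) + length(p$b) +
      (if (is.null(p$gamma)) 0L else length(p$gamma) + length(p$beta))
  }, 0L))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

mod_forward <- function(m, p, x, training) {
  switch(m$type,
    conv = list(y = nn_conv_fw(x, p$W, p$b), cache = list(x = x), p = p),
    bnreluconv = {
      bn <- nn_bnrelu_fw(x, p$gamma, p$beta, BN_EPS, training, p$rmean,
                         p$rvar, BN_MOMENTUM)
      a <- bn$y
      y <- nn_conv_fw(a, p$W, p$b)
      if (training) {
        p$rmean <- bn$rmean
        p$rvar <- bn$rvar
      }
      list(y = y, cache = list(x = x, mu = bn$mu, var = bn$var, a = a), p = p)
    },
    transition_down = {
      bn <- nn_bnrelu_fw(x, p$gamma, p$beta, BN_EPS, training, p$rmean,
                         p$rvar, BN_MOMENTUM)
      a <- bn$y
      y <- nn_conv_fw(a, p$W, p$b)
      if (training) {
        p$rmean <- bn$rmean
        p$rvar <- bn$rvar
      }
      list(y = nn_avgpool_fw(y),
           cache = list(x = x, mu = bn$mu, var = bn$var, a = a,
                        H = dim(y)[1], W = dim(y)[2]),
           p = p)
    },
    convt = list(y = nn_convt_fw(x, p$W, p$b), cache = list(x = x), p = p),
    stopf("unknown module type '%s'", m$type))
}

mod_backward <- function(m, p, cache, gy) {
  switch(m$type,
    conv = {
      cb <- nn_conv_bw(cache$x, p$W, gy)
      list(gx = cb$gx, grads = list(W = cb$gw, b = cb$gb))
    },
    bnreluconv = {
      cb <- nn_conv_bw(cache$a, p$W, gy)
      bb <- nn_bnrelu_bw(cache$x, cache$a, p$gamma, cache$mu, cache$var,
                         BN_EPS, cb$gx)
      list(gx = bb$gx, grads = list(W = cb$gw, b = cb$gb,
                                    gamma = bb$dgamma, beta = bb$dbeta))
    },
    transition_down = {
      gpool <- nn_avgpool_bw(gy, cache$H, cache$W)
      cb <- nn_conv_bw(cache$a, p$W, gpool)
      bb <- nn_bnrelu_bw(cache$x, cache$a, p$gamma, cache$mu, cache$var,
                         BN_EPS, cb$gx)
      list(gx = bb$gx, grads = list(W = cb$gw, b = cb$gb,
                                    gamma = bb$dgamma, beta = bb$dbeta))
    },
    convt = {
      cb <- nn_convt_bw(cache$x, p$W, gy)
      list(gx = cb$gx, grads = list(W = cb$gw, b = cb$gb))
    })
}

check_forward_input <- function(net, x) {
  d <- dim(x)
  if (length(d) != 4 || d[3] != net$spec$input_channels) {
    stopf("forward: input must be H x W x %d x N", net$spec$input_channels)
  }
  div <- 2^net$spec$n_blocks_down
  if (d[1] %% div != 0 || d[2] %% div != 0) {
    stopf("forward: spatial dims %d x %d not divisible by %d", d[1], d[2], div)
  }
}

# Forward pass. x: (H, W, C_in, N). Returns list(p = probabilities
# (H, W, 1, N), caches = per-module caches when training or keep_caches).
unet_forward <- function(net, x, training = FALSE, keep_caches = training) {
  check_forward_input(net, x)
  mods <- net$modules
  caches <- if (keep_caches) vector("list", length(mods)) else NULL
  skips <- vector("list", length(net$skip_ch))
  h <- x
  for (mi in seq_along(mods)) {
    m <- mods[[mi]]
    if (m$type == "transition_down") {
      b <- as.integer(sub("td", "", m$name))
      skips[[b]] <- h
    }
    r <- mod_forward(m, net$params[[m$name]], h, training)
    if (training) net$params[[m$name]] <- r$p
    if (keep_caches) caches[[mi]] <- r$cache
    h <- switch(m$type,
      bnreluconv = nn_concat(h, r$y),
      convt = {
        b <- as.integer(sub("tu", "", m$name))
        nn_concat(r$y, skips[[b]])
      },
      r$y)
  }
  list(p = sigmoid(h), z = h, caches = caches)
}

# Backward pass from the gradient w.r.t. the pre-sigmoid logits z.
# Returns a named list of per-module gradient lists.
unet_backward <- function(net, caches, gz) {
  mods <- net$modules
  grads <- vector("list", length(mods))
  names(grads) <- names(mods)
  skip_grads <- vector("list", length(net$skip_ch))
  g <- gz
  for (mi in rev(seq_along(mods))) {
    m <- mods[[mi]]
    p <- net$params[[m$name]]
    if (m$type == "bnreluconv") {
      gy <- nn_slice_channels(g, m$cin + 1L, m$cin + m$cout)
      g <- nn_slice_channels(g, 1L, m$cin)
      r <- mod_backward(m, p, caches[[mi]], gy)
      g <- g + r$gx
    } else if (m$type == "convt") {
      b <- as.integer(sub("tu", "", m$name))
      gtu <- nn_slice_channels(g, 1L, m$cout)
      skip_grads[[b]] <- nn_slice_channels(g, m$cout + 1L,
                                           m$cout + net$skip_ch[b])
      r <- mod_backward(m, p, caches[[mi]], gtu)
      g <- r$gx
    } else if (m$type == "transition_down") {
      b <- as.integer(sub("td", "", m$name))
      r <- mod_backward(m, p, caches[[mi]], g)
      g <- r$gx + skip_grads[[b]]
    } else {  # conv: head or stem
      r <- mod_backward(m, p, caches[[mi]], g)
      g <- r$gx
    }
    grads[[m$name]] <- r$grads
  }
  grads
}

#' Predict vessel probabilities for a batch of patches
#'
#' Runs the network in inference mode (batch-norm running statistics).
#'
#' @param model a `dense_unet`.
#' @param x `H x W x N` array (or `H x W` matrix) of unit-range inputs;
#'   sides must be divisible by `2^n_blocks_down`.
#' @return `H x W x N` array of probabilities in (0, 1).
#' @export
predict_patches <- function(model, x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1))
  d <- dim(x)
  xb <- array(x, dim = c(d[1], d[2], 1, d[3]))
  p <- unet_forward(model, xb, training = FALSE, keep_caches = FALSE)$p
  array(p, dim = d)
}

#' Save a model checkpoint
#'
#' NPZ container holding every parameter tensor (`<module>.<field>`) plus a
#' `meta` JSON member embedding the [network_spec].
#'
#' @param model a `dense_unet`.
#' @param path output `.npz` path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  arrays <- list()
  for (nm in names(model$params)) {
    for (f in names(model$params[[nm]])) {
      arrays[[paste0(nm, ".", f)]] <- model$params[[nm]][[f]]
    }
  }
  meta <- jsonlite::toJSON(list(spec = unclass(model$spec),
                                format = "retseg-checkpoint-1"),
                           auto_unbox = TRUE)
  arrays$meta <- charToRaw(as.character(meta))
  npz_write(path, arrays)
}

#' Load a model checkpoint
#'
#' Rebuilds the network from the embedded spec and restores all parameters;
#' forward outputs round-trip exactly.
#'
#' @param path `.npz` checkpoint path.
#' @param spec optional [network_spec] the caller expects; a mismatch with
#'   the embedded spec is an error naming both.
#' @return A `dense_unet`.
#' @export
load_checkpoint <- function(path, spec = NULL) {
  z <- npz_read(path)
  if (is.null(z$meta)) stopf("'%s' is not a retseg checkpoint", path)
  meta <- jsonlite::fromJSON(rawToChar(z$meta))
  saved <- do.call(network_spec, as.list(meta$spec))
  if (!is.null(spec) && !identical(unclass(spec), unclass(saved))) {
    stopf("checkpoint spec mismatch:\n  file:      %s\n  requested: %s",
          paste(deparse(unlist(unclass(saved))), collapse = ""),
          paste(deparse(unlist(unclass(spec))), collapse = ""))
  }
  net <- build_network(saved, seed = 1L)
  for (nm in names(net$params)) {
    for (f in names(net$params[[nm]])) {
      key <- paste0(nm, ".", f)
      if (is.null(z[[key]])) stopf("checkpoint missing tensor '%s'", key)
      v <- z[[key]]
      if (!identical(length(v), length(net$params[[nm]][[f]]))) {
        stopf("checkpoint tensor '%s' has wrong size", key)
      }
      if (!is.null(dim(net$params[[nm]][[f]])) && is.null(dim(v))) {
        dim(v) <- dim(net$params[[nm]][[f]])
      }
      net$params[[nm]][[f]] <- v
    }
  }
  net
}
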