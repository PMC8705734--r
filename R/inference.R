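# Whole-image segmentation by overlapping-patch prediction.

reflect_index <- function(i, n) {
  # symmetric reflection with edge duplication, 1-based
  j <- (i - 1) %% (2 * n)
  ifelse(j < n, j + 1, 2 * n - j)
}

#' Segment a whole image with an overlapping patch grid
#'
#' The image is reflect-padded so a `patch_size` window stepped by `stride`
#' tiles it exactly; every pixel's probability is the mean of all patch
#' predictions covering it (with `stride == patch_size` each pixel is
#' predicted exactly once). Pixels outside the FOV are set to 0.
#'
#' @param model a trained `dense_unet`.
#' @param u `H x W` unit-range matrix (preprocessed image).
#' @param fov optional `H x W` binary FOV mask.
#' @param patch_size square window side (must match the network input
#'   divisibility constraint).
#' @param stride step between windows, `1 <= stride <= patch_size`.
#'   Smaller strides smooth patch-border seams at linear cost in 1/stride^2.
#' @param batch_size patches per forward pass.
#' @return A `probability_map`: list with `values` (`H x W` in [0, 1]) and
#'   `fov`.
#' @export
predict_image <- function(model, u, fov = NULL, patch_size = 48L,
                          stride = 8L, batch_size = 64L) {
  if (stride <= 0) stopf("predict_image: stride must be positive")
  if (stride > patch_size) stopf("predict_image: stride > patch_size")
  H <- nrow(u); W <- ncol(u)
  ps <- as.integer(patch_size)
  nsr <- if (H <= ps) 0L else ceiling((H - ps) / stride)
  nsc <- if (W <= ps) 0L else ceiling((W - ps) / stride)
  Hp <- ps + nsr * stride
  Wp <- ps + nsc * stride
  up <- u[reflect_index(seq_len(Hp), H), reflect_index(seq_len(Wp), W)]
  r0 <- seq(1L, Hp - ps + 1L, by = stride)
  c0 <- seq(1L, Wp - ps + 1L, by = stride)
  grid <- expand.grid(r = r0, c = c0)
  acc <- matrix(0, Hp, Wp)
  cnt <- matrix(0, Hp, Wp)
  for (start in seq(1, nrow(grid), by = batch_size)) {
    idx <- start:min(start + batch_size - 1, nrow(grid))
    xb <- array(0, dim = c(ps, ps, 1, length(idx)))
    for (j in seq_along(idx)) {
      g <- grid[idx[j], ]
      xb[, , 1, j] <- up[g$r:(g$r + ps - 1), g$c:(g$c + ps - 1)]
    }
    pb <- unet_forward(model, xb, training = FALSE, keep_caches = FALSE)$p
    for (j in seq_along(idx)) {
      g <- grid[idx[j], ]
      rr <- g$r:(g$r + ps - 1); cc <- g$c:(g$c + ps - 1)
      acc[rr, cc] <- acc[rr, cc] + pb[, , 1, j]
      cnt[rr, cc] <- cnt[rr, cc] + 1
    }
  }
  vals <- (acc / cnt)[seq_len(H), seq_len(W)]
  if (is.null(fov)) fov <- matrix(1L, H, W)
  vals[fov == 0] <- 0
  structure(list(values = vals, fov = fov), class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map %d x %d, %.1f%% in FOV, mean %.3f>\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$fov),
              mean(x$values[x$fov == 1])))
  invisible(x)
}

#' Threshold a probability map into a binary vessel mask
#'
#' @param pm a `probability_map` (or plain matrix plus `fov`).
#' @param threshold decision threshold in (0, 1); a pixel is vessel when
#'   its probability is >= threshold and inside the FOV.
#' @param fov FOV mask when `pm` is a plain matrix.
#' @return `H x W` binary integer matrix.
#' @export
binarize <- function(pm, threshold = 0.5, fov = NULL) {
  if (inherits(pm, "probability_map")) {
    vals <- pm$values
    fov <- pm$fov
  } else {
    vals <- pm
    if (is.null(fov)) fov <- matrix(1L, nrow(vals), ncol(vals))
  }
  if (threshold <= 0 || threshold >= 1) {
    stopf("binarize: threshold must be in (0, 1)")
  }
  m <- (vals >= threshold & fov == 1) + 0L
  matrix(as.integer(m), nrow(vals), ncol(vals))
}
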