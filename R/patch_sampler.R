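# Random patch amplification.
#
# A small training set (20 DRIVE images) is amplified by sampling many
# 48x48 sub-windows with uniformly random centers; at the default DRIVE
# configuration 190,000 patches are drawn, 9,500 per image.
#
# A patch_set is stored lazily: per-patch top-left corners plus references
# to the source images. 190,000 dense float patches would occupy ~3.5 GB,
# while corners occupy ~1.5 MB; pixels are materialized on demand with
# [patch_arrays()] (mini-batches, caches). Index alignment between image
# and label crops is structural: one corner serves both.

#' Sample random patches from paired images and labels
#'
#' Patch centers are uniform over all positions where the patch lies fully
#' inside the image (no padding); `n_total` is allocated equally across
#' images. Sampling is reproducible from `seed`.
#'
#' @param images list of `H x W` unit-range matrices (preprocessed images).
#' @param labels list of paired [label_image]s (or binary matrices).
#' @param n_total total number of patches; must be divisible by the number
#'   of images.
#' @param patch_size square patch side (default 48).
#' @param seed integer RNG seed.
#' @return A `patch_set` object; see [patch_arrays()].
#' @export
sample_patches <- function(images, labels, n_total, patch_size = 48L,
                           seed = 1L) {
  if (length(images) == 0 || length(images) != length(labels)) {
    stopf("sample_patches: need equally many images and labels")
  }
  labels <- lapply(labels, function(l) {
    if (inherits(l, "label_image")) l$vessels else l
  })
  n_img <- length(images)
  if (n_total %% n_img != 0) {
    stopf("sample_patches: n_total (%d) not divisible by image count (%d)",
          n_total, n_img)
  }
  per <- n_total %/% n_img
  patch_size <- as.integer(patch_size)
  corners <- matrix(0L, n_total, 2)
  src <- rep(seq_len(n_img), each = per)
  for (i in seq_len(n_img)) {
    H <- nrow(images[[i]]); W <- ncol(images[[i]])
    if (!identical(dim(labels[[i]]), c(H, W))) {
      stopf("sample_patches: image/label shape mismatch at index %d", i)
    }
    if (patch_size > H || patch_size > W) {
      stopf("sample_patches: patch_size %d exceeds image %d x %d",
            patch_size, H, W)
    }
    rows <- (i - 1) * per + seq_len(per)
    with_seed(derive_seed(seed, paste0("patches/", i)), {
      corners[rows, 1] <- sample.int(H - patch_size + 1L, per, replace = TRUE)
      corners[rows, 2] <- sample.int(W - patch_size + 1L, per, replace = TRUE)
    })
  }
  source_ids <- names(images)
  if (is.null(source_ids)) source_ids <- as.character(seq_len(n_img))
  structure(list(mode = "lazy", images = images, labels = labels,
                 corners = corners, src = src, source_ids = source_ids,
                 patch_size = patch_size, seed = as.integer(seed)),
            class = "patch_set")
}

#' Number of patches in a patch set
#' @param ps a `patch_set`.
#' @return Integer count.
#' @export
n_patches <- function(ps) {
  if (identical(ps$mode, "dense")) dim(ps$patches)[3] else nrow(ps$corners)
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set: %d patches of %d x %d from %d image(s), seed %d>\n",
              n_patches(x), x$patch_size, x$patch_size,
              if (identical(x$mode, "dense")) length(unique(x$source_id)) else
                length(x$images), x$seed))
  invisible(x)
}

#' Materialize patch pixel arrays
#'
#' @param ps a `patch_set`.
#' @param idx indices of the patches to materialize (default: all; avoid on
#'   very large sets).
#' @return List with `x` (`s x s x n` image patches in [0, 1]), `y`
#'   (`s x s x n` binary label patches) and `source_id` (length-n character).
#' @export
patch_arrays <- function(ps, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(n_patches(ps))
  s <- ps$patch_size
  if (identical(ps$mode, "dense")) {
    return(list(x = ps$patches[, , idx, drop = FALSE],
                y = ps$labels[, , idx, drop = FALSE],
                source_id = ps$source_id[idx]))
  }
  n <- length(idx)
  x <- array(0, dim = c(s, s, n))
  y <- array(0L, dim = c(s, s, n))
  for (j in seq_len(n)) {
    i <- idx[j]
    r <- ps$corners[i, 1]; c <- ps$corners[i, 2]; k <- ps$src[i]
    x[, , j] <- ps$images[[k]][r:(r + s - 1), c:(c + s - 1)]
    y[, , j] <- ps$labels[[k]][r:(r + s - 1), c:(c + s - 1)]
  }
  list(x = x, y = y, source_id = ps$source_ids[ps$src[idx]])
}

subset_patchset <- function(ps, idx) {
  if (identical(ps$mode, "dense")) {
    out <- list(mode = "dense", patches = ps$patches[, , idx, drop = FALSE],
                labels = ps$labels[, , idx, drop = FALSE],
                source_id = ps$source_id[idx], patch_size = ps$patch_size,
                seed = ps$seed)
  } else {
    out <- ps
    out$corners <- ps$corners[idx, , drop = FALSE]
    out$src <- ps$src[idx]
  }
  structure(out, class = "patch_set")
}

#' Split a patch set into training and validation parts
#'
#' Shuffles indices with `seed` and partitions them disjointly into
#' `round(N * (1 - val_fraction))` training and the remaining validation
#' patches.
#'
#' @param ps a `patch_set`.
#' @param val_fraction validation fraction in (0, 1).
#' @param seed RNG seed for the shuffle.
#' @return List with elements `train` and `val` (both `patch_set`s).
#' @export
split_train_val <- function(ps, val_fraction = 0.1, seed = 1L) {
  if (val_fraction <= 0 || val_fraction >= 1) {
    stopf("split_train_val: val_fraction must be in (0, 1), got %g",
          val_fraction)
  }
  n <- n_patches(ps)
  perm <- with_seed(derive_seed(seed, "split"), sample.int(n))
  n_tr <- round(n * (1 - val_fraction))
  if (n_tr < 1 || n_tr >= n) stopf("split_train_val: degenerate split")
  list(train = subset_patchset(ps, perm[seq_len(n_tr)]),
       val = subset_patchset(ps, perm[(n_tr + 1):n]))
}

#' Save a patch set to an NPZ cache
#'
#' Materializes the patches and writes datasets `patches` (float64,
#' `s x s x N`), `labels` (uint8 bytes) and `meta` (JSON as raw bytes:
#' source ids, patch size, seed). Intended for modest N; the DRIVE-scale
#' 190,000-patch set should be sampled lazily instead.
#'
#' @param ps a `patch_set`.
#' @param path output `.npz` path.
#' @return `path`, invisibly.
#' @export
save_patch_cache <- function(ps, path) {
  arr <- patch_arrays(ps)
  meta <- jsonlite::toJSON(list(source_id = arr$source_id,
                                patch_size = ps$patch_size, seed = ps$seed),
                           auto_unbox = TRUE)
  npz_write(path, list(patches = arr$x,
                       labels = as.raw(as.integer(arr$y)),
                       meta = charToRaw(as.character(meta))))
}

#' Load a patch-set cache written by [save_patch_cache()]
#'
#' @param path `.npz` path.
#' @return A dense `patch_set` (patches held in memory).
#' @export
load_patch_cache <- function(path) {
  z <- npz_read(path)
  for (nm in c("patches", "labels", "meta")) {
    if (is.null(z[[nm]])) stopf("'%s' is not a patch cache: missing '%s'",
                                path, nm)
  }
  meta <- jsonlite::fromJSON(rawToChar(z$meta))
  d <- dim(z$patches)
  labels <- array(as.integer(z$labels), dim = d)
  structure(list(mode = "dense", patches = z$patches, labels = labels,
                 source_id = meta$source_id,
                 patch_size = as.integer(meta$patch_size),
                 seed = as.integer(meta$seed)),
            class = "patch_set")
}
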