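# Synthetic fundus generator.
#
# Emulates the properties of real fundus photographs that the pipeline
# depends on: a circular FOV, darker-than-background vessels of 1-8 px
# width arranged in branching trees, a radial illumination gradient,
# additive Gaussian noise, and a vessel-pixel fraction near 10% of the FOV
# (the class imbalance that motivates the Dice loss). Ground truth is exact
# by construction. It does not attempt photorealism: no optic disc, fovea,
# lesions or texture.

#' Synthetic fundus configuration
#'
#' Defaults mirror the DRIVE geometry (565 x 584) and the ~10% vessel-pixel
#' statistic of real fundus images.
#'
#' @param height,width image dimensions in pixels (>= 48).
#' @param n_trees scales the cap on vessel trees grown from the FOV
#'   boundary: trees are added (at most `10 * n_trees`) until
#'   `target_vessel_fraction` is reached.
#' @param branch_prob per-step probability that a segment bifurcates.
#' @param max_depth maximum bifurcation depth (0 = unbranched curves).
#' @param root_width trunk width in pixels at the FOV boundary.
#' @param width_decay factor applied to both daughter widths at a
#'   bifurcation, in (0, 1).
#' @param vessel_contrast green-channel intensity drop on vessels (0-255).
#' @param illum_strength relative brightness loss at the FOV edge due to
#'   the radial illumination gradient, in [0, 1].
#' @param noise_sigma additive Gaussian noise s.d. (intensity levels).
#' @param target_vessel_fraction desired vessel fraction of the FOV.
#' @return A `synth_config` list.
#' @export
synth_config <- function(height = 584L, width = 565L, n_trees = 12L,
                         branch_prob = 0.08, max_depth = 7L, root_width = 7,
                         width_decay = 0.7, vessel_contrast = 70,
                         illum_strength = 0.3, noise_sigma = 8,
                         target_vessel_fraction = 0.10) {
  if (height < 48 || width < 48) stopf("synth_config: dimensions must be >= 48")
  if (width_decay <= 0 || width_decay >= 1) {
    stopf("synth_config: width_decay must be in (0, 1)")
  }
  if (branch_prob < 0 || branch_prob > 1) {
    stopf("synth_config: branch_prob must be in [0, 1]")
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_trees = as.integer(n_trees), branch_prob = branch_prob,
                 max_depth = as.integer(max_depth), root_width = root_width,
                 width_decay = width_decay, vessel_contrast = vessel_contrast,
                 illum_strength = illum_strength, noise_sigma = noise_sigma,
                 target_vessel_fraction = target_vessel_fraction),
            class = "synth_config")
}

fov_circle <- function(H, W) {
  r0 <- (H + 1) / 2
  c0 <- (W + 1) / 2
  R <- 0.48 * min(H, W)
  d2 <- outer((seq_len(H) - r0)^2, (seq_len(W) - c0)^2, `+`)
  (d2 <= R^2) + 0L
}

paint_disk <- function(grid, r, c, radius) {
  H <- nrow(grid); W <- ncol(grid)
  ir <- round(radius)
  rr <- max(1, round(r) - ir):min(H, round(r) + ir)
  cc <- max(1, round(c) - ir):min(W, round(c) + ir)
  if (length(rr) == 0 || length(cc) == 0) return(grid)
  sub <- outer((rr - r)^2, (cc - c)^2, `+`) <= max(radius, 0.5)^2
  grid[rr, cc][sub] <- 1L
  grid
}

#' Generate a branching vessel tree mask
#'
#' Trees are grown by random walks: each starts at the FOV boundary aimed
#' inward, advances in small steps with random heading changes, bifurcates
#' with probability `branch_prob` per step (both daughters' widths scaled
#' by `width_decay`), tapers slowly along its length, and terminates when
#' its width falls below 1 px or it exits the FOV. Segments are rasterized
#' with a round brush. Trees are grown one at a time (at most
#' `10 * n_trees`) until the in-FOV vessel fraction reaches
#' `target_vessel_fraction`, so the stated class imbalance is part of the
#' generated world rather than an accident of the tree parameters.
#'
#' @param cfg a [synth_config].
#' @param seed integer seed; the same seed reproduces the grid exactly.
#' @return `H x W` binary integer matrix of vessel pixels.
#' @export
generate_vessel_tree <- function(cfg = synth_config(), seed = 1L) {
  H <- cfg$height; W <- cfg$width
  fov <- fov_circle(H, W)
  n_fov <- sum(fov)
  r0 <- (H + 1) / 2; c0 <- (W + 1) / 2
  R <- 0.48 * min(H, W)
  vess <- matrix(0L, H, W)
  step <- 2

  grow_tree <- function(vess) {
    phi <- runif(1, 0, 2 * pi)
    # start just inside the FOV boundary, heading inward
    stack <- list(list(r = r0 + 0.95 * R * sin(phi),
                       c = c0 + 0.95 * R * cos(phi),
                       heading = phi + pi + rnorm(1, 0, 0.3),
                       width = cfg$root_width, depth = 0L))
    steps <- 0L
    while (length(stack) > 0 && steps < 5000L) {
      seg <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      repeat {
        steps <- steps + 1L
        if (steps >= 5000L) break
        seg$heading <- seg$heading + rnorm(1, 0, 0.12)
        seg$r <- seg$r + step * sin(seg$heading)
        seg$c <- seg$c + step * cos(seg$heading)
        inside <- (seg$r - r0)^2 + (seg$c - c0)^2 <= R^2
        if (!inside || seg$width < 1) break
        vess <- paint_disk(vess, seg$r, seg$c, seg$width / 2)
        seg$width <- seg$width * 0.995  # slow taper -> 1-px terminal twigs
        if (seg$depth < cfg$max_depth && runif(1) < cfg$branch_prob) {
          dphi <- runif(1, 0.35, 0.8)
          w <- seg$width * cfg$width_decay
          stack[[length(stack) + 1L]] <-
            list(r = seg$r, c = seg$c, heading = seg$heading + dphi,
                 width = w, depth = seg$depth + 1L)
          seg$heading <- seg$heading - dphi
          seg$width <- w
          seg$depth <- seg$depth + 1L
        }
      }
    }
    vess
  }

  with_seed(derive_seed(seed, "tree"), {
    t <- 0L
    while (t < 10L * cfg$n_trees &&
           sum(vess[fov == 1]) / n_fov < cfg$target_vessel_fraction) {
      vess <- grow_tree(vess)
      t <- t + 1L
    }
  })
  vess * fov
}

#' Render a fundus-like photograph from a vessel mask
#'
#' Green channel: background level shaded by a radial illumination field,
#' minus `vessel_contrast` on vessel pixels, plus Gaussian noise, clipped
#' to [0, 255]. Red and blue are correlated lower-contrast copies. Pixels
#' outside the circular FOV are black. Before noise, the rendered darkening
#' coincides pixel-for-pixel with the vessel mask.
#'
#' @param vessels `H x W` binary vessel mask.
#' @param cfg a [synth_config].
#' @param seed integer seed (noise stream).
#' @param image_id identifier for the resulting image.
#' @return A [fundus_image] with the circular FOV attached.
#' @export
render_fundus <- function(vessels, cfg = synth_config(), seed = 1L,
                          image_id = "synthetic") {
  H <- nrow(vessels); W <- ncol(vessels)
  fov <- fov_circle(H, W)
  r0 <- (H + 1) / 2; c0 <- (W + 1) / 2
  R <- 0.48 * min(H, W)
  d2 <- outer((seq_len(H) - r0)^2, (seq_len(W) - c0)^2, `+`)
  illum <- 1 - cfg$illum_strength * pmin(d2 / R^2, 1)
  green <- 180 * illum - cfg$vessel_contrast * vessels
  with_seed(derive_seed(seed, "noise"), {
    if (cfg$noise_sigma > 0) {
      green <- green + matrix(rnorm(H * W, 0, cfg$noise_sigma), H, W)
    }
  })
  clip255 <- function(x) pmin(pmax(round(x), 0), 255)
  green <- clip255(green)
  red <- clip255(0.45 * green + 120)
  blue <- clip255(0.35 * green + 15)
  px <- array(0L, dim = c(H, W, 3))
  px[, , 1] <- red * fov
  px[, , 2] <- green * fov
  px[, , 3] <- blue * fov
  fundus_image(px, fov_mask = fov, image_id = image_id)
}

#' Generate a synthetic dataset with ground truth
#'
#' Per-image seeds are derived deterministically from the master seed, so
#' the dataset is reproducible and any two master seeds give different
#' data.
#'
#' @param n_images number of samples.
#' @param cfg a [synth_config].
#' @param seed master seed.
#' @param prefix id prefix for the samples.
#' @return List of samples; each has `image` ([fundus_image]), `label`
#'   ([label_image]), `fov` (binary matrix) and `seed`.
#' @export
generate_dataset <- function(n_images, cfg = synth_config(), seed = 1L,
                             prefix = "synth") {
  if (n_images < 1) stopf("generate_dataset: n_images must be >= 1")
  lapply(seq_len(n_images), function(i) {
    si <- derive_seed(seed, paste0("image/", i))
    id <- sprintf("%s%03d", prefix, i)
    vess <- generate_vessel_tree(cfg, seed = si)
    img <- render_fundus(vess, cfg, seed = si + 1L, image_id = id)
    list(image = img, label = label_image(vess, image_id = id),
         fov = img$fov_mask, seed = si)
  })
}

#' Write synthetic samples in the DRIVE directory layout
#'
#' Creates `dir/training/{images,1st_manual,mask}` and the same under
#' `dir/test`, with DRIVE-style numeric file names (training ids start at
#' 21, test ids at 1), as PNG. The output can be read back with
#' [load_drive_split()], exercising the same code path as real data.
#'
#' @param train_samples,test_samples sample lists from
#'   [generate_dataset()].
#' @param dir output root directory.
#' @return `dir`, invisibly.
#' @export
write_drive_layout <- function(train_samples, test_samples, dir) {
  write_split <- function(samples, sub, id0, tag) {
    for (d in c("images", "1st_manual", "mask")) {
      dir.create(file.path(dir, sub, d), recursive = TRUE,
                 showWarnings = FALSE)
    }
    for (i in seq_along(samples)) {
      s <- samples[[i]]
      id <- id0 + i - 1
      png::writePNG(aperm(array(s$image$pixels / 255,
                                dim = dim(s$image$pixels)), c(1, 2, 3)),
                    file.path(dir, sub, "images",
                              sprintf("%02d_%s.png", id, tag)))
      write_mask(s$label$vessels,
                 file.path(dir, sub, "1st_manual",
                           sprintf("%02d_manual1.png", id)))
      write_mask(s$fov,
                 file.path(dir, sub, "mask",
                           sprintf("%02d_%s_mask.png", id, tag)))
    }
  }
  write_split(train_samples, "training", 21, "training")
  write_split(test_samples, "test", 1, "test")
  invisible(dir)
}
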