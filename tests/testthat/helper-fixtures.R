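# Shared fixtures, built in code and memoized across test files.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- force(expr)
  fixture_env[[key]]
}

# Small synthetic configuration: fast to generate, same statistical story
# (darker vessels, radial illumination, noise, ~10% vessel fraction).
small_synth_cfg <- function(height = 96L, width = 96L) {
  synth_config(height = height, width = width, n_trees = 4L,
               branch_prob = 0.1, max_depth = 5L, root_width = 4,
               width_decay = 0.75, vessel_contrast = 70,
               illum_strength = 0.3, noise_sigma = 6,
               target_vessel_fraction = 0.10)
}

small_samples <- function(n = 3, seed = 301) {
  memo(sprintf("small-%d-%d", n, seed),
       generate_dataset(n, small_synth_cfg(), seed = seed))
}

# One sample at the full default (DRIVE-like) geometry; generated once.
default_sample <- function() {
  memo("default-sample", generate_dataset(1, synth_config(), seed = 77)[[1]])
}

toy_spec <- function() {
  network_spec(growth_rate = 1, layers_per_block = 1, n_blocks_down = 1,
               initial_channels = 1, input_size = 8)
}

tiny_spec <- function(input_size = 48L) {
  network_spec(growth_rate = 4, layers_per_block = 1, n_blocks_down = 2,
               initial_channels = 4, input_size = input_size)
}

# Separable world: vessels are exactly the pixels with intensity < 0.3.
separable_data <- function(n_images = 4, H = 64, W = 64, seed = 99) {
  memo(sprintf("sep-%d-%d-%d-%d", n_images, H, W, seed), {
    withr::with_seed(seed, {
      lapply(seq_len(n_images), function(i) {
        mask <- matrix(rbinom(H * W, 1, 0.1), H, W)
        u <- matrix(runif(H * W, 0.5, 1), H, W)
        u[mask == 1] <- runif(sum(mask), 0.02, 0.2)
        list(u = u, label = mask)
      })
    })
  })
}

expect_same_array <- function(a, b, tol = 0) {
  if (tol == 0) expect_identical(dim(a), dim(b))
  expect_equal(as.vector(a), as.vector(b), tolerance = if (tol == 0) NULL else tol)
}
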