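# YAML configuration with full defaults, strict key validation, and the
# end-to-end pipeline driver.

#' Default run configuration
#'
#' Every tunable of the toolchain with its default; [parse_config()]
#' validates user YAML against this structure (unknown keys and type
#' mismatches are errors).
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 42L,
    log_level = "info",
    data = list(
      use_synth = TRUE,   # generate synthetic data in memory
      dir = "",           # DRIVE-layout directory when use_synth is FALSE
      n_train = 10L,      # synthetic training images
      n_test = 5L         # synthetic test images
    ),
    preprocess = list(
      clahe_clip = 2.0,
      clahe_tiles = c(8L, 8L),
      median_kernel = 3L,
      gamma_bounds = c(0.5, 2.5),
      enhance_k = 1.0,
      scales = c(1L, 2L, 3L, 4L),
      weights = c(0.25, 0.25, 0.25, 0.25)
    ),
    sampler = list(
      n_total = 190000L,
      patch_size = 48L,
      val_fraction = 0.1
    ),
    model = list(
      growth_rate = 12L,
      layers_per_block = 4L,
      n_blocks_down = 2L,
      initial_channels = 16L
    ),
    train = list(
      lr = 0.01,
      momentum = 0.9,
      batch_size = 32L,
      epochs = 20L
    ),
    loss = list(eps = 1.0),
    infer = list(stride = 8L, threshold = 0.5),
    synth = list(
      height = 584L, width = 565L, n_trees = 12L, branch_prob = 0.08,
      max_depth = 7L, root_width = 7, width_decay = 0.7,
      vessel_contrast = 70, illum_strength = 0.3, noise_sigma = 8,
      target_vessel_fraction = 0.10
    )
  )
}

merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(base)) stopf("unknown config key '%s'", full)
    b <- base[[key]]
    u <- user[[key]]
    if (is.list(b)) {
      if (!is.list(u)) stopf("config key '%s' must be a section", full)
      base[[key]] <- merge_config(b, u, full)
    } else {
      if (is.character(b) != is.character(u)) {
        stopf("config key '%s': expected %s, got %s", full,
              if (is.character(b)) "string" else "number",
              if (is.character(u)) "string" else class(u)[1])
      }
      if (!is.character(b) && !is.numeric(u)) {
        stopf("config key '%s': expected number, got %s", full, class(u)[1])
      }
      if (is.integer(b) && is.numeric(u)) {
        if (any(u != round(u))) {
          stopf("config key '%s': expected integer, got %s", full,
                paste(u, collapse = ", "))
        }
        u <- as.integer(u)
      }
      base[[key]] <- u
    }
  }
  base
}

#' Parse and validate a run configuration
#'
#' Reads a YAML file (or starts from the defaults), applies `overrides`,
#' and validates: unknown keys, wrong types and non-integer values for
#' integer fields are errors naming the offending key. An empty file
#' yields all defaults.
#'
#' @param path optional YAML file path.
#' @param overrides optional nested list merged on top of the file.
#' @return Validated config list of class `run_config`.
#' @export
parse_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("config file '%s' does not exist", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) {
      if (!is.list(user)) stopf("config file '%s' is not a YAML mapping", path)
      cfg <- merge_config(cfg, user)
    }
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  structure(cfg, class = c("run_config", "list"))
}

config_echo <- function(cfg, con = stderr()) {
  writeLines(yaml::as.yaml(unclass(cfg)), con)
}

log_msg <- function(cfg, ...) {
  if (!identical(cfg$log_level, "quiet")) message(sprintf(...))
}

#' Run the full pipeline: data, preprocessing, training, evaluation
#'
#' Generates (or loads) a dataset, preprocesses every image, samples and
#' splits patches, trains a dense-block U-Net, segments the test images,
#' and writes `metrics.json` (pooled and per-image), `trainlog.csv`,
#' `best.npz` and an `effective-config.yaml` echo to `out_dir`. All
#' randomness derives from `cfg$seed`, so identical configs give identical
#' artifacts.
#'
#' @param cfg a `run_config` from [parse_config()].
#' @param out_dir output directory (created if needed).
#' @return The metrics list, invisibly.
#' @export
run_pipeline <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(yaml::as.yaml(unclass(cfg)),
             file.path(out_dir, "effective-config.yaml"))

  scfg <- do.call(synth_config, cfg$synth)
  if (isTRUE(cfg$data$use_synth)) {
    log_msg(cfg, "generating %d + %d synthetic images",
            cfg$data$n_train, cfg$data$n_test)
    train_raw <- generate_dataset(cfg$data$n_train, scfg,
                                  seed = derive_seed(cfg$seed, "train-data"))
    test_raw <- generate_dataset(cfg$data$n_test, scfg,
                                 seed = derive_seed(cfg$seed, "test-data"))
  } else {
    if (!nzchar(cfg$data$dir) || !dir.exists(cfg$data$dir)) {
      stopf("data directory '%s' not found and synthetic data disabled",
            cfg$data$dir)
    }
    split <- load_drive_split(cfg$data$dir)
    attach_fov <- function(pair) {
      list(image = pair$image, label = pair$label,
           fov = pair$image$fov_mask)
    }
    train_raw <- lapply(split$training, attach_fov)
    test_raw <- lapply(split$test, attach_fov)
  }

  pcfg <- do.call(preprocess_config, cfg$preprocess)
  log_msg(cfg, "preprocessing %d images", length(train_raw) + length(test_raw))
  train_u <- lapply(train_raw, function(s) preprocess_pipeline(s$image, pcfg))
  names(train_u) <- vapply(train_raw, function(s) s$image$image_id, "")
  test_u <- lapply(test_raw, function(s) preprocess_pipeline(s$image, pcfg))

  ps <- sample_patches(train_u, lapply(train_raw, `[[`, "label"),
                       n_total = cfg$sampler$n_total,
                       patch_size = cfg$sampler$patch_size,
                       seed = derive_seed(cfg$seed, "sampler"))
  sp <- split_train_val(ps, cfg$sampler$val_fraction,
                        seed = derive_seed(cfg$seed, "split"))

  spec <- network_spec(growth_rate = cfg$model$growth_rate,
                       layers_per_block = cfg$model$layers_per_block,
                       n_blocks_down = cfg$model$n_blocks_down,
                       initial_channels = cfg$model$initial_channels,
                       input_size = cfg$sampler$patch_size)
  model <- build_network(spec, seed = derive_seed(cfg$seed, "init"))
  tcfg <- train_config(lr = cfg$train$lr, momentum = cfg$train$momentum,
                       batch_size = cfg$train$batch_size,
                       epochs = cfg$train$epochs,
                       seed = derive_seed(cfg$seed, "train"),
                       checkpoint_dir = out_dir, eps = cfg$loss$eps)
  log_msg(cfg, "training %d epochs on %d patches", tcfg$epochs,
          n_patches(sp$train))
  tr <- train_unet(model, sp$train, sp$val, tcfg,
                   verbose = !identical(cfg$log_level, "quiet"))
  write.csv(tr$log, file.path(out_dir, "trainlog.csv"), row.names = FALSE)

  log_msg(cfg, "segmenting %d test images", length(test_raw))
  pooled <- list(prob = c(), gold = c())
  per_image <- list()
  counts <- list(TP = 0, TN = 0, FP = 0, FN = 0)
  for (i in seq_along(test_raw)) {
    s <- test_raw[[i]]
    pm <- predict_image(tr$model, test_u[[i]], fov = s$fov,
                        patch_size = cfg$sampler$patch_size,
                        stride = cfg$infer$stride)
    ev <- evaluate_segmentation(pm, s$label, cfg$infer$threshold)
    per_image[[s$image$image_id]] <-
      ev[c("acc", "sp", "sn", "ppv", "auc")]
    for (f in names(counts)) counts[[f]] <- counts[[f]] + ev$counts[[f]]
    pooled$prob <- c(pooled$prob, pm$values[s$fov == 1])
    pooled$gold <- c(pooled$gold, s$label$vessels[s$fov == 1])
  }
  pooled_auc <- roc_auc(matrix(pooled$prob), matrix(pooled$gold))$auc
  metrics <- c(seg_metrics(counts),
               list(auc = pooled_auc, counts = counts,
                    per_image = per_image))
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg(cfg, "acc %.4f sp %.4f sn %.4f ppv %.4f auc %.4f",
          metrics$acc, metrics$sp, metrics$sn, metrics$ppv, metrics$auc)
  invisible(metrics)
}
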