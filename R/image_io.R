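# Reading and writing fundus images, vessel labels and FOV masks.
#
# Backend: the `png` package. The DRIVE distribution ships TIFF images and
# GIF masks; no TIFF/GIF reader exists in this R environment, so those
# formats raise an informative error asking for a one-off conversion to PNG
# (see README). All retseg-generated data is PNG.

#' Construct a fundus image object
#'
#' A fundus image is an `H x W x 3` integer array of 0-255 intensities with
#' an optional binary field-of-view (FOV) mask marking the circular camera
#' aperture. Coordinates are row-major, `(row, col)`, 1-based (R native).
#'
#' @param pixels `H x W x 3` numeric array, values in 0-255.
#' @param fov_mask optional `H x W` binary matrix (1 = inside FOV).
#' @param image_id identifier string used for pairing with labels.
#' @return An object of class `fundus_image`.
#' @export
fundus_image <- function(pixels, fov_mask = NULL, image_id = "") {
  d <- dim(pixels)
  if (length(d) != 3 || d[3] != 3) {
    stopf("fundus_image: pixels must be H x W x 3, got [%s]",
          paste(d, collapse = " x "))
  }
  if (d[1] < 48 || d[2] < 48) {
    stopf("fundus_image: image must be at least 48 x 48, got %d x %d",
          d[1], d[2])
  }
  if (min(pixels) < 0 || max(pixels) > 255) {
    stopf("fundus_image: pixel values outside [0, 255]")
  }
  if (!is.null(fov_mask)) {
    if (!identical(dim(fov_mask), d[1:2])) {
      stopf("fundus_image: fov_mask is %s but image is %d x %d",
            paste(dim(fov_mask), collapse = " x "), d[1], d[2])
    }
    if (!is_binary_grid(fov_mask)) stopf("fundus_image: fov_mask not binary")
    storage.mode(fov_mask) <- "integer"
  }
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, fov_mask = fov_mask,
                 image_id = as.character(image_id)),
            class = "fundus_image")
}

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fundus_image '%s' %d x %d, FOV %s>\n", x$image_id,
              d[1], d[2], if (is.null(x$fov_mask)) "absent" else "present"))
  invisible(x)
}

#' Construct a binary vessel label image
#'
#' @param vessels `H x W` strictly binary matrix (1 = vessel).
#' @param image_id identifier string.
#' @return An object of class `label_image`.
#' @export
label_image <- function(vessels, image_id = "") {
  if (!is.matrix(vessels) || !is_binary_grid(vessels)) {
    stopf("label_image: vessels must be a binary matrix")
  }
  storage.mode(vessels) <- "integer"
  structure(list(vessels = vessels, image_id = as.character(image_id)),
            class = "label_image")
}

read_image_grid <- function(path) {
  if (!file.exists(path)) stopf("cannot read '%s': file does not exist", path)
  magic <- readBin(path, "raw", n = 4L)
  is_png <- length(magic) >= 4 &&
    identical(magic, as.raw(c(0x89, 0x50, 0x4e, 0x47)))
  if (!is_png) {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("tif", "tiff", "gif")) {
      stopf(paste0("cannot read '%s': no TIFF/GIF reader is available in ",
                   "this build; convert to PNG first"), path)
    }
    stopf("cannot read '%s': not a PNG file", path)
  }
  a <- tryCatch(png::readPNG(path),
                error = function(e) stopf("cannot read '%s': %s", path,
                                          conditionMessage(e)))
  round(a * 255)
}

#' Read a fundus photograph
#'
#' Reads a PNG image as a [fundus_image]. Grayscale files are replicated to
#' three identical channels with a warning; an alpha channel, if present, is
#' dropped.
#'
#' @param path path to a PNG file.
#' @param fov_mask optional `H x W` binary FOV matrix to attach.
#' @param image_id identifier; defaults to the file name without extension.
#' @return A [fundus_image].
#' @export
read_fundus <- function(path, fov_mask = NULL, image_id = NULL) {
  a <- read_image_grid(path)
  if (is.null(image_id)) {
    image_id <- tools::file_path_sans_ext(basename(path))
  }
  if (is.matrix(a)) {
    warnf("'%s' is grayscale; replicating to 3 channels", path)
    a <- array(a, dim = c(dim(a), 3))
  } else if (dim(a)[3] == 2) {
    warnf("'%s' is grayscale; replicating to 3 channels", path)
    a <- array(a[, , 1], dim = c(dim(a)[1:2], 3))
  } else if (dim(a)[3] == 4) {
    a <- a[, , 1:3]
  }
  fundus_image(a, fov_mask = fov_mask, image_id = image_id)
}

#' Read a binary mask (vessel label or FOV)
#'
#' The raw grid must contain at most two distinct values; values above 50%
#' of the maximum map to 1. An anti-aliased or multi-level file is rejected
#' rather than silently thresholded.
#'
#' @param path path to a PNG file.
#' @param image_id identifier; defaults to the file name without extension.
#' @return A [label_image].
#' @export
read_label <- function(path, image_id = NULL) {
  a <- read_image_grid(path)
  if (is.null(image_id)) {
    image_id <- tools::file_path_sans_ext(basename(path))
  }
  if (!is.matrix(a)) a <- a[, , 1]
  vals <- unique(as.vector(a))
  if (length(vals) > 2) {
    stopf("'%s' is not a binary mask: %d distinct values (e.g. %s)",
          path, length(vals), paste(utils::head(sort(vals), 4), collapse = ", "))
  }
  m <- max(a)
  v <- if (m == 0) a * 0L else (a > 0.5 * m) + 0L
  label_image(matrix(as.integer(v), nrow(a), ncol(a)), image_id = image_id)
}

#' Write a binary mask as an 8-bit PNG
#'
#' Values {0,1} are written as {0,255}; the file round-trips bit-exactly
#' through [read_label()].
#'
#' @param mask `H x W` binary matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (!is.matrix(mask) || !is_binary_grid(mask)) {
    stopf("write_mask: mask must be a binary matrix")
  }
  ok <- tryCatch({
    png::writePNG(matrix(as.double(mask), nrow(mask), ncol(mask)), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path)) stopf("write_mask: cannot write '%s'", path)
  invisible(path)
}

drive_id <- function(fname) {
  m <- regmatches(fname, regexpr("^[0-9]+", fname))
  if (length(m) == 0) NA_character_ else m
}

load_drive_subdir <- function(dir) {
  imgs <- list.files(file.path(dir, "images"), full.names = TRUE)
  labs <- list.files(file.path(dir, "1st_manual"), full.names = TRUE)
  fovs <- list.files(file.path(dir, "mask"), full.names = TRUE)
  iid <- vapply(basename(imgs), drive_id, "")
  lid <- vapply(basename(labs), drive_id, "")
  fid <- vapply(basename(fovs), drive_id, "")
  orphan <- c(imgs[!(iid %in% lid) | !(iid %in% fid)],
              labs[!(lid %in% iid)], fovs[!(fid %in% iid)])
  if (length(orphan) > 0) {
    stopf("unpaired files under '%s': %s", dir,
          paste(basename(orphan), collapse = ", "))
  }
  if (length(imgs) == 0) stopf("no images found under '%s'", dir)
  ord <- order(iid)
  lapply(ord, function(i) {
    fov <- read_label(fovs[match(iid[i], fid)])
    img <- read_fundus(imgs[i], fov_mask = fov$vessels, image_id = iid[i])
    lab <- read_label(labs[match(iid[i], lid)], image_id = iid[i])
    if (!identical(dim(lab$vessels), dim(img$pixels)[1:2])) {
      stopf("label/image shape mismatch for id '%s'", iid[i])
    }
    list(image = img, label = lab)
  })
}

#' Load a DRIVE-layout directory
#'
#' Expects `root/training` and `root/test`, each with `images/`,
#' `1st_manual/` and `mask/` subdirectories; files are paired by their
#' leading numeric id and returned sorted by id. Unpaired files are an
#' error naming the orphans.
#'
#' @param root dataset root directory.
#' @return A list with elements `training` and `test`, each a list of
#'   `list(image =` [fundus_image]`, label =` [label_image]`)` pairs.
#' @export
load_drive_split <- function(root) {
  if (!dir.exists(root)) stopf("'%s' is not a directory", root)
  for (s in c("training", "test")) {
    if (!dir.exists(file.path(root, s))) {
      stopf("'%s' does not follow the DRIVE layout: missing '%s/'", root, s)
    }
  }
  list(training = load_drive_subdir(file.path(root, "training")),
       test = load_drive_subdir(file.path(root, "test")))
}
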