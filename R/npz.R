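# Minimal NPY v1.0 / NPZ reader-writer.
#
# Patch caches and model checkpoints use the NPZ dialect (a zip of .npy
# members) so they can be inspected with standard numpy tooling. Supported
# dtypes: '<f8' (double), '<i4' (integer), '|u1' (raw bytes). Arrays are
# written in Fortran order, matching R's column-major layout.

npy_write <- function(x, path) {
  if (is.raw(x)) {
    descr <- "|u1"
    dims <- length(x)
  } else {
    dims <- if (is.null(dim(x))) length(x) else dim(x)
    descr <- if (is.integer(x)) "<i4" else "<f8"
  }
  shape <- if (length(dims) == 1) sprintf("(%d,)", dims) else
    sprintf("(%s)", paste(dims, collapse = ", "))
  hdr <- sprintf("{'descr': '%s', 'fortran_order': True, 'shape': %s, }",
                 descr, shape)
  base <- 6 + 2 + 2  # magic + version + header length field
  pad <- 64 - ((base + nchar(hdr) + 1) %% 64)
  if (pad == 64) pad <- 0
  hdr <- paste0(hdr, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59, 0x01, 0x00)), con)
  writeBin(as.integer(nchar(hdr)), con, size = 2, endian = "little")
  writeChar(hdr, con, eos = NULL)
  if (is.raw(x)) {
    writeBin(x, con)
  } else if (is.integer(x)) {
    writeBin(as.vector(x), con, size = 4, endian = "little")
  } else {
    writeBin(as.vector(as.double(x)), con, size = 8, endian = "little")
  }
  invisible(path)
}

npy_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 8)
  if (!identical(magic[1:6],
                 as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59)))) {
    stopf("'%s' is not an NPY file", path)
  }
  hlen <- readBin(con, "integer", size = 2, endian = "little", signed = FALSE)
  hdr <- rawToChar(readBin(con, "raw", n = hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", hdr)
  fortran <- grepl("'fortran_order':\\s*True", hdr)
  shp <- sub(".*'shape': \\(([0-9, ]*)\\).*", "\\1", hdr)
  dims <- as.integer(strsplit(gsub("\\s", "", shp), ",")[[1]])
  if (length(dims) == 0 || all(is.na(dims))) dims <- integer(0)
  n <- if (length(dims) == 0) 1L else prod(dims)
  x <- switch(descr,
    "<f8" = readBin(con, "double", n = n, size = 8, endian = "little"),
    "<i4" = readBin(con, "integer", n = n, size = 4, endian = "little"),
    "|u1" = readBin(con, "raw", n = n),
    stopf("unsupported NPY dtype '%s' in '%s'", descr, path))
  if (length(dims) > 1) {
    if (!fortran) dims <- rev(dims)
    dim(x) <- dims
    if (!fortran) x <- aperm(x, rev(seq_along(dims)))
  }
  x
}

#' Write a named list of arrays as an NPZ container
#'
#' @param path output `.npz` path.
#' @param arrays named list; each element a double/integer array/vector or a
#'   raw vector.
#' @return `path`, invisibly.
#' @export
npz_write <- function(path, arrays) {
  if (is.null(names(arrays)) || any(names(arrays) == "")) {
    stopf("npz_write: all arrays must be named")
  }
  tmp <- tempfile("npz")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  files <- character(0)
  for (nm in names(arrays)) {
    f <- file.path(tmp, paste0(nm, ".npy"))
    npy_write(arrays[[nm]], f)
    files <- c(files, f)
  }
  path <- normalizePath(path, mustWork = FALSE)
  zip::zip(path, files = basename(files), root = tmp,
           include_directories = FALSE)
  invisible(path)
}

#' Read an NPZ container into a named list
#'
#' @param path `.npz` path.
#' @return Named list of arrays (names without the `.npy` suffix).
#' @export
npz_read <- function(path) {
  if (!file.exists(path)) stopf("cannot read '%s': file does not exist", path)
  tmp <- tempfile("npz")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  zip::unzip(path, exdir = tmp)
  files <- list.files(tmp, pattern = "\\.npy$", full.names = TRUE)
  out <- lapply(files, npy_read)
  names(out) <- sub("\\.npy$", "", basename(files))
  out
}
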