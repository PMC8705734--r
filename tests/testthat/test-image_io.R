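# image IO: PNG read/write, label thresholding, DRIVE layout loading

test_that("read_fundus preserves shape and channel structure", {
  # color round trip
  f <- withr::local_tempfile(fileext = ".png")
  px <- array(runif(60 * 50 * 3), dim = c(60, 50, 3))
  png::writePNG(px, f)
  img <- read_fundus(f)
  expect_s3_class(img, "fundus_image")
  expect_identical(dim(img$pixels), c(60L, 50L, 3L))
  expect_identical(img$pixels, array(as.integer(round(px * 255)),
                                     dim = c(60, 50, 3)))

  # grayscale replicated to three identical channels, with a warning
  g <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(runif(50 * 60), 50, 60), g)
  expect_warning(img2 <- read_fundus(g), "grayscale")
  expect_identical(img2$pixels[, , 1], img2$pixels[, , 2])
  expect_identical(img2$pixels[, , 2], img2$pixels[, , 3])

  # alpha channel dropped silently
  a <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(runif(48 * 48 * 4), dim = c(48, 48, 4)), a)
  expect_identical(dim(read_fundus(a)$pixels), c(48L, 48L, 3L))
})

test_that("read_fundus rejects unreadable and unsupported files", {
  # truncated PNG
  f <- withr::local_tempfile(fileext = ".png")
  ok <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(runif(48 * 48 * 3), dim = c(48, 48, 3)), ok)
  writeBin(readBin(ok, "raw", 60), f)
  expect_error(read_fundus(f), f, fixed = TRUE)

  expect_error(read_fundus(file.path(tempdir(), "nope.png")), "does not exist")

  # DRIVE's native formats are a documented limitation of this build
  tf <- withr::local_tempfile(fileext = ".tif")
  writeBin(as.raw(c(0x49, 0x49, 0x2a, 0x00, 1:20)), tf)
  expect_error(read_fundus(tf), "TIFF/GIF")
})

test_that("read_label thresholds at 50% of max and rejects non-binary grids", {
  f <- withr::local_tempfile(fileext = ".png")
  m <- matrix(sample(c(0, 1), 30 * 40, replace = TRUE), 30, 40)
  png::writePNG(m, f)  # values {0, 255} on disk
  lab <- read_label(f)
  expect_identical(lab$vessels, matrix(as.integer(m), 30, 40))

  png::writePNG(matrix(0, 20, 20), f)
  expect_identical(read_label(f)$vessels, matrix(0L, 20, 20))

  png::writePNG(matrix(c(0, 100, 200) / 255, 30, 30), f)
  expect_error(read_label(f), "3 distinct values")
})

test_that("write_mask round-trips bit-exactly and validates input", {
  f <- withr::local_tempfile(fileext = ".png")
  m <- matrix(rbinom(48 * 60, 1, 0.2), 48, 60)
  write_mask(m, f)
  expect_identical(read_label(f)$vessels, matrix(as.integer(m), 48, 60))

  # a 1-valued mask is written as full intensity 255
  write_mask(matrix(1, 1, 1), f)
  expect_equal(as.vector(png::readPNG(f)), 1)

  expect_error(write_mask(matrix(c(0, 0.5), 1, 2), f), "binary")
  expect_error(write_mask(m, file.path(tempdir(), "no/such/dir/x.png")),
               "cannot write")
})

test_that("DRIVE layout loads as sorted, paired training/test splits", {
  root <- withr::local_tempdir()
  tr <- small_samples(2, seed = 310)
  te <- small_samples(2, seed = 311)
  write_drive_layout(tr, te, root)

  split <- load_drive_split(root)
  expect_length(split$training, 2)
  expect_length(split$test, 2)
  for (s in c("training", "test")) {
    ids_img <- vapply(split[[s]], function(p) p$image$image_id, "")
    ids_lab <- vapply(split[[s]], function(p) p$label$image_id, "")
    expect_identical(ids_img, ids_lab)     # loader never reorders pairs
    expect_identical(ids_img, sort(ids_img))
    for (p in split[[s]]) expect_false(is.null(p$image$fov_mask))
  }
  # labels survive the disk round trip exactly
  expect_identical(split$test[[1]]$label$vessels, te[[1]]$label$vessels)

  # orphan detection names the file
  unlink(file.path(root, "test", "1st_manual", "01_manual1.png"))
  expect_error(load_drive_split(root), "01")

  expect_error(load_drive_split(withr::local_tempdir()), "DRIVE layout")
})
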