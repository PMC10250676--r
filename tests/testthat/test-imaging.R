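test_that("gray_image validates pixels and bit depth", {
  img <- gray_image(matrix(0:255, 16, 16))
  expect_s3_class(img, "gray_image")
  expect_identical(bit_depth(img), 8L)
  expect_error(gray_image(matrix(-1, 2, 2)), class = "stromatex_error_validation")
  expect_error(gray_image(matrix(256, 2, 2), bit_depth = 8),
               class = "stromatex_error_validation")
  expect_error(gray_image(matrix(2, 2, 2), bit_depth = 1),
               class = "stromatex_error_validation")
  expect_error(gray_image(1:4), class = "stromatex_error_validation")
})

test_that("RGB to gray uses the BT.601 luma weights", {
  mk <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))
  expect_equal(as.integer(rgb_to_gray(mk(0, 0, 0))), 0L)
  expect_equal(as.integer(rgb_to_gray(mk(255, 255, 255))), 255L)
  expect_equal(as.integer(rgb_to_gray(mk(100, 150, 200))), 141L)
  # per-pixel oracle on a random RGB raster
  set.seed(5)
  rgb <- array(sample(0:255, 10 * 7 * 3, replace = TRUE), dim = c(10, 7, 3))
  got <- rgb_to_gray(rgb)
  expected <- matrix(0L, 10, 7)
  for (r in 1:10) {
    for (c in 1:7) {
      expected[r, c] <- as.integer(round(
        0.299 * rgb[r, c, 1] + 0.587 * rgb[r, c, 2] + 0.114 * rgb[r, c, 3]
      ))
    }
  }
  expect_identical(unclass(got)[, ], expected)
  expect_error(rgb_to_gray(mk(300, 0, 0)), class = "stromatex_error_validation")
})

test_that("quantization is the floor map, idempotent, and commutes with crop", {
  img <- gray_image(matrix(c(0L, 255L, 16L, 17L), 2, 2))
  q4 <- quantize_levels(img, 4)
  expect_identical(as.integer(q4), as.integer(c(0, 15, 1, 1)))
  expect_identical(bit_depth(q4), 4L)
  expect_identical(quantize_levels(img, 8), img)
  set.seed(1)
  big <- gray_image(matrix(sample(0:255, 100, replace = TRUE), 10, 10))
  expect_identical(
    quantize_levels(crop_image(big, 2, 3, 5), 4),
    crop_image(quantize_levels(big, 4), 2, 3, 5)
  )
  expect_error(quantize_levels(img, 0), class = "stromatex_error_validation")
  expect_error(quantize_levels(img, 9), class = "stromatex_error_validation")
})

test_that("crop uses 0-based half-open coordinates", {
  ramp <- gray_image(matrix(0:99, 10, 10))
  full <- crop_image(ramp, 0, 0, 10)
  expect_identical(unclass(full), unclass(ramp))
  sub <- crop_image(ramp, 1, 1, 3)
  for (r in 1:3) {
    for (c in 1:3) {
      expect_identical(sub[r, c], ramp[1 + r, 1 + c])
    }
  }
  expect_error(crop_image(ramp, 8, 0, 3), class = "stromatex_error_validation")
})

test_that("PNG round trip is bit exact", {
  skip_if_not_installed("png")
  set.seed(11)
  img <- gray_image(matrix(sample(0:255, 30 * 20, replace = TRUE), 30, 20))
  path <- withr::local_tempfile(fileext = ".png")
  write_micrograph(img, path)
  back <- read_micrograph(path)
  expect_identical(unclass(back), unclass(img))
})

test_that("24-bit and 8-bit BMP files read back with correct luma values", {
  set.seed(3)
  r <- matrix(sample(0:255, 35, replace = TRUE), 5, 7)
  g <- matrix(sample(0:255, 35, replace = TRUE), 5, 7)
  b <- matrix(sample(0:255, 35, replace = TRUE), 5, 7)
  p24 <- withr::local_tempfile(fileext = ".bmp")
  write_bmp24(r, g, b, p24)
  got <- read_micrograph(p24)
  expect_identical(dim(unclass(got)), c(5L, 7L))
  expect_identical(unclass(got)[, ],
                   matrix(as.integer(round(0.299 * r + 0.587 * g + 0.114 * b)), 5, 7))

  px <- matrix(sample(0:255, 6 * 9, replace = TRUE), 6, 9)
  p8 <- withr::local_tempfile(fileext = ".bmp")
  write_bmp8_gray(px, p8)
  got8 <- read_micrograph(p8)
  expect_identical(unclass(got8)[, ], matrix(as.integer(px), 6, 9))

  # all-white 24-bit image maps to the max gray level
  white <- matrix(255L, 4, 4)
  pw <- withr::local_tempfile(fileext = ".bmp")
  write_bmp24(white, white, white, pw)
  expect_true(all(unclass(read_micrograph(pw)) == 255L))
})

test_that("unreadable or unsupported inputs raise typed errors", {
  expect_error(read_micrograph("does/not/exist.png"), class = "stromatex_error_io")
  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines("x", bad)
  expect_error(read_micrograph(bad), class = "stromatex_error_format")
  notbmp <- withr::local_tempfile(fileext = ".bmp")
  writeBin(as.raw(rep(0, 100)), notbmp)
  expect_error(read_micrograph(notbmp), class = "stromatex_error_format")
})

test_that("ROI extraction is seeded, in bounds, and reproducible", {
  set.seed(2)
  img <- gray_image(matrix(sample(0:255, 400 * 300, replace = TRUE), 400, 300))
  rois <- extract_rois(img, n = 3, size = 100, seed = 9, image_id = "m1")
  expect_identical(nrow(rois), 3L)
  expect_true(all(rois$row0 >= 0 & rois$row0 + rois$size <= 400))
  expect_true(all(rois$col0 >= 0 & rois$col0 + rois$size <= 300))
  again <- extract_rois(img, n = 3, size = 100, seed = 9, image_id = "m1")
  expect_identical(rois, again)
  different <- extract_rois(img, n = 3, size = 100, seed = 10, image_id = "m1")
  expect_false(identical(rois, different))
})

test_that("full-frame ROI is the only placement at maximal size", {
  sq <- gray_image(matrix(0:24, 5, 5))
  roi <- extract_rois(sq, n = 1, size = 5, seed = 1)
  expect_identical(roi$row0, 0L)
  expect_identical(roi$col0, 0L)
})

test_that("non-overlapping extraction yields pairwise-disjoint ROIs", {
  img <- gray_image(matrix(0L, 20, 20))
  rois <- extract_rois(img, n = 4, size = 10, seed = 21, allow_overlap = FALSE)
  expect_identical(nrow(rois), 4L)
  # brute-force rectangle intersection over all pairs
  for (a in 1:3) {
    for (b in (a + 1):4) {
      overlap_rows <- max(0, min(rois$row0[a], rois$row0[b]) + 10 -
                               max(rois$row0[a], rois$row0[b]))
      overlap_cols <- max(0, min(rois$col0[a], rois$col0[b]) + 10 -
                               max(rois$col0[a], rois$col0[b]))
      expect_identical(overlap_rows * overlap_cols, 0)
    }
  }
  expect_error(
    extract_rois(img, n = 5, size = 10, seed = 21, allow_overlap = FALSE,
                 max_attempts = 50),
    class = "stromatex_error_placement"
  )
  expect_error(extract_rois(img, n = 1, size = 21),
               class = "stromatex_error_validation")
})

test_that("ROI manifests crop against their source images", {
  imgs <- list(
    a = gray_image(matrix(0:99, 10, 10)),
    b = gray_image(matrix(100:199, 10, 10))
  )
  manifest <- tibble::tibble(
    image_id = c("a", "b"), row0 = c(0L, 2L), col0 = c(0L, 3L), size = 4L
  )
  crops <- crop_rois(manifest, imgs)
  expect_identical(unclass(crops[[1]]), unclass(crop_image(imgs$a, 0, 0, 4)))
  expect_identical(unclass(crops[[2]]), unclass(crop_image(imgs$b, 2, 3, 4)))
  manifest$image_id[2] <- "zzz"
  expect_error(crop_rois(manifest, imgs), class = "stromatex_error_validation")
})
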