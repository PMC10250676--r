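#' Construct a grayscale image
#'
#' A `gray_image` is an integer matrix of gray levels (row-major, origin at
#' the top-left) together with its bit depth. All texture computations in the
#' package consume this type. Pixel values must lie in
#' `[0, 2^bit_depth - 1]`.
#'
#' @param pixels Numeric or integer matrix of gray levels. Rows index the
#'   vertical (y) axis, columns the horizontal (x) axis.
#' @param bit_depth Bits per gray level; the image has `2^bit_depth` levels.
#'   Default 8 (256 levels), the usual depth for brightfield micrographs
#'   converted to grayscale.
#' @return An object of class `gray_image`: an integer matrix with a
#'   `bit_depth` attribute.
#' @examples
#' img <- gray_image(matrix(0:255, 16, 16), bit_depth = 8)
#' dim(img)
#' @export
gray_image <- function(pixels, bit_depth = 8L) {
  if (!is.matrix(pixels)) {
    abort_validation("`pixels` must be a matrix.")
  }
  if (nrow(pixels) < 1 || ncol(pixels) < 1) {
    abort_validation("Image must have at least one row and one column.")
  }
  bit_depth <- as.integer(bit_depth)
  if (is.na(bit_depth) || bit_depth < 1L || bit_depth > 16L) {
    abort_validation("`bit_depth` must be an integer in [1, 16].")
  }
  px <- pixels
  if (is.double(px)) {
    if (any(abs(px - round(px)) > 1e-8, na.rm = TRUE)) {
      abort_validation("Pixel values must be whole numbers.")
    }
    px <- round(px)
  }
  storage.mode(px) <- "integer"
  if (anyNA(px)) abort_validation("Pixel values must not be missing.")
  lim <- 2L^bit_depth - 1L
  if (min(px) < 0L || max(px) > lim) {
    abort_validation(sprintf(
      "Pixel values must lie in [0, %d] for bit depth %d.", lim, bit_depth
    ))
  }
  structure(px, bit_depth = bit_depth, class = c("gray_image", "matrix", "array"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf(
    "<gray_image> %d x %d, %d-bit (%d levels), range [%d, %d]\n",
    nrow(x), ncol(x), bit_depth(x), 2L^bit_depth(x), min(x), max(x)
  ))
  invisible(x)
}

#' Bit depth of a grayscale image
#' @param img A `gray_image`.
#' @return Integer number of bits per gray level.
#' @export
bit_depth <- function(img) {
  attr(img, "bit_depth", exact = TRUE)
}

is_gray_image <- function(x) inherits(x, "gray_image")

assert_gray_image <- function(img, arg = "img") {
  if (!is_gray_image(img)) {
    abort_validation(sprintf("`%s` must be a gray_image.", arg))
  }
  invisible(img)
}

#' Convert RGB pixel data to grayscale
#'
#' Collapses an RGB raster to 8-bit gray levels using the ITU-R BT.601 luma
#' weights `0.299 R + 0.587 G + 0.114 B`, the conventional conversion for
#' brightfield color micrographs.
#'
#' @param rgb A `height x width x 3` numeric array with channel values in
#'   `[0, 255]`.
#' @return A `gray_image` with `bit_depth = 8`.
#' @examples
#' px <- array(c(100, 150, 200), dim = c(1, 1, 3))
#' rgb_to_gray(px)  # round(0.299*100 + 0.587*150 + 0.114*200) = 141
#' @export
rgb_to_gray <- function(rgb) {
  if (!is.array(rgb) || length(dim(rgb)) != 3L || dim(rgb)[3] != 3L) {
    abort_validation("`rgb` must be a height x width x 3 array.")
  }
  if (anyNA(rgb) || min(rgb) < 0 || max(rgb) > 255) {
    abort_validation("RGB channel values must lie in [0, 255].")
  }
  g <- 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  g <- pmin(pmax(round(g), 0), 255)
  gray_image(matrix(g, nrow = dim(rgb)[1]), bit_depth = 8L)
}

#' Read a micrograph from disk
#'
#' Reads a PNG, TIFF or uncompressed BMP raster and returns it as an 8-bit
#' `gray_image`. 24-bit RGB inputs are converted with [rgb_to_gray()];
#' already-grayscale inputs pass through unchanged.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff` or `.bmp` file.
#' @return A `gray_image` with `bit_depth = 8`.
#' @export
read_micrograph <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    abort_validation("`path` must be a single file path.")
  }
  if (!file.exists(path)) {
    abort_io(sprintf("File not found: '%s'.", path))
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = {
      if (!requireNamespace("png", quietly = TRUE)) {
        abort_config("Package 'png' is required to read PNG files.")
      }
      tryCatch(png::readPNG(path), error = function(e) {
        abort_io(sprintf("Failed to read PNG '%s': %s", path, conditionMessage(e)))
      })
    },
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        abort_config("Package 'tiff' is required to read TIFF files.")
      }
      tryCatch(tiff::readTIFF(path), error = function(e) {
        abort_io(sprintf("Failed to read TIFF '%s': %s", path, conditionMessage(e)))
      })
    },
    bmp = return(read_bmp(path)),
    abort_format(sprintf("Unsupported raster format '.%s' for '%s'.", ext, path))
  )
  raster_to_gray(arr, path)
}

# Normalize the [0,1]-scaled array png/tiff return into a gray_image.
raster_to_gray <- function(arr, path) {
  if (is.matrix(arr)) {
    return(gray_image(round(arr * 255), bit_depth = 8L))
  }
  if (is.array(arr) && length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    if (nc == 3L) {
      return(rgb_to_gray(arr * 255))
    }
    if (nc == 2L) {
      # gray + alpha: keep the gray channel only if alpha is trivial
      if (all(arr[, , 2] == 1)) {
        return(gray_image(round(arr[, , 1] * 255), bit_depth = 8L))
      }
      abort_format(sprintf("Unsupported color model (gray + alpha) in '%s'.", path))
    }
    if (nc == 4L) {
      if (all(arr[, , 4] == 1)) {
        return(rgb_to_gray(arr[, , 1:3] * 255))
      }
      abort_format(sprintf("Unsupported color model (RGBA with transparency) in '%s'.", path))
    }
  }
  abort_format(sprintf("Unsupported raster layout in '%s'.", path))
}

# Minimal reader for uncompressed (BI_RGB) Windows BMP files: 24-bit RGB and
# 8-bit paletted images, both bottom-up and top-down row orders. No installed
# R package reads BMP, and the format's uncompressed variants are simple
# fixed-layout rasters.
read_bmp <- function(path) {
  raw <- tryCatch(readBin(path, "raw", n = file.info(path)$size),
    error = function(e) abort_io(sprintf("Failed to read '%s': %s", path, conditionMessage(e)))
  )
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.numeric(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  i32 <- function(off) {
    v <- u32(off)
    if (v >= 2147483648) v - 4294967296 else v
  }
  if (length(raw) < 54 || rawToChar(raw[1:2]) != "BM") {
    abort_format(sprintf("'%s' is not a BMP file.", path))
  }
  data_off <- u32(10)
  header_size <- u32(14)
  if (header_size < 40) abort_format(sprintf("Unsupported BMP header in '%s'.", path))
  width <- i32(18)
  height_raw <- i32(22)
  bpp <- u16(28)
  compression <- u32(30)
  if (compression != 0) {
    abort_format(sprintf("Compressed BMP (method %d) is not supported: '%s'.", compression, path))
  }
  if (!bpp %in% c(8, 24)) {
    abort_format(sprintf("Only 8-bit and 24-bit uncompressed BMP are supported (got %d-bit): '%s'.", bpp, path))
  }
  top_down <- height_raw < 0
  height <- abs(height_raw)
  if (width < 1 || height < 1) abort_format(sprintf("Degenerate BMP dimensions in '%s'.", path))
  row_bytes <- ceiling(width * bpp / 8 / 4) * 4
  need <- data_off + row_bytes * height
  if (length(raw) < need) {
    abort_io(sprintf("Truncated BMP '%s': expected %d bytes, found %d.", path, need, length(raw)))
  }
  if (bpp == 8) {
    n_colors <- u32(46)
    if (n_colors == 0) n_colors <- 256
    pal_off <- 14 + header_size
    pal <- matrix(as.integer(raw[pal_off + seq_len(4 * n_colors)]), ncol = 4, byrow = TRUE)
    # palette entries are stored B, G, R, reserved
    pal_gray <- pmin(pmax(round(0.299 * pal[, 3] + 0.587 * pal[, 2] + 0.114 * pal[, 1]), 0), 255)
    out <- matrix(0L, nrow = height, ncol = width)
    for (r in seq_len(height)) {
      row <- as.integer(raw[data_off + (r - 1) * row_bytes + seq_len(width)])
      dest <- if (top_down) r else height - r + 1L
      out[dest, ] <- pal_gray[row + 1L]
    }
    return(gray_image(out, bit_depth = 8L))
  }
  out <- matrix(0L, nrow = height, ncol = width)
  for (r in seq_len(height)) {
    row <- as.integer(raw[data_off + (r - 1) * row_bytes + seq_len(3 * width)])
    b <- row[seq(1, 3 * width, by = 3)]
    g <- row[seq(2, 3 * width, by = 3)]
    rr <- row[seq(3, 3 * width, by = 3)]
    dest <- if (top_down) r else height - r + 1L
    out[dest, ] <- pmin(pmax(round(0.299 * rr + 0.587 * g + 0.114 * b), 0), 255)
  }
  gray_image(out, bit_depth = 8L)
}

#' Write a grayscale image to a PNG file
#'
#' @param img A `gray_image` (8-bit).
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(img, path) {
  assert_gray_image(img)
  if (bit_depth(img) != 8L) {
    abort_validation("Only 8-bit images can be written to PNG.")
  }
  if (!requireNamespace("png", quietly = TRUE)) {
    abort_config("Package 'png' is required to write PNG files.")
  }
  png::writePNG(unclass(img) / 255, target = path)
  invisible(path)
}

#' Reduce the number of gray levels of an image
#'
#' Requantizes gray levels to a smaller bit depth by the order-preserving map
#' `floor(pixel / 2^(bit_depth - target_bits))`. GLCM feature magnitudes
#' depend on the number of gray levels, so features are always reported
#' together with the bit depth they were computed at; this function supports
#' sensitivity analyses over that choice.
#'
#' @param img A `gray_image`.
#' @param target_bits Target bit depth, `1 <= target_bits <= bit_depth(img)`.
#' @return A `gray_image` with `bit_depth = target_bits`.
#' @examples
#' img <- gray_image(matrix(c(0, 255), 1, 2))
#' quantize_levels(img, 4)  # 255 -> floor(255/16) = 15
#' @export
quantize_levels <- function(img, target_bits) {
  assert_gray_image(img)
  target_bits <- as.integer(target_bits)
  bd <- bit_depth(img)
  if (is.na(target_bits) || target_bits < 1L || target_bits > bd) {
    abort_validation(sprintf("`target_bits` must be in [1, %d].", bd))
  }
  if (target_bits == bd) return(img)
  shift <- 2L^(bd - target_bits)
  gray_image(unclass(img) %/% shift, bit_depth = target_bits)
}

#' Crop a square region out of an image
#'
#' Coordinates are 0-based with half-open extents: the crop covers rows
#' `[row0, row0 + size)` and columns `[col0, col0 + size)` of the source.
#'
#' @param img A `gray_image`.
#' @param row0,col0 Top-left corner (0-based).
#' @param size Side length in pixels.
#' @return A `size x size` `gray_image`.
#' @export
crop_image <- function(img, row0, col0, size) {
  assert_gray_image(img)
  row0 <- as.integer(row0); col0 <- as.integer(col0); size <- as.integer(size)
  if (anyNA(c(row0, col0, size))) abort_validation("Crop coordinates must be integers.")
  if (size < 1L) abort_validation("`size` must be >= 1.")
  if (row0 < 0L || col0 < 0L ||
      row0 + size > nrow(img) || col0 + size > ncol(img)) {
    abort_validation(sprintf(
      "Crop [%d, %d) x [%d, %d) exceeds the %d x %d image.",
      row0, row0 + size, col0, col0 + size, nrow(img), ncol(img)
    ))
  }
  gray_image(unclass(img)[row0 + seq_len(size), col0 + seq_len(size), drop = FALSE],
             bit_depth = bit_depth(img))
}

#' Display a grayscale image with ggplot2
#'
#' @param object A `gray_image`.
#' @param ... Unused.
#' @return A ggplot object rendering the image as a raster.
#' @export
autoplot.gray_image <- function(object, ...) {
  df <- tibble::tibble(
    col = rep(seq_len(ncol(object)), each = nrow(object)),
    row = rep(seq_len(nrow(object)), times = ncol(object)),
    gray = as.vector(unclass(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$gray)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 2^bit_depth(object) - 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal(expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, fill = "gray") +
    ggplot2::theme_minimal()
}
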