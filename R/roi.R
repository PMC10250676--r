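#' Extract square regions of interest from an image
#'
#' Draws `n` square ROIs with top-left corners sampled uniformly from all
#' valid positions, using a seeded generator so placements are reproducible.
#' The original analysis used manually chosen "representative" 300 x 300
#' windows; seeded uniform placement replaces that manual step with a
#' reproducible one.
#'
#' @param img A `gray_image`.
#' @param n Number of ROIs to draw.
#' @param size Side length in pixels (default 300).
#' @param seed Integer seed for the placement generator.
#' @param allow_overlap If `FALSE`, ROIs are drawn by rejection sampling until
#'   pairwise disjoint (bounded attempts).
#' @param image_id Identifier recorded with each ROI (default `"image"`).
#' @param label Optional class label recorded with each ROI.
#' @param max_attempts Attempt budget for non-overlapping placement.
#' @return A tibble with columns `image_id`, `row0`, `col0`, `size`, `label`;
#'   corners are 0-based and extents half-open, so ROI `r` covers rows
#'   `[row0, row0 + size)`.
#' @examples
#' img <- gray_image(matrix(0L, 40, 40))
#' extract_rois(img, n = 3, size = 10, seed = 1)
#' @export
extract_rois <- function(img, n, size = 300L, seed = 1L, allow_overlap = TRUE,
                         image_id = "image", label = NA_character_,
                         max_attempts = 10000L) {
  assert_gray_image(img)
  n <- as.integer(n); size <- as.integer(size)
  if (is.na(n) || n < 1L) abort_validation("`n` must be a positive integer.")
  if (is.na(size) || size < 2L) abort_validation("`size` must be >= 2 (a GLCM needs at least one pixel pair).")
  max_r <- nrow(img) - size
  max_c <- ncol(img) - size
  if (max_r < 0L || max_c < 0L) {
    abort_validation(sprintf(
      "ROI size %d exceeds the %d x %d image.", size, nrow(img), ncol(img)
    ))
  }
  corners <- with_seed(derive_seed(seed, 101L), {
    if (allow_overlap) {
      tibble::tibble(
        row0 = sample.int(max_r + 1L, n, replace = TRUE) - 1L,
        col0 = sample.int(max_c + 1L, n, replace = TRUE) - 1L
      )
    } else {
      # rejection sampling first; tight packings that rejection cannot reach
      # fall back to sampling cells of the disjoint size x size tiling
      placed <- matrix(integer(0), ncol = 2)
      attempts <- 0L
      while (nrow(placed) < n && attempts < max_attempts) {
        attempts <- attempts + 1L
        r0 <- sample.int(max_r + 1L, 1L) - 1L
        c0 <- sample.int(max_c + 1L, 1L) - 1L
        if (nrow(placed) == 0L ||
            all(abs(placed[, 1] - r0) >= size | abs(placed[, 2] - c0) >= size)) {
          placed <- rbind(placed, c(r0, c0))
        }
      }
      if (nrow(placed) < n) {
        tiles_r <- nrow(img) %/% size
        tiles_c <- ncol(img) %/% size
        if (tiles_r * tiles_c < n) {
          abort_placement(sprintf(
            "Could not place %d non-overlapping %d x %d ROIs after %d attempts (placed %d); the image only tiles %d disjoint ROIs.",
            n, size, size, attempts, nrow(placed), tiles_r * tiles_c
          ))
        }
        cells <- sample.int(tiles_r * tiles_c, n) - 1L
        placed <- cbind((cells %% tiles_r) * size, (cells %/% tiles_r) * size)
      }
      tibble::tibble(row0 = as.integer(placed[, 1]), col0 = as.integer(placed[, 2]))
    }
  })
  tibble::tibble(
    image_id = image_id,
    row0 = corners$row0,
    col0 = corners$col0,
    size = size,
    label = label
  )
}

#' Crop the ROIs described by a manifest out of their source images
#'
#' @param rois A tibble with columns `image_id`, `row0`, `col0`, `size` (as
#'   produced by [extract_rois()] or read from a ROI manifest CSV).
#' @param images Either a single `gray_image` (used for all ROIs) or a named
#'   list of `gray_image`s keyed by `image_id`.
#' @return A list of `gray_image` crops, one per manifest row.
#' @export
crop_rois <- function(rois, images) {
  required <- c("image_id", "row0", "col0", "size")
  if (!all(required %in% names(rois))) {
    abort_validation(sprintf(
      "ROI manifest must have columns: %s.", paste(required, collapse = ", ")
    ))
  }
  purrr::pmap(
    list(rois$image_id, rois$row0, rois$col0, rois$size),
    function(id, r0, c0, sz) {
      img <- if (is_gray_image(images)) {
        images
      } else {
        if (!id %in% names(images)) {
          abort_validation(sprintf("ROI references unknown image_id '%s'.", id))
        }
        images[[id]]
      }
      crop_image(img, r0, c0, sz)
    }
  )
}
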