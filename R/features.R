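#' Full texture feature vector of one region of interest
#'
#' Combines the five GLCM features and the three wavelet detail-subband
#' energies into a single one-row tibble, together with the configuration
#' (bit depth, offset, symmetry, wavelet) they were computed at.
#'
#' @param img A `gray_image` (the ROI).
#' @param bits,offset,symmetric Passed to [glcm_features()].
#' @param wavelet Passed to [wavelet_energies()].
#' @return A one-row tibble with the eight features `asm`, `idm`, `contrast`,
#'   `correlation`, `sum_variance`, `en_lh`, `en_hl`, `en_hh` plus config
#'   columns. Constant-texture ROIs raise an `undefined_feature` error
#'   (correlation does not exist there).
#' @export
texture_features <- function(img, bits = 8L, offset = c(0L, 1L),
                             symmetric = FALSE, wavelet = "haar") {
  g <- glcm_features(img, bits = bits, offset = offset, symmetric = symmetric)
  w <- wavelet_energies(img, wavelet = wavelet)
  dplyr::bind_cols(
    g[, c("asm", "idm", "contrast", "correlation", "sum_variance")],
    w[, c("en_lh", "en_hl", "en_hh")],
    g[, c("bits", "offset_row", "offset_col", "symmetric")],
    w[, c("wavelet", "level")]
  )
}

texture_feature_names <- function() {
  c("idm", "contrast", "correlation", "asm", "sum_variance",
    "en_lh", "en_hl", "en_hh")
}

#' Compute the per-ROI feature table for a set of images
#'
#' The workhorse that turns labeled images (and optionally a ROI manifest)
#' into the samples-by-features table consumed by the group statistics and
#' the classifiers. ROIs whose correlation feature is undefined (constant
#' texture) are dropped, with a message reporting how many.
#'
#' @param images A tibble with columns `image_id`, `label` and a list column
#'   `image` of `gray_image`s, as returned by [generate_micrograph_set()].
#' @param rois Optional ROI manifest tibble (`image_id`, `row0`, `col0`,
#'   `size`); when `NULL` (default) each image contributes one full-frame
#'   ROI.
#' @param bits,offset,symmetric,wavelet Feature configuration, see
#'   [texture_features()].
#' @return A tibble with one row per retained ROI: `image_id`, `row0`,
#'   `col0`, `size`, `label`, the eight features and the config columns.
#' @export
compute_feature_table <- function(images, rois = NULL, bits = 8L,
                                  offset = c(0L, 1L), symmetric = FALSE,
                                  wavelet = "haar") {
  req <- c("image_id", "label", "image")
  if (!is.data.frame(images) || !all(req %in% names(images))) {
    abort_validation("`images` must have columns image_id, label, image.")
  }
  if (is.null(rois)) {
    rois <- tibble::tibble(
      image_id = images$image_id,
      row0 = 0L,
      col0 = 0L,
      size = purrr::map_int(images$image, nrow)
    )
  }
  if (nrow(rois) == 0L) {
    return(tibble::tibble(
      image_id = character(), row0 = integer(), col0 = integer(),
      size = integer(), label = character()
    ))
  }
  img_lookup <- stats::setNames(images$image, images$image_id)
  lab_lookup <- stats::setNames(images$label, images$image_id)
  missing_ids <- setdiff(unique(rois$image_id), names(img_lookup))
  if (length(missing_ids) > 0L) {
    abort_validation(sprintf(
      "ROI manifest references unknown image_id(s): %s.",
      paste(utils::head(missing_ids, 5), collapse = ", ")
    ))
  }
  dropped <- 0L
  rows <- purrr::pmap(
    list(rois$image_id, rois$row0, rois$col0, rois$size, seq_len(nrow(rois))),
    function(id, r0, c0, sz, k) {
      roi_img <- crop_image(img_lookup[[id]], r0, c0, sz)
      feats <- tryCatch(
        texture_features(roi_img, bits = bits, offset = offset,
                         symmetric = symmetric, wavelet = wavelet),
        stromatex_error_undefined_feature = function(e) NULL
      )
      if (is.null(feats)) {
        dropped <<- dropped + 1L
        return(NULL)
      }
      dplyr::bind_cols(
        tibble::tibble(image_id = id, row0 = as.integer(r0),
                       col0 = as.integer(c0), size = as.integer(sz),
                       label = lab_lookup[[id]]),
        feats
      )
    }
  )
  if (dropped > 0L) {
    rlang::inform(sprintf(
      "Dropped %d ROI(s) with undefined correlation (constant texture).", dropped
    ))
  }
  dplyr::bind_rows(rows)
}
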