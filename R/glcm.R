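#' Gray-level co-occurrence matrix
#'
#' Builds the normalized joint distribution `p(i, j)` of gray-level pairs at
#' a fixed spatial offset. The default offset `(0, 1)` pairs each pixel with
#' its immediate right-hand neighbour, the classical single-direction
#' convention for second-order texture statistics of histology micrographs.
#' By default accumulation is asymmetric (only the `(i, j)` order is
#' counted); `symmetric = TRUE` additionally counts the reversed pair, for
#' comparison with toolkits that symmetrize.
#'
#' @param img A `gray_image`; its bit depth fixes the matrix dimension
#'   `Ng = 2^bit_depth`.
#' @param offset Integer displacement `c(drow, dcol)` from the reference
#'   pixel to its neighbour. Default `c(0, 1)`.
#' @param symmetric Accumulate the reversed pair as well? Default `FALSE`.
#' @return An object of class `glcm`: a list with elements `p` (the
#'   `Ng x Ng` probability matrix over levels `0 .. Ng-1`), `n_levels`,
#'   `offset`, `symmetric` and `pair_count`.
#' @examples
#' img <- gray_image(matrix(c(0L, 0L, 1L, 1L), 2, 2), bit_depth = 1)
#' compute_glcm(img)$p  # all mass on p(0, 1)
#' @export
compute_glcm <- function(img, offset = c(0L, 1L), symmetric = FALSE) {
  assert_gray_image(img)
  offset <- as.integer(offset)
  if (length(offset) != 2L || anyNA(offset)) {
    abort_validation("`offset` must be two integers c(drow, dcol).")
  }
  if (all(offset == 0L)) abort_validation("`offset` must be nonzero.")
  h <- nrow(img); w <- ncol(img)
  dr <- offset[1]; dc <- offset[2]
  if (abs(dr) >= h || abs(dc) >= w) {
    abort_validation(sprintf(
      "Offset (%d, %d) leaves no valid pixel pairs in a %d x %d image.",
      dr, dc, h, w
    ))
  }
  rows <- seq_len(h - abs(dr))
  cols <- seq_len(w - abs(dc))
  if (dr < 0L) rows <- rows + abs(dr)
  if (dc < 0L) cols <- cols + abs(dc)
  px <- unclass(img)
  i <- px[rows, cols, drop = FALSE]
  j <- px[rows + dr, cols + dc, drop = FALSE]
  ng <- 2L^bit_depth(img)
  idx <- as.vector(i) * ng + as.vector(j) + 1L
  counts <- tabulate(idx, nbins = ng * ng)
  if (symmetric) {
    counts <- counts + tabulate(as.vector(j) * ng + as.vector(i) + 1L, nbins = ng * ng)
  }
  total <- sum(counts)
  p <- matrix(counts / total, nrow = ng, ncol = ng, byrow = TRUE)
  structure(
    list(p = p, n_levels = ng, offset = offset, symmetric = symmetric,
         pair_count = length(idx) * (1L + symmetric)),
    class = "glcm"
  )
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf(
    "<glcm> %d levels, offset (%d, %d), %s, %d pairs\n",
    x$n_levels, x$offset[1], x$offset[2],
    if (x$symmetric) "symmetric" else "asymmetric", x$pair_count
  ))
  invisible(x)
}

assert_glcm <- function(G) {
  if (!inherits(G, "glcm")) abort_validation("`G` must be a glcm object.")
  invisible(G)
}

#' Marginal statistics of a co-occurrence matrix
#'
#' Computes the row and column marginals `px`, `py` with their means and
#' standard deviations, and the gray-level-sum distribution `p_{x+y}` with its
#' mean (the sum average). These feed the correlation and sum-variance
#' features.
#'
#' @param G A `glcm` object.
#' @return A list with `px`, `py`, `mu_x`, `mu_y`, `sigma_x`, `sigma_y`,
#'   `p_sum` (indexed by `k = i + j` from 0 to `2(Ng-1)`), and `sum_average`.
#' @export
glcm_marginals <- function(G) {
  assert_glcm(G)
  p <- G$p
  ng <- G$n_levels
  lev <- 0:(ng - 1)
  px <- rowSums(p)
  py <- colSums(p)
  mu_x <- sum(lev * px)
  mu_y <- sum(lev * py)
  sigma_x <- sqrt(max(sum((lev - mu_x)^2 * px), 0))
  sigma_y <- sqrt(max(sum((lev - mu_y)^2 * py), 0))
  # p_{x+y}(k): mass on anti-diagonals i + j = k
  k <- outer(lev, lev, `+`)
  p_sum <- as.vector(tapply(as.vector(p), as.vector(k), sum))
  ks <- 0:(2 * (ng - 1))
  sum_average <- sum(ks * p_sum)
  list(px = px, py = py, mu_x = mu_x, mu_y = mu_y,
       sigma_x = sigma_x, sigma_y = sigma_y,
       p_sum = p_sum, sum_average = sum_average)
}

#' Angular second moment (textural uniformity)
#'
#' `ASM = sum_ij p(i,j)^2`. Equals 1 exactly when all co-occurrence mass sits
#' in a single cell (perfectly uniform texture); small values indicate many
#' distinct gray-level pairs.
#'
#' @param G A `glcm` object.
#' @return A number in `(0, 1]`.
#' @export
glcm_asm <- function(G) {
  assert_glcm(G)
  sum(G$p^2)
}

#' Inverse difference moment (local homogeneity)
#'
#' `IDM = sum_ij p(i,j) / (1 + (i - j)^2)`. Equals 1 exactly when all mass is
#' on the diagonal (neighbouring pixels always equal).
#'
#' @param G A `glcm` object.
#' @return A number in `(0, 1]`.
#' @export
glcm_idm <- function(G) {
  assert_glcm(G)
  lev <- 0:(G$n_levels - 1)
  w <- 1 / (1 + outer(lev, lev, `-`)^2)
  sum(G$p * w)
}

#' GLCM contrast (local intensity variation)
#'
#' `CON = sum_ij (i - j)^2 p(i,j)`, the classical second-moment contrast.
#' Zero exactly when all mass is on the diagonal.
#'
#' @param G A `glcm` object.
#' @return A non-negative number, at most `(Ng - 1)^2`.
#' @export
glcm_contrast <- function(G) {
  assert_glcm(G)
  lev <- 0:(G$n_levels - 1)
  d2 <- outer(lev, lev, `-`)^2
  sum(G$p * d2)
}

#' GLCM correlation (linear dependency of gray levels)
#'
#' `COR = (sum_ij i*j*p(i,j) - mu_x mu_y) / (sigma_x sigma_y)`. Undefined
#' when either marginal is degenerate (e.g. a constant image); that case
#' raises a typed `undefined_feature` error rather than returning NaN, so
#' pipelines can drop such ROIs explicitly.
#'
#' @param G A `glcm` object.
#' @param S Optional precomputed [glcm_marginals()] result.
#' @return A number in `[-1, 1]` (up to numerical slack).
#' @export
glcm_correlation <- function(G, S = glcm_marginals(G)) {
  assert_glcm(G)
  if (S$sigma_x <= 0 || S$sigma_y <= 0) {
    abort_undefined_feature(
      "GLCM correlation is undefined: a marginal has zero variance (constant texture)."
    )
  }
  lev <- 0:(G$n_levels - 1)
  sum_ij <- sum(G$p * outer(lev, lev))
  (sum_ij - S$mu_x * S$mu_y) / (S$sigma_x * S$sigma_y)
}

#' GLCM sum variance (dispersion of gray-level sums)
#'
#' The variance of the gray-level-sum distribution `p_{x+y}` about the sum
#' average: `SVAR = sum_k (k - SA)^2 p_{x+y}(k)` with
#' `SA = sum_k k p_{x+y}(k)`. Zero exactly when `p_{x+y}` is a point mass.
#'
#' @param G A `glcm` object.
#' @param S Optional precomputed [glcm_marginals()] result.
#' @return A non-negative number.
#' @export
glcm_sum_variance <- function(G, S = glcm_marginals(G)) {
  assert_glcm(G)
  ks <- 0:(2 * (G$n_levels - 1))
  sum((ks - S$sum_average)^2 * S$p_sum)
}

#' All five GLCM features of a region of interest
#'
#' Quantizes the ROI to `bits` gray levels, builds the co-occurrence matrix
#' at the requested offset and returns the five second-order features as a
#' one-row tibble together with the configuration they were computed at
#' (feature magnitudes depend on the gray-level count, so the two always
#' travel together).
#'
#' @param img A `gray_image` (the ROI).
#' @param bits Gray-level bit depth used for the GLCM (default 8, i.e. 256
#'   levels). Must not exceed the image's own depth.
#' @param offset,symmetric Passed to [compute_glcm()].
#' @return A one-row tibble with columns `asm`, `idm`, `contrast`,
#'   `correlation`, `sum_variance`, `bits`, `offset_row`, `offset_col`,
#'   `symmetric`. Raises an `undefined_feature` error for constant-texture
#'   ROIs, where correlation does not exist.
#' @export
glcm_features <- function(img, bits = 8L, offset = c(0L, 1L), symmetric = FALSE) {
  assert_gray_image(img)
  q <- quantize_levels(img, bits)
  G <- compute_glcm(q, offset = offset, symmetric = symmetric)
  S <- glcm_marginals(G)
  tibble::tibble(
    asm = glcm_asm(G),
    idm = glcm_idm(G),
    contrast = glcm_contrast(G),
    correlation = glcm_correlation(G, S),
    sum_variance = glcm_sum_variance(G, S),
    bits = as.integer(bits),
    offset_row = as.integer(offset[1]),
    offset_col = as.integer(offset[2]),
    symmetric = symmetric
  )
}
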