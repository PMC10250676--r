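#' Parameters of the synthetic stromal texture model
#'
#' The generator composes, on a `[0, 1]` gray scale: (1) an oriented
#' sinusoidal band pattern standing in for the lamellar collagen fibers,
#' amplitude-modulated by a seeded low-pass noise field so bands wax and wane
#' as they do in sections; (2) sparse dark ellipses standing in for
#' keratocyte nuclei (flattened, hematoxylin-dark, occupying a few percent of
#' the field at most); (3) additive Gaussian speckle noise standing in for
#' fine-grain tissue texture; (4) a Gaussian blur emulating optical blur and
#' treatment-induced homogenization; and (5) an affine map to 8-bit gray
#' levels with clamping. The speckle precedes the blur, so harsher severity
#' grades genuinely read as smoother texture rather than as a blurred pattern
#' under an unchanged noise floor. The defaults target the statistical
#' signature of intact stroma in brightfield sections, not visual realism.
#'
#' @param size Image side length in pixels (default 512).
#' @param fiber_wavelength Dominant lamellar band period in pixels (default 16).
#' @param fiber_orientation Band orientation in radians (default 0.35; the
#'   bands then vary mostly along the horizontal axis probed by the default
#'   GLCM offset).
#' @param fiber_contrast Amplitude of the banding on the `[0, 1]` gray scale
#'   (default 0.18).
#' @param nucleus_density Expected nuclei per 10^4 pixels (default 2; nuclei
#'   then cover under 2 percent of the frame, consistent with the sparsity of
#'   keratocytes in stroma).
#' @param nucleus_axes Major and minor ellipse semi-axes in pixels (default
#'   `c(8, 3)`: flattened nuclei elongated along the fiber direction).
#' @param nucleus_darkness Gray-level drop inside a nucleus on the `[0, 1]`
#'   scale (default 0.45).
#' @param smoothing_sigma Gaussian blur width in pixels applied after
#'   composition (default 1).
#' @param noise_sd Additive Gaussian noise SD on the `[0, 1]` scale
#'   (default 0.04).
#' @param seed Integer seed; the generated image is a pure function of the
#'   parameter set, including the seed.
#' @return An object of class `stroma_params` (a validated list).
#' @export
stroma_params <- function(size = 512L,
                          fiber_wavelength = 16,
                          fiber_orientation = 0.35,
                          fiber_contrast = 0.18,
                          nucleus_density = 2,
                          nucleus_axes = c(8, 3),
                          nucleus_darkness = 0.45,
                          smoothing_sigma = 1,
                          noise_sd = 0.04,
                          seed = 1L) {
  p <- list(
    size = as.integer(size),
    fiber_wavelength = as.numeric(fiber_wavelength),
    fiber_orientation = as.numeric(fiber_orientation),
    fiber_contrast = as.numeric(fiber_contrast),
    nucleus_density = as.numeric(nucleus_density),
    nucleus_axes = as.numeric(nucleus_axes),
    nucleus_darkness = as.numeric(nucleus_darkness),
    smoothing_sigma = as.numeric(smoothing_sigma),
    noise_sd = as.numeric(noise_sd),
    seed = as.integer(seed)
  )
  if (is.na(p$size) || p$size < 4L) abort_validation("`size` must be >= 4 pixels.")
  if (p$fiber_wavelength < 2) abort_validation("`fiber_wavelength` must be >= 2 pixels.")
  if (p$fiber_contrast < 0 || p$nucleus_density < 0 || p$nucleus_darkness < 0 ||
      p$smoothing_sigma < 0 || p$noise_sd < 0) {
    abort_validation("Contrasts, densities, darkness, blur and noise must be >= 0.")
  }
  if (length(p$nucleus_axes) != 2L || any(p$nucleus_axes <= 0)) {
    abort_validation("`nucleus_axes` must be two positive semi-axes (major, minor).")
  }
  if (p$fiber_contrast + p$nucleus_darkness > 1) {
    abort_validation("`fiber_contrast + nucleus_darkness` must be <= 1 to avoid clipping by construction.")
  }
  if (is.na(p$seed)) abort_validation("`seed` must be an integer.")
  structure(p, class = "stroma_params")
}

#' Decellularization severity grades
#'
#' Five grades emulating a native group plus four graded treatment
#' conditions (increasing detergent dose/duration). A grade scales the
#' nucleus density (decellularization removes keratocytes) and adds blur
#' (treated tissue reads as locally homogenized texture). The native grade is
#' the identity: multiplier 1, no extra blur.
#'
#' @return A tibble with columns `name`, `nucleus_density_multiplier`,
#'   `extra_smoothing` for grades `native`, `g1` .. `g4` (mildest to
#'   harshest).
#' @export
severity_grades <- function() {
  tibble::tibble(
    name = c("native", "g1", "g2", "g3", "g4"),
    nucleus_density_multiplier = c(1, 0.1, 0.05, 0.02, 0),
    extra_smoothing = c(0, 0.5, 0.75, 1, 1)
  )
}

resolve_grade <- function(grade) {
  grades <- severity_grades()
  if (is.character(grade) && length(grade) == 1L) {
    if (!grade %in% grades$name) {
      abort_validation(sprintf(
        "Unknown grade '%s'; expected one of %s.",
        grade, paste(grades$name, collapse = ", ")
      ))
    }
    return(grades[grades$name == grade, ])
  }
  if (is.data.frame(grade) && nrow(grade) == 1L &&
      all(c("name", "nucleus_density_multiplier", "extra_smoothing") %in% names(grade))) {
    if (grade$nucleus_density_multiplier < 0 || grade$nucleus_density_multiplier > 1 ||
        grade$extra_smoothing < 0) {
      abort_validation("Grade multiplier must be in [0, 1] and extra_smoothing >= 0.")
    }
    return(grade)
  }
  abort_validation("`grade` must be a grade name or a one-row grade tibble.")
}

gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  # cap the brush at the largest odd size that fits the image
  radius <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  fit <- min(dim(x))
  if (fit %% 2L == 0L) fit <- fit - 1L
  EBImage::gblur(x, sigma = sigma, radius = min(radius, fit),
                 boundary = "replicate")
}

#' Generate one synthetic stromal micrograph
#'
#' Deterministically renders an 8-bit grayscale image of synthetic stromal
#' texture for a given parameter set and severity grade (see
#' [stroma_params()] for the composition model). The realized number of
#' nuclei is attached as the `nucleus_count` attribute and the grade name as
#' `grade`.
#'
#' @param params A [stroma_params()] object.
#' @param grade A grade name (`"native"`, `"g1"` .. `"g4"`) or a one-row
#'   grade tibble (see [severity_grades()]).
#' @return A `gray_image` of side `params$size` with attributes
#'   `nucleus_count` and `grade`.
#' @examples
#' img <- generate_stroma_image(stroma_params(size = 64, seed = 7), "native")
#' attr(img, "nucleus_count")
#' @export
generate_stroma_image <- function(params = stroma_params(), grade = "native") {
  if (!inherits(params, "stroma_params")) {
    abort_validation("`params` must be created with stroma_params().")
  }
  g <- resolve_grade(grade)
  sz <- params$size
  with_seed(params$seed, {
    f <- matrix(0.62, nrow = sz, ncol = sz)

    if (params$fiber_contrast > 0) {
      xs <- matrix(rep(seq_len(sz), each = sz), nrow = sz)    # column index
      ys <- matrix(rep(seq_len(sz), times = sz), nrow = sz)   # row index
      phase <- 2 * pi * (xs * cos(params$fiber_orientation) +
                           ys * sin(params$fiber_orientation)) / params$fiber_wavelength
      modn <- gaussian_blur(matrix(stats::rnorm(sz * sz), sz, sz),
                            sigma = params$fiber_wavelength / 2)
      rng <- range(modn)
      mod <- if (diff(rng) > 0) 0.5 + 0.5 * (modn - rng[1]) / diff(rng) else matrix(1, sz, sz)
      f <- f + params$fiber_contrast * mod * sin(phase)
    }

    lambda <- params$nucleus_density * g$nucleus_density_multiplier * sz^2 / 1e4
    n_nuclei <- if (lambda > 0) stats::rpois(1L, lambda) else 0L
    if (n_nuclei > 0) {
      a <- params$nucleus_axes[1]
      b <- params$nucleus_axes[2]
      cx <- stats::runif(n_nuclei, 1, sz)
      cy <- stats::runif(n_nuclei, 1, sz)
      ang <- params$fiber_orientation + stats::rnorm(n_nuclei, 0, 0.25)
      half <- ceiling(a) + 1L
      for (k in seq_len(n_nuclei)) {
        r0 <- max(1L, floor(cy[k]) - half); r1 <- min(sz, ceiling(cy[k]) + half)
        c0 <- max(1L, floor(cx[k]) - half); c1 <- min(sz, ceiling(cx[k]) + half)
        lx <- outer(rep(1, r1 - r0 + 1L), (c0:c1) - cx[k])
        ly <- outer((r0:r1) - cy[k], rep(1, c1 - c0 + 1L))
        u <- lx * cos(ang[k]) + ly * sin(ang[k])
        v <- -lx * sin(ang[k]) + ly * cos(ang[k])
        inside <- (u / a)^2 + (v / b)^2 <= 1
        blk <- f[r0:r1, c0:c1, drop = FALSE]
        blk[inside] <- blk[inside] - params$nucleus_darkness
        f[r0:r1, c0:c1] <- blk
      }
    }

    # fine-grain tissue speckle: part of the specimen, hence applied before
    # the optical/homogenization blur so that harsher grades read as smoother
    if (params$noise_sd > 0) {
      f <- f + matrix(stats::rnorm(sz * sz, 0, params$noise_sd), sz, sz)
    }

    f <- gaussian_blur(f, params$smoothing_sigma + g$extra_smoothing)

    f <- pmin(pmax(f, 0), 1)
    img <- gray_image(round(f * 255), bit_depth = 8L)
    attr(img, "nucleus_count") <- n_nuclei
    attr(img, "grade") <- g$name
    img
  })
}

#' Generate a labeled set of synthetic micrographs
#'
#' Renders `n_per_group` images per grade, each with an independent image
#' seed derived deterministically from `(seed, grade, index)`, so the whole
#' set is a pure function of its arguments.
#'
#' @param n_per_group Images per grade (>= 1).
#' @param grades Character vector of grade names (default
#'   `c("native", "g4")`, the intact-versus-fully-decellularized contrast).
#' @param params A [stroma_params()] template; its `seed` field is ignored in
#'   favour of per-image derived seeds.
#' @param seed Master seed for the set.
#' @return A tibble with columns `image_id`, `label` (the grade name),
#'   `nucleus_count` and `image` (a list column of `gray_image`s).
#' @examples
#' set <- generate_micrograph_set(2, c("native", "g4"),
#'                                stroma_params(size = 64), seed = 1)
#' dplyr::count(set, label)
#' @export
generate_micrograph_set <- function(n_per_group, grades = c("native", "g4"),
                                    params = stroma_params(), seed = 1L) {
  n_per_group <- as.integer(n_per_group)
  if (is.na(n_per_group) || n_per_group < 1L) {
    abort_validation("`n_per_group` must be >= 1.")
  }
  if (length(grades) < 1L) abort_validation("`grades` must name at least one grade.")
  grade_rows <- purrr::map(grades, resolve_grade)
  purrr::imap_dfr(grade_rows, function(g, gi) {
    purrr::map_dfr(seq_len(n_per_group), function(i) {
      p_i <- params
      p_i$seed <- derive_seed(seed, gi * 10007L, i)
      img <- generate_stroma_image(p_i, g)
      tibble::tibble(
        image_id = sprintf("%s_%04d", g$name, i),
        label = g$name,
        nucleus_count = attr(img, "nucleus_count"),
        image = list(img)
      )
    })
  })
}
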