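# Worked 2x2 cases used throughout: the matrices are written row-wise, i.e.
# rbind(), so [[0,1],[0,1]] has columns (0,0) and (1,1).
img_01 <- gray_image(rbind(c(0L, 1L), c(0L, 1L)), bit_depth = 1)  # [[0,1],[0,1]]
img_0011 <- gray_image(rbind(c(0L, 0L), c(1L, 1L)), bit_depth = 1)  # [[0,0],[1,1]]
img_const <- gray_image(matrix(7L, 4, 4), bit_depth = 8)

test_that("co-occurrence accumulation matches hand-enumerated pairs", {
  G <- compute_glcm(img_01)
  expect_equal(G$p[1, 2], 1)  # p(0,1) = 1
  expect_equal(sum(G$p), 1)
  expect_identical(G$pair_count, 2L)

  Gc <- compute_glcm(img_const)
  expect_equal(Gc$p[8, 8], 1)  # single cell p(7,7)
  expect_equal(sum(Gc$p != 0), 1)

  Gs <- compute_glcm(img_01, symmetric = TRUE)
  expect_equal(Gs$p[1, 2], 0.5)
  expect_equal(Gs$p[2, 1], 0.5)
  expect_equal(sum(Gs$p), 1)

  expect_error(compute_glcm(img_01, offset = c(0L, 5L)),
               class = "stromatex_error_validation")
  expect_error(compute_glcm(img_01, offset = c(0L, 0L)),
               class = "stromatex_error_validation")
})

test_that("features reproduce the worked closed-form cases", {
  G1 <- compute_glcm(img_01)
  expect_equal(glcm_asm(G1), 1)
  expect_equal(glcm_idm(G1), 0.5)
  expect_equal(glcm_contrast(G1), 1)
  expect_equal(glcm_sum_variance(G1), 0)
  expect_error(glcm_correlation(G1), class = "stromatex_error_undefined_feature")

  G2 <- compute_glcm(img_0011)
  expect_equal(glcm_asm(G2), 0.5)
  expect_equal(glcm_idm(G2), 1)
  expect_equal(glcm_contrast(G2), 0)
  expect_equal(glcm_correlation(G2), 1)
  expect_equal(glcm_sum_variance(G2), 1)

  # perfectly anti-correlated two-level pattern
  img_anti <- gray_image(rbind(c(0L, 1L), c(1L, 0L)), bit_depth = 1)
  expect_equal(glcm_correlation(compute_glcm(img_anti)), -1)

  Gc <- compute_glcm(img_const)
  expect_equal(glcm_asm(Gc), 1)
  expect_equal(glcm_idm(Gc), 1)
  expect_equal(glcm_contrast(Gc), 0)
  expect_equal(glcm_sum_variance(Gc), 0)
  expect_error(glcm_correlation(Gc), class = "stromatex_error_undefined_feature")
})

test_that("all five features match the pair-enumeration oracle on random images", {
  set.seed(100)
  for (case in 1:40) {
    levels <- sample(c(2, 4, 8, 16), 1)
    offset <- c(0L, 0L)
    while (all(offset == 0L)) offset <- sample(-2:2, 2, replace = TRUE)
    symmetric <- sample(c(TRUE, FALSE), 1)
    img <- random_gray(seed = 9000 + case, h = 16, w = 16, levels = levels)
    G <- compute_glcm(img, offset = offset, symmetric = symmetric)
    P <- oracle_glcm(img, offset, symmetric)
    expect_equal(G$p, P, tolerance = 1e-14)
    ref <- oracle_features(P)
    S <- glcm_marginals(G)
    expect_equal(glcm_asm(G), ref$asm, tolerance = 1e-12)
    expect_equal(glcm_idm(G), ref$idm, tolerance = 1e-12)
    expect_equal(glcm_contrast(G), ref$contrast, tolerance = 1e-12)
    expect_equal(glcm_correlation(G, S), ref$correlation, tolerance = 1e-12)
    expect_equal(glcm_sum_variance(G, S), ref$sum_variance, tolerance = 1e-12)
  }
})

test_that("feature bounds hold on random images", {
  for (seed in 1:25) {
    img <- random_gray(seed, levels = sample(c(4, 8, 16), 1))
    G <- compute_glcm(img)
    ng <- G$n_levels
    expect_gt(glcm_asm(G), 0)
    expect_lte(glcm_asm(G), 1)
    expect_gt(glcm_idm(G), 0)
    expect_lte(glcm_idm(G), 1)
    expect_gte(glcm_contrast(G), 0)
    expect_lte(glcm_contrast(G), (ng - 1)^2)
    expect_lte(abs(glcm_correlation(G)), 1 + 1e-9)
  }
})

test_that("contrast and ASM are invariant to constant gray-level shifts", {
  set.seed(42)
  base <- matrix(sample(0:100, 12 * 12, replace = TRUE), 12, 12)
  img_a <- gray_image(base)
  img_b <- gray_image(base + 50L)  # no clipping: max 150 < 255
  Ga <- compute_glcm(img_a)
  Gb <- compute_glcm(img_b)
  expect_equal(glcm_contrast(Ga), glcm_contrast(Gb), tolerance = 1e-12)
  expect_equal(glcm_asm(Ga), glcm_asm(Gb), tolerance = 1e-12)
  expect_equal(glcm_idm(Ga), glcm_idm(Gb), tolerance = 1e-12)
  # correlation is invariant under level translation too
  expect_equal(glcm_correlation(Ga), glcm_correlation(Gb), tolerance = 1e-12)
})

test_that("Gaussian blur does not decrease IDM on average (homogenization)", {
  deltas <- vapply(1:10, function(seed) {
    img <- random_gray(seed, h = 64, w = 64, levels = 256)
    blurred <- EBImage::gblur(unclass(img) + 0, sigma = 1.5, boundary = "replicate")
    blurred_img <- gray_image(pmin(pmax(round(blurred), 0), 255))
    glcm_idm(compute_glcm(blurred_img)) - glcm_idm(compute_glcm(img))
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})

test_that("glcm_features assembles the per-ROI row with its config", {
  row <- glcm_features(img_0011, bits = 1)
  expect_identical(nrow(row), 1L)
  expect_equal(row$asm, 0.5)
  expect_equal(row$correlation, 1)
  expect_identical(row$bits, 1L)
  expect_identical(row$offset_col, 1L)
  expect_false(row$symmetric)
  expect_error(glcm_features(img_const), class = "stromatex_error_undefined_feature")

  # quantization happens before the matrix is built
  set.seed(8)
  img <- gray_image(matrix(sample(0:255, 64, replace = TRUE), 8, 8))
  row4 <- glcm_features(img, bits = 4)
  ref <- oracle_features(oracle_glcm(quantize_levels(img, 4), c(0L, 1L)))
  expect_equal(row4$contrast, ref$contrast, tolerance = 1e-12)
  expect_equal(row4$sum_variance, ref$sum_variance, tolerance = 1e-12)
})
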