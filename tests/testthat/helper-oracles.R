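# Independent brute-force references used to validate the vectorized
# implementations. Deliberately naive: explicit loops, no shared code with R/.

# Random test image with `levels` gray levels.
random_gray <- function(seed, h = 16, w = 16, levels = 16) {
  set.seed(seed)
  bits <- as.integer(log2(levels))
  gray_image(matrix(sample(0:(levels - 1), h * w, replace = TRUE), h, w),
             bit_depth = bits)
}

# Co-occurrence probabilities by explicit pair enumeration.
oracle_glcm <- function(img, offset, symmetric = FALSE) {
  px <- unclass(img)
  ng <- 2^attr(img, "bit_depth")
  p <- matrix(0, ng, ng)
  h <- nrow(px); w <- ncol(px)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      r2 <- r + offset[1]; c2 <- c + offset[2]
      if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
        i <- px[r, c]; j <- px[r2, c2]
        p[i + 1, j + 1] <- p[i + 1, j + 1] + 1
        if (symmetric) p[j + 1, i + 1] <- p[j + 1, i + 1] + 1
      }
    }
  }
  p / sum(p)
}

# All five features from a probability matrix, by explicit double loops.
oracle_features <- function(p) {
  ng <- nrow(p)
  asm <- 0; idm <- 0; con <- 0; sij <- 0
  for (i in 0:(ng - 1)) {
    for (j in 0:(ng - 1)) {
      q <- p[i + 1, j + 1]
      asm <- asm + q^2
      idm <- idm + q / (1 + (i - j)^2)
      con <- con + (i - j)^2 * q
      sij <- sij + i * j * q
    }
  }
  px <- rowSums(p); py <- colSums(p)
  mux <- sum((0:(ng - 1)) * px); muy <- sum((0:(ng - 1)) * py)
  sx <- sqrt(sum(((0:(ng - 1)) - mux)^2 * px))
  sy <- sqrt(sum(((0:(ng - 1)) - muy)^2 * py))
  cor <- if (sx > 0 && sy > 0) (sij - mux * muy) / (sx * sy) else NA_real_
  psum <- rep(0, 2 * ng - 1)
  for (i in 0:(ng - 1)) {
    for (j in 0:(ng - 1)) {
      psum[i + j + 1] <- psum[i + j + 1] + p[i + 1, j + 1]
    }
  }
  sa <- sum((0:(2 * ng - 2)) * psum)
  svar <- sum(((0:(2 * ng - 2)) - sa)^2 * psum)
  list(asm = asm, idm = idm, contrast = con, correlation = cor,
       sum_variance = svar)
}

# AUC as the normalized Mann-Whitney statistic: pairwise comparison of every
# (positive, negative) score pair, ties counted 1/2.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (a in pos) {
    for (b in neg) {
      total <- total + (a > b) + 0.5 * (a == b)
    }
  }
  total / (length(pos) * length(neg))
}

# Kruskal-Wallis H on mid-ranks with the standard tie correction.
oracle_kw_h <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  h <- 0
  for (g in unique(groups)) {
    rg <- r[groups == g]
    h <- h + sum(rg)^2 / length(rg)
  }
  h <- 12 / (n * (n + 1)) * h - 3 * (n + 1)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / correction
}

# Minimal uncompressed BMP writers (bottom-up row order, 4-byte row padding)
# used to exercise the BMP reader against known pixel values.
write_bmp24 <- function(r, g, b, path) {
  h <- nrow(r); w <- ncol(r)
  row_bytes <- ceiling(w * 3 / 4) * 4
  pad <- row_bytes - w * 3
  data_size <- row_bytes * h
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  writeBin(as.integer(54 + data_size), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")
  writeBin(54L, con, size = 4, endian = "little")
  writeBin(40L, con, size = 4, endian = "little")
  writeBin(as.integer(w), con, size = 4, endian = "little")
  writeBin(as.integer(h), con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(24L, con, size = 2, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  writeBin(c(2835L, 2835L, 0L, 0L), con, size = 4, endian = "little")
  for (row in h:1) {  # bottom-up
    bytes <- as.raw(as.vector(rbind(b[row, ], g[row, ], r[row, ])))
    writeBin(c(bytes, rep(as.raw(0), pad)), con)
  }
  invisible(path)
}

write_bmp8_gray <- function(px, path) {
  h <- nrow(px); w <- ncol(px)
  row_bytes <- ceiling(w / 4) * 4
  pad <- row_bytes - w
  data_off <- 54 + 256 * 4
  data_size <- row_bytes * h
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  writeBin(as.integer(data_off + data_size), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")
  writeBin(as.integer(data_off), con, size = 4, endian = "little")
  writeBin(40L, con, size = 4, endian = "little")
  writeBin(as.integer(w), con, size = 4, endian = "little")
  writeBin(as.integer(h), con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(8L, con, size = 2, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  writeBin(c(2835L, 2835L, 256L, 0L), con, size = 4, endian = "little")
  for (v in 0:255) {  # grayscale palette, B G R reserved
    writeBin(as.raw(c(v, v, v, 0)), con)
  }
  for (row in h:1) {
    writeBin(c(as.raw(px[row, ]), rep(as.raw(0), pad)), con)
  }
  invisible(path)
}

# A balanced two-class feature table with Gaussian clouds `shift` apart
# (in SD units) on every feature, for classifier tests.
toy_feature_table <- function(n_per_class, shift, seed, labels = c("native", "g4")) {
  set.seed(seed)
  feats <- stromatex:::texture_feature_names()
  make_class <- function(lab, mu) {
    df <- as.data.frame(matrix(rnorm(n_per_class * length(feats), mean = mu),
                               nrow = n_per_class))
    names(df) <- feats
    df$label <- lab
    df
  }
  tibble::as_tibble(rbind(make_class(labels[1], 0), make_class(labels[2], shift)))
}
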