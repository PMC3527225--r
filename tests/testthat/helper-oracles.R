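# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package internals.

# Bilinear interpolation at a single (possibly fractional) position,
# lerp-form (exact on flat patches).
oracle_bilerp <- function(img, y, x) {
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0; fx <- x - x0
  y1 <- if (fy > 0) y0 + 1 else y0
  x1 <- if (fx > 0) x0 + 1 else x0
  top <- img[y0, x0] * (1 - fx) + img[y0, x1] * fx
  if (fx == 0) top <- img[y0, x0]
  bot <- img[y1, x0] * (1 - fx) + img[y1, x1] * fx
  if (fx == 0) bot <- img[y1, x0]
  if (fy == 0) return(top)
  top + fy * (bot - top)
}

# LBP code of one pixel by direct per-neighbor interpolation + comparison.
oracle_lbp_code <- function(img, r, c, radius = 2) {
  code <- 0
  for (b in 0:7) {
    theta <- 2 * pi * b / 8
    ny <- r - radius * sin(theta)
    nx <- c + radius * cos(theta)
    nb <- oracle_bilerp(img, ny, nx)
    if (nb >= img[r, c]) code <- code + 2^b
  }
  code
}

# Exhaustive per-pixel LBP histogram over all interior positions.
oracle_lbp_histogram <- function(img, radius = 2) {
  m <- ceiling(radius)
  h <- rep(0L, 256)
  for (r in (m + 1):(nrow(img) - m)) {
    for (c in (m + 1):(ncol(img) - m)) {
      code <- oracle_lbp_code(img, r, c, radius)
      h[code + 1] <- h[code + 1] + 1L
    }
  }
  names(h) <- as.character(0:255)
  h
}

# All-pairs Mann-Whitney AUC with half credit for ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (n in neg) {
    if (p > n) wins <- wins + 1
    else if (p == n) wins <- wins + 0.5
  }
  wins / (length(pos) * length(neg))
}
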