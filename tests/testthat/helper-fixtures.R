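# fixtures are built in code; oracles here are deliberately naive
# implementations kept independent of the package internals

# smooth red-dominant texture with integer channels
texturedImage <- function(seed, N = 32, contrast = c(90, 60, 50)) {
  set.seed(seed)
  base <- EBImage::gblur(matrix(runif(N * N), N, N), max(2, N / 16))
  base <- (base - min(base)) / diff(range(base))
  px <- array(0, c(N, N, 3))
  px[, , 1] <- round(130 + contrast[1] * base)
  px[, , 2] <- round(55 + contrast[2] * base)
  px[, , 3] <- round(45 + contrast[3] * base)
  RgbImage(px)
}

rectMask <- function(N, rows, cols) {
  m <- matrix(0L, N, N)
  m[rows, cols] <- 1L
  HighlightMask(m)
}

# brute-force grayscale erosion/dilation with an arbitrary 0/1 kernel
naiveMorph <- function(x, kern, op = c("erode", "dilate")) {
  op <- match.arg(op)
  H <- nrow(x); W <- ncol(x)
  r <- (nrow(kern) - 1) / 2
  out <- x
  for (y in 1:H) for (x_ in 1:W) {
    vals <- c()
    for (dy in -r:r) for (dx in -r:r) {
      if (kern[dy + r + 1, dx + r + 1] == 0) next
      yy <- y + dy; xx <- x_ + dx
      if (yy < 1 || yy > H || xx < 1 || xx > W) next
      vals <- c(vals, x[yy, xx])
    }
    out[y, x_] <- if (op == "erode") min(vals) else max(vals)
  }
  out
}

# exhaustive best-match scan: every center whose patch is fully inside the
# image and mask-free, SSD over the target's known pixels, first minimum
# in (y, x) order
naiveBestMatch <- function(p, px, m, patchSide = 9) {
  H <- nrow(m); W <- ncol(m)
  r <- (patchSide - 1) / 2
  best <- NULL; bssd <- Inf
  for (cy in (r + 1):(H - r)) for (cx in (r + 1):(W - r)) {
    if (any(m[(cy - r):(cy + r), (cx - r):(cx + r)] == 1)) next
    ssd <- 0
    for (dy in -r:r) for (dx in -r:r) {
      ty <- p[1] + dy; tx <- p[2] + dx
      if (ty < 1 || ty > H || tx < 1 || tx > W) next
      if (m[ty, tx] == 1) next
      ssd <- ssd + sum((px[ty, tx, ] - px[cy + dy, cx + dx, ])^2)
    }
    if (ssd < bssd) { bssd <- ssd; best <- c(cy, cx) }
  }
  list(q = best, ssd = bssd)
}

# flood fill of the background from the border; unreached zero pixels are
# enclosed holes
naiveHoleFill <- function(m) {
  H <- nrow(m); W <- ncol(m)
  reach <- matrix(FALSE, H, W)
  frontier <- which((row(m) == 1 | row(m) == H | col(m) == 1 | col(m) == W) &
                      m == 0)
  reach[frontier] <- TRUE
  while (length(frontier)) {
    nxt <- c()
    for (i in frontier) {
      y <- ((i - 1) %% H) + 1; x <- ((i - 1) %/% H) + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        yy <- y + d[1]; xx <- x + d[2]
        if (yy < 1 || yy > H || xx < 1 || xx > W) next
        j <- (xx - 1) * H + yy
        if (!reach[j] && m[yy, xx] == 0) { reach[j] <- TRUE; nxt <- c(nxt, j) }
      }
    }
    frontier <- nxt
  }
  out <- m
  out[m == 0 & !reach] <- 1L
  out
}
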