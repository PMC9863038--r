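test_that("top-hat/bottom-hat contrast enhancement matches brute-force morphology", {
  cst <- RgbImage(array(90, c(8, 8, 3)))
  expect_identical(contrastEnhance(cst, radius = 2)@.Data, cst@.Data)
  # single bright pixel on a flat background is amplified to saturation
  px <- array(100, c(5, 5, 3)); px[3, 3, ] <- 200
  ce <- contrastEnhance(RgbImage(px), radius = 1)
  expect_equal(ce@.Data[3, 3, 1], 255)
  # full-output check against naive min/max morphology
  k <- endospec:::.discKernel(1)
  x <- px[, , 1]
  opening <- naiveMorph(naiveMorph(x, k, "erode"), k, "dilate")
  closing <- naiveMorph(naiveMorph(x, k, "dilate"), k, "erode")
  expected <- pmin(pmax(x + (x - opening) - (closing - x), 0), 255)
  expect_equal(ce@.Data[, , 1], expected)
  expect_true(all(ce@.Data >= 0 & ce@.Data <= 255))
})

test_that("channel statistics are sample mean and sd of G and B", {
  px <- array(0, c(1, 2, 3)); px[1, , 2] <- c(10, 20); px[1, , 3] <- c(10, 20)
  st <- channelStats(RgbImage(px))
  expect_equal(st$muG, 15); expect_equal(st$sigmaG, sqrt(50))
  px2 <- array(0, c(1, 3, 3)); px2[1, , 3] <- c(0, 0, 30)
  st2 <- channelStats(RgbImage(px2))
  expect_equal(st2$muB, 10); expect_equal(st2$sigmaB, sqrt(300))
  expect_equal(channelStats(RgbImage(array(77, c(3, 3, 3))))$sigmaG, 0)
  expect_error(channelStats(RgbImage(array(1, c(1, 1, 3)))), "2 pixels")
})

test_that("the adaptive threshold follows Th = maxgb - tau * mean channel spread", {
  st0 <- list(muG = 0, muB = 0, sigmaG = 0, sigmaB = 0)
  expect_equal(absoluteThreshold(st0, "medium", 255), 255)
  st <- list(muG = 0, muB = 0, sigmaG = 20, sigmaB = 30)
  expect_equal(absoluteThreshold(st, "medium", 250), 250 - 0.8 * 25)
  expect_equal(absoluteThreshold(st, "high", 250), 250 - 0.3 * 25)
  expect_equal(absoluteThreshold(st, "low", 250), 250 - 1.1 * 25)
  # high brightness gives the largest (most conservative) threshold
  expect_gt(absoluteThreshold(st, "high", 250), absoluteThreshold(st, "medium", 250))
})

test_that("absolute detection flags saturated G/B pixels above the global threshold", {
  # near-constant image: degenerate guard declares no absolute highlights
  flat <- RgbImage(array(140, c(10, 10, 3)))
  m0 <- detectAbsolute(flat, "medium")
  expect_equal(sum(m0@.Data), 0L)
  expect_true(is.na(attr(m0, "Th")))
  # saturated blob on a moderate background (enhanced = identity pass-through)
  px <- array(0, c(20, 20, 3))
  px[, , 1] <- 150; px[, , 2] <- 100; px[, , 3] <- 90
  px[8:11, 8:11, ] <- 255
  img <- RgbImage(px)
  m <- detectAbsolute(img, "medium", enhanced = img)
  st <- channelStats(img)
  Th <- absoluteThreshold(st, "medium", 255)
  expect_identical(m@.Data == 1L, pmax(px[, , 2], px[, , 3]) >= Th)
  expect_true(all(m@.Data[8:11, 8:11] == 1L))
  expect_equal(sum(m@.Data), 16L)
  # single saturated pixel on zero G/B background
  px1 <- array(0, c(12, 12, 3)); px1[5, 7, 2:3] <- 255
  m1 <- detectAbsolute(RgbImage(px1), "medium", enhanced = RgbImage(px1))
  expect_identical(which(m1@.Data == 1L), which(px1[, , 2] == 255))
})

test_that("tau ordering makes the absolute masks nested across classes", {
  for (seed in c(5, 6)) {
    fx <- generateFixture(syntheticSpec(seed = seed, height = 96, width = 96))
    ce <- contrastEnhance(fx$image)
    mh <- detectAbsolute(fx$image, "high", enhanced = ce)@.Data
    mm <- detectAbsolute(fx$image, "medium", enhanced = ce)@.Data
    ml <- detectAbsolute(fx$image, "low", enhanced = ce)@.Data
    expect_true(all(mh <= mm))
    expect_true(all(mm <= ml))
  }
})

test_that("relative detection finds sharp bright transitions and fills rings", {
  expect_equal(sum(detectRelative(RgbImage(array(50, c(16, 16, 3))))@.Data), 0L)
  # ideal vertical step 0 -> 255 exceeds the threshold along the edge
  # (bright quarter keeps the intensity floor below the bright plateau)
  px <- array(0, c(16, 16, 3)); px[, 13:16, ] <- 255
  mr <- detectRelative(RgbImage(px))
  expect_gt(sum(mr@.Data[, 12:13]), 0)
  expect_equal(sum(mr@.Data[, 1:10]), 0L)
  # bright disc on dark ground: ring is detected, interior hole filled
  N <- 32; px2 <- array(40, c(N, N, 3))
  d <- sqrt((row(matrix(0, N, N)) - 16)^2 + (col(matrix(0, N, N)) - 16)^2)
  disc <- d <= 6
  for (ch in 1:3) px2[, , ch][disc] <- 230
  m2 <- detectRelative(RgbImage(px2))@.Data
  expect_true(all(m2[d <= 5] == 1L))          # interior filled
  expect_true(all(m2[d > 9] == 0L))           # background untouched
  # agreement with an independent per-pixel Sobel + flood-fill hole oracle
  gray <- 0.299 * px2[, , 1] + 0.587 * px2[, , 2] + 0.114 * px2[, , 3]
  at <- function(y, x) gray[min(max(y, 1), N), min(max(x, 1), N)]
  g <- matrix(0, N, N)
  for (y in 1:N) for (x in 1:N) {
    gx <- at(y - 1, x + 1) + 2 * at(y, x + 1) + at(y + 1, x + 1) -
      at(y - 1, x - 1) - 2 * at(y, x - 1) - at(y + 1, x - 1)
    gy <- at(y + 1, x - 1) + 2 * at(y + 1, x) + at(y + 1, x + 1) -
      at(y - 1, x - 1) - 2 * at(y - 1, x) - at(y - 1, x + 1)
    g[y, x] <- sqrt(gx^2 + gy^2)
  }
  cand <- (g >= 4 * mean(g)) & (gray >= mean(gray) + sd(as.vector(gray)))
  expect_identical(m2, naiveHoleFill(matrix(as.integer(cand), N, N)))
})

test_that("disc dilation produces digital discs and is monotone", {
  empty <- HighlightMask(matrix(0L, 9, 9))
  expect_identical(dilateMask(empty, 2)@.Data, empty@.Data)
  one <- matrix(0L, 9, 9); one[5, 5] <- 1L
  d1 <- dilateMask(HighlightMask(one), 1)@.Data
  expect_equal(sum(d1), 5L)  # plus shape
  d2 <- dilateMask(HighlightMask(one), 2)@.Data
  expect_equal(sum(d2), 13L) # digital disc r = 2
  # brute-force distance oracle
  dist <- sqrt((row(one) - 5)^2 + (col(one) - 5)^2)
  expect_identical(d2 == 1L, dist <= 2)
  expect_true(all(d1 <= d2))                       # radius monotone
  expect_identical(dilateMask(HighlightMask(one), 0)@.Data, one)
})

test_that("full detection: union structure, blob coverage, degenerate emptiness", {
  fx <- generateFixture(syntheticSpec(seed = 12, height = 128, width = 128))
  det <- detectHighlights(fx$image)
  expect_identical(det$union@.Data,
                   matrix(as.integer(det$maskAbsolute@.Data |
                                       det$maskRelative@.Data), 128, 128))
  # each ground-truth blob is covered, components match the blob count
  regsGT <- extractRegions(fx$mask)
  regsDet <- extractRegions(det$mask)
  expect_equal(length(regsDet), length(regsGT))
  expect_true(all(det$mask@.Data[fx$mask@.Data == 1L] == 1L))
  # near-constant highlight-free frame -> empty mask via the degenerate guard
  det0 <- detectHighlights(RgbImage(array(130, c(64, 64, 3))))
  expect_equal(sum(det0$mask@.Data), 0L)
  expect_identical(det0$overlay@.Data, det0$work@.Data)
})
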