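test_that("region extraction: components, contours, bounding boxes", {
  m <- matrix(0L, 20, 20)
  m[3:5, 3:5] <- 1L; m[12:14, 10:12] <- 1L
  regs <- extractRegions(HighlightMask(m))
  expect_length(regs, 2)
  # raster-encounter order
  expect_equal(regs[[1]]@yup, 3L); expect_equal(regs[[2]]@yup, 12L)
  # a 3x3 square has an 8-pixel contour (all but the center)
  expect_equal(regs[[1]]@lc, 8L)
  expect_equal(regs[[2]]@lc, 8L)
  expect_equal(regionHeight(regs[[1]]), 3L)
  expect_equal(regionWidth(regs[[2]]), 3L)
  # single pixel: lc = 1, degenerate bbox
  one <- matrix(0L, 10, 10); one[4, 7] <- 1L
  r1 <- extractRegions(HighlightMask(one))[[1]]
  expect_equal(r1@lc, 1L)
  expect_equal(c(regionHeight(r1), regionWidth(r1)), c(1L, 1L))
  # diagonal adjacency joins components (8-connectivity)
  dg <- matrix(0L, 8, 8); dg[2, 2] <- 1L; dg[3, 3] <- 1L
  expect_length(extractRegions(HighlightMask(dg)), 1)
  # empty mask -> empty list; full mask -> error
  expect_length(extractRegions(HighlightMask(matrix(0L, 5, 5))), 0)
  expect_error(extractRegions(HighlightMask(matrix(1L, 5, 5))), "entire image")
})

test_that("confidence term is the known-information fraction of the patch", {
  conf <- matrix(1, 30, 30); m <- matrix(0L, 30, 30)
  expect_equal(confidenceTerm(c(15, 15), conf, m), 1)
  # 41 of the 81 patch pixels masked -> Cp = 40/81
  m2 <- m
  m2[11:19, 11:15] <- 1L          # 45 masked
  m2[11:14, 11] <- 0L             # unmask 4 -> 41 masked
  expect_equal(confidenceTerm(c(15, 15), conf, m2), 40 / 81)
  # patch entirely inside the hole
  m3 <- m; m3[5:25, 5:25] <- 1L
  expect_equal(confidenceTerm(c(15, 15), 1 - m3, m3), 0)
  # border crop: corner patch uses the cropped area as denominator
  expect_equal(confidenceTerm(c(1, 1), conf, m), 1)
  m4 <- m; m4[1:3, 1:5] <- 1L     # 15 of the 25 corner-patch pixels masked
  expect_equal(confidenceTerm(c(1, 1), conf, m4), 10 / 25)
})

test_that("data term measures isophote strength against the front normal", {
  N <- 15
  m <- matrix(0L, N, N); m[8:N, ] <- 1L     # lower half masked, front at row 8
  p <- c(8, 7)
  # horizontal ramp: isophotes vertical, hitting the front head-on
  ramp <- matrix(rep(255 * (1:N), each = N), N, N)
  expect_equal(dataTerm(p, ramp, m), 1)
  ramp20 <- matrix(rep(20 * (1:N), each = N), N, N)
  expect_equal(dataTerm(p, ramp20, m), 20 / 255)
  # vertical ramp: isophotes parallel to the front, no structure crosses
  vramp <- matrix(rep(255 * (1:N), times = N), N, N)
  expect_equal(dataTerm(p, vramp, m), 0)
  # locally constant image: zero gradient, zero data term
  expect_equal(dataTerm(p, matrix(42, N, N), m), 0)
})

test_that("curvature term vanishes on ramps and matches 1/r on a cone", {
  N <- 64
  ramp <- matrix(rep(1:N, each = N), N, N) * 3
  expect_equal(curvatureTerm(c(32, 32), ramp), 0)
  expect_equal(curvatureTerm(c(10, 50), matrix(5, N, N)), 0)  # eps guard
  cone <- sqrt((row(matrix(0, N, N)) - 32)^2 + (col(matrix(0, N, N)) - 32)^2) * 10
  for (r in c(8, 15, 25)) {
    k <- curvatureTerm(c(32, 32 + r), cone)
    expect_lt(abs(abs(k) - 1 / r) / (1 / r), 0.2)
  }
})

test_that("priority branches follow the hybrid formula", {
  params <- inpaintParams()
  # fully known neighborhood, constant image: Cp = 1, Dp = 0, Kp = 0 -> P = 1
  conf <- matrix(1, 20, 20); m <- matrix(0L, 20, 20); m[10, 10] <- 1L
  img <- matrix(50, 20, 20)
  pr <- patchPriority(c(10, 10), conf, img, m, params)
  expect_equal(pr$Cp, 80 / 81)
  expect_equal(pr$P, pr$Cp * (0 + 1))
  # low-confidence branch: additive with regularized confidence
  m2 <- matrix(1L, 20, 20); m2[1:10, ] <- 0L   # rows 1..10 known
  conf2 <- 1 - m2
  p2 <- c(11, 10)
  pr2 <- patchPriority(p2, conf2, img, m2, params)
  CpExp <- confidenceTerm(p2, conf2, m2)
  expect_lt(CpExp, 0.5)
  expect_equal(pr2$P, (1 - params$w) * CpExp + params$w + params$beta * pr2$Dp)
  # w -> 1 limit: regularized confidence saturates at 1
  prW <- patchPriority(p2, conf2, img, m2, inpaintParams(w = 0.999))
  expect_equal(prW$P, 0.999 + (1 - 0.999) * CpExp + 0.5 * prW$Dp, tolerance = 1e-12)
  # original form is the plain product
  prO <- patchPriority(p2, conf2, img, m2, inpaintParams(priorityForm = "original"))
  expect_equal(prO$P, prO$Cp * prO$Dp)
})

test_that("search window expands the bbox by n times its size and clips", {
  params <- inpaintParams(a = 26)
  reg <- new("HighlightRegion", label = 1L,
             pixels = cbind(y = 11:21, x = rep(31, 11)),
             contour = cbind(y = 11:21, x = rep(31, 11)), lc = 30L,
             yup = 11L, ydown = 21L, xleft = 31L, xright = 41L)
  win <- searchWindow(reg, c(100, 100), params)
  # h = w = 11, lc = 30 >= a -> n = n2 = 4 would give different bounds;
  # with lc just under a the short-contour coefficient n1 = 2 applies
  regShort <- reg; regShort@lc <- 25L
  ws <- searchWindow(regShort, c(100, 100), params)
  expect_equal(ws$n, 2L)
  expect_equal(ws$us, 1L)    # 11 - 22 clipped
  expect_equal(ws$ds, 43L)   # 21 + 22
  expect_equal(ws$ls, 9L)    # 31 - 22
  expect_equal(ws$rs, 63L)   # 41 + 22
  # pivot boundary: lc = a chooses n2
  regAt <- reg; regAt@lc <- 26L
  expect_equal(searchWindow(regAt, c(200, 200), params)$n, 4L)
  expect_equal(win$n, 4L)
  # full-frame region window is the whole image
  regBig <- new("HighlightRegion", label = 1L,
                pixels = cbind(y = c(1L, 50L), x = c(1L, 50L)),
                contour = cbind(y = 1L, x = 1L), lc = 1L,
                yup = 1L, ydown = 50L, xleft = 1L, xright = 50L)
  wb <- searchWindow(regBig, c(50, 50), inpaintParams())
  expect_equal(unlist(wb[c("us", "ds", "ls", "rs")]),
               c(us = 1, ds = 50, ls = 1, rs = 50))
})

test_that("window grows until a fully-known candidate patch exists", {
  m <- matrix(1L, 40, 40)
  m[1:12, 1:12] <- 0L                       # known corner only
  m[20:22, 20:22] <- 1L
  reg <- extractRegions(HighlightMask(m))[[1]]
  # the region is the whole masked area; craft a small region instead
  m2 <- matrix(0L, 40, 40); m2[20:22, 20:22] <- 1L
  reg2 <- extractRegions(HighlightMask(m2))[[1]]
  # under the combined mask the initial +-2h window holds no known patch
  win <- searchWindow(reg2, c(40, 40), inpaintParams(a = 100), mask = m)
  got <- endospec:::.validCenters(m, win, 4L)
  expect_gt(length(got$y), 0)
  expect_gt(win$n, 2)
})

test_that("SSD sums squared channel differences over valid pixels", {
  a <- array(0, c(3, 3, 3)); b <- a
  v <- matrix(FALSE, 3, 3); v[2, 2] <- TRUE
  expect_equal(patchSsd(a, a, matrix(TRUE, 3, 3)), 0)
  b[2, 2, ] <- c(1, 2, 2)
  expect_equal(patchSsd(a, b, v), 9)
  expect_equal(patchSsd(b, a, v), patchSsd(a, b, v))
  expect_error(patchSsd(a, b, matrix(FALSE, 3, 3)), "valid")
})

test_that("best match agrees with the exhaustive oracle and breaks ties low", {
  img <- texturedImage(17, 21)
  m <- matrix(0L, 21, 21); m[10:12, 10:12] <- 1L
  win <- list(us = 1L, ds = 21L, ls = 1L, rs = 21L)
  p <- c(10, 10)
  bm <- bestMatch(p, win, img, m, 9L)
  oracle <- naiveBestMatch(p, img@.Data, m, 9)
  expect_equal(bm$q, oracle$q)
  expect_equal(bm$ssd, oracle$ssd)
  # uniform image: every candidate ties at 0; first (y, x) wins
  u <- RgbImage(array(80, c(21, 21, 3)))
  bmu <- bestMatch(p, win, u, m, 9L)
  expect_equal(bmu$ssd, 0)
  expect_equal(bmu$q, c(5, 5))
  # a fully known target present verbatim scores 0 at its own center
  m0 <- matrix(0L, 21, 21)
  bm0 <- bestMatch(c(11, 11), win, img, m0, 9L)
  expect_equal(bm0$ssd, 0)
})

test_that("fill step copies the source into the hole and updates state locally", {
  img <- texturedImage(23, 21)
  m <- matrix(0L, 21, 21); m[10, 10] <- 1L
  st <- list(img = img@.Data, mask = m, conf = 1 - m)
  st2 <- fillStep(st, c(10, 10), c(4, 4), Cp = 0.62, patchSide = 9L)
  expect_equal(attr(st2, "nFilled"), 1L)
  expect_equal(sum(st2$mask), 0)
  expect_equal(st2$conf[10, 10], 0.62)
  expect_equal(st2$img[10, 10, ], st$img[4, 4, ])
  # nothing outside the filled pixel changed
  st2$img[10, 10, ] <- st$img[10, 10, ]
  expect_identical(st2$img, st$img)
})

test_that("region inpainting fills uniformly, continues edges, terminates", {
  # 3x3 hole in a uniform image: exact recovery
  u <- RgbImage(array(100, c(21, 21, 3)))
  m <- matrix(0L, 21, 21); m[10:12, 10:12] <- 1L
  reg <- extractRegions(HighlightMask(m))[[1]]
  res <- inpaintRegion(u, reg)
  expect_identical(res$image@.Data, u@.Data)
  expect_equal(sum(res$mask@.Data), 0L)
  expect_lte(res$steps, 9)
  # single-pixel region: exactly one step
  m1 <- matrix(0L, 21, 21); m1[5, 5] <- 1L
  res1 <- inpaintRegion(u, extractRegions(HighlightMask(m1))[[1]])
  expect_equal(res1$steps, 1L)
  # 5x5 hole across a straight two-tone edge: each side keeps its tone
  px <- array(60, c(24, 24, 3)); px[, 13:24, ] <- 200
  m2 <- matrix(0L, 24, 24); m2[10:14, 10:14] <- 1L
  out <- inpaintImage(RgbImage(px), HighlightMask(m2))
  expect_true(all(out@.Data[10:14, 10:12, ] == 60))
  expect_true(all(out@.Data[10:14, 13:14, ] == 200))
})

test_that("inpainting is mask-exact, bounded, and keeps confidence in [0,1]", {
  for (seed in c(3, 8, 19)) {
    img <- texturedImage(seed, 40)
    set.seed(seed + 100)
    m <- matrix(0L, 40, 40)
    for (k in 1:2) {
      cy <- sample(8:32, 1); cx <- sample(8:32, 1)
      m[cy:(cy + 3), cx:(cx + 3)] <- 1L
    }
    nOmega <- sum(m)
    res <- inpaintImage(img, HighlightMask(m), report = TRUE)
    r <- res$report
    expect_lte(r$steps, nOmega)              # each step fills >= 1 pixel
    keep <- rep(m == 0L, 3)
    expect_identical(res$image@.Data[keep], img@.Data[keep])  # mask-exact
    regs <- extractRegions(HighlightMask(m))
    cres <- inpaintRegion(img, regs[[1]], mask = m)
    expect_true(all(cres$conf >= 0 & cres$conf <= 1))
  }
})

test_that("empty and full masks behave as identity and error", {
  img <- texturedImage(2, 16)
  empty <- HighlightMask(matrix(0L, 16, 16))
  expect_identical(inpaintImage(img, empty)@.Data, img@.Data)
  expect_error(inpaintImage(img, HighlightMask(matrix(1L, 16, 16))),
               "entire image")
  expect_error(inpaintImage(RgbImage(array(1, c(8, 8, 3))),
                            HighlightMask(matrix(0L, 8, 8))),
               "patchSide")
})

test_that("improved mode reproduces the classic algorithm under forced settings", {
  for (seed in c(41, 42)) {
    img <- texturedImage(seed, 32)
    m <- matrix(0L, 32, 32); m[14:17, 15:18] <- 1L
    a <- inpaintImage(img, HighlightMask(m), inpaintParams(mode = "criminisi"))
    b <- inpaintImage(img, HighlightMask(m),
                      inpaintParams(forceFullWindow = TRUE,
                                    priorityForm = "original"))
    expect_identical(a@.Data, b@.Data)
  }
})

test_that("far-apart regions with disjoint windows commute", {
  img <- texturedImage(55, 64)
  mA <- matrix(0L, 64, 64); mA[6:8, 6:8] <- 1L
  mB <- matrix(0L, 64, 64); mB[55:57, 55:57] <- 1L
  both <- HighlightMask(mA | mB)
  seq1 <- inpaintImage(img, both)
  # repair B first, then A, via single-region calls on the combined mask
  regs <- extractRegions(both)
  sB <- inpaintRegion(img, regs[[2]], mask = both@.Data)
  sBA <- inpaintRegion(sB$image, regs[[1]], mask = sB$mask@.Data)
  expect_identical(seq1@.Data, sBA$image@.Data)
})
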