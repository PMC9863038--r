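#' Specification of a synthetic endoscopic fixture
#'
#' Describes one generated test frame: a red-dominant tissue background
#' (hemoglobin makes the R channel dominate G and B), darker curvilinear
#' vessels, soft yellowish fat blobs, and near-saturated specular blobs
#' (channels within 8 of each other, intensity >= 240) with an optional
#' darker halo ring. The global exposure is adjusted so the frame lands in
#' the requested brightness class. The same spec always produces the same
#' frame, byte for byte.
#'
#' @param seed integer RNG seed.
#' @param height,width frame size in pixels (default 192 x 192).
#' @param targetClass `"high"`, `"medium"` or `"low"`.
#' @param nHighlights number of specular blobs (default 3).
#' @param radiusRange min/max blob radius in pixels (default `c(4, 9)`).
#' @param halo add a 1-2 px darker annulus around each blob (default
#'   `TRUE`), mimicking the halo effect around bright spots.
#' @param vesselCount number of vessel random walks (default 3).
#' @param fatBlobs number of fat blobs (default 2).
#' @return a validated spec list.
#' @export
syntheticSpec <- function(seed = 1L, height = 192L, width = 192L,
                          targetClass = c("medium", "high", "low"),
                          nHighlights = 3L, radiusRange = c(4, 9),
                          halo = TRUE, vesselCount = 3L, fatBlobs = 2L) {
  targetClass <- match.arg(targetClass)
  if (height < 32L || width < 32L) stop("frame must be at least 32 x 32")
  if (nHighlights < 0L || vesselCount < 0L || fatBlobs < 0L)
    stop("counts must be >= 0")
  if (radiusRange[1L] > radiusRange[2L] ||
      2 * radiusRange[2L] + 6 >= min(height, width))
    stop("radiusRange must be increasing and fit inside the frame")
  list(seed = as.integer(seed), height = as.integer(height),
       width = as.integer(width), targetClass = targetClass,
       nHighlights = as.integer(nHighlights), radiusRange = radiusRange,
       halo = isTRUE(halo), vesselCount = as.integer(vesselCount),
       fatBlobs = as.integer(fatBlobs))
}

# smoothed uniform noise in [0, 1]
.smoothNoise <- function(H, W, sigma) {
  x <- matrix(stats::runif(H * W), H, W)
  x <- EBImage::gblur(x, sigma = sigma)
  rng <- range(x)
  if (diff(rng) < 1e-12) return(matrix(0.5, H, W))
  (x - rng[1L]) / diff(rng)
}

# soft saturating camera response: linear scene intensity -> 8-bit display
.toneMap <- function(s) 255 * (1 - exp(-s / 170))

#' Generate one synthetic endoscopic frame with ground truth
#'
#' @param spec a [syntheticSpec()] list.
#' @return list with `image` (an [RgbImage-class]), `mask` (the
#'   ground-truth [HighlightMask-class] of exactly the specular blobs),
#'   `gain` (the exposure factor used) and `spec`.
#' @examples
#' fx <- generateFixture(syntheticSpec(seed = 7, targetClass = "low"))
#' classifyBrightness(fx$image)$class  # "low"
#' @export
generateFixture <- function(spec = syntheticSpec()) {
  .withSeed(spec$seed, {
    H <- spec$height; W <- spec$width
    t1 <- .smoothNoise(H, W, sigma = min(H, W) / 14)
    t2 <- .smoothNoise(H, W, sigma = min(H, W) / 14)
    t3 <- .smoothNoise(H, W, sigma = min(H, W) / 14)
    base <- array(0, c(H, W, 3L))
    base[, , 1L] <- 130 + 70 * t1
    base[, , 2L] <- 55 + 55 * (0.7 * t1 + 0.3 * t2)
    base[, , 3L] <- 45 + 45 * (0.6 * t1 + 0.4 * t3)

    # vessels: darker red random walks, slightly blurred
    vf <- matrix(1, H, W)
    if (spec$vesselCount > 0L) {
      for (v in seq_len(spec$vesselCount)) {
        y <- stats::runif(1, 0.15 * H, 0.85 * H)
        x <- stats::runif(1, 0.15 * W, 0.85 * W)
        ang <- stats::runif(1, 0, 2 * pi)
        for (s in seq_len(round(0.5 * (H + W)))) {
          ang <- ang + stats::rnorm(1, 0, 0.18)
          y <- y + sin(ang); x <- x + cos(ang)
          iy <- round(y); ix <- round(x)
          if (iy < 2L || iy > H - 1L || ix < 2L || ix > W - 1L) break
          vf[(iy - 1L):(iy + 1L), (ix - 1L):(ix + 1L)] <- 0.7
          vf[iy, ix] <- 0.5
        }
      }
      vf <- EBImage::gblur(vf, sigma = 0.8)
    }
    for (ch in 1:3) base[, , ch] <- base[, , ch] * vf

    # fat: soft-edged yellowish blobs (diffuse, low gradient)
    if (spec$fatBlobs > 0L) {
      yy <- row(vf); xx <- col(vf)
      for (fb in seq_len(spec$fatBlobs)) {
        cy <- stats::runif(1, 0.1 * H, 0.9 * H)
        cx <- stats::runif(1, 0.1 * W, 0.9 * W)
        r <- stats::runif(1, 8, 16)
        a <- exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * (r / 1.6)^2))
        fat <- c(225, 205, 90) * stats::runif(3, 0.95, 1.05)
        for (ch in 1:3)
          base[, , ch] <- (1 - a) * base[, , ch] + a * fat[ch]
      }
    }

    # specular blobs: near-equal channels, >= 240, optional darker halo
    gt <- matrix(0L, H, W)
    halo <- matrix(1, H, W)
    hl <- vector("list", spec$nHighlights)
    if (spec$nHighlights > 0L) {
      yy <- row(gt); xx <- col(gt)
      rmax <- spec$radiusRange[2L]
      for (hb in seq_len(spec$nHighlights)) {
        r <- stats::runif(1, spec$radiusRange[1L], spec$radiusRange[2L])
        cy <- stats::runif(1, rmax + 4, H - rmax - 4)
        cx <- stats::runif(1, rmax + 4, W - rmax - 4)
        ay <- r * stats::runif(1, 0.8, 1.2)
        ax <- r * stats::runif(1, 0.8, 1.2)
        d <- sqrt(((yy - cy) / ay)^2 + ((xx - cx) / ax)^2)
        core <- d <= 1
        gt[core] <- 1L
        if (spec$halo) halo[d > 1 & d <= 1 + 1.5 / r] <- 0.55
        v <- stats::runif(1, 244, 251)
        hl[[hb]] <- list(sel = core, v = v)
      }
    }

    compose <- function(gain) {
      out <- array(0, c(H, W, 3L))
      for (ch in 1:3)
        out[, , ch] <- .toneMap(gain * base[, , ch] * halo)
      for (hb in seq_along(hl)) {
        sel <- hl[[hb]]$sel
        n <- sum(sel)
        for (ch in 1:3)
          out[, , ch][sel] <- .clip(hl[[hb]]$v + stats::runif(n, -3, 3),
                                    240, 255)
      }
      .round8(out)
    }
    # the per-pixel highlight noise is drawn under a frozen sub-seed so the
    # gain bisection below sees the same frame at every iteration
    laTarget <- switch(spec$targetClass, high = 190, medium = 120, low = 65)
    lo <- 0.05; hi <- 8
    gain <- 1
    for (i in seq_len(20L)) {
      gain <- (lo + hi) / 2
      la <- .withSeed(spec$seed + 1L,
                      meanBrightness(RgbImage(compose(gain))))
      if (la < laTarget) lo <- gain else hi <- gain
    }
    img <- .withSeed(spec$seed + 1L, RgbImage(compose(gain)))
    got <- classifyBrightness(img)$class
    if (got != spec$targetClass)
      stop(sprintf("could not reach brightness class '%s' (got '%s')",
                   spec$targetClass, got))
    list(image = img, mask = HighlightMask(gt), gain = gain, spec = spec)
  })
}

#' Generate a seeded dataset of fixtures
#'
#' `n` fixtures with seeds `baseSeed .. baseSeed + n - 1` and brightness
#' classes cycled high / medium / low.
#'
#' @param n number of fixtures (>= 1).
#' @param baseSeed first seed.
#' @param template a [syntheticSpec()] whose non-seed, non-class fields are
#'   reused.
#' @return list of [generateFixture()] results.
#' @export
generateDataset <- function(n, baseSeed = 1L, template = syntheticSpec()) {
  stopifnot(n >= 1L)
  classes <- c("high", "medium", "low")
  lapply(seq_len(n), function(i) {
    sp <- template
    sp$seed <- as.integer(baseSeed + i - 1L)
    sp$targetClass <- classes[((i - 1L) %% 3L) + 1L]
    generateFixture(sp)
  })
}
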