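#' Specular detector parameters
#'
#' Brightness-dependent weights of the adaptive absolute-highlight
#' threshold and the structural parameters of the two detection branches.
#' Larger `tau` gives a smaller threshold, i.e. a more permissive detector;
#' hence `tauHigh < tauMed < tauLow` (low-brightness images are thresholded
#' after enhancement).
#'
#' @param tauHigh,tauMed,tauLow threshold weights per brightness class
#'   (defaults 0.3, 0.8, 1.1).
#' @param tophatRadius disc radius (pixels) of the top-hat/bottom-hat
#'   structuring element; `NULL` (default) picks 5 px for images up to
#'   512 px and scales as `round(5 * max(H, W) / 512)` above.
#' @param sobelThreshold gradient-magnitude cut for the relative branch;
#'   `NULL` (default) uses 4x the image's mean gradient magnitude.
#' @param minIntensityRel intensity floor for relative-highlight
#'   candidates; `NULL` (default) uses `mean(gray) + sd(gray)`.
#' @param dilateRadius disc radius of the final mask dilation (default 2).
#' @return a named parameter list.
#' @export
detectorParams <- function(tauHigh = 0.3, tauMed = 0.8, tauLow = 1.1,
                           tophatRadius = NULL, sobelThreshold = NULL,
                           minIntensityRel = NULL, dilateRadius = 2L) {
  if (!(tauHigh < tauMed && tauMed < tauLow))
    stop("tau weights must satisfy tauHigh < tauMed < tauLow")
  if (dilateRadius < 0) stop("dilateRadius must be >= 0")
  list(tauHigh = tauHigh, tauMed = tauMed, tauLow = tauLow,
       tophatRadius = tophatRadius, sobelThreshold = sobelThreshold,
       minIntensityRel = minIntensityRel, dilateRadius = as.integer(dilateRadius))
}

# 3x3 Sobel gradient magnitude, replicate border, exact spatial-domain
# arithmetic (a constant image yields an exactly zero field)
.sobelMagnitude <- function(gray) {
  H <- nrow(gray); W <- ncol(gray)
  sh <- function(dy, dx) {
    ys <- .clip(seq_len(H) + dy, 1L, H)
    xs <- .clip(seq_len(W) + dx, 1L, W)
    gray[ys, xs, drop = FALSE]
  }
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
    (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
    (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  sqrt(gx^2 + gy^2)
}

.tophatRadiusFor <- function(dims, params) {
  if (!is.null(params$tophatRadius)) return(as.integer(params$tophatRadius))
  m <- max(dims[1L], dims[2L])
  if (m <= 512L) 5L else as.integer(round(5 * m / 512))
}

#' Top-hat/bottom-hat contrast enhancement
#'
#' Per channel, `out = clip(in + tophat(in) - bottomhat(in))` where the
#' top-hat is the image minus its morphological opening and the bottom-hat
#' the closing minus the image, both with a Euclidean disc structuring
#' element. Small bright structures (specular blobs) are amplified, small
#' dark ones suppressed. A constant image is unchanged.
#'
#' @param image an [RgbImage-class].
#' @param radius disc radius in pixels; `NULL` uses the size-scaled default
#'   of [detectorParams()].
#' @return an [RgbImage-class] with integer intensities.
#' @export
contrastEnhance <- function(image, radius = NULL) {
  px <- .asPixels(image)
  r <- if (is.null(radius)) .tophatRadiusFor(dim(px), detectorParams())
       else as.integer(radius)
  k <- .discKernel(r)
  out <- px
  for (ch in 1:3) {
    x <- px[, , ch] / 255
    op <- EBImage::opening(x, k)
    cl <- EBImage::closing(x, k)
    out[, , ch] <- .round8((3 * x - op - cl) * 255)
  }
  RgbImage(out)
}

#' Mean and standard deviation of the G and B channels
#'
#' Sample statistics (denominator `n - 1`) of the green and blue channels,
#' as used by the adaptive absolute-highlight threshold. Computed on
#' whatever image is passed in; the detector passes the contrast-enhanced
#' image.
#'
#' @param image an [RgbImage-class].
#' @return list with `muG`, `muB`, `sigmaG`, `sigmaB`.
#' @export
channelStats <- function(image) {
  px <- .asPixels(image)
  if (prod(dim(px)[1:2]) < 2L)
    stop("channel statistics need at least 2 pixels")
  g <- as.vector(px[, , 2L]); b <- as.vector(px[, , 3L])
  list(muG = mean(g), muB = mean(b),
       sigmaG = stats::sd(g), sigmaB = stats::sd(b))
}

#' Brightness-adaptive absolute-highlight threshold
#'
#' `Th = maxgb - tau(class) * (sigmaG + sigmaB) / 2`, clipped below at 0,
#' where `maxgb` is the global maximum intensity over the G and B channels
#' and `tau` the class-dependent weight of [detectorParams()]. High
#' brightness gives the smallest `tau`, hence the largest (most
#' conservative) threshold.
#'
#' @param stats a [channelStats()] list.
#' @param class `"high"`, `"medium"` or `"low"`.
#' @param maxgb global max of the G and B channels, in `[0, 255]`.
#' @param params a [detectorParams()] list.
#' @return the scalar threshold `Th`.
#' @export
absoluteThreshold <- function(stats, class, maxgb, params = detectorParams()) {
  tau <- switch(class, high = params$tauHigh, medium = params$tauMed,
                low = params$tauLow,
                stop("unknown brightness class: ", class))
  max(0, maxgb - tau * (stats$sigmaG + stats$sigmaB) / 2)
}

#' Detect absolute (saturated) highlights
#'
#' Thresholds the contrast-enhanced image: a pixel is flagged when
#' `max(G(p), B(p)) >= Th` with the single global threshold of
#' [absoluteThreshold()]. When the channel spread is degenerate
#' (`sigmaG + sigmaB < 1`, near-constant image) the threshold collapses to
#' the global maximum and every pixel would qualify, so no absolute
#' highlights are declared.
#'
#' @param image an [RgbImage-class] (the frame to analyse; contrast
#'   enhancement is applied internally).
#' @param class brightness class of the frame (see [classifyBrightness()]).
#' @param params a [detectorParams()] list.
#' @param enhanced optionally, a pre-computed [contrastEnhance()] result to
#'   reuse.
#' @return a [HighlightMask-class], with the threshold attached as
#'   attribute `Th` (`NA` when the degenerate guard fired).
#' @export
detectAbsolute <- function(image, class, params = detectorParams(),
                           enhanced = NULL) {
  ce <- if (is.null(enhanced)) contrastEnhance(image, params$tophatRadius)
        else enhanced
  px <- .asPixels(ce)
  st <- channelStats(ce)
  gb <- pmax(px[, , 2L], px[, , 3L])
  if (st$sigmaG + st$sigmaB < 1) {
    m <- HighlightMask(matrix(0L, dim(px)[1L], dim(px)[2L]))
    attr(m, "Th") <- NA_real_
    return(m)
  }
  Th <- absoluteThreshold(st, class, max(gb), params)
  m <- HighlightMask(gb >= Th)
  attr(m, "Th") <- Th
  m
}

#' Detect relative highlights from the gradient map
#'
#' Fainter highlights with unstable intensity still show sharp brightness
#' transitions. The grayscale image is filtered with the 3x3 Sobel
#' operator; pixels whose gradient magnitude reaches `sobelThreshold`
#' become candidates, candidates darker than `minIntensityRel` are
#' discarded, and holes enclosed by candidate rings are filled so a bright
#' blob outlined by its own edge is flagged in full.
#'
#' @param image an [RgbImage-class].
#' @param params a [detectorParams()] list.
#' @return a [HighlightMask-class].
#' @export
detectRelative <- function(image, params = detectorParams()) {
  px <- .asPixels(image)
  gray <- .luma(px)
  g <- .sobelMagnitude(gray)
  thr <- if (is.null(params$sobelThreshold)) 4 * mean(g) else params$sobelThreshold
  if (thr <= 0)  # gradient-free frame: no relative highlights by definition
    return(HighlightMask(matrix(0L, nrow(gray), ncol(gray))))
  floorI <- if (is.null(params$minIntensityRel))
    mean(gray) + stats::sd(as.vector(gray)) else params$minIntensityRel
  cand <- (g >= thr) & (gray >= floorI)
  filled <- EBImage::fillHull(matrix(as.integer(cand), nrow(cand)))
  HighlightMask(filled >= 1L)
}

#' Dilate a binary mask with a disc
#'
#' Binary dilation by a Euclidean disc (pixels at distance <= radius from
#' the center); radius 0 is the identity. Dilation never removes set
#' pixels and is monotone in the radius.
#'
#' @param mask a [HighlightMask-class].
#' @param radius disc radius in pixels (>= 0).
#' @return a [HighlightMask-class].
#' @export
dilateMask <- function(mask, radius) {
  m <- .asMaskMatrix(mask)
  if (radius == 0 || sum(m) == 0L) return(HighlightMask(m))
  HighlightMask(EBImage::dilate(m, .discKernel(radius)) >= 1L)
}

#' Full specular-highlight detection
#'
#' The complete detection pipeline: classify the frame's brightness,
#' enhance it if low, contrast-enhance for the absolute branch, take the
#' union of the absolute (adaptive G/B threshold) and relative (Sobel)
#' masks, dilate with a disc (halo rings around bright spots are thereby
#' covered), and render the green overlay.
#'
#' @param image an [RgbImage-class].
#' @param params a [detectorParams()] list.
#' @param classifier a [classifierParams()] list.
#' @return a list with `mask` (final [HighlightMask-class]), `overlay`
#'   (green-marked [RgbImage-class]), `work` (the analysed image: enhanced
#'   for low-brightness frames, the input otherwise), `class`, `Th`,
#'   `maskAbsolute`, `maskRelative`, and `union` (pre-dilation mask).
#' @export
detectHighlights <- function(image, params = detectorParams(),
                             classifier = classifierParams()) {
  cls <- classifyBrightness(image, classifier)$class
  work <- if (cls == "low") enhanceBrightness(image) else image
  ce <- contrastEnhance(work, params$tophatRadius)
  mAbs <- detectAbsolute(work, cls, params, enhanced = ce)
  mRel <- detectRelative(work, params)
  u <- HighlightMask((mAbs@.Data | mRel@.Data))
  final <- dilateMask(u, params$dilateRadius)
  list(mask = final, overlay = overlayMask(work, final), work = work,
       class = cls, Th = attr(mAbs, "Th"),
       maskAbsolute = mAbs, maskRelative = mRel, union = u)
}
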