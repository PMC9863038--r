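#' Brightness classifier parameters
#'
#' `La` is the expected global average brightness of a normally exposed
#' endoscopic frame (8-bit intensity units) and `t1` the relative-deviation
#' threshold separating the three brightness classes. The defaults (112 and
#' 0.3) are the values reported to give the best class separation on
#' clinical endoscopic material.
#'
#' @param La expected average brightness, in `(0, 255]`. Default 112.
#' @param t1 relative-deviation threshold, in `(0, 1)`. Default 0.3.
#' @param channel scalar-brightness definition: `"luma"` (ITU-R BT.601
#'   0.299R + 0.587G + 0.114B, the default), `"v"` (HSV value channel,
#'   max(R,G,B)), or `"gray"` (plain channel mean).
#' @return a named list of validated parameters.
#' @export
classifierParams <- function(La = 112, t1 = 0.3,
                             channel = c("luma", "v", "gray")) {
  channel <- match.arg(channel)
  if (!(La > 0 && La <= 255)) stop("La must lie in (0, 255]")
  if (!(t1 > 0 && t1 < 1)) stop("t1 must lie in (0, 1)")
  list(La = La, t1 = t1, channel = channel)
}

#' Average brightness of an image
#'
#' The arithmetic mean `la` of the per-pixel scalar brightness, by default
#' the BT.601 luma.
#'
#' @param image an [RgbImage-class].
#' @param channel see [classifierParams()].
#' @return a single value in `[0, 255]`.
#' @examples
#' meanBrightness(RgbImage(array(112, c(4, 4, 3))))  # 112
#' @export
meanBrightness <- function(image, channel = c("luma", "v", "gray")) {
  channel <- match.arg(channel)
  px <- .asPixels(image)
  if (length(px) == 0L) stop("empty image")
  switch(channel,
         luma = mean(.luma(px)),
         v    = mean(pmax(px[, , 1L], px[, , 2L], px[, , 3L])),
         gray = mean(px))
}

#' Relative brightness deviation
#'
#' `T1 = (la - La) / la`: the deviation of the observed average brightness
#' `la` from the expected brightness `La`, relative to the observed value.
#' Positive when the image is brighter than expected.
#'
#' @param la observed average brightness (must be > 0).
#' @param La expected average brightness.
#' @return a signed dimensionless value.
#' @export
relativeDeviation <- function(la, La = 112) {
  if (la <= 0) stop("relative deviation undefined for la <= 0")
  (la - La) / la
}

#' Classify an image as high-, medium- or low-brightness
#'
#' The image is `"high"` when `T1 > t1`, `"low"` when `T1 < -t1`, and
#' `"medium"` otherwise (boundary ties go to medium). A fully black image
#' (`la = 0`, `T1` undefined) is classified `"low"`.
#'
#' @param image an [RgbImage-class].
#' @param params a [classifierParams()] list.
#' @return a list with `class` (`"high"`, `"medium"` or `"low"`), `la` and
#'   `T1` (`NA` when `la = 0`).
#' @examples
#' classifyBrightness(RgbImage(array(200, c(4, 4, 3))))$class  # "high"
#' @export
classifyBrightness <- function(image, params = classifierParams()) {
  la <- meanBrightness(image, params$channel)
  if (la == 0)
    return(list(class = "low", la = 0, T1 = NA_real_))
  T1 <- relativeDeviation(la, params$La)
  cls <- if (T1 > params$t1) "high" else if (T1 < -params$t1) "low" else "medium"
  list(class = cls, la = la, T1 = T1)
}
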