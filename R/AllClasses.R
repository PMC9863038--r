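#' RgbImage: an 8-bit RGB raster
#'
#' The universal image carrier of the package: a numeric `H x W x 3` array
#' indexed `[y, x, channel]` (row-major thinking: `y` increases downward),
#' channels ordered R, G, B, intensities on the 8-bit scale `[0, 255]`.
#'
#' @slot .Data numeric array of dimension `c(height, width, 3)`.
#' @seealso [RgbImage()], [loadImage()], [HighlightMask-class]
#' @export
setClass("RgbImage", contains = "array", validity = function(object) {
  d <- dim(object)
  if (length(d) != 3L || d[3L] != 3L)
    return("pixels must be an H x W x 3 array (R,G,B)")
  if (d[1L] < 1L || d[2L] < 1L)
    return("image must have at least one pixel")
  v <- object@.Data
  if (anyNA(v)) return("pixel intensities must not be NA")
  if (min(v) < 0 || max(v) > 255)
    return("pixel intensities must lie in [0, 255]")
  TRUE
})

#' HighlightMask: a binary specular mask
#'
#' An `H x W` integer matrix with values in \{0, 1\}; 1 marks a specular
#' pixel (the region to inpaint, often written \eqn{\Omega}), 0 a known
#' pixel (\eqn{\phi}). Dimensions must match the paired [RgbImage-class].
#'
#' @slot .Data integer matrix of 0/1 values.
#' @seealso [HighlightMask()], [overlayMask()], [extractRegions()]
#' @export
setClass("HighlightMask", contains = "matrix", validity = function(object) {
  v <- object@.Data
  if (!is.numeric(v)) return("mask values must be numeric 0/1")
  if (anyNA(v)) return("mask values must not be NA")
  if (!all(v == 0L | v == 1L)) return("mask values must be 0 or 1")
  TRUE
})

#' HighlightRegion: one connected specular component
#'
#' One 8-connected component of a [HighlightMask-class]: its pixels, its
#' contour (mask pixels 4-adjacent to at least one unmasked pixel), the
#' contour length `lc`, and the bounding extremes used by the adaptive
#' search window.
#'
#' @slot label integer component id (raster-encounter order).
#' @slot pixels two-column integer matrix of (y, x) coordinates (1-based).
#' @slot contour two-column integer matrix of boundary (y, x) coordinates.
#' @slot lc integer, contour length in pixels.
#' @slot yup,ydown,xleft,xright integer bounding extremes.
#' @seealso [extractRegions()], [searchWindow()]
#' @export
setClass("HighlightRegion", representation(
  label = "integer", pixels = "matrix", contour = "matrix",
  lc = "integer", yup = "integer", ydown = "integer",
  xleft = "integer", xright = "integer"
), validity = function(object) {
  if (nrow(object@pixels) < 1L) return("region must contain pixels")
  if (object@lc < 1L) return("contour length must be >= 1")
  if (object@yup > object@ydown || object@xleft > object@xright)
    return("degenerate bounding box")
  TRUE
})

#' @describeIn RgbImage-class construct from an array (coerced to [0,255]).
#' @param pixels numeric `H x W x 3` array.
#' @export
RgbImage <- function(pixels) {
  new("RgbImage", pixels)
}

#' @describeIn HighlightMask-class construct from a 0/1 matrix.
#' @param values numeric or logical `H x W` matrix.
#' @export
HighlightMask <- function(values) {
  if (is.logical(values)) {
    values <- matrix(as.integer(values), nrow(values), ncol(values))
  }
  storage.mode(values) <- "integer"
  new("HighlightMask", values)
}

#' @export
setMethod("show", "RgbImage", function(object) {
  d <- dim(object)
  cat(sprintf("RgbImage: %d x %d pixels, 3 channels (R,G,B), range [%g, %g]\n",
              d[1L], d[2L], min(object@.Data), max(object@.Data)))
})

#' @export
setMethod("show", "HighlightMask", function(object) {
  d <- dim(object)
  n <- sum(object@.Data)
  cat(sprintf("HighlightMask: %d x %d, %d specular pixels (%.2f%%)\n",
              d[1L], d[2L], n, 100 * n / prod(d)))
})

#' @export
setMethod("show", "HighlightRegion", function(object) {
  cat(sprintf(
    "HighlightRegion #%d: %d pixels, contour length %d, bbox rows %d..%d cols %d..%d\n",
    object@label, nrow(object@pixels), object@lc,
    object@yup, object@ydown, object@xleft, object@xright))
})

#' Region bounding-box height and width
#'
#' Height `h = ydown - yup + 1` and width `w = xright - xleft + 1` of a
#' region's bounding box, as used by the adaptive search window.
#'
#' @param region a [HighlightRegion-class].
#' @return integer of length one.
#' @export
regionHeight <- function(region) region@ydown - region@yup + 1L

#' @rdname regionHeight
#' @export
regionWidth <- function(region) region@xright - region@xleft + 1L

#' Contour length of a region
#' @param region a [HighlightRegion-class].
#' @return integer: number of contour pixels.
#' @export
contourLength <- function(region) region@lc
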