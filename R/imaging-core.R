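#' Read an 8-bit RGB image from PNG or JPEG
#'
#' Decodes a PNG or JPEG file into an [RgbImage-class] with channels in
#' R,G,B order and intensities on `[0, 255]`. Grayscale files are promoted
#' to three identical channels; an alpha channel, if present, is dropped.
#'
#' @param path path to an 8-bit PNG or JPEG file.
#' @return an [RgbImage-class].
#' @examples
#' img <- RgbImage(array(128, c(8, 8, 3)))
#' f <- tempfile(fileext = ".png")
#' saveImage(img, f)
#' identical(loadImage(f)@.Data, img@.Data)
#' @export
loadImage <- function(path) {
  if (!file.exists(path)) stop("cannot read image: file not found: ", path)
  im <- tryCatch(EBImage::readImage(path),
                 error = function(e) stop("cannot decode image '", path,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  a <- EBImage::imageData(im)
  if (length(dim(a)) == 2L) {
    a <- array(rep(a, 3L), c(dim(a), 3L))
  } else if (dim(a)[3L] >= 3L) {
    a <- a[, , 1:3, drop = FALSE]
  } else {
    stop("unsupported channel layout in '", path, "'")
  }
  v <- a * 255
  if (max(abs(v - round(v))) > 1e-6)
    stop("image '", path, "' is not 8-bit; only 8-bit PNG/JPEG are supported")
  RgbImage(aperm(round(v), c(2L, 1L, 3L)))
}

#' Write an RgbImage as PNG
#'
#' Processed outputs are always written as PNG (lossless); JPEG is accepted
#' on input only, to avoid recompression loss.
#'
#' @param image an [RgbImage-class].
#' @param path output path (PNG).
#' @return invisibly, `path`.
#' @export
saveImage <- function(image, path) {
  px <- .asPixels(image)
  im <- EBImage::Image(aperm(px / 255, c(2L, 1L, 3L)), colormode = "Color")
  EBImage::writeImage(im, path, type = "png", bits.per.sample = 8L)
  invisible(path)
}

#' Read and write binary highlight masks
#'
#' On disk a mask is a single-channel 8-bit PNG with 1 stored as 255 and 0
#' as 0. Loading thresholds at >= 128 so antialiased masks binarize
#' deterministically.
#'
#' @param mask a [HighlightMask-class].
#' @param path PNG path.
#' @return `loadMask` returns a [HighlightMask-class]; `saveMask` returns
#'   `path` invisibly.
#' @export
saveMask <- function(mask, path) {
  m <- .asMaskMatrix(mask)
  im <- EBImage::Image(t(m))
  EBImage::writeImage(im, path, type = "png", bits.per.sample = 8L)
  invisible(path)
}

#' @rdname saveMask
#' @export
loadMask <- function(path) {
  if (!file.exists(path)) stop("cannot read mask: file not found: ", path)
  im <- tryCatch(EBImage::readImage(path),
                 error = function(e) stop("cannot decode mask '", path,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  a <- EBImage::imageData(im)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  HighlightMask(t(a * 255 >= 128))
}

#' Mark a specular mask in green on an image
#'
#' Pixels where the mask is 1 are replaced by pure green `(0, 255, 0)`;
#' all other pixels are byte-identical to the input.
#'
#' @param image an [RgbImage-class].
#' @param mask a [HighlightMask-class] of matching dimensions.
#' @return an [RgbImage-class].
#' @export
overlayMask <- function(image, mask) {
  px <- .asPixels(image)
  m <- .asMaskMatrix(mask)
  .checkSameDim(px, m)
  sel <- m == 1L
  px[, , 1L][sel] <- 0
  px[, , 2L][sel] <- 255
  px[, , 3L][sel] <- 0
  RgbImage(px)
}

#' RGB/HSV raster conversion
#'
#' `rgbToHsvRaster` converts an 8-bit RGB raster to H, S in `[0, 1]` and an
#' 8-bit value channel `V = max(R, G, B)`. `hsvToRgbRaster` inverts it; the
#' round trip reproduces the raster within +/- 1 per channel (quantization).
#'
#' @param image an [RgbImage-class] or `H x W x 3` array.
#' @return `rgbToHsvRaster`: list with matrices `h`, `s` (in `[0,1]`) and
#'   `v` (on `[0,255]`); `hsvToRgbRaster`: an `H x W x 3` array on `[0,255]`
#'   (unrounded).
#' @export
rgbToHsvRaster <- function(image) {
  px <- .asPixels(image)
  d <- dim(px)
  hsv <- grDevices::rgb2hsv(
    r = as.vector(px[, , 1L]), g = as.vector(px[, , 2L]),
    b = as.vector(px[, , 3L]), maxColorValue = 255)
  list(h = matrix(hsv[1L, ], d[1L], d[2L]),
       s = matrix(hsv[2L, ], d[1L], d[2L]),
       v = matrix(hsv[3L, ] * 255, d[1L], d[2L]))
}

#' @rdname rgbToHsvRaster
#' @param h,s hue and saturation matrices in `[0, 1]`.
#' @param v value matrix on `[0, 255]`.
#' @export
hsvToRgbRaster <- function(h, s, v) {
  c_ <- as.vector(v) * as.vector(s)
  h6 <- as.vector(h) * 6
  x <- c_ * (1 - abs(h6 %% 2 - 1))
  m <- as.vector(v) - c_
  sector <- pmin(floor(h6), 5)
  r <- g <- b <- numeric(length(c_))
  idx <- sector == 0; r[idx] <- c_[idx]; g[idx] <- x[idx]
  idx <- sector == 1; r[idx] <- x[idx];  g[idx] <- c_[idx]
  idx <- sector == 2; g[idx] <- c_[idx]; b[idx] <- x[idx]
  idx <- sector == 3; g[idx] <- x[idx];  b[idx] <- c_[idx]
  idx <- sector == 4; r[idx] <- x[idx];  b[idx] <- c_[idx]
  idx <- sector == 5; r[idx] <- c_[idx]; b[idx] <- x[idx]
  d <- dim(h)
  out <- array(0, c(d[1L], d[2L], 3L))
  out[, , 1L] <- r + m
  out[, , 2L] <- g + m
  out[, , 3L] <- b + m
  out
}
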