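# internal helpers shared across modules

# round half away from zero, then clip to the 8-bit range
.round8 <- function(x) {
  pmin(pmax(sign(x) * floor(abs(x) + 0.5), 0), 255)
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# ITU-R BT.601 luma of an H x W x 3 array, H x W double (dims preserved
# even for single-row/column rasters)
.luma <- function(pixels) {
  d <- dim(pixels)
  matrix(0.299 * pixels[, , 1L] + 0.587 * pixels[, , 2L] +
           0.114 * pixels[, , 3L], d[1L], d[2L])
}

.asPixels <- function(image) {
  if (is(image, "RgbImage")) image@.Data else image
}

.asMaskMatrix <- function(mask) {
  m <- if (is(mask, "HighlightMask")) mask@.Data else mask
  if (is.logical(m)) m <- matrix(as.integer(m), nrow(m), ncol(m))
  m
}

.checkSameDim <- function(a, b, what = "mask") {
  if (!identical(dim(a)[1:2], dim(b)[1:2]))
    stop(sprintf("%s dimensions (%s) do not match image dimensions (%s)",
                 what, paste(dim(b)[1:2], collapse = "x"),
                 paste(dim(a)[1:2], collapse = "x")), call. = FALSE)
  invisible(TRUE)
}

# run `expr` under a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Euclidean disc structuring element: pixels at distance <= radius
.discKernel <- function(radius) {
  r <- as.integer(radius)
  if (r < 0L) stop("radius must be >= 0")
  if (r == 0L) return(matrix(1, 1L, 1L))
  d <- seq(-r, r)
  k <- outer(d^2, d^2, "+") <= radius^2
  matrix(as.numeric(k), 2L * r + 1L)
}
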