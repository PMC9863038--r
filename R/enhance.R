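#' Adaptive gamma correction of a value channel
#'
#' Mean-anchored gamma: `gamma = log(0.5) / log(mu/255)` with `mu` the mean
#' of `V` clipped to `[1, 254]`, so the mean intensity is mapped towards
#' mid-gray. `gamma < 1` (brightening) whenever `mu < 127.5`. 0 and 255 are
#' fixed points for any gamma.
#'
#' @param V numeric matrix on `[0, 255]`.
#' @param gamma optional fixed exponent overriding the adaptive rule.
#' @param quantize round the result to 8-bit integers (default `TRUE`; the
#'   enhancement chain keeps unrounded values internally).
#' @return a matrix on `[0, 255]`.
#' @examples
#' adaptiveGamma(matrix(64, 4, 4))[1, 1]  # approx 128
#' @export
adaptiveGamma <- function(V, gamma = NULL, quantize = TRUE) {
  if (length(V) == 0L) stop("empty value channel")
  if (is.null(gamma)) {
    mu <- .clip(mean(V), 1, 254)
    gamma <- log(0.5) / log(mu / 255)
  }
  out <- 255 * (V / 255)^gamma
  if (quantize) .round8(out) else out
}

#' Single-level 2-D Haar wavelet transform
#'
#' Orthonormal Haar analysis producing one approximation (low-frequency)
#' band and three detail bands (horizontal, vertical, diagonal). Odd
#' dimensions are handled by replicating the last row/column before the
#' transform; `haarIdwt` crops back, so the round trip is exact to
#' floating-point precision. A constant matrix `c` yields a constant
#' approximation band `2c` and zero detail bands.
#'
#' @param x numeric matrix with both dimensions >= 2.
#' @return a list with `LF` (approximation), `HF` (list of `h`, `v`, `d`
#'   detail matrices) and `dim`, the original input dimension.
#' @export
haarDwt <- function(x) {
  d0 <- dim(x)
  if (is.null(d0) || d0[1L] < 2L || d0[2L] < 2L)
    stop("wavelet transform needs a matrix of at least 2 x 2")
  if (d0[1L] %% 2L) x <- rbind(x, x[d0[1L], , drop = FALSE])
  if (d0[2L] %% 2L) x <- cbind(x, x[, ncol(x), drop = FALSE])
  s2 <- sqrt(2)
  oy <- seq(1L, nrow(x), 2L)
  rl <- (x[oy, , drop = FALSE] + x[oy + 1L, , drop = FALSE]) / s2
  rh <- (x[oy, , drop = FALSE] - x[oy + 1L, , drop = FALSE]) / s2
  ox <- seq(1L, ncol(x), 2L)
  list(LF = (rl[, ox, drop = FALSE] + rl[, ox + 1L, drop = FALSE]) / s2,
       HF = list(
         h = (rh[, ox, drop = FALSE] + rh[, ox + 1L, drop = FALSE]) / s2,
         v = (rl[, ox, drop = FALSE] - rl[, ox + 1L, drop = FALSE]) / s2,
         d = (rh[, ox, drop = FALSE] - rh[, ox + 1L, drop = FALSE]) / s2),
       dim = d0)
}

#' @rdname haarDwt
#' @param bands a list as returned by `haarDwt` (possibly with modified
#'   `LF`/`HF`).
#' @export
haarIdwt <- function(bands) {
  s2 <- sqrt(2)
  LF <- bands$LF; HF <- bands$HF
  rl <- matrix(0, nrow(LF), 2L * ncol(LF))
  rh <- matrix(0, nrow(LF), 2L * ncol(LF))
  ox <- seq(1L, ncol(rl), 2L)
  rl[, ox] <- (LF + HF$v) / s2;  rl[, ox + 1L] <- (LF - HF$v) / s2
  rh[, ox] <- (HF$h + HF$d) / s2; rh[, ox + 1L] <- (HF$h - HF$d) / s2
  x <- matrix(0, 2L * nrow(LF), ncol(rl))
  oy <- seq(1L, nrow(x), 2L)
  x[oy, ] <- (rl + rh) / s2
  x[oy + 1L, ] <- (rl - rh) / s2
  x[seq_len(bands$dim[1L]), seq_len(bands$dim[2L]), drop = FALSE]
}

#' Singular-value equalization of the approximation band
#'
#' With the SVD `LF = U D V'`, the correction factor
#' `xi = (max(D) + max(D_gamma)) / (2 max(D))` rescales the whole singular
#' spectrum of `LF`, transferring half of the intensity gain of the
#' gamma-corrected band `LF_gamma` while keeping the singular vectors of
#' the original band. Degenerate all-zero `LF` falls back to `LF_gamma`.
#'
#' @param LF,LFgamma approximation bands of the original and
#'   gamma-corrected value channel (same shape).
#' @return a list with the equalized band `LF` and the factor `xi`.
#' @export
singularEqualize <- function(LF, LFgamma) {
  if (!identical(dim(LF), dim(LFgamma)))
    stop("LF and LFgamma must have the same shape")
  s <- svd(LF)
  dmax <- s$d[1L]
  if (dmax == 0) return(list(LF = LFgamma, xi = NA_real_))
  dgmax <- svd(LFgamma, nu = 0L, nv = 0L)$d[1L]
  xi <- (dmax + dgmax) / (2 * dmax)
  list(LF = s$u %*% (xi * s$d * t(s$v)), xi = xi)
}

#' Soft-threshold denoising of detail bands
#'
#' Universal threshold `lambda = sigma * sqrt(2 log N)` with the noise
#' scale `sigma` estimated as `median(|diagonal band|) / 0.6745` (MAD rule)
#' and `N` the pixels per band; every detail coefficient is shrunk as
#' `sign(x) * max(|x| - lambda, 0)`.
#'
#' @param HF list of detail matrices `h`, `v`, `d` from [haarDwt()].
#' @return the shrunk band list, with the threshold attached as attribute
#'   `lambda`.
#' @export
softThresholdBands <- function(HF) {
  sigma <- stats::median(abs(HF$d)) / 0.6745
  lambda <- sigma * sqrt(2 * log(length(HF$d)))
  shrink <- function(x) sign(x) * pmax(abs(x) - lambda, 0)
  out <- lapply(HF, shrink)
  attr(out, "lambda") <- lambda
  out
}

#' Enhance the brightness component of a (low-brightness) image
#'
#' The HSV value channel is gamma-corrected, both the original and the
#' corrected channel are decomposed with a single-level Haar transform,
#' the approximation band of the original is singular-value equalized
#' against the corrected one, the detail bands are soft-threshold denoised,
#' and the inverse transform gives the enhanced value channel. Hue and
#' saturation are untouched, so colors are preserved up to the final 8-bit
#' requantization (+/- 1 per channel).
#'
#' @param image an [RgbImage-class].
#' @param gamma optional fixed gamma exponent (e.g. `1` disables the
#'   correction); `NULL` (default) uses the adaptive rule.
#' @param denoise soft-threshold the detail bands (default `TRUE`).
#' @param details if `TRUE` return a list with the enhanced image plus the
#'   pre-requantization `h`, `s`, value channels before/after, `gamma` and
#'   `xi`.
#' @return an [RgbImage-class], or a list when `details = TRUE`.
#' @export
enhanceBrightness <- function(image, gamma = NULL, denoise = TRUE,
                              details = FALSE) {
  hsv <- rgbToHsvRaster(image)
  V <- hsv$v
  Vg <- adaptiveGamma(V, gamma = gamma, quantize = FALSE)
  gammaUsed <- if (is.null(gamma)) {
    log(0.5) / log(.clip(mean(V), 1, 254) / 255)
  } else gamma
  bands <- haarDwt(V)
  bandsG <- haarDwt(Vg)
  eq <- singularEqualize(bands$LF, bandsG$LF)
  HF <- if (denoise) softThresholdBands(bands$HF) else bands$HF
  Venh <- .clip(haarIdwt(list(LF = eq$LF, HF = HF, dim = bands$dim)), 0, 255)
  out <- RgbImage(.round8(hsvToRgbRaster(hsv$h, hsv$s, Venh)))
  if (!details) return(out)
  list(image = out, h = hsv$h, s = hsv$s, vBefore = V, vAfter = Venh,
       gamma = gammaUsed, xi = eq$xi)
}
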