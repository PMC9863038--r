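#' Exemplar-based inpainter parameters
#'
#' @param patchSide side of the square target/source patch, odd (default 9).
#' @param w regularization factor smoothing the confidence curve,
#'   `0 < w < 1` (default 0.7).
#' @param beta data-term weight in the additive (low-confidence) branch of
#'   the priority (default 0.5).
#' @param alpha data-term normalization constant (default 255, the 8-bit
#'   intensity range).
#' @param a contour-length pivot selecting the window expansion
#'   coefficient; `NULL` (default) resolves to `0.05 * (H + W)` at run
#'   time (resolution-dependent).
#' @param n1,n2 search-window expansion coefficients for short (`lc < a`)
#'   and long contours (defaults 2 and 4).
#' @param mode `"improved"` (per-region local priority, adaptive local
#'   search) or `"criminisi"` (the classic global-boundary, global-search
#'   reference algorithm).
#' @param forceFullWindow force the improved mode's search window to the
#'   whole image (used to cross-check the two modes).
#' @param priorityForm `"improved"` (hybrid confidence/data/curvature
#'   branches) or `"original"` (the classic product `Cp * Dp`).
#' @return a named parameter list.
#' @export
inpaintParams <- function(patchSide = 9L, w = 0.7, beta = 0.5, alpha = 255,
                          a = NULL, n1 = 2L, n2 = 4L,
                          mode = c("improved", "criminisi"),
                          forceFullWindow = FALSE,
                          priorityForm = c("improved", "original")) {
  mode <- match.arg(mode)
  priorityForm <- match.arg(priorityForm)
  patchSide <- as.integer(patchSide)
  if (patchSide < 3L || patchSide %% 2L == 0L)
    stop("patchSide must be odd and >= 3")
  if (!(w > 0 && w < 1)) stop("w must lie in (0, 1)")
  if (beta <= 0) stop("beta must be > 0")
  if (!is.null(a) && a <= 0) stop("a must be > 0")
  if (n1 > n2) stop("n1 must be <= n2")
  list(patchSide = patchSide, w = w, beta = beta, alpha = alpha, a = a,
       n1 = as.integer(n1), n2 = as.integer(n2), mode = mode,
       forceFullWindow = forceFullWindow, priorityForm = priorityForm)
}

.resolveA <- function(params, dims) {
  if (!is.null(params$a)) params$a else 0.05 * (dims[1L] + dims[2L])
}

#' Confidence term of a boundary pixel
#'
#' `Cp` is the fraction of reliable information in the patch centered at
#' `p`: the sum of the confidence values of the known pixels in the patch
#' divided by the full patch area. Patches cropped at the image border use
#' the cropped area as denominator.
#'
#' @param p pixel as `c(y, x)` (1-based).
#' @param conf confidence matrix, values in `[0, 1]`.
#' @param mask 0/1 mask matrix (1 = unknown).
#' @param patchSide odd patch side (default 9).
#' @return `Cp` in `[0, 1]`.
#' @export
confidenceTerm <- function(p, conf, mask, patchSide = 9L) {
  m <- .asMaskMatrix(mask)
  r <- (patchSide - 1L) %/% 2L
  ys <- max(1L, p[1L] - r):min(nrow(m), p[1L] + r)
  xs <- max(1L, p[2L] - r):min(ncol(m), p[2L] + r)
  known <- m[ys, xs, drop = FALSE] == 0L
  sum(conf[ys, xs, drop = FALSE][known]) / (length(ys) * length(xs))
}

# per-pixel gradients of `gray` over a window, using known pixels only:
# central difference where both axis neighbors are known, one-sided where
# exactly one is (valid only at known centers), 0 otherwise. Returns dy,
# dx matrices for the window rows ys x cols xs.
.knownGradientField <- function(gray, known, ys, xs) {
  H <- nrow(gray); W <- ncol(gray)
  shift <- function(mat, dy, dx, fill) {
    yy <- ys + dy; xx <- xs + dx
    ok <- outer(yy >= 1L & yy <= H, xx >= 1L & xx <= W, "&")
    out <- matrix(fill, length(ys), length(xs))
    out[ok] <- mat[cbind(pmin(pmax(rep(yy, length(xs)), 1L), H),
                         pmin(pmax(rep(xx, each = length(ys)), 1L), W))][ok]
    out
  }
  v0 <- gray[ys, xs, drop = FALSE]
  axisGrad <- function(dy, dx) {
    kLo <- shift(known, -dy, -dx, FALSE); vLo <- shift(gray, -dy, -dx, 0)
    kHi <- shift(known, dy, dx, FALSE);  vHi <- shift(gray, dy, dx, 0)
    g <- matrix(0, length(ys), length(xs))
    both <- kLo & kHi
    g[both] <- (vHi[both] - vLo[both]) / 2
    hiOnly <- kHi & !kLo
    g[hiOnly] <- vHi[hiOnly] - v0[hiOnly]
    loOnly <- kLo & !kHi
    g[loOnly] <- v0[loOnly] - vLo[loOnly]
    g
  }
  list(dy = axisGrad(1L, 0L), dx = axisGrad(0L, 1L))
}

#' Data term of a boundary pixel
#'
#' `Dp = |isophote . n_p| / alpha`, clipped to `[0, 1]`: the strength of
#' the image structure hitting the fill-front at `p`. The isophote at `p`
#' is estimated from the known pixels of the patch centered at `p`: the
#' grayscale gradient is computed at every known patch pixel by central
#' differences over known pixels only (one-sided at the fill front), the
#' strongest gradient in the patch is rotated 90 degrees, and its
#' projection on the front normal `n_p` (from the gradient of the evolving
#' mask) is normalized by `alpha`. A front with an undefined normal
#' (isolated pixel) uses `(1, 0)` by convention.
#'
#' @param p pixel as `c(y, x)`.
#' @param image grayscale matrix, or an [RgbImage-class] (converted to
#'   luma).
#' @param mask 0/1 mask matrix (1 = unknown).
#' @param alpha normalization constant (default 255).
#' @param patchSide odd patch side (default 9).
#' @return `Dp` in `[0, 1]`.
#' @export
dataTerm <- function(p, image, mask, alpha = 255, patchSide = 9L) {
  gray <- if (is(image, "RgbImage")) .luma(image@.Data) else image
  m <- .asMaskMatrix(mask)
  known <- m == 0L
  r <- (patchSide - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  y <- p[1L]; x <- p[2L]
  ys <- max(1L, y - r):min(H, y + r)
  xs <- max(1L, x - r):min(W, x + r)
  gf <- .knownGradientField(gray, known, ys, xs)
  mag2 <- gf$dy^2 + gf$dx^2
  mag2[!known[ys, xs, drop = FALSE]] <- -1   # only known pixels carry isophotes
  i <- which.max(mag2)
  g <- if (mag2[i] <= 0) c(0, 0) else c(gf$dy[i], gf$dx[i])
  iso <- c(-g[2L], g[1L])                    # rotate (dy, dx) by 90 degrees
  mm <- function(yy, xx) m[.clip(yy, 1L, H), .clip(xx, 1L, W)]
  nrm <- c((mm(y + 1L, x) - mm(y - 1L, x)) / 2,
           (mm(y, x + 1L) - mm(y, x - 1L)) / 2)
  len <- sqrt(sum(nrm^2))
  nrm <- if (len < 1e-12) c(1, 0) else nrm / len
  .clip(abs(sum(iso * nrm)) / alpha, 0, 1)
}

#' Curvature term of a boundary pixel
#'
#' `Kp = div(grad I / |grad I|)` by central finite differences on the
#' grayscale: the curvature of the isophote through `p`. Straight isophotes
#' (e.g. a linear ramp) give 0; where the gradient magnitude is below
#' `eps` the term is defined as 0.
#'
#' @param p pixel as `c(y, x)`.
#' @param image grayscale matrix or [RgbImage-class].
#' @param eps gradient-magnitude guard (default 1e-6).
#' @return the signed curvature `Kp`.
#' @export
curvatureTerm <- function(p, image, eps = 1e-6) {
  gray <- if (is(image, "RgbImage")) .luma(image@.Data) else image
  H <- nrow(gray); W <- ncol(gray)
  at <- function(y, x) gray[.clip(y, 1L, H), .clip(x, 1L, W)]
  grad <- function(y, x) {
    c((at(y + 1L, x) - at(y - 1L, x)) / 2, (at(y, x + 1L) - at(y, x - 1L)) / 2)
  }
  g0 <- grad(p[1L], p[2L])
  if (sqrt(sum(g0^2)) <= eps) return(0)
  unitc <- function(y, x, comp) {
    g <- grad(y, x)
    n <- sqrt(sum(g^2))
    if (n <= eps) 0 else g[comp] / n
  }
  duy <- (unitc(p[1L] + 1L, p[2L], 1L) - unitc(p[1L] - 1L, p[2L], 1L)) / 2
  dvx <- (unitc(p[1L], p[2L] + 1L, 2L) - unitc(p[1L], p[2L] - 1L, 2L)) / 2
  duy + dvx
}

#' Fill-front priority of a boundary pixel
#'
#' The improved priority uses two branches. With the smoothed confidence
#' `R_C(p) = (1 - w) Cp + w`: when `Cp < 0.5` the priority is the weighted
#' sum `R_C(p) + beta * Dp` (the regularized confidence keeps the data term
#' influential even when little is known); when `Cp >= 0.5` it is the
#' product `Cp * (Dp + 1 / (1 + |Kp|))` (confidence dominates, and the
#' curvature-penalized constant keeps the priority away from zero when the
#' data term vanishes while favoring straight isophotes). The
#' `"original"` form is the classic product `Cp * Dp`.
#'
#' @param p pixel as `c(y, x)`.
#' @param conf confidence matrix.
#' @param image grayscale matrix or [RgbImage-class].
#' @param mask 0/1 mask matrix.
#' @param params an [inpaintParams()] list.
#' @return list with `P`, `Cp`, `Dp`, `Kp` (`Kp` is `NA` when not used).
#' @export
patchPriority <- function(p, conf, image, mask, params = inpaintParams()) {
  Cp <- confidenceTerm(p, conf, mask, params$patchSide)
  Dp <- dataTerm(p, image, mask, params$alpha, params$patchSide)
  if (params$priorityForm == "original")
    return(list(P = Cp * Dp, Cp = Cp, Dp = Dp, Kp = NA_real_))
  if (Cp < 0.5) {
    RC <- (1 - params$w) * Cp + params$w
    list(P = RC + params$beta * Dp, Cp = Cp, Dp = Dp, Kp = NA_real_)
  } else {
    Kp <- curvatureTerm(p, image)
    list(P = Cp * (Dp + 1 / (1 + abs(Kp))), Cp = Cp, Dp = Dp, Kp = Kp)
  }
}

#' Adaptive local search window of a region
#'
#' The region's bounding box is expanded by `n` times its own height
#' (rows) and width (columns), with `n = n1` for short contours
#' (`lc < a`) and `n = n2` otherwise, then clipped to the image. If a mask
#' is supplied and the clipped window contains no fully-known candidate
#' patch, `n` grows by 1 and the window is recomputed, up to the full
#' image.
#'
#' @param region a [HighlightRegion-class].
#' @param dims image dimensions `c(H, W)`.
#' @param params an [inpaintParams()] list.
#' @param mask optional 0/1 mask used to verify that at least one
#'   candidate source patch exists.
#' @return list with inclusive 1-based bounds `us`, `ds`, `ls`, `rs` and
#'   the expansion coefficient `n` used.
#' @export
searchWindow <- function(region, dims, params = inpaintParams(), mask = NULL) {
  h <- regionHeight(region); w <- regionWidth(region)
  a <- .resolveA(params, dims)
  n <- if (region@lc < a) params$n1 else params$n2
  r <- (params$patchSide - 1L) %/% 2L
  repeat {
    win <- list(us = max(1L, region@yup - n * h),
                ds = min(dims[1L], region@ydown + n * h),
                ls = max(1L, region@xleft - n * w),
                rs = min(dims[2L], region@xright + n * w),
                n = n)
    full <- win$us == 1L && win$ls == 1L &&
      win$ds == dims[1L] && win$rs == dims[2L]
    if (is.null(mask) || full) return(win)
    cand <- .validCenters(.asMaskMatrix(mask), win, r)
    if (length(cand$y) > 0L) return(win)
    n <- n + 1L
  }
}

# candidate source-patch centers: full patch inside the window and free of
# masked pixels; returned in lexicographic (y, x) order
.validCenters <- function(m, win, r) {
  if (win$ds - win$us < 2L * r || win$rs - win$ls < 2L * r)
    return(list(y = integer(0), x = integer(0)))
  ys <- seq.int(win$us + r, win$ds - r)
  xs <- seq.int(win$ls + r, win$rs - r)
  sub <- m[win$us:win$ds, win$ls:win$rs, drop = FALSE]
  ii <- rbind(0, apply(sub, 2L, cumsum))
  ii <- cbind(0, t(apply(ii, 1L, cumsum)))
  side <- 2L * r + 1L
  a <- seq_along(ys); b <- seq_along(xs)   # patch top-left in sub coords
  boxes <- ii[a + side, b + side, drop = FALSE] -
    ii[a, b + side, drop = FALSE] - ii[a + side, b, drop = FALSE] +
    ii[a, b, drop = FALSE]
  ok <- t(boxes) == 0                       # transposed: rows = x
  idx <- which(ok)
  nx <- length(xs)
  list(y = ys[((idx - 1L) %/% nx) + 1L], x = xs[((idx - 1L) %% nx) + 1L])
}

#' Sum of squared differences between two patches
#'
#' Per-channel squared differences summed over the valid pixels (the
#' target's known pixels). Symmetric in its patch arguments.
#'
#' @param patchA,patchB numeric arrays `p x p x 3` (or matching cropped
#'   shapes).
#' @param valid logical matrix marking the pixels to compare.
#' @return non-negative SSD value.
#' @export
patchSsd <- function(patchA, patchB, valid) {
  if (!identical(dim(patchA), dim(patchB)))
    stop("patches must have the same shape")
  if (!any(valid)) stop("SSD undefined: no valid pixels to compare")
  d2 <- (patchA - patchB)^2
  sum(d2[, , 1L][valid] + d2[, , 2L][valid] + d2[, , 3L][valid])
}

#' Best-matching source patch within a search window
#'
#' Scans every candidate center whose patch lies fully inside the window
#' and contains no masked pixel, computes the SSD against the target patch
#' over the target's known pixels, and returns the minimizer; ties are
#' broken by the smallest `(y, x)` in lexicographic order.
#'
#' @param p target patch center `c(y, x)`.
#' @param win a [searchWindow()] list.
#' @param image an [RgbImage-class] or `H x W x 3` array.
#' @param mask 0/1 mask matrix (1 = unknown; both the original mask and
#'   still-unfilled pixels count as masked).
#' @param patchSide odd patch side (default 9).
#' @return list with `q` (source center), `ssd`, and `nCandidates`; `NULL`
#'   when the window holds no candidate (callers grow the window).
#' @export
bestMatch <- function(p, win, image, mask, patchSide = 9L) {
  px <- .asPixels(image)
  m <- .asMaskMatrix(mask)
  H <- nrow(m); W <- ncol(m)
  r <- (patchSide - 1L) %/% 2L
  cand <- .validCenters(m, win, r)
  if (length(cand$y) == 0L) return(NULL)
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  py <- p[1L] + offs$dy; px_ <- p[2L] + offs$dx
  inside <- py >= 1L & py <= H & px_ >= 1L & px_ <= W
  knownOff <- inside
  knownOff[inside] <- m[cbind(py[inside], px_[inside])] == 0L
  if (!any(knownOff)) stop("target patch has no known pixels")
  base <- (cand$x - 1L) * H + cand$y
  HW <- H * W
  v <- as.vector(px)
  ssd <- numeric(length(base))
  for (k in which(knownOff)) {
    oi <- offs$dx[k] * H + offs$dy[k]
    for (ch in 1:3) {
      tval <- px[py[k], px_[k], ch]
      ssd <- ssd + (v[base + oi + (ch - 1L) * HW] - tval)^2
    }
  }
  i <- which.min(ssd)
  list(q = c(cand$y[i], cand$x[i]), ssd = ssd[i],
       nCandidates = length(base))
}

#' One fill step of the exemplar inpainter
#'
#' Copies the source patch centered at `q` into the unknown pixels of the
#' target patch centered at `p`, sets the confidence of each newly filled
#' pixel to the target's confidence `Cp` at priority time, and clears those
#' pixels from the mask (they become usable sources for later steps). No
#' pixel outside the target patch's unknown area changes.
#'
#' @param state list with `img` (`H x W x 3` array), `mask` (0/1 matrix)
#'   and `conf` (confidence matrix).
#' @param p,q target and source centers `c(y, x)`.
#' @param Cp confidence value assigned to the filled pixels.
#' @param patchSide odd patch side (default 9).
#' @return the updated state, with the filled pixel count as attribute
#'   `nFilled`.
#' @export
fillStep <- function(state, p, q, Cp, patchSide = 9L) {
  H <- nrow(state$mask); W <- ncol(state$mask)
  r <- (patchSide - 1L) %/% 2L
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  ty <- p[1L] + offs$dy; tx <- p[2L] + offs$dx
  sy <- q[1L] + offs$dy; sx <- q[2L] + offs$dx
  ok <- ty >= 1L & ty <= H & tx >= 1L & tx <= W &
    sy >= 1L & sy <= H & sx >= 1L & sx <= W
  ok[ok] <- state$mask[cbind(ty[ok], tx[ok])] == 1L
  if (any(ok)) {
    tIdx <- cbind(ty[ok], tx[ok]); sIdx <- cbind(sy[ok], sx[ok])
    for (ch in 1:3) {
      t3 <- cbind(tIdx, ch); s3 <- cbind(sIdx, ch)
      state$img[t3] <- state$img[s3]
    }
    state$conf[tIdx] <- Cp
    state$mask[tIdx] <- 0L
  }
  attr(state, "nFilled") <- sum(ok)
  state
}
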