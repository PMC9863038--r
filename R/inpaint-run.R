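# region-local inpainting engine: all per-step work happens on a crop of
# the image around the region's search window, so the cost of one fill
# step depends on the highlight size, never on the canvas size. `genv` is
# an environment holding the full-size `img`, `mask` and `conf`, modified
# in place to avoid whole-canvas copies.
.inpaintRegionEngine <- function(genv, region, params) {
  H <- nrow(genv$mask); W <- ncol(genv$mask)
  r <- (params$patchSide - 1L) %/% 2L
  win <- if (params$forceFullWindow)
    list(us = 1L, ds = H, ls = 1L, rs = W, n = NA_integer_)
  else searchWindow(region, c(H, W), params, mask = genv$mask)
  margin <- r + 2L
  cu <- max(1L, win$us - margin); cd <- min(H, win$ds + margin)
  cl <- max(1L, win$ls - margin); cr <- min(W, win$rs + margin)
  simg <- genv$img[cu:cd, cl:cr, , drop = FALSE]
  smask <- genv$mask[cu:cd, cl:cr, drop = FALSE]
  sconf <- genv$conf[cu:cd, cl:cr, drop = FALSE]
  cwin <- list(us = win$us - cu + 1L, ds = win$ds - cu + 1L,
               ls = win$ls - cl + 1L, rs = win$rs - cl + 1L)
  ch <- nrow(smask); cw <- ncol(smask)
  rem <- matrix(FALSE, ch, cw)
  rem[cbind(region@pixels[, 1L] - cu + 1L, region@pixels[, 2L] - cl + 1L)] <- TRUE
  gray <- .luma(simg)
  steps <- 0L; evals <- 0
  while (any(rem)) {
    idx <- which(rem)
    ys <- ((idx - 1L) %% ch) + 1L
    xs <- ((idx - 1L) %/% ch) + 1L
    ord <- order(ys, xs)
    ys <- ys[ord]; xs <- xs[ord]
    knownAt <- function(y, x) y >= 1L & y <= ch & x >= 1L & x <= cw &
      smask[cbind(.clip(y, 1L, ch), .clip(x, 1L, cw))] == 0L
    onFront <- knownAt(ys - 1L, xs) | knownAt(ys + 1L, xs) |
      knownAt(ys, xs - 1L) | knownAt(ys, xs + 1L)
    if (!any(onFront))
      stop("inpainting stalled: region has no reachable fill front")
    by <- ys[onFront]; bx <- xs[onFront]
    best <- NULL; bestP <- -Inf
    for (i in seq_along(by)) {
      p <- c(by[i], bx[i])
      pr <- patchPriority(p, sconf, gray, smask, params)
      if (pr$P > bestP) { bestP <- pr$P; best <- list(p = p, Cp = pr$Cp) }
    }
    bm <- bestMatch(best$p, cwin, simg, smask, params$patchSide)
    if (is.null(bm))
      stop("internal error: search window contains no candidate patch")
    evals <- evals + bm$nCandidates
    st <- fillStep(list(img = simg, mask = smask, conf = sconf),
                   best$p, bm$q, best$Cp, params$patchSide)
    if (attr(st, "nFilled") < 1L)
      stop("internal error: fill step did not shrink the region")
    simg <- st$img; smask <- st$mask; sconf <- st$conf
    rem <- rem & smask == 1L
    ry <- max(1L, best$p[1L] - r):min(ch, best$p[1L] + r)
    rx <- max(1L, best$p[2L] - r):min(cw, best$p[2L] + r)
    gray[ry, rx] <- .luma(simg[ry, rx, , drop = FALSE])
    steps <- steps + 1L
  }
  genv$img[cu:cd, cl:cr, ] <- simg
  genv$mask[cu:cd, cl:cr] <- smask
  genv$conf[cu:cd, cl:cr] <- sconf
  list(window = win, steps = steps, evals = evals)
}

# classic exemplar algorithm: global fill front, priority Cp * Dp, and an
# exhaustive global source search; kept as an independently coded
# reference mode
.inpaintCriminisi <- function(state, params) {
  H <- nrow(state$mask); W <- ncol(state$mask)
  r <- (params$patchSide - 1L) %/% 2L
  steps <- 0L; evals <- 0
  while (sum(state$mask) > 0L) {
    gray <- .luma(state$img)
    idx <- which(state$mask == 1L)
    ys <- ((idx - 1L) %% H) + 1L
    xs <- ((idx - 1L) %/% H) + 1L
    ord <- order(ys, xs)
    ys <- ys[ord]; xs <- xs[ord]
    knownAt <- function(y, x) y >= 1L & y <= H & x >= 1L & x <= W &
      state$mask[cbind(.clip(y, 1L, H), .clip(x, 1L, W))] == 0L
    front <- knownAt(ys - 1L, xs) | knownAt(ys + 1L, xs) |
      knownAt(ys, xs - 1L) | knownAt(ys, xs + 1L)
    if (!any(front)) stop("inpainting stalled: no reachable fill front")
    by <- ys[front]; bx <- xs[front]
    best <- NULL; bestP <- -Inf
    for (i in seq_along(by)) {
      p <- c(by[i], bx[i])
      Cp <- confidenceTerm(p, state$conf, state$mask, params$patchSide)
      Dp <- dataTerm(p, gray, state$mask, params$alpha, params$patchSide)
      if (Cp * Dp > bestP) { bestP <- Cp * Dp; best <- list(p = p, Cp = Cp) }
    }
    p <- best$p
    offs <- expand.grid(dy = -r:r, dx = -r:r)
    ty <- p[1L] + offs$dy; tx <- p[2L] + offs$dx
    tin <- ty >= 1L & ty <= H & tx >= 1L & tx <= W
    tknown <- tin
    tknown[tin] <- state$mask[cbind(ty[tin], tx[tin])] == 0L
    bq <- NULL; bssd <- Inf
    for (cy in (r + 1L):(H - r)) {
      for (cx in (r + 1L):(W - r)) {
        if (any(state$mask[(cy - r):(cy + r), (cx - r):(cx + r)] == 1L)) next
        evals <- evals + 1
        ssd <- 0
        for (k in which(tknown)) {
          dt <- state$img[ty[k], tx[k], ] -
            state$img[cy + offs$dy[k], cx + offs$dx[k], ]
          ssd <- ssd + sum(dt^2)
        }
        if (ssd < bssd) { bssd <- ssd; bq <- c(cy, cx) }
      }
    }
    if (is.null(bq)) stop("no fully-known source patch exists in the image")
    state <- fillStep(state, p, bq, best$Cp, params$patchSide)
    if (attr(state, "nFilled") < 1L)
      stop("internal error: fill step did not shrink the region")
    steps <- steps + 1L
  }
  attr(state, "stats") <- list(steps = steps, evals = evals)
  state
}

#' Inpaint a single highlight region
#'
#' Repairs one connected region with the improved exemplar loop: the
#' fill-front priority is computed on this region's boundary only, the
#' best-matching source patch is searched inside the region's adaptive
#' local window, and the patch is copied in; the loop ends when the region
#' is empty. Each fill step must shrink the region by at least one pixel.
#'
#' @param image an [RgbImage-class].
#' @param region a [HighlightRegion-class] (from [extractRegions()]).
#' @param params an [inpaintParams()] list.
#' @param mask optional full [HighlightMask-class]; defaults to a mask
#'   containing only this region's pixels.
#' @return list with `image` (repaired [RgbImage-class]), `mask` (residual
#'   mask), `conf` (final confidence map), `steps`, `evals` (candidate
#'   patches scored) and `window`.
#' @export
inpaintRegion <- function(image, region, params = inpaintParams(),
                          mask = NULL) {
  px <- .asPixels(image)
  H <- dim(px)[1L]; W <- dim(px)[2L]
  m <- if (is.null(mask)) {
    mm <- matrix(0L, H, W)
    mm[region@pixels] <- 1L
    mm
  } else .asMaskMatrix(mask)
  genv <- new.env(parent = emptyenv())
  genv$img <- px; genv$mask <- m; genv$conf <- 1 - m
  st <- .inpaintRegionEngine(genv, region, params)
  list(image = RgbImage(genv$img), mask = HighlightMask(genv$mask),
       conf = genv$conf, steps = st$steps, evals = st$evals,
       window = st$window)
}

#' Remove specular regions by exemplar-based inpainting
#'
#' In `"improved"` mode the mask's 8-connected regions are repaired one at
#' a time in raster-encounter order, each with local priorities and its
#' own adaptive search window. In `"criminisi"` mode the classic algorithm
#' runs instead: global fill front, priority `Cp * Dp`, and the whole
#' image as search range. Pixels outside the original mask are
#' byte-identical to the input; an empty mask returns the input unchanged.
#'
#' @param image an [RgbImage-class] (at least `patchSide` pixels in each
#'   dimension).
#' @param mask a [HighlightMask-class] with at least one unmasked pixel.
#' @param params an [inpaintParams()] list.
#' @param report if `TRUE`, return a list with the image and a per-region
#'   report (windows, fill steps, candidate evaluations).
#' @return an [RgbImage-class], or `list(image, report)` when
#'   `report = TRUE`.
#' @export
inpaintImage <- function(image, mask, params = inpaintParams(),
                         report = FALSE) {
  px <- .asPixels(image)
  m <- .asMaskMatrix(mask)
  .checkSameDim(px, m)
  H <- dim(px)[1L]; W <- dim(px)[2L]
  if (H < params$patchSide || W < params$patchSide)
    stop("image must be at least patchSide x patchSide for inpainting")
  nMasked <- sum(m)
  if (nMasked == length(m))
    stop("mask covers the entire image; no known pixels to inpaint from")
  if (nMasked == 0L) {
    out <- RgbImage(px)
    return(if (report) list(image = out, report = list(
      mode = params$mode, regions = list(), steps = 0L, evals = 0)) else out)
  }
  if (params$mode == "criminisi") {
    state <- .inpaintCriminisi(list(img = px, mask = m, conf = 1 - m), params)
    st <- attr(state, "stats")
    rep_ <- list(mode = "criminisi", regions = list(),
                 steps = st$steps, evals = st$evals)
    out <- RgbImage(state$img)
  } else {
    regions <- .extractRegionsCore(m)
    genv <- new.env(parent = emptyenv())
    genv$img <- px; genv$mask <- m; genv$conf <- 1 - m
    regs <- vector("list", length(regions))
    total <- 0L; evals <- 0
    for (i in seq_along(regions)) {
      st <- .inpaintRegionEngine(genv, regions[[i]], params)
      regs[[i]] <- list(label = regions[[i]]@label, window = st$window,
                        steps = st$steps, evals = st$evals,
                        nPixels = nrow(regions[[i]]@pixels))
      total <- total + st$steps; evals <- evals + st$evals
    }
    rep_ <- list(mode = "improved", regions = regs,
                 steps = total, evals = evals)
    out <- RgbImage(genv$img)
  }
  if (report) list(image = out, report = rep_) else out
}
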