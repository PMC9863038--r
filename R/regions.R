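# 8-connected component labeling, raster-encounter order.
# BFS with vectorized frontier expansion: cost scales with the number of
# set pixels, not the canvas area (no full-image passes beyond the initial
# which()). Returns the linear pixel indices of each component.
.label8 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  idx <- which(m == 1L)
  if (length(idx) == 0L) return(list())
  ys <- ((idx - 1L) %% H) + 1L
  xs <- ((idx - 1L) %/% H) + 1L
  # raster order: row-major (y, then x)
  idx <- idx[order(ys, xs)]
  offs <- c(-1L, 1L, -H, H, -H - 1L, -H + 1L, H - 1L, H + 1L)
  doffY <- c(-1L, 1L, 0L, 0L, -1L, 1L, -1L, 1L)
  inMask <- matrix(FALSE, H, W); inMask[idx] <- TRUE
  seen <- matrix(FALSE, H, W)
  comps <- list()
  for (seed in idx) {
    if (seen[seed]) next
    members <- seed
    frontier <- seed
    seen[seed] <- TRUE
    while (length(frontier)) {
      fy <- ((frontier - 1L) %% H) + 1L
      nb <- rep(frontier, each = 8L) + rep(offs, length(frontier))
      nby <- rep(fy, each = 8L) + rep(doffY, length(frontier))
      keep <- nb >= 1L & nb <= H * W & nby >= 1L & nby <= H &
        nby == ((nb - 1L) %% H) + 1L
      nb <- unique(nb[keep])
      nb <- nb[inMask[nb] & !seen[nb]]
      seen[nb] <- TRUE
      members <- c(members, nb)
      frontier <- nb
    }
    comps[[length(comps) + 1L]] <- members
  }
  comps
}

# core extraction on a plain 0/1 matrix (no revalidation)
.extractRegionsCore <- function(m) {
  H <- nrow(m); W <- ncol(m)
  comps <- .label8(m)
  lapply(seq_along(comps), function(k) {
    idx <- comps[[k]]
    ys <- ((idx - 1L) %% H) + 1L
    xs <- ((idx - 1L) %/% H) + 1L
    ord <- order(ys, xs)
    ys <- ys[ord]; xs <- xs[ord]
    known <- function(y, x) y >= 1L & y <= H & x >= 1L & x <= W &
      m[cbind(pmin(pmax(y, 1L), H), pmin(pmax(x, 1L), W))] == 0L
    isContour <- known(ys - 1L, xs) | known(ys + 1L, xs) |
      known(ys, xs - 1L) | known(ys, xs + 1L)
    new("HighlightRegion", label = k,
        pixels = cbind(y = ys, x = xs),
        contour = cbind(y = ys[isContour], x = xs[isContour]),
        lc = as.integer(sum(isContour)),
        yup = min(ys), ydown = max(ys), xleft = min(xs), xright = max(xs))
  })
}

#' Extract connected highlight regions from a mask
#'
#' Decomposes the mask into 8-connected components, ordered by first
#' raster-scan encounter (rows scanned top to bottom, left to right). Each
#' region carries its contour -- the mask pixels that are 4-adjacent to at
#' least one unmasked pixel -- the contour length `lc`, and the bounding
#' extremes used by the adaptive search window.
#'
#' @param mask a [HighlightMask-class].
#' @return a list of [HighlightRegion-class] objects (empty for an empty
#'   mask). A mask covering the whole frame is an error: there would be no
#'   known pixels to copy from.
#' @export
extractRegions <- function(mask) {
  m <- .asMaskMatrix(mask)
  if (sum(m) == length(m))
    stop("mask covers the entire image; no known pixels to inpaint from")
  .extractRegionsCore(m)
}
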