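#' @include contrast.R
NULL

#' Contrast-limited adaptive histogram equalization in 3D
#'
#' Tiled histogram equalization for display of aggregation-contrast
#' volumes: the volume is divided into tiles of \code{kernelShape} voxels,
#' a histogram of \code{nBins} bins is built per tile, counts are clipped
#' at \code{clipLimit} times the tile voxel count with the excess
#' redistributed uniformly over the bins, each tile's clipped CDF becomes
#' its intensity mapping, and mappings are trilinearly interpolated
#' between tile centers. Output values lie in [0, 1].
#'
#' When a mask is given, histograms are built from masked voxels only and
#' the background stays 0 — otherwise air dominates the histograms. A
#' degenerate dynamic range (max == min) returns an all-zero image with a
#' warning rather than an error.
#'
#' @param image A \linkS4class{ContrastImage} (not already equalized) or a
#'   3D numeric array.
#' @param kernelShape Tile size in voxels per axis (length 1 or 3);
#'   default one eighth of the image shape per axis, floor 4 voxels.
#' @param clipLimit Histogram clip limit as a fraction of the tile voxel
#'   count, in (0, 1]; default 0.01. 1.0 disables clipping.
#' @param nBins Number of histogram bins, >= 2; default 256.
#' @param mask Optional 3D logical array restricting the equalization.
#' @return Same class as the input; a \linkS4class{ContrastImage} has its
#'   \code{equalized} flag set and the parameters recorded.
#' @export
equalizeAdaptive <- function(image, kernelShape = NULL, clipLimit = 0.01,
                             nBins = 256L, mask = NULL) {
  isCI <- is(image, "ContrastImage")
  v <- if (isCI) image@values else image
  if (isCI && image@equalized)
    stop("image is already equalized")
  sp <- dim(v)
  if (is.null(kernelShape)) kernelShape <- pmax(sp %/% 8L, 4L)
  if (length(kernelShape) == 1L) kernelShape <- rep(kernelShape, 3L)
  kernelShape <- pmin(as.integer(kernelShape), sp)
  stopifnot(length(kernelShape) == 3L, all(kernelShape >= 1L),
            clipLimit > 0, clipLimit <= 1, nBins >= 2L)
  out <- .clahe3d(v, kernelShape, clipLimit, as.integer(nBins), mask)
  if (!isCI) return(out)
  new("ContrastImage", values = out, affine = image@affine,
      method = image@method, bThreshold = image@bThreshold,
      shell = image@shell, equalized = TRUE,
      equalizeParams = list(kernelShape = kernelShape,
                            clipLimit = clipLimit, nBins = as.integer(nBins),
                            masked = !is.null(mask)))
}

.clahe3d <- function(v, kernel, clipLimit, nBins, mask = NULL) {
  sp <- dim(v)
  inMask <- if (is.null(mask)) rep(TRUE, length(v)) else {
    if (!identical(dim(mask), sp)) stop("mask shape does not match image")
    as.vector(mask) != 0
  }
  vals <- as.vector(v)[inMask]
  if (!length(vals)) return(array(0, sp))
  mn <- min(vals); mx <- max(vals)
  if (mx == mn) {
    warning("degenerate dynamic range (max == min); returning all zeros")
    return(array(0, sp))
  }
  ## 0-based bin index per voxel over the (masked) global range
  bin <- pmin(as.integer(floor((as.vector(v) - mn) / (mx - mn) * nBins)),
              nBins - 1L)
  bin <- pmax(bin, 0L)

  nt <- pmax((sp + kernel - 1L) %/% kernel, 1L)  # tiles per axis
  ## tile index (1-based) of each voxel position along each axis
  tileOf <- lapply(1:3, function(a)
    pmin((seq_len(sp[a]) - 1L) %/% kernel[a] + 1L, nt[a]))
  tIdx <- lapply(1:3, function(a) tileOf[[a]][slice.index(v, a)])
  tileLin <- tIdx[[1]] + nt[1] * (tIdx[[2]] - 1L) +
    nt[1] * nt[2] * (tIdx[[3]] - 1L)

  ## per-tile clipped-CDF mappings, columns of M (nBins x nTiles)
  nTiles <- prod(nt)
  M <- matrix(0, nBins, nTiles)
  ramp <- (seq_len(nBins) - 0.5) / nBins   # identity for empty tiles
  tl <- as.vector(tileLin)
  maskedIdx <- which(inMask)
  binsByTile <- split(bin[maskedIdx], tl[maskedIdx])
  for (t in seq_len(nTiles)) {
    tb <- binsByTile[[as.character(t)]]
    cnt <- length(tb)
    if (cnt == 0L || is.null(tb)) { M[, t] <- ramp; next }
    h <- tabulate(tb + 1L, nbins = nBins)
    clip <- max(ceiling(clipLimit * cnt), 1)
    excess <- sum(pmax(h - clip, 0))
    if (excess > 0) {
      h <- pmin(h, clip) + excess / nBins
    }
    M[, t] <- cumsum(h) / sum(h)
  }

  ## trilinear interpolation of the mappings between tile centers
  centers <- lapply(1:3, function(a) {
    t <- seq_len(nt[a])
    lo <- (t - 1L) * kernel[a]
    hi <- pmin(t * kernel[a], sp[a]) - 1L
    (lo + hi) / 2
  })
  interp <- lapply(1:3, function(a) {
    pos <- seq_len(sp[a]) - 1L
    ctr <- centers[[a]]
    loT <- findInterval(pos, ctr)          # 0 below first center
    loT <- pmin(pmax(loT, 1L), nt[a])
    hiT <- pmin(loT + 1L, nt[a])
    w <- numeric(length(pos))
    gap <- ctr[hiT] - ctr[loT]
    inside <- gap > 0
    w[inside] <- pmin(pmax(
      (pos[inside] - ctr[loT[inside]]) / gap[inside], 0), 1)
    list(lo = loT, hi = hiT, w = w)
  })
  axArr <- function(a, what) interp[[a]][[what]][slice.index(v, a)]
  w1 <- axArr(1, "w"); w2 <- axArr(2, "w"); w3 <- axArr(3, "w")
  lo1 <- axArr(1, "lo"); hi1 <- axArr(1, "hi")
  lo2 <- axArr(2, "lo"); hi2 <- axArr(2, "hi")
  lo3 <- axArr(3, "lo"); hi3 <- axArr(3, "hi")

  b1 <- bin + 1L
  lookup <- function(t1, t2, t3)
    M[b1 + nBins * (t1 - 1L + nt[1] * (t2 - 1L + nt[2] * (t3 - 1L)))]
  out <- (1 - w1) * (1 - w2) * (1 - w3) * lookup(lo1, lo2, lo3) +
         w1 * (1 - w2) * (1 - w3) * lookup(hi1, lo2, lo3) +
         (1 - w1) * w2 * (1 - w3) * lookup(lo1, hi2, lo3) +
         w1 * w2 * (1 - w3) * lookup(hi1, hi2, lo3) +
         (1 - w1) * (1 - w2) * w3 * lookup(lo1, lo2, hi3) +
         w1 * (1 - w2) * w3 * lookup(hi1, lo2, hi3) +
         (1 - w1) * w2 * w3 * lookup(lo1, hi2, hi3) +
         w1 * w2 * w3 * lookup(hi1, hi2, hi3)
  out[!inMask] <- 0
  out <- pmin(pmax(out, 0), 1)
  array(out, sp)
}
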