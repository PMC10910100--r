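#' @include dwi-io.R
NULL

.AGG_METHODS <- c("mean", "median", "centromean", "sum", "l2norm")

#' Select diffusion-weighted volumes by b-value
#'
#' Returns the indices of volumes with b strictly above the threshold
#' (default 100 s/mm^2, which drops b0 and very low-b volumes while keeping
#' every diffusion-weighted shell). If a nominal shell is given, only
#' volumes within \code{shellTolerance} of it are kept, reproducing
#' single-shell usage on multi-shell data.
#'
#' @param ds A \linkS4class{DWIDataset} or \linkS4class{GradientTable}.
#' @param bThreshold Strict lower b-value bound, s/mm^2 (default 100).
#' @param shell Optional nominal shell b-value, s/mm^2.
#' @param shellTolerance Half-width of the shell window, s/mm^2
#'   (default 50).
#' @return Integer vector of 1-based volume indices, order preserved.
#' @examples
#' gt <- gradientTable(c(0, 5, 1000, 1500, 2000),
#'                     matrix(rep(c(1, 0, 0), 5), 3))
#' selectWeighted(gt)                 # 3 4 5
#' selectWeighted(gt, shell = 1000)   # 3
#' @export
selectWeighted <- function(ds, bThreshold = 100, shell = NULL,
                           shellTolerance = 50) {
  b <- if (is(ds, "GradientTable")) ds@bvals else bValues(ds)
  stopifnot(bThreshold >= 0)
  if (!is.null(shell) && shell <= bThreshold)
    stop("shell (", shell, ") must exceed the b-value threshold (",
         bThreshold, ")")
  idx <- which(b > bThreshold)
  if (!is.null(shell))
    idx <- idx[abs(b[idx] - shell) <= shellTolerance]
  if (!length(idx))
    stop(sprintf(
      "no diffusion-weighted volumes selected (threshold %g%s; available b-values: %s)",
      bThreshold,
      if (is.null(shell)) "" else sprintf(", shell %g +/- %g", shell,
                                          shellTolerance),
      paste(sort(unique(b)), collapse = ", ")))
  idx
}

#' Compute the direct anatomical contrast by voxelwise aggregation
#'
#' The contrast is the voxelwise aggregate of the diffusion-weighted
#' volumes (b above the threshold): dark where water diffuses isotropically
#' and fast (CSF), bright where diffusion is restricted or anisotropic
#' (white matter), with thalamic subnuclei at intermediate, histologically
#' driven levels. Aggregation methods:
#' \describe{
#'   \item{mean}{arithmetic mean (the reference method)}
#'   \item{median}{standard median (even counts: average of the two
#'     central values)}
#'   \item{centromean}{mean of the middle 50\%: the lowest floor(n/4) and
#'     highest floor(n/4) of the n sorted values are discarded}
#'   \item{sum}{arithmetic sum}
#'   \item{l2norm}{square root of the sum of squares}
#' }
#' Each voxel's series is sorted before aggregation, so results are
#' bit-identical under any permutation of the volumes.
#'
#' @param ds A \linkS4class{DWIDataset}.
#' @param method One of "mean", "median", "centromean", "sum", "l2norm".
#' @param bThreshold Strict lower b-value bound, s/mm^2 (default 100).
#' @param shell,shellTolerance Optional shell selection (see
#'   \code{\link{selectWeighted}}).
#' @param mask Optional 3D logical array; voxels outside it are 0.
#' @return A \linkS4class{ContrastImage}.
#' @examples
#' gt <- gradientTable(c(0, 1500, 1500),
#'                     cbind(0, c(1, 0, 0), c(0, 1, 0)))
#' sig <- array(1, c(2, 2, 2, 3)); sig[, , , 2] <- 10; sig[, , , 3] <- 30
#' ci <- computeContrast(dwiDataset(sig, gt), "mean")
#' imageData(ci)[1, 1, 1]  # 20
#' @export
computeContrast <- function(ds, method = "mean", bThreshold = 100,
                            shell = NULL, shellTolerance = 50,
                            mask = NULL) {
  method <- match.arg(method, .AGG_METHODS)
  sel <- selectWeighted(ds, bThreshold, shell, shellTolerance)
  vals <- .aggregateVolumes(ds@signal, sel, method, mask)
  new("ContrastImage", values = vals, affine = ds@affine, method = method,
      bThreshold = as.numeric(bThreshold),
      shell = if (is.null(shell)) NA_real_ else as.numeric(shell),
      equalized = FALSE, equalizeParams = list())
}

#' Mean of the b0 (non-diffusion-weighted) volumes
#'
#' Convenience companion to \code{\link{computeContrast}} with the
#' threshold semantics inverted: volumes with b <= \code{bMax} are
#' averaged. Useful as an anatomical reference ("B0 average").
#'
#' @param ds A \linkS4class{DWIDataset}.
#' @param bMax Inclusive upper b-value bound, s/mm^2 (default 100).
#' @param mask Optional 3D logical array.
#' @return A \linkS4class{ContrastImage} with method "b0_mean".
#' @export
b0Mean <- function(ds, bMax = 100, mask = NULL) {
  b <- bValues(ds)
  sel <- which(b <= bMax)
  if (!length(sel))
    stop(sprintf("no b0 volumes (b <= %g) found; available b-values: %s",
                 bMax, paste(sort(unique(b)), collapse = ", ")))
  vals <- .aggregateVolumes(ds@signal, sel, "mean", mask)
  new("ContrastImage", values = vals, affine = ds@affine,
      method = "b0_mean", bThreshold = as.numeric(bMax), shell = NA_real_,
      equalized = FALSE, equalizeParams = list())
}

## Voxelwise aggregation over selected volumes. The per-voxel series is
## row-sorted first (one global order() call, not apply()), which makes
## every aggregate, including floating-point sums, independent of volume
## order.
.aggregateVolumes <- function(signal, sel, method, mask = NULL) {
  sp <- dim(signal)[1:3]
  n <- length(sel)
  m <- matrix(signal[, , , sel, drop = FALSE], nrow = prod(sp), ncol = n)
  if (!is.null(mask)) {
    if (!identical(dim(mask), sp))
      stop("mask shape does not match the image grid")
    keep <- which(as.vector(mask) != 0)
    m <- m[keep, , drop = FALSE]
  }
  s <- matrix(m[order(row(m), m)], nrow = nrow(m), byrow = TRUE)
  out <- switch(method,
    mean = rowSums(s) / n,
    sum = rowSums(s),
    l2norm = sqrt(rowSums(s^2)),
    median = if (n %% 2L == 1L) s[, (n + 1L) %/% 2L]
             else (s[, n %/% 2L] + s[, n %/% 2L + 1L]) / 2,
    centromean = {
      k <- n %/% 4L
      rowSums(s[, (k + 1L):(n - k), drop = FALSE]) / (n - 2L * k)
    })
  if (!is.null(mask)) {
    full <- numeric(prod(sp))
    full[keep] <- out
    out <- full
  }
  array(out, dim = sp)
}

#' Per-label intensity statistics of a contrast image
#'
#' @param image A \linkS4class{ContrastImage}.
#' @param labels A \linkS4class{LabelMap} on the same grid (affine must
#'   agree within 1e-4).
#' @return data.frame with one row per nonzero label present in the map:
#'   label, name, mean, sd, n_voxels.
#' @export
regionStats <- function(image, labels) {
  .checkSameGeometry(dim(image@values), image@affine,
                     dim(labels@labels), labels@affine)
  lab <- as.vector(labels@labels)
  val <- as.vector(image@values)
  present <- setdiff(sort(unique(lab)), 0L)
  res <- lapply(present, function(k) {
    v <- val[lab == k]
    data.frame(label = k,
               name = unname(labels@names[as.character(k)]),
               mean = mean(v), sd = stats::sd(v), n_voxels = length(v))
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

.checkSameGeometry <- function(dimA, affA, dimB, affB, tol = 1e-4) {
  if (!identical(as.integer(dimA), as.integer(dimB)))
    stop(sprintf("geometry mismatch: grids %s vs %s; inputs must share a voxel grid (pre-registered)",
                 paste(dimA, collapse = "x"), paste(dimB, collapse = "x")))
  if (max(abs(affA - affB)) > tol)
    stop("geometry mismatch: affines differ by more than ", tol,
         "; inputs must be pre-registered to a common grid")
  invisible(TRUE)
}
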