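#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## GradientTable
## ---------------------------------------------------------------------------

#' Diffusion gradient table
#'
#' Per-volume b-values (s/mm^2) and unit gradient directions for a 4D
#' diffusion acquisition, in the FSL bvals/bvecs convention (directions in
#' image coordinates; a zero vector is permitted wherever b = 0).
#'
#' @slot bvals Numeric vector of b-values, one per volume, all >= 0.
#' @slot bvecs 3 x N numeric matrix of directions, one column per volume;
#'   unit Euclidean norm (within 1e-3) wherever the b-value is positive.
#' @export
setClass("GradientTable",
  representation(bvals = "numeric", bvecs = "matrix"),
  validity = function(object) {
    msgs <- character()
    b <- object@bvals
    g <- object@bvecs
    if (!is.numeric(g)) msgs <- c(msgs, "bvecs must be numeric")
    if (nrow(g) != 3L)
      msgs <- c(msgs, "bvecs must have 3 rows (one column per volume)")
    if (length(b) != ncol(g))
      msgs <- c(msgs, sprintf(
        "gradient count mismatch: %d b-values but %d directions",
        length(b), ncol(g)))
    if (any(!is.finite(b)) || any(b < 0))
      msgs <- c(msgs, "all b-values must be finite and >= 0")
    if (length(b) == ncol(g) && length(b) > 0) {
      nrm <- sqrt(colSums(g^2))
      bad <- b > 0 & abs(nrm - 1) > 1e-3
      if (any(bad))
        msgs <- c(msgs, sprintf(
          "%d direction(s) with b > 0 are not unit-norm (max |norm-1| = %.3g); renormalize or fix the bvecs file",
          sum(bad), max(abs(nrm[bad] - 1))))
    }
    if (length(msgs)) msgs else TRUE
  })

#' Construct a GradientTable
#'
#' @param bvals Numeric vector of b-values (s/mm^2).
#' @param bvecs 3 x N matrix (or N x 3, auto-transposed) of directions.
#' @param renormalize If TRUE, directions with b > 0 are rescaled to unit
#'   norm instead of failing validation.
#' @return A \linkS4class{GradientTable}.
#' @examples
#' gradientTable(c(0, 1500), cbind(c(0, 0, 0), c(1, 0, 0)))
#' @export
gradientTable <- function(bvals, bvecs, renormalize = FALSE) {
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L && ncol(bvecs) == 3L) bvecs <- t(bvecs)
  storage.mode(bvecs) <- "double"
  bvals <- as.numeric(bvals)
  if (renormalize && length(bvals) == ncol(bvecs)) {
    nrm <- sqrt(colSums(bvecs^2))
    fix <- bvals > 0 & nrm > 0
    bvecs[, fix] <- sweep(bvecs[, fix, drop = FALSE], 2, nrm[fix], "/")
  }
  new("GradientTable", bvals = bvals, bvecs = bvecs)
}

#' @rdname bValues
#' @export
setMethod("bValues", "GradientTable", function(x) x@bvals)

#' @rdname bVectors
#' @export
setMethod("bVectors", "GradientTable", function(x) x@bvecs)

#' @rdname nVolumes
#' @export
setMethod("nVolumes", "GradientTable", function(x) length(x@bvals))

setMethod("show", "GradientTable", function(object) {
  b <- object@bvals
  cat("GradientTable:", length(b), "volumes;",
      sum(b > 0), "diffusion-weighted,", sum(b == 0), "b0\n")
  if (length(b))
    cat("  b-values (s/mm^2):",
        paste(unique(round(sort(b))), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## DWIDataset
## ---------------------------------------------------------------------------

#' 4D diffusion-weighted dataset
#'
#' @slot signal 4D non-negative array (x, y, z, volume), all values finite.
#' @slot affine 4 x 4 invertible voxel-to-world transform (mm).
#' @slot gradients \linkS4class{GradientTable} describing the 4th axis.
#' @export
setClass("DWIDataset",
  representation(signal = "array", affine = "matrix",
                 gradients = "GradientTable"),
  validity = function(object) {
    msgs <- character()
    if (length(dim(object@signal)) != 4L)
      msgs <- c(msgs, "signal must be a 4D array (x, y, z, volume)")
    else if (dim(object@signal)[4] != nVolumes(object@gradients))
      msgs <- c(msgs, sprintf(
        "volume count mismatch: signal has %d volumes, gradient table %d",
        dim(object@signal)[4], nVolumes(object@gradients)))
    if (any(!is.finite(object@signal)))
      msgs <- c(msgs, "signal contains non-finite values")
    msgs <- c(msgs, .checkAffine(object@affine))
    if (length(msgs)) msgs else TRUE
  })

.checkAffine <- function(a) {
  if (!is.numeric(a) || !identical(dim(a), c(4L, 4L)))
    return("affine must be a 4 x 4 numeric matrix")
  if (!all(is.finite(a)) || abs(det(a)) < .Machine$double.eps * 100)
    return("affine must be finite and invertible")
  character()
}

#' Construct a DWIDataset
#'
#' @param signal 4D array (x, y, z, volume).
#' @param gradients A \linkS4class{GradientTable}.
#' @param affine 4 x 4 voxel-to-world matrix; default identity.
#' @return A \linkS4class{DWIDataset}.
#' @export
dwiDataset <- function(signal, gradients, affine = diag(4)) {
  new("DWIDataset", signal = signal, affine = affine, gradients = gradients)
}

#' @rdname bValues
#' @export
setMethod("bValues", "DWIDataset", function(x) x@gradients@bvals)

#' @rdname bVectors
#' @export
setMethod("bVectors", "DWIDataset", function(x) x@gradients@bvecs)

#' @rdname nVolumes
#' @export
setMethod("nVolumes", "DWIDataset", function(x) dim(x@signal)[4])

#' @rdname imageAffine
#' @export
setMethod("imageAffine", "DWIDataset", function(x) x@affine)

#' @rdname imageData
#' @export
setMethod("imageData", "DWIDataset", function(x) x@signal)

setMethod("show", "DWIDataset", function(object) {
  d <- dim(object@signal)
  vs <- sqrt(colSums(object@affine[1:3, 1:3]^2))
  cat(sprintf("DWIDataset: %d x %d x %d voxels, %d volumes\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel size: %s mm\n",
              paste(signif(vs, 4), collapse = " x ")))
  show(object@gradients)
})

## ---------------------------------------------------------------------------
## ContrastImage
## ---------------------------------------------------------------------------

#' Aggregated diffusion contrast image
#'
#' A 3D scalar image produced by voxelwise aggregation of the
#' diffusion-weighted volumes (b above a threshold), together with the
#' provenance needed to reproduce it: the aggregation method, the b-value
#' threshold, the optional shell, and any equalization settings.
#'
#' @slot values 3D scalar array; finite, >= 0 when not equalized, in [0, 1]
#'   when equalized.
#' @slot affine 4 x 4 voxel-to-world transform (mm).
#' @slot method One of "mean", "median", "centromean", "sum", "l2norm",
#'   or "b0_mean".
#' @slot bThreshold b-value threshold (s/mm^2); volumes with b strictly
#'   above it were aggregated ("b0_mean": b <= threshold).
#' @slot shell Nominal shell b-value (s/mm^2) or NA when all weighted
#'   volumes were used.
#' @slot equalized Logical; TRUE after adaptive histogram equalization.
#' @slot equalizeParams List of equalization parameters (kernelShape,
#'   clipLimit, nBins) or empty when not equalized.
#' @export
setClass("ContrastImage",
  representation(values = "array", affine = "matrix", method = "character",
                 bThreshold = "numeric", shell = "numeric",
                 equalized = "logical", equalizeParams = "list"),
  validity = function(object) {
    msgs <- character()
    if (length(dim(object@values)) != 3L)
      msgs <- c(msgs, "values must be a 3D array")
    if (any(!is.finite(object@values)))
      msgs <- c(msgs, "values must be finite")
    else if (object@equalized) {
      if (min(object@values) < 0 || max(object@values) > 1)
        msgs <- c(msgs, "equalized values must lie in [0, 1]")
    } else if (min(object@values) < 0)
      msgs <- c(msgs, "unequalized contrast values must be >= 0")
    msgs <- c(msgs, .checkAffine(object@affine))
    if (length(msgs)) msgs else TRUE
  })

#' @rdname imageAffine
#' @export
setMethod("imageAffine", "ContrastImage", function(x) x@affine)

#' @rdname imageData
#' @export
setMethod("imageData", "ContrastImage", function(x) x@values)

setMethod("show", "ContrastImage", function(object) {
  d <- dim(object@values)
  cat(sprintf("ContrastImage (%s): %d x %d x %d voxels\n",
              object@method, d[1], d[2], d[3]))
  cat(sprintf("  b threshold: %g s/mm^2%s\n", object@bThreshold,
              if (is.na(object@shell)) ""
              else sprintf(", shell %g s/mm^2", object@shell)))
  cat(sprintf("  range: [%.4g, %.4g]%s\n", min(object@values),
              max(object@values),
              if (object@equalized) " (equalized)" else ""))
})

## ---------------------------------------------------------------------------
## LabelMap
## ---------------------------------------------------------------------------

#' Multilabel segmentation volume
#'
#' Integer labels on a 3D grid; 0 is reserved for background, and every
#' nonzero label present in the volume has an entry in the name dictionary
#' (THOMAS-style nucleus abbreviations such as VLPv, VPL, MD, CM).
#'
#' @slot labels 3D array of non-negative integers.
#' @slot affine 4 x 4 voxel-to-world transform (mm).
#' @slot names Named character vector mapping label id (as string) to
#'   nucleus name.
#' @export
setClass("LabelMap",
  representation(labels = "array", affine = "matrix", names = "character"),
  validity = function(object) {
    msgs <- character()
    if (length(dim(object@labels)) != 3L)
      msgs <- c(msgs, "labels must be a 3D array")
    if (any(!is.finite(object@labels)) || any(object@labels < 0))
      msgs <- c(msgs, "labels must be finite and non-negative")
    present <- setdiff(unique(as.vector(object@labels)), 0)
    missing <- setdiff(as.character(present), names(object@names))
    if (length(missing))
      msgs <- c(msgs, sprintf("labels without a name entry: %s",
                              paste(missing, collapse = ", ")))
    msgs <- c(msgs, .checkAffine(object@affine))
    if (length(msgs)) msgs else TRUE
  })

#' Construct a LabelMap
#'
#' Missing names for labels present in the volume are auto-filled as
#' "label_<k>".
#'
#' @param labels 3D integer array (0 = background).
#' @param affine 4 x 4 voxel-to-world matrix; default identity.
#' @param names Named character vector (names are label ids as strings),
#'   e.g. c("1" = "VLPv", "2" = "VPL"); may be NULL.
#' @return A \linkS4class{LabelMap}.
#' @export
labelMap <- function(labels, affine = diag(4), names = NULL) {
  labels <- .asIntegerArray(labels)
  nm <- if (is.null(names)) character() else {
    stopifnot(!is.null(base::names(names)))
    stats::setNames(as.character(names), base::names(names))
  }
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  missing <- setdiff(as.character(present), base::names(nm))
  if (length(missing))
    nm[missing] <- paste0("label_", missing)
  new("LabelMap", labels = labels, affine = affine, names = nm)
}

.asIntegerArray <- function(x, tol = 1e-6) {
  if (!is.integer(x)) {
    r <- round(x)
    if (any(abs(x - r) > tol))
      stop("label volume contains non-integer values (beyond tolerance ",
           tol, ")")
    x <- r
    storage.mode(x) <- "integer"
  }
  x
}

#' @rdname imageAffine
#' @export
setMethod("imageAffine", "LabelMap", function(x) x@affine)

#' @rdname imageData
#' @export
setMethod("imageData", "LabelMap", function(x) x@labels)

#' @rdname labelNames
#' @export
setMethod("labelNames", "LabelMap", function(x) x@names)

setMethod("show", "LabelMap", function(object) {
  d <- dim(object@labels)
  present <- setdiff(sort(unique(as.vector(object@labels))), 0L)
  cat(sprintf("LabelMap: %d x %d x %d voxels, %d foreground label(s)\n",
              d[1], d[2], d[3], length(present)))
  if (length(present)) {
    nm <- object@names[as.character(present)]
    cat("  ", paste(sprintf("%d=%s", present, nm), collapse = ", "), "\n")
  }
})

## ---------------------------------------------------------------------------
## DirectionSet
## ---------------------------------------------------------------------------

#' Unit gradient direction set
#'
#' A set of unit vectors sampling the half-sphere (diffusion is symmetric
#' under sign flip, so g and -g are equivalent); no two vectors may
#' antipodally coincide.
#'
#' @slot vectors 3 x n matrix of unit-norm columns.
#' @export
setClass("DirectionSet",
  representation(vectors = "matrix"),
  validity = function(object) {
    v <- object@vectors
    msgs <- character()
    if (nrow(v) != 3L) msgs <- c(msgs, "vectors must be a 3 x n matrix")
    else {
      nrm <- sqrt(colSums(v^2))
      if (any(abs(nrm - 1) > 1e-6))
        msgs <- c(msgs, "all direction vectors must be unit-norm (1e-6)")
      if (ncol(v) > 1) {
        dots <- abs(crossprod(v))
        diag(dots) <- 0
        if (max(dots) > 1 - 1e-6)
          msgs <- c(msgs,
            "two directions coincide (antipodally) within tolerance")
      }
    }
    if (length(msgs)) msgs else TRUE
  })

#' Construct a DirectionSet
#'
#' @param vectors 3 x n (or n x 3, auto-transposed) matrix of unit vectors.
#' @return A \linkS4class{DirectionSet}.
#' @export
directionSet <- function(vectors) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) != 3L && ncol(vectors) == 3L) vectors <- t(vectors)
  storage.mode(vectors) <- "double"
  new("DirectionSet", vectors = vectors)
}

#' @rdname bVectors
#' @export
setMethod("bVectors", "DirectionSet", function(x) x@vectors)

setMethod("show", "DirectionSet", function(object) {
  n <- ncol(object@vectors)
  cat("DirectionSet:", n, "directions")
  if (n >= 2)
    cat(sprintf("; min folded angle %.2f deg",
                minFoldedAngle(object) * 180 / pi))
  cat("\n")
})

setMethod("length", "DirectionSet", function(x) ncol(x@vectors))

## ---------------------------------------------------------------------------
## PhantomSpec
## ---------------------------------------------------------------------------

#' Declarative diffusion-tensor phantom specification
#'
#' Describes a labeled multi-region phantom: grid geometry, one diffusion
#' tensor and baseline signal per region, the acquisition scheme, and the
#' Rician noise level. Overlapping regions resolve by list order (later
#' regions win).
#'
#' @slot gridShape Integer vector of 3 voxel counts.
#' @slot voxelSize Voxel edge length, mm (isotropic).
#' @slot regions List of region descriptions; each a list with elements
#'   label (integer id), name, geometry (list(type, ...) with type one of
#'   "box", "ellipsoid", "slab_stack"), tensor (3 x 3 SPD, mm^2/s) and
#'   S0 (baseline signal).
#' @slot acquisition List: nDirections, bval (s/mm^2), nB0, directionSeed.
#' @slot noiseSigma Rician noise sigma, absolute signal units, >= 0.
#' @slot noiseSeed Integer seed for the noise stream.
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", voxelSize = "numeric",
                 regions = "list", acquisition = "list",
                 noiseSigma = "numeric", noiseSeed = "integer"),
  validity = function(object) {
    msgs <- character()
    if (length(object@gridShape) != 3L || any(object@gridShape < 1))
      msgs <- c(msgs, "gridShape must be 3 positive voxel counts")
    if (object@voxelSize <= 0) msgs <- c(msgs, "voxelSize must be > 0")
    if (object@noiseSigma < 0) msgs <- c(msgs, "noiseSigma must be >= 0")
    acq <- object@acquisition
    need <- c("nDirections", "bval", "nB0", "directionSeed")
    if (!all(need %in% names(acq)))
      msgs <- c(msgs, paste("acquisition must contain:",
                            paste(need, collapse = ", ")))
    for (i in seq_along(object@regions)) {
      r <- object@regions[[i]]
      if (!all(c("label", "name", "geometry", "tensor", "S0") %in% names(r))) {
        msgs <- c(msgs, sprintf("region %d is missing required fields", i))
        next
      }
      D <- r$tensor
      if (!is.matrix(D) || !identical(dim(D), c(3L, 3L)) ||
          max(abs(D - t(D))) > 1e-12 * max(abs(D), 1e-300) ||
          min(eigen(D, symmetric = TRUE, only.values = TRUE)$values) <= 0)
        msgs <- c(msgs, sprintf(
          "region %d ('%s'): tensor must be symmetric positive-definite",
          i, r$name))
      if (!r$geometry$type %in% c("box", "ellipsoid", "slab_stack"))
        msgs <- c(msgs, sprintf("region %d: unknown geometry type '%s'",
                                i, r$geometry$type))
    }
    if (length(msgs)) msgs else TRUE
  })

#' Construct a PhantomSpec
#'
#' @param gridShape Three voxel counts.
#' @param voxelSize Isotropic voxel size, mm.
#' @param regions List of region lists (see \linkS4class{PhantomSpec}).
#' @param acquisition List with nDirections, bval, nB0, directionSeed.
#' @param noiseSigma Rician sigma in signal units (default 0, noise-free).
#' @param noiseSeed Integer seed for noise generation.
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(gridShape, voxelSize, regions, acquisition,
                        noiseSigma = 0, noiseSeed = 1L) {
  new("PhantomSpec", gridShape = as.integer(gridShape),
      voxelSize = as.numeric(voxelSize), regions = regions,
      acquisition = acquisition, noiseSigma = as.numeric(noiseSigma),
      noiseSeed = as.integer(noiseSeed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %s voxels @ %g mm, %d region(s)\n",
              paste(object@gridShape, collapse = " x "),
              object@voxelSize, length(object@regions)))
  acq <- object@acquisition
  cat(sprintf("  acquisition: %d directions @ b=%g s/mm^2 + %d b0\n",
              acq$nDirections, acq$bval, acq$nB0))
  cat(sprintf("  Rician sigma: %g\n", object@noiseSigma))
})

## ---------------------------------------------------------------------------
## DiceReport
## ---------------------------------------------------------------------------

#' Pairwise Dice reproducibility report
#'
#' Per-nucleus Dice coefficients over all unordered pairs of co-registered
#' label maps (session/rater comparisons), with a per-label summary.
#'
#' @slot records data.frame with columns label, name, id_a, id_b, dice,
#'   voxels_a, voxels_b.
#' @slot summary data.frame with columns label, name, mean_dice, sd_dice,
#'   n_comparisons.
#' @slot metadata List; records conventions (e.g. the empty-mask rule).
#' @export
setClass("DiceReport",
  representation(records = "data.frame", summary = "data.frame",
                 metadata = "list"),
  validity = function(object) {
    msgs <- character()
    need <- c("label", "name", "id_a", "id_b", "dice",
              "voxels_a", "voxels_b")
    if (!all(need %in% names(object@records)))
      msgs <- c(msgs, paste("records must have columns:",
                            paste(need, collapse = ", ")))
    else if (nrow(object@records) &&
             (min(object@records$dice) < 0 || max(object@records$dice) > 1))
      msgs <- c(msgs, "all Dice coefficients must lie in [0, 1]")
    if (length(msgs)) msgs else TRUE
  })

setMethod("show", "DiceReport", function(object) {
  cat(sprintf("DiceReport: %d comparison record(s), %d label(s)\n",
              nrow(object@records), nrow(object@summary)))
  if (nrow(object@summary)) {
    s <- object@summary
    s$mean_dice <- round(s$mean_dice, 3)
    s$sd_dice <- round(s$sd_dice, 3)
    print(s, row.names = FALSE)
  }
})
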