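#' @include AllGenerics.R
NULL

#' b-values of a gradient table or dataset
#'
#' @param x A \linkS4class{GradientTable} or \linkS4class{DWIDataset}.
#' @return Numeric vector of b-values (s/mm^2), one per 4D volume.
#' @export
setGeneric("bValues", function(x) standardGeneric("bValues"))

#' Gradient directions
#'
#' @param x A \linkS4class{GradientTable}, \linkS4class{DWIDataset} or
#'   \linkS4class{DirectionSet}.
#' @return A 3 x N numeric matrix of gradient directions (columns are
#'   vectors; unit norm where the b-value is positive).
#' @export
setGeneric("bVectors", function(x) standardGeneric("bVectors"))

#' Number of 4D volumes described
#'
#' @param x A \linkS4class{GradientTable} or \linkS4class{DWIDataset}.
#' @return Integer count of volumes.
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))

#' Voxel-to-world affine transform
#'
#' @param x An image-bearing object.
#' @return A 4 x 4 numeric matrix (mm).
#' @export
setGeneric("imageAffine", function(x) standardGeneric("imageAffine"))

#' Voxel data of an image-bearing object
#'
#' @param x An image-bearing object.
#' @return The underlying array (3D or 4D).
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))

#' Label-id to nucleus-name dictionary
#'
#' @param x A \linkS4class{LabelMap}.
#' @return Named character vector; names are label ids as strings.
#' @export
setGeneric("labelNames", function(x) standardGeneric("labelNames"))
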