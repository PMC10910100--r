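#' @include gradients.R
NULL

#' Read a 4D diffusion dataset (NIfTI volume + bvals/bvecs trio)
#'
#' Reads the standard diffusion-MRI file trio and validates gradient and
#' geometric consistency: the number of 4D volumes must match the gradient
#' table, and every direction with b > 0 must be unit-norm. Directions are
#' kept as stored (image-coordinate, FSL convention); no world-coordinate
#' rotation is applied, since the aggregation contrast is insensitive to a
#' global rotation of the scheme.
#'
#' @param volumePath Path to a 4D NIfTI-1 volume (.nii or .nii.gz).
#' @param bvalPath,bvecPath Paths to the FSL-style sidecar text files.
#' @param renormalize Rescale near-unit directions to exact unit norm
#'   rather than failing validation.
#' @param zeroFillNonfinite Non-finite voxels are an error by default; set
#'   TRUE to replace them with 0 and warn instead.
#' @return A validated \linkS4class{DWIDataset}.
#' @examples
#' \dontrun{
#' ds <- readDWI("dwi.nii.gz", "bvals", "bvecs")
#' }
#' @export
readDWI <- function(volumePath, bvalPath, bvecPath, renormalize = FALSE,
                    zeroFillNonfinite = FALSE) {
  img <- .readNiftiChecked(volumePath)
  arr <- .plainArray(img)
  if (length(dim(arr)) != 4L)
    stop("'", volumePath, "' is not a 4D volume (found ",
         length(dim(arr)), " dimensions)")
  if (any(!is.finite(arr))) {
    if (zeroFillNonfinite) {
      n <- sum(!is.finite(arr))
      arr[!is.finite(arr)] <- 0
      warning(n, " non-finite voxel value(s) in '", volumePath,
              "' replaced with 0")
    } else {
      stop("'", volumePath, "' contains non-finite voxel values; pass ",
           "zeroFillNonfinite = TRUE to zero-fill them")
    }
  }
  gtab <- readGradientTable(bvalPath, bvecPath, renormalize = renormalize)
  if (dim(arr)[4] != nVolumes(gtab))
    stop(sprintf(
      "volume count mismatch: '%s' has %d volumes but the gradient table describes %d",
      volumePath, dim(arr)[4], nVolumes(gtab)))
  dwiDataset(arr, gtab, affine = .niftiAffine(img))
}

.readNiftiChecked <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "'")
  RNifti::readNifti(path)
}

## plain numeric array, shedding the niftiImage class and header attributes
.plainArray <- function(img) {
  a <- as.array(img)
  array(as.vector(a), dim(a))
}

.niftiAffine <- function(img) {
  a <- unclass(RNifti::xform(img))
  attributes(a) <- list(dim = c(4L, 4L))
  a
}

#' Write a 3D scalar image as NIfTI-1
#'
#' Values are stored as 32-bit float (labels: 16- or 32-bit integer), so a
#' round-trip read reproduces values to float precision and the affine
#' exactly for representable spacings.
#'
#' @param image A 3D (or 4D) numeric array, a \linkS4class{ContrastImage},
#'   or a \linkS4class{LabelMap}.
#' @param path Output path (.nii or .nii.gz).
#' @param affine 4 x 4 voxel-to-world matrix; ignored (taken from the
#'   object) for ContrastImage/LabelMap inputs.
#' @param datatype NIfTI storage type; default "float" for scalar images.
#' @return Invisibly, the path written.
#' @export
writeImage <- function(image, path, affine = diag(4), datatype = "float") {
  if (is(image, "ContrastImage")) {
    affine <- image@affine
    image <- image@values
  } else if (is(image, "LabelMap")) {
    affine <- image@affine
    datatype <- if (max(image@labels) > 32767L) "int32" else "int16"
    image <- image@labels
  }
  if (!all(is.finite(image))) stop("image contains non-finite values")
  err <- .checkAffine(affine)
  if (length(err)) stop(err)
  img <- RNifti::asNifti(image)
  RNifti::pixdim(img) <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  ok <- tryCatch({
    RNifti::writeNifti(img, path, datatype = datatype)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read a multilabel segmentation volume
#'
#' Voxels must be integers (floats exactly representing integers are
#' accepted to a 1e-6 tolerance). Labels present in the volume but absent
#' from the name mapping are auto-filled as "label_<k>".
#'
#' @param path Path to a NIfTI-1 label volume.
#' @param names Optional named character vector or path to a JSON mapping
#'   file like {"1": "VLPv", "2": "VPL"}.
#' @return A \linkS4class{LabelMap}.
#' @export
readLabelMap <- function(path, names = NULL) {
  img <- .readNiftiChecked(path)
  arr <- .plainArray(img)
  if (length(dim(arr)) != 3L)
    stop("'", path, "' is not a 3D volume")
  if (is.character(names) && length(names) == 1L && file.exists(names))
    names <- readLabelNames(names)
  labelMap(arr, affine = .niftiAffine(img), names = names)
}

#' Read a label-name mapping from JSON
#'
#' @param path JSON file of the form {"1": "VLPv", "2": "VPL", ...}.
#' @return Named character vector (names are label ids as strings).
#' @export
readLabelNames <- function(path) {
  x <- jsonlite::read_json(path)
  stats::setNames(vapply(x, as.character, character(1)), names(x))
}

#' Write a label-name mapping as JSON
#'
#' @param names Named character vector (names are label ids as strings).
#' @param path Output JSON path.
#' @return Invisibly, the path.
#' @export
writeLabelNames <- function(names, path) {
  jsonlite::write_json(as.list(names), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
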