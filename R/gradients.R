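#' @include AllClasses.R
NULL

#' Read FSL-style bvals and bvecs sidecars
#'
#' Parses the whitespace-separated text files that accompany a 4D diffusion
#' volume. The canonical bvecs dialect is 3 rows x N columns; a transposed
#' N x 3 file is auto-detected by shape, accepted, and reported with a
#' warning (both dialects circulate and a silent misread would be
#' catastrophic). Parsing is whitespace-robust: runs of spaces or tabs and
#' trailing newlines are all equivalent.
#'
#' @param bvalPath Path to the bvals file (numbers on one or more lines).
#' @param bvecPath Path to the bvecs file (3 x N, or N x 3 auto-detected).
#' @param renormalize If TRUE, near-unit directions with b > 0 are rescaled
#'   to exact unit norm instead of failing validation.
#' @return A \linkS4class{GradientTable}.
#' @export
readGradientTable <- function(bvalPath, bvecPath, renormalize = FALSE) {
  bvals <- .scanNumeric(bvalPath)
  raw <- .scanNumericLines(bvecPath)
  nr <- length(raw)
  if (nr == 3L) {
    bvecs <- do.call(rbind, raw)
  } else if (nr > 0 && all(lengths(raw) == 3L)) {
    warning("bvecs file '", bvecPath, "' is in the transposed N x 3 ",
            "dialect; transposing to the canonical 3 x N layout")
    bvecs <- t(do.call(rbind, raw))
  } else {
    stop("bvecs file '", bvecPath, "' is neither 3 x N nor N x 3")
  }
  if (length(unique(lengths(raw))) > 1L && nr == 3L)
    stop("bvecs file '", bvecPath, "' has ragged rows")
  if (length(bvals) != ncol(bvecs))
    stop(sprintf(
      "gradient count mismatch: %d b-values in '%s' but %d directions in '%s'",
      length(bvals), bvalPath, ncol(bvecs), bvecPath))
  gradientTable(bvals, bvecs, renormalize = renormalize)
}

.scanNumeric <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "'")
  x <- scan(path, what = double(), quiet = TRUE)
  if (!length(x)) stop("'", path, "' contains no numbers")
  x
}

.scanNumericLines <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "'")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l)
    as.numeric(strsplit(trimws(l), "[ \t]+")[[1]]))
}

#' Write FSL-style bvals and bvecs sidecars
#'
#' @param gtab A \linkS4class{GradientTable}.
#' @param bvalPath Output path for the single-line bvals file.
#' @param bvecPath Output path for the 3-row bvecs file.
#' @return Invisibly, the two paths.
#' @export
writeGradientTable <- function(gtab, bvalPath, bvecPath) {
  writeLines(paste(format(gtab@bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bvalPath)
  writeLines(apply(gtab@bvecs, 1, function(r)
    paste(format(r, trim = TRUE, digits = 17), collapse = " ")), bvecPath)
  invisible(c(bvalPath, bvecPath))
}

#' Subset a gradient table (and report which volumes to keep)
#'
#' @param gtab A \linkS4class{GradientTable}.
#' @param indices 1-based volume indices to keep, in order.
#' @return A \linkS4class{GradientTable} over the kept volumes.
#' @export
subsetGradientTable <- function(gtab, indices) {
  gradientTable(gtab@bvals[indices], gtab@bvecs[, indices, drop = FALSE])
}
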