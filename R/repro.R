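#' @include AllClasses.R
NULL

#' Dice overlap coefficient of two binary masks
#'
#' DC = 2 |A and B| / (|A| + |B|). Conventions for empty masks: both empty
#' is perfect agreement on absence (1.0); exactly one empty is complete
#' disagreement (0.0).
#'
#' @param a,b 3D logical (or 0/1) arrays of identical shape.
#' @return Dice coefficient in [0, 1].
#' @examples
#' a <- array(FALSE, c(4, 4, 4)); a[1:2, 1, 1] <- TRUE
#' b <- array(FALSE, c(4, 4, 4)); b[2:3, 1, 1] <- TRUE
#' diceCoefficient(a, b)  # 2*1 / (2+2) = 0.5
#' @export
diceCoefficient <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("geometry mismatch: mask shapes differ (",
         paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), ")")
  a <- as.vector(a) != 0
  b <- as.vector(b) != 0
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(1.0)
  2 * sum(a & b) / (na + nb)
}

#' Per-label Dice coefficients between two segmentations
#'
#' Computes one Dice coefficient per label over the union of nonzero
#' labels present in either map. Inputs must already be co-registered to
#' a common grid; no resampling is performed (hidden resampling would
#' corrupt the overlap values).
#'
#' @param a,b \linkS4class{LabelMap}s on the same grid (affines within
#'   1e-4).
#' @param idA,idB Identifiers for the two inputs (e.g. session or rater).
#' @return data.frame with columns label, name, id_a, id_b, dice,
#'   voxels_a, voxels_b; one row per label, sorted by label.
#' @export
multilabelDice <- function(a, b, idA = "a", idB = "b") {
  .checkSameGeometry(dim(a@labels), a@affine, dim(b@labels), b@affine)
  la <- as.vector(a@labels)
  lb <- as.vector(b@labels)
  labs <- setdiff(sort(unique(c(la, lb))), 0L)
  nm <- c(a@names, b@names[setdiff(names(b@names), names(a@names))])
  rows <- lapply(labs, function(k) {
    ma <- la == k; mb <- lb == k
    na <- sum(ma); nb <- sum(mb)
    dc <- if (na + nb == 0L) 1.0 else 2 * sum(ma & mb) / (na + nb)
    data.frame(label = k,
               name = if (as.character(k) %in% names(nm))
                 unname(nm[as.character(k)]) else paste0("label_", k),
               id_a = idA, id_b = idB, dice = dc,
               voxels_a = na, voxels_b = nb)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Pairwise Dice reproducibility report over several segmentations
#'
#' Evaluates all C(k, 2) unordered pairs of k co-registered label maps
#' (the test-retest and inter-rater designs: 8 sessions of one subject
#' give 28 comparisons per nucleus, 3 raters give 3) and summarizes the
#' per-label mean and SD.
#'
#' @param maps List of >= 2 \linkS4class{LabelMap}s; element names are
#'   used as session/rater identifiers (default map1, map2, ...).
#' @return A \linkS4class{DiceReport}; records are sorted by label then
#'   identifier pair.
#' @export
pairwiseDiceReport <- function(maps) {
  k <- length(maps)
  if (k < 2) stop("need at least 2 label maps, got ", k)
  ids <- names(maps)
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- paste0("map", seq_len(k))
  pairs <- utils::combn(k, 2)
  recs <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    multilabelDice(maps[[i]], maps[[j]], idA = ids[i], idB = ids[j])
  })
  records <- do.call(rbind, recs)
  records <- records[order(records$label, records$id_a, records$id_b), ,
                     drop = FALSE]
  rownames(records) <- NULL
  agg <- lapply(split(records, records$label), function(d)
    data.frame(label = d$label[1], name = d$name[1],
               mean_dice = mean(d$dice),
               sd_dice = if (nrow(d) > 1) stats::sd(d$dice) else 0,
               n_comparisons = nrow(d)))
  summary <- do.call(rbind, c(agg, list(make.row.names = FALSE)))
  new("DiceReport", records = records, summary = summary,
      metadata = list(
        n_maps = k, ids = ids,
        empty_mask_rule = "both empty -> 1.0; exactly one empty -> 0.0"))
}

#' Write a Dice report as CSV
#'
#' Writes the per-pair records to \code{path} and the per-label summary
#' to a companion file with "_summary" inserted before the extension.
#'
#' @param report A \linkS4class{DiceReport}.
#' @param path Output CSV path for the records.
#' @return Invisibly, the two paths written.
#' @export
writeDiceReport <- function(report, path) {
  utils::write.csv(report@records, path, row.names = FALSE)
  sumPath <- sub("(\\.[^.]+)?$", "_summary\\1", path)
  if (identical(sumPath, path)) sumPath <- paste0(path, "_summary")
  utils::write.csv(report@summary, sumPath, row.names = FALSE)
  invisible(c(path, sumPath))
}

#' Perturb segmentation boundaries (synthetic rater variability)
#'
#' Each foreground boundary voxel (one whose 6-neighborhood contains a
#' different label, background included; volume faces border background)
#' is independently reassigned, with the given probability, to a label
#' drawn uniformly from its differing 6-neighbor labels. Seeded and
#' deterministic; emulates inter-rater boundary disagreement.
#'
#' @param map A \linkS4class{LabelMap}.
#' @param rate Flip probability per boundary voxel, in [0, 1].
#' @param seed Integer seed.
#' @return A perturbed \linkS4class{LabelMap} on the same grid.
#' @export
perturbLabels <- function(map, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  lab <- map@labels
  if (rate == 0) return(map)
  sp <- dim(lab)
  shift <- function(ax, by) {
    out <- array(0L, sp)     # out-of-volume neighbors read as background
    src <- dst <- list(seq_len(sp[1]), seq_len(sp[2]), seq_len(sp[3]))
    if (by == 1L) { dst[[ax]] <- 2:sp[ax]; src[[ax]] <- 1:(sp[ax] - 1L) }
    else { dst[[ax]] <- 1:(sp[ax] - 1L); src[[ax]] <- 2:sp[ax] }
    out[dst[[1]], dst[[2]], dst[[3]]] <- lab[src[[1]], src[[2]], src[[3]]]
    out
  }
  nbr <- cbind(as.vector(shift(1, 1L)), as.vector(shift(1, -1L)),
               as.vector(shift(2, 1L)), as.vector(shift(2, -1L)),
               as.vector(shift(3, 1L)), as.vector(shift(3, -1L)))
  lv <- as.vector(lab)
  differs <- nbr != lv
  boundary <- which(lv > 0L & rowSums(differs) > 0)
  if (!length(boundary)) return(map)
  newLab <- .withSeed(seed, function() {
    flip <- boundary[stats::runif(length(boundary)) < rate]
    if (!length(flip)) return(lv)
    d <- differs[flip, , drop = FALSE]
    nd <- rowSums(d)
    pick <- pmax(ceiling(stats::runif(length(flip)) * nd), 1)  # k-th differing nbr
    cum <- t(apply(d, 1, cumsum))
    col <- max.col(cum == pick, ties.method = "first")
    lv[flip] <- nbr[flip, , drop = FALSE][cbind(seq_along(flip), col)]
    lv
  })
  labelMap(array(newLab, sp), affine = map@affine, names = map@names)
}
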