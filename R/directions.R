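#' @include AllClasses.R
NULL

## Run fn() under a temporary RNG state seeded with `seed`; the caller's
## .Random.seed is restored afterwards so no hidden global state leaks.
.withSeed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

## Antipodally symmetrized electrostatic energy of a 3 x n direction set:
## sum over i < j of 1/|vi - vj| + 1/|vi + vj|.
.pairEnergy <- function(v) {
  n <- ncol(v)
  if (n < 2) return(0)
  G <- crossprod(v)                     # dot products
  dm <- sqrt(pmax(2 - 2 * G, 0))        # |vi - vj|
  dp <- sqrt(pmax(2 + 2 * G, 0))        # |vi + vj|
  iu <- upper.tri(G)
  sum(1 / dm[iu]) + sum(1 / dp[iu])
}

#' Generate a uniformly distributed gradient direction set
#'
#' Places n unit vectors on the half-sphere by minimizing the antipodally
#' symmetrized electrostatic energy
#' E = sum_(i<j) 1/|vi - vj| + 1/|vi + vj|
#' (each direction repels both every other direction and its antipode,
#' since g and -g are equivalent for diffusion weighting). Starting from a
#' seeded random configuration, points move along the tangential component
#' of the net repulsive force with an adaptive step until the relative
#' energy change drops below 1e-8 or 10,000 iterations are reached.
#' Deterministic for a fixed seed.
#'
#' @param n Number of directions, >= 3.
#' @param seed Integer seed for the random start.
#' @return A \linkS4class{DirectionSet}.
#' @examples
#' ds <- makeDirections(3, seed = 1)
#' round(crossprod(bVectors(ds)), 3)  # near-orthogonal triad
#' @export
makeDirections <- function(n, seed = 1L) {
  if (n < 3) stop("n must be >= 3")
  v0 <- .withSeed(seed, function() {
    v <- matrix(stats::rnorm(3 * n), 3, n)
    sweep(v, 2, sqrt(colSums(v^2)), "/")
  })
  directionSet(.repelDirections(v0))
}

.repelDirections <- function(v, relTol = 1e-8, maxIter = 10000L) {
  n <- ncol(v)
  e <- .pairEnergy(v)
  step <- 0.1 / n
  for (it in seq_len(maxIter)) {
    G <- crossprod(v)
    dm3 <- (pmax(2 - 2 * G, 1e-300))^1.5
    dp3 <- (pmax(2 + 2 * G, 1e-300))^1.5
    diag(dm3) <- Inf
    diag(dp3) <- Inf
    ## force on column i: sum_j (vi - vj)/|vi-vj|^3 + (vi + vj)/|vi+vj|^3
    wm <- 1 / dm3; wp <- 1 / dp3
    F <- v %*% (diag(rowSums(wm + wp)) ) -
      v %*% wm + v %*% wp
    ## tangential component
    F <- F - sweep(v, 2, colSums(F * v), "*")
    vNew <- v + step * F
    vNew <- sweep(vNew, 2, sqrt(colSums(vNew^2)), "/")
    eNew <- .pairEnergy(vNew)
    if (eNew < e) {
      conv <- (e - eNew) / e < relTol
      v <- vNew
      e <- eNew
      step <- step * 1.2
      if (conv) break
    } else {
      step <- step / 2
      if (step < 1e-14) break
    }
  }
  v
}

#' Minimum folded pairwise angle of a direction set
#'
#' The folded angle between two directions treats g and -g as equivalent:
#' acos(|gi . gj|). The minimum over all pairs is the standard uniformity
#' figure of merit for a diffusion scheme.
#'
#' @param ds A \linkS4class{DirectionSet} or 3 x n matrix.
#' @return Minimum folded angle in radians.
#' @export
minFoldedAngle <- function(ds) {
  v <- if (is(ds, "DirectionSet")) ds@vectors else ds
  if (ncol(v) < 2) return(NA_real_)
  G <- abs(crossprod(v))
  acos(min(max(G[upper.tri(G)]), 1))
}

#' Subsample a direction set, preserving uniformity
#'
#' Greedy selection of an m-subset with low antipodal electrostatic
#' energy, emulating a shorter acquisition drawn from the same scheme:
#' start from the pair with the largest folded angle, repeatedly add the
#' candidate direction that minimizes the energy of the grown subset,
#' then polish with deterministic single-member exchanges: first swaps
#' that strictly lower the subset energy, then swaps that strictly raise
#' the subset's minimum folded angle (the uniformity figure of merit the
#' energy stands in for), until no improving swap remains.
#' Deterministic (ties break on the lowest index).
#'
#' @param ds A \linkS4class{DirectionSet}.
#' @param m Subset size, 3 <= m <= length(ds); m = n returns the input.
#' @return A list with elements \code{directions}
#'   (\linkS4class{DirectionSet}) and \code{indices} (1-based positions of
#'   the kept directions in the input set).
#' @export
subsampleDirections <- function(ds, m) {
  v <- ds@vectors
  n <- ncol(v)
  if (m < 3 || m > n)
    stop("m must be between 3 and the set size (", n, "), got ", m)
  if (m == n)
    return(list(directions = ds, indices = seq_len(n)))
  G <- abs(crossprod(v))
  diag(G) <- Inf
  best <- which(G == min(G), arr.ind = TRUE)[1, ]
  chosen <- sort(as.integer(best))
  remaining <- setdiff(seq_len(n), chosen)
  ## incremental energy of adding candidate c to the current subset
  while (length(chosen) < m) {
    add <- vapply(remaining, function(c) {
      d <- v[, chosen, drop = FALSE] - v[, c]
      s <- v[, chosen, drop = FALSE] + v[, c]
      sum(1 / sqrt(colSums(d^2))) + sum(1 / sqrt(colSums(s^2)))
    }, numeric(1))
    pick <- remaining[which.min(add)]
    chosen <- c(chosen, pick)
    remaining <- setdiff(remaining, pick)
  }
  chosen <- .exchangeRefine(v, chosen)
  chosen <- .maximinRefine(v, chosen)
  list(directions = directionSet(v[, chosen, drop = FALSE]),
       indices = chosen)
}

## Second polishing stage on the uniformity figure of merit itself:
## accept the swap that most increases the minimum folded angle, repeat
## until no swap improves it.
.maximinRefine <- function(v, chosen) {
  n <- ncol(v)
  minAng <- function(ix) minFoldedAngle(v[, ix, drop = FALSE])
  repeat {
    bestA <- minAng(chosen)
    bestSwap <- NULL
    for (i in seq_along(chosen)) {
      for (c in setdiff(seq_len(n), chosen)) {
        cand <- chosen
        cand[i] <- c
        a <- minAng(cand)
        if (a > bestA + 1e-12) {
          bestA <- a
          bestSwap <- cand
        }
      }
    }
    if (is.null(bestSwap)) break
    chosen <- bestSwap
  }
  sort(chosen)
}

## Deterministic local search: replace one chosen direction with one
## unchosen one whenever that strictly lowers the subset energy; repeat
## with the best available swap until none improves.
.exchangeRefine <- function(v, chosen) {
  n <- ncol(v)
  repeat {
    e0 <- .pairEnergy(v[, chosen, drop = FALSE])
    bestE <- e0
    bestSwap <- NULL
    for (i in seq_along(chosen)) {
      for (c in setdiff(seq_len(n), chosen)) {
        cand <- chosen
        cand[i] <- c
        e <- .pairEnergy(v[, cand, drop = FALSE])
        if (e < bestE - 1e-12) {
          bestE <- e
          bestSwap <- cand
        }
      }
    }
    if (is.null(bestSwap)) break
    chosen <- bestSwap
  }
  sort(chosen)
}
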