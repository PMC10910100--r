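# Fixtures are built in code; nothing is stored on disk.

# Random 4D dataset with nB0 b0 volumes and the rest at b = 1500
makeRandomDWI <- function(shape = c(6, 6, 6), nVol = 12, nB0 = 2,
                          seed = 42, bWeighted = 1500) {
  set.seed(seed)
  nW <- nVol - nB0
  v <- matrix(rnorm(3 * nW), 3)
  v <- sweep(v, 2, sqrt(colSums(v^2)), "/")
  gt <- gradientTable(c(rep(0, nB0), rep(bWeighted, nW)),
                      cbind(matrix(0, 3, nB0), v))
  sig <- array(runif(prod(shape) * nVol, 1, 100), c(shape, nVol))
  dwiDataset(sig, gt)
}

# Cubic single-label map: side^3 voxels of label `lab` at offset `at`
makeCubeLabel <- function(shape = c(16, 16, 16), at = c(4, 4, 4),
                          side = 10, lab = 1L, name = "VLPv") {
  arr <- array(0L, shape)
  arr[at[1]:(at[1] + side - 1), at[2]:(at[2] + side - 1),
      at[3]:(at[3] + side - 1)] <- lab
  labelMap(arr, names = stats::setNames(name, as.character(lab)))
}

# Random multilabel map over nLabels labels (plus background)
makeRandomLabels <- function(shape = c(16, 16, 16), nLabels = 3,
                             seed = 7) {
  set.seed(seed)
  labelMap(array(sample(0:nLabels, prod(shape), replace = TRUE), shape))
}

# Brute-force per-voxel aggregation oracle, written independently of the
# vectorized implementation (explicit triple loop, R's own mean/median)
bruteForceAggregate <- function(signal, sel, method) {
  sp <- dim(signal)[1:3]
  out <- array(NA_real_, sp)
  for (i in seq_len(sp[1])) for (j in seq_len(sp[2]))
    for (k in seq_len(sp[3])) {
      x <- signal[i, j, k, sel]
      out[i, j, k] <- switch(method,
        mean = mean(x),
        median = stats::median(x),
        centromean = {
          s <- sort(x); q <- length(s) %/% 4
          mean(s[(q + 1):(length(s) - q)])
        },
        sum = sum(x),
        l2norm = sqrt(sum(x^2)))
    }
  out
}

expect_error_matching <- function(expr, pattern) {
  testthat::expect_error(expr, regexp = pattern)
}
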