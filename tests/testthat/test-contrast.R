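test_that("b-threshold selection keeps exactly the b > threshold volumes", {
  gt <- gradientTable(c(0, 5, 1000, 1500, 2000),
                      matrix(rep(c(1, 0, 0), 5), 3))
  expect_identical(selectWeighted(gt, 100), c(3L, 4L, 5L))
  expect_identical(selectWeighted(gt, 100, shell = 1000,
                                  shellTolerance = 50), 3L)
  gt0 <- gradientTable(c(0, 0), matrix(0, 3, 2))
  expect_error(selectWeighted(gt0, 100), "no diffusion-weighted")
  expect_error(selectWeighted(gt, 100, shell = 50), "exceed")
})

test_that("every aggregation method matches the brute-force oracle", {
  for (rep in 1:5) {
    ds <- makeRandomDWI(shape = c(6, 6, 6), nVol = 12, nB0 = 2,
                        seed = 100 + rep)
    sel <- selectWeighted(ds)
    for (m in c("mean", "median", "centromean", "sum", "l2norm")) {
      got <- imageData(computeContrast(ds, m))
      want <- bruteForceAggregate(ds@signal, sel, m)
      expect_lt(max(abs(got - want)) / max(abs(want)), 1e-10,
                label = sprintf("method %s rep %d rel err", m, rep))
    }
  }
})

test_that("aggregation follows the stated per-voxel rules", {
  # (10, 20, 30): mean 20; (3, 4): l2norm 5; (1,2,3,4,100): centromean 3
  mk <- function(series) {
    n <- length(series)
    v <- diag(3)[, rep(1, n), drop = FALSE]
    gt <- gradientTable(rep(1500, n), v)
    sig <- array(rep(series, each = 8), c(2, 2, 2, n))
    dwiDataset(sig, gt)
  }
  expect_equal(imageData(computeContrast(mk(c(10, 20, 30)), "mean"))[1, 1, 1], 20)
  expect_equal(imageData(computeContrast(mk(c(3, 4)), "l2norm"))[1, 1, 1], 5)
  expect_equal(imageData(computeContrast(mk(c(1, 2, 3, 4, 100)),
                                         "centromean"))[1, 1, 1], 3)
  expect_equal(imageData(computeContrast(mk(c(1, 2, 3, 4)),
                                         "median"))[1, 1, 1], 2.5)
  # single weighted volume: mean returns that volume exactly
  ds1 <- makeRandomDWI(nVol = 3, nB0 = 2, seed = 5)
  expect_identical(imageData(computeContrast(ds1, "mean")),
                   array(ds1@signal[, , , 3], dim(ds1@signal)[1:3]))
})

test_that("contrast is bit-identical under volume permutation", {
  ds <- makeRandomDWI(shape = c(5, 5, 5), nVol = 14, nB0 = 2, seed = 11)
  set.seed(3)
  perm <- sample(nVolumes(ds))
  dsP <- dwiDataset(ds@signal[, , , perm, drop = FALSE],
                    subsetGradientTable(ds@gradients, perm), ds@affine)
  for (m in c("mean", "median", "centromean", "sum", "l2norm"))
    expect_identical(imageData(computeContrast(ds, m)),
                     imageData(computeContrast(dsP, m)),
                     label = paste("method", m))
})

test_that("mean equals sum/n and variants rank-agree on a noisy phantom", {
  spec <- presetThalamus(seed = 3, noiseSigma = 2)
  built <- buildPhantom(spec)
  fg <- as.vector(imageData(built$labels)) > 0
  ciMean <- computeContrast(built$dwi, "mean")
  ciSum <- computeContrast(built$dwi, "sum")
  n <- length(selectWeighted(built$dwi))
  expect_lt(max(abs(imageData(ciMean) - imageData(ciSum) / n)) /
              max(imageData(ciMean)), 1e-12)
  mv <- as.vector(imageData(ciMean))[fg]
  for (m in c("centromean", "sum", "l2norm")) {
    ov <- as.vector(imageData(computeContrast(built$dwi, m)))[fg]
    rho <- cor(mv, ov, method = "spearman")
    expect_gt(rho, 0.95, label = paste("spearman mean vs", m))
  }
  # the median's rank agreement inside large homogeneous regions is
  # bounded by the mean-median sampling correlation (~sqrt(2/pi) = 0.80
  # for Gaussian samples); between-region structure must lift it above
  # that noise-only baseline
  ovMed <- as.vector(imageData(computeContrast(built$dwi, "median")))[fg]
  expect_gt(cor(mv, ovMed, method = "spearman"), sqrt(2 / pi))
})

test_that("variants rank-agree above 0.95 across a full dynamic range", {
  # graded-slab phantom: many distinct intensity levels spanning the
  # CSF-to-white-matter range, so ranks reflect structure, not noise
  built <- buildPhantom(presetGradedSlabs(seed = 4, noiseSigma = 2))
  fg <- as.vector(imageData(built$labels)) > 0
  mv <- as.vector(imageData(computeContrast(built$dwi, "mean")))[fg]
  for (m in c("median", "centromean", "sum", "l2norm")) {
    ov <- as.vector(imageData(computeContrast(built$dwi, m)))[fg]
    expect_gt(cor(mv, ov, method = "spearman"), 0.95,
              label = paste("graded phantom, mean vs", m))
  }
})

test_that("masking restricts the contrast and zeroes the background", {
  ds <- makeRandomDWI(shape = c(6, 6, 6), nVol = 8, seed = 21)
  mask <- array(FALSE, c(6, 6, 6)); mask[2:4, 2:4, 2:4] <- TRUE
  ci <- computeContrast(ds, "mean", mask = mask)
  full <- computeContrast(ds, "mean")
  expect_true(all(imageData(ci)[!mask] == 0))
  expect_identical(imageData(ci)[mask], imageData(full)[mask])
})

test_that("b0 mean averages only the b <= threshold volumes", {
  ds <- makeRandomDWI(shape = c(4, 4, 4), nVol = 6, nB0 = 2, seed = 31)
  ci <- b0Mean(ds)
  want <- (ds@signal[, , , 1] + ds@signal[, , , 2]) / 2
  expect_equal(imageData(ci), array(want, c(4, 4, 4)))
  expect_identical(ci@method, "b0_mean")
  gtNoB0 <- makeRandomDWI(nVol = 6, nB0 = 0, seed = 1)
  expect_error(b0Mean(gtNoB0), "no b0")
})

test_that("region statistics are exact on piecewise-constant images", {
  arr <- array(0L, c(6, 6, 6))
  arr[1:2, 1:5, 1] <- 1L          # 10 voxels
  arr[5:6, 1:6, 6] <- 2L
  lm <- labelMap(arr, names = c("1" = "VLPv", "2" = "VPL"))
  vals <- array(5, c(6, 6, 6)); vals[arr == 2L] <- 2
  ci <- new("ContrastImage", values = vals, affine = diag(4),
            method = "mean", bThreshold = 100, shell = NA_real_,
            equalized = FALSE, equalizeParams = list())
  st <- regionStats(ci, lm)
  expect_equal(st$mean, c(5, 2))
  expect_equal(st$sd, c(0, 0))
  expect_equal(st$n_voxels, c(10L, 12L))
  expect_setequal(st$name, c("VLPv", "VPL"))
  # affine mismatch is a geometry error
  lm2 <- labelMap(arr, affine = diag(c(2, 2, 2, 1)))
  expect_error(regionStats(ci, lm2), "geometry")
})
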