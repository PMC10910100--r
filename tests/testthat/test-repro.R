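test_that("binary Dice follows the set formula and edge conventions", {
  a <- array(FALSE, c(8, 8, 8)); a[1:2, 1, 1] <- TRUE
  expect_equal(diceCoefficient(a, a), 1.0)
  b <- array(FALSE, c(8, 8, 8)); b[5:6, 5, 5] <- TRUE
  expect_equal(diceCoefficient(a, b), 0.0)
  c2 <- array(FALSE, c(8, 8, 8)); c2[2:3, 1, 1] <- TRUE
  expect_equal(diceCoefficient(a, c2), 0.5)   # |a|=2, |b|=2, overlap 1
  empty <- array(FALSE, c(8, 8, 8))
  expect_equal(diceCoefficient(empty, empty), 1.0)
  expect_equal(diceCoefficient(a, empty), 0.0)
  expect_equal(diceCoefficient(a, b), diceCoefficient(b, a))
  expect_error(diceCoefficient(a, array(FALSE, c(4, 4, 4))), "geometry")
})

test_that("a unit shift of a 10-voxel cube gives Dice 0.9 exactly", {
  a <- makeCubeLabel(shape = c(16, 16, 16), at = c(3, 3, 3), side = 10)
  b <- makeCubeLabel(shape = c(16, 16, 16), at = c(4, 3, 3), side = 10)
  rec <- multilabelDice(a, b)
  expect_equal(rec$dice, 2 * 900 / (1000 + 1000))
  expect_equal(rec$voxels_a, 1000L)
})

test_that("multilabel Dice covers the union of labels in either map", {
  arrA <- array(0L, c(8, 8, 8)); arrA[1:3, 1:3, 1:3] <- 1L
  arrB <- arrA; arrB[6:8, 6:8, 6:8] <- 2L
  a <- labelMap(arrA, names = c("1" = "VLPv"))
  b <- labelMap(arrB, names = c("1" = "VLPv", "2" = "VPL"))
  rec <- multilabelDice(a, b)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$dice[rec$label == 1], 1.0)
  expect_equal(rec$dice[rec$label == 2], 0.0)  # present in b only
  # identical maps with many labels: all 1.0
  m <- makeRandomLabels(nLabels = 12, seed = 3)
  recId <- multilabelDice(m, m)
  expect_true(all(recId$dice == 1.0))
  expect_equal(nrow(recId), 12)
  # mismatched grids must fail loudly (inputs must be pre-registered)
  small <- makeRandomLabels(shape = c(8, 8, 8), seed = 1)
  expect_error(multilabelDice(m, small), "pre-registered")
})

test_that("multilabel Dice agrees exactly with a voxel-set oracle", {
  for (seed in c(1, 2, 3)) {
    a <- makeRandomLabels(shape = c(16, 16, 16), nLabels = 4, seed = seed)
    b <- makeRandomLabels(shape = c(16, 16, 16), nLabels = 4,
                          seed = seed + 100)
    rec <- multilabelDice(a, b)
    # oracle: explicit coordinate sets and set intersection
    coords <- function(m, k)
      apply(which(imageData(m) == k, arr.ind = TRUE), 1, paste,
            collapse = ",")
    for (k in rec$label) {
      sa <- coords(a, k); sb <- coords(b, k)
      want <- if (!length(sa) && !length(sb)) 1.0
              else 2 * length(intersect(sa, sb)) / (length(sa) + length(sb))
      expect_identical(rec$dice[rec$label == k], want)
    }
  }
})

test_that("pairwise reports have C(k,2) comparisons per label", {
  m <- makeRandomLabels(nLabels = 3, seed = 5)
  rep8 <- pairwiseDiceReport(rep(list(m), 8))     # test-retest design
  expect_equal(unique(rep8@summary$n_comparisons), 28)
  expect_true(all(rep8@records$dice == 1.0))
  expect_true(all(rep8@summary$sd_dice == 0))
  rep3 <- pairwiseDiceReport(rep(list(m), 3))     # inter-rater design
  expect_equal(unique(rep3@summary$n_comparisons), 3)
  rep2 <- pairwiseDiceReport(rep(list(m), 2))
  expect_equal(unique(rep2@summary$n_comparisons), 1)
  expect_error(pairwiseDiceReport(list(m)), "at least 2")
  expect_match(rep8@metadata$empty_mask_rule, "both empty")
})

test_that("dice reports write records and summary CSVs", {
  d <- withr::local_tempdir()
  a <- makeCubeLabel(at = c(3, 3, 3))
  b <- makeCubeLabel(at = c(4, 3, 3))
  report <- pairwiseDiceReport(list(s1 = a, s2 = b))
  paths <- writeDiceReport(report, file.path(d, "report.csv"))
  expect_true(all(file.exists(paths)))
  rec <- utils::read.csv(paths[1])
  expect_equal(rec$dice, 0.9)
  expect_equal(rec$id_a, "s1")
  smry <- utils::read.csv(paths[2])
  expect_equal(smry$n_comparisons, 1)
})

test_that("boundary perturbation is seeded, monotone, and identity at 0", {
  m <- makeCubeLabel(shape = c(20, 20, 20), at = c(6, 6, 6), side = 10)
  expect_identical(imageData(perturbLabels(m, 0)), imageData(m))
  p1 <- perturbLabels(m, 0.3, seed = 4)
  p2 <- perturbLabels(m, 0.3, seed = 4)
  expect_identical(imageData(p1), imageData(p2))
  # mean dice decreases strictly as the flip rate grows
  meanDice <- vapply(c(0.05, 0.2, 0.5), function(rate) {
    mean(vapply(1:100, function(s)
      multilabelDice(m, perturbLabels(m, rate, seed = s))$dice,
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meanDice) < 0))
  # a 1-voxel label surrounded by background can vanish at rate 1
  tiny <- array(0L, c(5, 5, 5)); tiny[3, 3, 3] <- 1L
  tm <- labelMap(tiny)
  gone <- perturbLabels(tm, 1, seed = 1)
  expect_equal(multilabelDice(tm, gone)$dice, 0)
})

test_that("smaller structures lose more Dice at equal flip rate", {
  arr <- array(0L, c(40, 40, 40))
  arr[2:31, 2:11, 2:11] <- 1L       # 3000-voxel slab
  arr[20:22, 25:27, 25:27] <- 2L    # ~30-voxel nugget (Hb-like)
  m <- labelMap(arr, names = c("1" = "VPL", "2" = "Hb"))
  dsmall <- dlarge <- numeric(30)
  for (s in 1:30) {
    rec <- multilabelDice(m, perturbLabels(m, 0.5, seed = s))
    dlarge[s] <- rec$dice[rec$label == 1]
    dsmall[s] <- rec$dice[rec$label == 2]
  }
  expect_lt(mean(dsmall), mean(dlarge))
})
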