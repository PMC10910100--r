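test_that("tensor signal follows the closed-form monoexponential model", {
  S0 <- 100
  # isotropic CSF-like tensor: S0 * exp(-b * d) for any direction
  Dcsf <- diag(3) * 3.0e-3
  for (g in list(c(1, 0, 0), c(0, 1, 0), c(1, 1, 1) / sqrt(3)))
    expect_equal(tensorSignal(Dcsf, 1500, g, S0), S0 * exp(-4.5),
                 tolerance = 1e-12)
  # axial ADC: D = diag(1.7e-3, 0.2e-3, 0.2e-3), g along the first axis
  Dax <- diag(c(1.7e-3, 0.2e-3, 0.2e-3))
  expect_equal(tensorSignal(Dax, 1500, c(1, 0, 0), S0),
               S0 * exp(-2.55), tolerance = 1e-12)
  # b = 0 returns S0 exactly, direction ignored
  expect_identical(tensorSignal(Dax, 0, c(0, 1, 0), S0), S0)
  # non-SPD tensors are rejected
  expect_error(tensorSignal(diag(c(1, 1, -1)) * 1e-3, 1500, c(1, 0, 0)),
               "positive-definite")
  expect_error(tensorSignal(matrix(1:9 * 1e-3, 3), 1500, c(1, 0, 0)),
               "symmetric")
})

test_that("signals are rotation-consistent and isotropy is direction-blind", {
  set.seed(12)
  D <- tensorFromFAMD(0.7, 0.9e-3, axis = c(1, 2, 0.5))
  g <- bVectors(makeDirections(20, seed = 3))
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  s1 <- tensorSignal(D, 1500, g, 100)
  s2 <- tensorSignal(R %*% D %*% t(R), 1500, R %*% g, 100)
  expect_lt(max(abs(s1 - s2)), 1e-8)
  # isotropic tensor: identical signal whatever the direction
  sIso <- tensorSignal(diag(3) * 0.7e-3, 1500, g, 100)
  expect_lt(diff(range(sIso)), 1e-12)
})

test_that("direction-average attenuation is minimized by isotropy (Jensen)", {
  g <- bVectors(makeDirections(48, seed = 5))
  md <- 0.7e-3; b <- 1500
  means <- vapply(c(0, 0.4, 0.8), function(fa)
    mean(tensorSignal(tensorFromFAMD(fa, md, axis = c(1, 0.3, 0.2)),
                      b, g, 100)), numeric(1))
  expect_lt(means[1], means[2])
  expect_lt(means[2], means[3])
})

test_that("noise-free phantom signal equals the closed form voxelwise", {
  spec <- presetThalamus(seed = 2, noiseSigma = 0)
  built <- buildPhantom(spec)
  sig <- imageData(built$dwi)
  lab <- imageData(built$labels)
  gt <- built$dwi@gradients
  # pick one voxel in each of two regions and check every volume
  for (k in c(1L, 4L)) {
    reg <- spec@regions[[which(vapply(spec@regions, function(r)
      r$label == k, logical(1)))[1]]]
    vox <- which(lab == k, arr.ind = TRUE)[1, ]
    want <- vapply(seq_len(nVolumes(gt)), function(i)
      tensorSignal(reg$tensor, bValues(gt)[i],
                   if (bValues(gt)[i] > 0) bVectors(gt)[, i] else c(1, 0, 0),
                   reg$S0), numeric(1))
    got <- sig[vox[1], vox[2], vox[3], ]
    expect_lt(max(abs(got - want)), 1e-10, label = paste("label", k))
  }
  # background voxels carry zero signal when noise-free
  expect_true(all(sig[1, 1, 1, ] == 0))
  expect_true(all(sig >= 0))
})

test_that("phantom builds are bit-identical for fixed seeds", {
  spec <- presetThalamus(seed = 5, noiseSigma = 2)
  a <- buildPhantom(spec)
  b <- buildPhantom(spec)
  expect_identical(imageData(a$dwi), imageData(b$dwi))
  expect_identical(imageData(a$labels), imageData(b$labels))
})

test_that("the Rayleigh noise floor has mean sigma * sqrt(pi/2)", {
  sigma <- 3
  set.seed(99)
  noise <- addRicianNoise(rep(0, 1e5), sigma)
  expect_true(all(noise >= 0))
  expect_equal(mean(noise), sigma * sqrt(pi / 2), tolerance = 0.02)
})

test_that("preset phantom has the stated anatomy and builds quickly", {
  t0 <- Sys.time()
  spec <- presetThalamus(seed = 1, noiseSigma = 0)
  built <- buildPhantom(spec)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 10)
  expect_identical(dim(imageData(built$labels)), c(48L, 48L, 48L))
  expect_equal(built$dwi@affine, diag(c(1.25, 1.25, 1.25, 1)))
  nm <- labelNames(built$labels)
  expect_true(all(c("CSF", "MD", "CM") %in% nm))
  # region-mean ordering: CSF-like < isotropic-gray-like < anisotropic
  ci <- computeContrast(built$dwi, "mean")
  st <- regionStats(ci, built$labels)
  m <- stats::setNames(st$mean, st$name)
  expect_lt(m["CSF"], m["MD"])
  expect_lt(m["MD"], m["VL_bright"])
  expect_lt(m["MD"], m["IC"])
  # numeric-quadrature oracle over the actual direction set
  g <- bVectors(built$dwi@gradients)[, bValues(built$dwi) > 0]
  csfReg <- spec@regions[[1]]
  expect_equal(unname(m["CSF"]),
               mean(tensorSignal(csfReg$tensor, 1500, g, csfReg$S0)),
               tolerance = 1e-10)
})

test_that("zebra laminae are detectable above the noise at sigma = 2% S0", {
  built <- buildPhantom(presetThalamus(seed = 11, noiseSigma = 2))
  ci <- computeContrast(built$dwi, "mean")
  st <- regionStats(ci, built$labels)
  bright <- st[st$name == "VL_bright", ]
  dark <- st[st$name == "VL_dark", ]
  contrast <- abs(bright$mean - dark$mean)
  withinSD <- max(bright$sd, dark$sd)
  expect_gt(contrast, 3 * withinSD)
})

test_that("isotropic contrast is independent of the direction scheme", {
  # two different uniform 48-direction schemes on an all-isotropic phantom
  spec <- presetThalamus(seed = 21, noiseSigma = 0)
  iso <- lapply(spec@regions, function(r) {
    r$tensor <- diag(3) * sum(diag(r$tensor)) / 3
    r
  })
  specA <- phantomSpec(spec@gridShape, spec@voxelSize, iso,
                       spec@acquisition, 0, 1L)
  acqB <- spec@acquisition; acqB$directionSeed <- 999L
  specB <- phantomSpec(spec@gridShape, spec@voxelSize, iso, acqB, 0, 1L)
  a <- computeContrast(buildPhantom(specA)$dwi, "mean")
  b <- computeContrast(buildPhantom(specB)$dwi, "mean")
  expect_lt(max(abs(imageData(a) - imageData(b))), 1e-10)
})

test_that("phantom specs round-trip through YAML", {
  d <- withr::local_tempdir()
  p <- file.path(d, "spec.yaml")
  yaml::write_yaml(list(
    gridShape = c(12L, 12L, 12L), voxelSize = 2,
    regions = list(list(
      label = 1L, name = "blob",
      geometry = list(type = "ellipsoid", center = c(5, 5, 5),
                      semiaxes = c(3, 3, 3)),
      tensor = list(fa = 0.5, md = 0.8e-3, axis = c(1, 0, 0)),
      S0 = 50)),
    acquisition = list(nDirections = 6L, bval = 1000, nB0 = 1L,
                       directionSeed = 3L),
    noiseSigma = 0.5, noiseSeed = 4L), p)
  spec <- readPhantomSpec(p)
  expect_s4_class(spec, "PhantomSpec")
  expect_equal(tensorFA(spec@regions[[1]]$tensor), 0.5, tolerance = 1e-8)
  built <- buildPhantom(spec)
  expect_equal(nVolumes(built$dwi), 7)
})
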