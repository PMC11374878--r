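mkMap <- function(data, affine) {
  new("ScalarMap", data = data, affine = affine, metric = "test",
      units = "1")
}

test_that("labeling picks the nearest below-threshold centroid", {
  c1 <- cbind(seq(0, 20, length.out = 21), 0, 0)
  c2 <- cbind(seq(0, 20, length.out = 21), 8, 0)
  atlas <- bundleAtlas(c("t1", "t2"), list(c1, c2), thresholds = 5)
  mk <- function(...) new("Tractogram", streamlines = list(...),
                          seedVoxel = rep(NA_integer_, length(list(...))))
  sEq <- c1                                   # equals a centroid
  sMid <- cbind(seq(0, 20, length.out = 21), 3, 0)  # below both, nearer t1
  sFar <- cbind(seq(0, 20, length.out = 21), 40, 0) # beyond every threshold
  lab <- labelTractogram(mk(sEq, sMid, sFar), atlas)
  expect_equal(streamlineLabels(lab), c("t1", "t1", "UNLABELED"))
  # a streamline nearer t2
  lab2 <- labelTractogram(mk(cbind(seq(0, 20, length.out = 21), 6, 0)),
                          atlas)
  expect_equal(streamlineLabels(lab2), "t2")
  expect_error(labelTractogram(mk(sEq), bundleAtlas(character(0), list())),
               "empty")
})

test_that("labeling equals brute-force enumeration on random streamlines", {
  set.seed(7)
  atlas <- makeToyAtlas()
  sl <- lapply(1:200, function(i) {
    base <- atlasCentroids(atlas)[[sample.int(3, 1)]]
    jitter <- matrix(rnorm(3, sd = runif(1, 0, 8)), nrow(base), 3,
                     byrow = TRUE)
    base + jitter + matrix(rnorm(length(base), sd = 0.5), nrow(base), 3)
  })
  tg <- new("Tractogram", streamlines = sl,
            seedVoxel = rep(NA_integer_, length(sl)))
  lab <- labelTractogram(tg, atlas)

  # independent oracle: direct per-pair distance enumeration
  oracle <- vapply(sl, function(s) {
    dists <- vapply(seq_along(atlasLabels(atlas)), function(ci)
      streamlineDistance(s, atlasCentroids(atlas)[[ci]]), numeric(1))
    ok <- dists <= atlasThresholds(atlas)
    if (!any(ok)) "UNLABELED" else atlasLabels(atlas)[which.min(
      ifelse(ok, dists, Inf))]
  }, character(1))
  expect_identical(streamlineLabels(lab), oracle)

  # labels partition the tractogram
  tab <- table(factor(streamlineLabels(lab),
                      levels = c(atlasLabels(atlas), "UNLABELED")))
  expect_equal(sum(tab), length(sl))

  # shrinking a threshold never increases that tract's count
  atlas2 <- atlas
  atlas2@thresholds <- atlas@thresholds / 2
  lab2 <- labelTractogram(tg, atlas2)
  for (tr in atlasLabels(atlas))
    expect_lte(sum(streamlineLabels(lab2) == tr),
               sum(streamlineLabels(lab) == tr))
})

test_that("the density mask counts distinct streamlines at the threshold", {
  aff <- tractometry:::defaultAffine(1)
  dims <- c(12L, 5L, 5L)
  s <- cbind(seq(0, 9, length.out = 50), 2, 2)   # crosses 10 voxels
  five <- rep(list(s), 5)
  mask <- densityMask(five, dims, aff, minFibers = 5L)
  expect_equal(sum(mask), 10L)
  expect_true(all(which(mask, arr.ind = TRUE)[, 2] == 3))
  four <- rep(list(s), 4)
  expect_equal(sum(densityMask(four, dims, aff, minFibers = 5L)), 0L)
  # adding a streamline never shrinks the mask
  set.seed(11)
  bundle <- lapply(1:8, function(i) randomStreamline(8, 4) + 4)
  m1 <- densityMask(bundle, dims, aff, minFibers = 2L)
  m2 <- densityMask(c(bundle, list(randomStreamline(8, 4) + 4)), dims, aff,
                    minFibers = 2L)
  expect_true(all(m2[m1]))
})

test_that("volumes come out in cm^3 with the right arithmetic", {
  m <- array(TRUE, c(8, 8, 8))
  expect_equal(bundleVolume(m, 1.25), 512 * 1.953125 / 1000)  # 1 cm^3
  expect_equal(bundleVolume(array(FALSE, c(4, 4, 4)), 1.25), 0)
  expect_equal(bundleVolume(array(TRUE, c(64, 64, 64)), 1), 262.144)
  expect_equal(normalizeVolume(25, 1250), 2.0)
  expect_equal(normalizeVolume(23.0, 1117), 2.059, tolerance = 1e-3)
  expect_equal(normalizeVolume(5, 5), 100)
  expect_error(normalizeVolume(1, 0), "positive")
})

test_that("along-tract means interpolate exactly on analytic fields", {
  aff <- tractometry:::defaultAffine(1)
  dims <- c(12L, 6L, 6L)
  grid <- array(0, dims)
  # constant field
  cmap <- mkMap(grid + 3.7, aff)
  s <- cbind(seq(0.5, 9.5, length.out = 30), 2.2, 3.1)
  expect_equal(as.numeric(tractMetricMean(list(s), cmap)), 3.7,
               tolerance = 1e-12)
  # field linear in x: mean over straight streamline = value at midpoint
  lin <- grid
  for (i in seq_len(dims[1])) lin[i, , ] <- (i - 1)   # world x (1 mm vox)
  lmap <- mkMap(lin, aff)
  s2 <- cbind(seq(0, 10, length.out = 11), 2, 2)
  expect_equal(as.numeric(tractMetricMean(list(s2), lmap)), 5,
               tolerance = 1e-9)
  # reversal invariance
  expect_equal(as.numeric(tractMetricMean(list(s2[11:1, ]), lmap)),
               as.numeric(tractMetricMean(list(s2), lmap)),
               tolerance = 1e-12)
  # brute-force oracle on a tiny grid
  set.seed(3)
  vol <- array(runif(12 * 6 * 6), dims)
  rmap <- mkMap(vol, aff)
  p <- resampleStreamline(s, 0.1)
  oracle <- mean(vapply(seq_len(nrow(p)), function(i) {
    v <- p[i, ] + 1           # 1-based voxel coords under unit affine
    x0 <- floor(v); f <- v - x0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
      acc <- acc + w * vol[x0[1] + dx, x0[2] + dy, x0[3] + dz]
    }
    acc
  }, numeric(1)))
  expect_equal(as.numeric(tractMetricMean(list(s), rmap)), oracle,
               tolerance = 1e-10)
  # bundles outside the map support fail loudly
  far <- cbind(seq(40, 50, length.out = 10), 2, 2)
  expect_error(tractMetricMean(list(far), rmap), "outside map support")
})

test_that("subject measures pull volumes and means together", {
  gt <- smallGtab()
  b <- tubeBundle("tube",
                  lineCurve(c(0, 3.75, 3.75), c(23.75, 3.75, 3.75)),
                  radius = 2.2)
  ph <- buildPhantom(phantomSpec(gridShape = c(20L, 8L, 8L),
                                 bundles = list(b), noiseSigma = 0,
                                 seed = 1L), gt, streamsPerBundle = 60L)
  atlas <- bundleAtlas(c("tube", "ghost"),
                       list(lineCurve(c(0, 3.75, 3.75),
                                      c(23.75, 3.75, 3.75)),
                            lineCurve(c(0, 30, 30), c(10, 30, 30))),
                       thresholds = 6)
  # label the phantom's true dense bundle against the atlas
  lab <- labelTractogram(ph$bundles$tube, atlas)
  expect_true(all(streamlineLabels(lab) == "tube"))
  sc <- tensorScalars(fitDti(ph$dwi, gt, ph$wmMask, ph$affine))
  maps <- list(fa = sc$fa, md = sc$md)
  meas <- measureSubject(lab, maps, ph$brainMask, ph$wmMask, ph$affine,
                         atlas, subject = "s1", sex = "M")
  expect_equal(nrow(meas), 2L)
  tube <- meas[meas$tract == "tube", ]
  ghost <- meas[meas$tract == "ghost", ]
  # tube volume within 15% of the analytic cylinder volume
  cylVol <- pi * 2.2^2 * 23.75 / 1000
  expect_lt(abs(tube$volume_cm3 - cylVol) / cylVol, 0.15)
  # normalization identity
  expect_equal(tube$volume_cm3, tube$vol_pct_tbv * tube$tbv_cm3 / 100,
               tolerance = 1e-12)
  expect_equal(tube$volume_cm3, tube$vol_pct_wmv * tube$wmv_cm3 / 100,
               tolerance = 1e-12)
  # TBV from the brain mask: whole grid
  expect_equal(tube$tbv_cm3, prod(dim(ph$brainMask)) * 1.25^3 / 1000)
  # empty tract: zero volume, missing metrics
  expect_equal(ghost$volume_cm3, 0)
  expect_true(is.na(ghost$fa))
  # tube FA mean tracks the single-fiber FA (0.799) but is diluted by rim
  # streamlines interpolating across the tube boundary, where FA drops to 0
  # outside the fitted mask
  expect_gt(tube$fa, 0.6)
  expect_lt(tube$fa, 0.81)
})

test_that("rigid motion of bundle and grid together preserves volume", {
  aff <- tractometry:::defaultAffine(1.25)
  dims <- c(16L, 16L, 16L)
  set.seed(21)
  bundle <- lapply(1:6, function(i)
    cbind(seq(2, 16, length.out = 40), 8 + rnorm(1, 0, 0.5),
          8 + rnorm(1, 0, 0.5)))
  v1 <- bundleVolume(densityMask(bundle, dims, aff, minFibers = 2L), 1.25)
  R <- tractometry:::withSeed(5, tractometry:::randomRotation())
  M <- rbind(cbind(R, c(2, -1, 3)), c(0, 0, 0, 1))
  bundle2 <- lapply(bundle, function(s)
    t(M %*% rbind(t(s), 1))[, 1:3])
  aff2 <- M %*% aff
  v2 <- bundleVolume(densityMask(bundle2, dims, aff2, minFibers = 2L), 1.25)
  # tolerance: one voxel layer over the bundle surface
  expect_lt(abs(v1 - v2) / v1, 0.35)
})
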