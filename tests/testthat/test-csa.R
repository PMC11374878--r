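test_that("an isotropic voxel yields a uniform ODF", {
  gt <- smallGtab()
  odf <- fitCsaOdf(voxelDwi(simulateSignalTensor(diag(rep(1e-3, 3)), gt,
                                                 100)), gt, shOrder = 8L)
  v <- sampleOdf(shCoefficients(odf)[1, 1, 1, ], sphereDirections(100))
  expect_true(all(abs(v - 1 / 100) < 1e-3))
  expect_equal(sum(v), 1, tolerance = 1e-12)
})

test_that("a single-fiber ODF peaks along the true axis within 5 degrees", {
  gt <- smallGtab()
  D <- diag(c(1.7e-3, 0.3e-3, 0.3e-3))
  odf <- fitCsaOdf(voxelDwi(simulateSignalTensor(D, gt, 100)), gt,
                   shOrder = 8L)
  pk <- odfPeaks(shCoefficients(odf)[1, 1, 1, ])
  expect_lt(axialAngleDeg(pk[1, , drop = FALSE], c(1, 0, 0)), 5)
})

test_that("a 90-degree crossing yields two maxima near the true axes", {
  gt <- smallGtab()
  s <- (simulateSignalTensor(diag(c(1.7e-3, 0.3e-3, 0.3e-3)), gt, 100) +
        simulateSignalTensor(diag(c(0.3e-3, 1.7e-3, 0.3e-3)), gt, 100)) / 2
  odf <- fitCsaOdf(voxelDwi(s), gt, shOrder = 8L)
  pk <- odfPeaks(shCoefficients(odf)[1, 1, 1, ], relThreshold = 0.7)
  expect_gte(nrow(pk), 2L)
  angX <- axialAngleDeg(pk[1:2, , drop = FALSE], c(1, 0, 0))
  angY <- axialAngleDeg(pk[1:2, , drop = FALSE], c(0, 1, 0))
  expect_lt(min(pmax(angX[1], angY[2]), pmax(angY[1], angX[2])), 10)
})

test_that("the ODF rotates with a joint rotation of tensor and gradients", {
  gt <- smallGtab()
  D0 <- diag(c(1.7e-3, 0.3e-3, 0.3e-3))
  set.seed(42)
  for (rep in 1:3) {
    R <- tractometry:::randomRotation()
    D <- R %*% D0 %*% t(R)
    odf <- fitCsaOdf(voxelDwi(simulateSignalTensor(D, gt, 100)), gt,
                     shOrder = 8L)
    pk <- odfPeaks(shCoefficients(odf)[1, 1, 1, ])
    expect_lt(axialAngleDeg(pk[1, , drop = FALSE], R[, 1]), 5)
  }
})

test_that("sh order handling: odd orders rejected, coefficient counts right", {
  gt <- smallGtab()
  dwi <- voxelDwi(simulateSignalTensor(diag(rep(1e-3, 3)), gt, 1))
  expect_error(fitCsaOdf(dwi, gt, shOrder = 7), "even")
  for (L in c(4L, 6L, 8L)) {
    odf <- fitCsaOdf(dwi, gt, shOrder = L)
    expect_equal(dim(shCoefficients(odf))[4], (L + 1) * (L + 2) / 2)
  }
  # too few directions for the order
  gtSmall <- makeGradientTable(20, c(1000, 2000), 2L, seed = 0L)
  expect_error(fitCsaOdf(voxelDwi(rep(1, 42)), gtSmall, shOrder = 8),
               "need >=")
})

test_that("GFA matches its definition on reference cases", {
  # one-hot ODF on N directions: population-sd / rms = sqrt((N-1)/N)
  oneHot <- c(1, rep(0, 99))
  gfaOracle <- function(v) {
    sqrt(mean((v - mean(v))^2)) / sqrt(mean(v^2))
  }
  expect_equal(gfaOracle(oneHot), sqrt(99 / 100), tolerance = 1e-12)
  expect_equal(gfaOracle(oneHot), 0.99499, tolerance = 1e-4)
  # uniform ODF has GFA 0; anisotropic voxels exceed isotropic ones
  gt <- smallGtab()
  iso <- fitCsaOdf(voxelDwi(simulateSignalTensor(diag(rep(1e-3, 3)), gt,
                                                 100)), gt, shOrder = 8L)
  fib <- fitCsaOdf(voxelDwi(simulateSignalTensor(
    diag(c(1.7e-3, 0.3e-3, 0.3e-3)), gt, 100)), gt, shOrder = 8L)
  gIso <- mapData(gfa(iso))[1]
  gFib <- mapData(gfa(fib))[1]
  expect_lt(gIso, 1e-3)
  expect_gt(gFib, gIso)
  expect_true(gFib >= 0 && gFib <= 1)
})

test_that("the SH basis is orthonormal on a dense sphere", {
  dirs <- sphereDirections(4096)
  B <- tractometry:::shBasis(dirs, 8L)
  G <- crossprod(B) * 4 * pi / nrow(dirs)
  expect_lt(max(abs(G - diag(ncol(B)))), 0.02)
})
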