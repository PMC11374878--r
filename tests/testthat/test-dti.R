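test_that("a noiseless tensor fit inverts the generator exactly", {
  gt <- smallGtab()
  D <- diag(c(1.7e-3, 0.3e-3, 0.3e-3))
  fit <- fitDti(voxelDwi(simulateSignalTensor(D, gt, 100)), gt)
  expect_equal(fit@evals[1, 1, 1, ], c(1.7e-3, 0.3e-3, 0.3e-3),
               tolerance = 1e-10)
  expect_equal(fit@s0[1, 1, 1], 100, tolerance = 1e-8)
  # rotated tensor: principal eigenvector recovered
  axis <- c(1, 1, 0) / sqrt(2)
  D2 <- tractometry:::axialTensor(c(1.7e-3, 0.3e-3, 0.3e-3), axis)
  fit2 <- fitDti(voxelDwi(simulateSignalTensor(D2, gt, 100)), gt)
  expect_lt(axialAngleDeg(matrix(fit2@evec1[1, 1, 1, ], 1), axis), 0.01)
})

test_that("only the b0 and b=1000 volumes enter the tensor fit", {
  gt <- smallGtab()
  D <- diag(c(1.2e-3, 0.5e-3, 0.4e-3))
  s <- simulateSignalTensor(D, gt, 80)
  sCorrupt <- s
  sCorrupt[shellIds(gt) %in% c(2L, 3L)] <- 1e3 * runif(sum(shellIds(gt) %in%
                                                             c(2L, 3L)))
  f1 <- fitDti(voxelDwi(s), gt)
  f2 <- fitDti(voxelDwi(sCorrupt), gt)
  expect_identical(f1@evals, f2@evals)
  expect_identical(f1@tensor, f2@tensor)
})

test_that("a gradient table without the required shell is rejected", {
  gt <- makeGradientTable(10, c(2000, 3000), 2L, seed = 0L)
  expect_error(fitDti(voxelDwi(rep(1, length(bValues(gt)))), gt),
               "no b = 1000 shell")
})

test_that("tensor scalars match their closed forms", {
  gt <- smallGtab()
  mkFit <- function(evals) {
    D <- diag(evals)
    fitDti(voxelDwi(simulateSignalTensor(D, gt, 1)), gt)
  }
  # prolate oracle, hand-evaluated from the eigenvalue formulas
  sc <- tensorScalars(mkFit(c(1.7e-3, 0.3e-3, 0.3e-3)))
  expect_equal(mapData(sc$fa)[1], 0.7990222, tolerance = 1e-6)
  expect_equal(mapData(sc$md)[1], 7.666667e-4, tolerance = 1e-6)
  expect_equal(mapData(sc$ad)[1], 1.7e-3, tolerance = 1e-9)
  expect_equal(mapData(sc$rd)[1], 0.3e-3, tolerance = 1e-9)
  # isotropy
  sc <- tensorScalars(mkFit(rep(1e-3, 3)))
  expect_equal(mapData(sc$fa)[1], 0, tolerance = 1e-8)
  expect_equal(mapData(sc$md)[1], 1e-3, tolerance = 1e-10)
})

test_that("the MD = (AD + 2 RD)/3 identity holds voxelwise", {
  ph <- tubePhantom()
  sc <- tensorScalars(fitDti(ph$dwi, smallGtab(), ph$wmMask, ph$affine))
  expect_equal(mapData(sc$md),
               (mapData(sc$ad) + 2 * mapData(sc$rd)) / 3,
               tolerance = 1e-12)
  # FA stays in [0, 1]
  expect_true(all(mapData(sc$fa) >= 0 & mapData(sc$fa) <= 1))
})
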