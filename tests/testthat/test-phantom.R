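test_that("noiseless tube voxels carry the exact closed-form signal", {
  ph <- tubePhantom()
  gt <- smallGtab()
  truth <- ph$truth
  vox <- which(truth@label == 1L, arr.ind = TRUE)
  expect_gt(nrow(vox), 50)
  pick <- vox[c(1, nrow(vox) %/% 2, nrow(vox)), , drop = FALSE]
  for (r in seq_len(nrow(pick))) {
    i <- pick[r, ]
    axis <- truth@orientation[i[1], i[2], i[3], ]
    D <- tractometry:::axialTensor(c(1.7e-3, 0.3e-3, 0.3e-3), axis)
    expected <- simulateSignalTensor(D, gt, 100)
    expect_equal(ph$dwi[i[1], i[2], i[3], ], expected, tolerance = 1e-12)
  }
  # background is isotropic free-water-like signal
  bg <- which(truth@label == 0L, arr.ind = TRUE)[1, ]
  expected <- simulateSignalTensor(diag(rep(3.0e-3, 3)), gt, 100)
  expect_equal(ph$dwi[bg[1], bg[2], bg[3], ], expected, tolerance = 1e-12)
})

test_that("masks are consistent and the phantom is reproducible", {
  ph <- tubePhantom()
  expect_true(all(ph$brainMask[ph$wmMask]))   # WM subset of brain
  b <- tubeBundle("tube",
                  lineCurve(c(0, 4.375, 4.375), c(23.75, 4.375, 4.375)),
                  radius = 2.2)
  spec <- phantomSpec(gridShape = c(20L, 8L, 8L), bundles = list(b),
                      noiseSigma = 3, seed = 7L)
  ph1 <- buildPhantom(spec, smallGtab())
  ph2 <- buildPhantom(spec, smallGtab())
  expect_identical(ph1$dwi, ph2$dwi)
})

test_that("the b0 SNR estimate matches s0/sigma under Rician noise", {
  gt <- fixture("snrGtab", function()
    makeGradientTable(6, 1000, 6L, seed = 0L))
  b <- tubeBundle("tube", lineCurve(c(0, 4.375, 4.375),
                                    c(11.25, 4.375, 4.375)), radius = 2.2)
  spec <- phantomSpec(gridShape = c(10L, 8L, 8L), bundles = list(b),
                      s0 = 100, noiseSigma = 100 / 20,
                      noiseModel = "rician", seed = 11L)
  ph <- buildPhantom(spec, gt)
  b0 <- ph$dwi[, , , shellIds(gt) == 0L]
  vox <- which(ph$wmMask, arr.ind = TRUE)
  snr <- apply(vox, 1, function(i) {
    x <- b0[i[1], i[2], i[3], ]
    mean(x) / stats::sd(x)
  })
  expect_lt(abs(median(snr) - 20) / 20, 0.2)
})

test_that("overlapping tubes error unless crossing mode is enabled", {
  mk <- function(crossing) {
    b1 <- tubeBundle("x", lineCurve(c(0, 6.25, 6.25), c(12.5, 6.25, 6.25)),
                     radius = 2)
    b2 <- tubeBundle("y", lineCurve(c(6.25, 0, 6.25), c(6.25, 12.5, 6.25)),
                     radius = 2)
    buildPhantom(phantomSpec(gridShape = c(11L, 11L, 11L),
                             bundles = list(b1, b2), noiseSigma = 0,
                             crossingMode = crossing), smallGtab())
  }
  expect_error(mk(FALSE), "crossingMode")
  ph <- mk(TRUE)
  cross <- ph$truth@label == -1L
  expect_gt(sum(cross), 0)
  # crossing voxels carry two roughly perpendicular orientations
  i <- which(cross, arr.ind = TRUE)[1, ]
  o1 <- ph$truth@orientation[i[1], i[2], i[3], ]
  o2 <- ph$truth@orientation2[i[1], i[2], i[3], ]
  expect_gt(acos(abs(sum(o1 * o2))) * 180 / pi, 80)
})

test_that("bundles that leave the grid are rejected", {
  b <- tubeBundle("far", lineCurve(c(0, 0, 0), c(100, 0, 0)))
  expect_error(buildPhantom(phantomSpec(gridShape = c(10L, 10L, 10L),
                                        bundles = list(b)), smallGtab()),
               "fit inside")
})
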