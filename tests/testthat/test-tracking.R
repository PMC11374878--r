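test_that("propagation domain dilation behaves morphologically", {
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  expect_identical(makePropagationDomain(m, 0L), m)      # identity
  d1 <- makePropagationDomain(m, 1L)
  expect_equal(sum(d1), 7L)                              # 6-neighborhood
  expect_true(all(d1[m]))                                # superset
  ph <- tubePhantom()
  dom <- makePropagationDomain(ph$wmMask, 1L)
  expect_true(all(dom[ph$wmMask]))
  expect_error(makePropagationDomain(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("tracking parameter invariants are enforced", {
  expect_error(trackingParams(stepMm = 2), "stepMm")
  expect_error(trackingParams(apertureDeg = 95), "apertureDeg")
  expect_error(trackingParams(temperature = 0), "temperature")
})

test_that("the tracker attempts 8 seeds per domain voxel and is seeded", {
  ph <- tubePhantom()
  odf <- tubeOdf()
  dom <- makePropagationDomain(ph$wmMask, 1L)
  tg1 <- track(odf, dom, trackingParams(seed = 3L))
  expect_equal(tg1@nSeedsAttempted, 8L * sum(dom))
  tg2 <- track(odf, dom, trackingParams(seed = 3L))
  expect_identical(streamlines(tg1), streamlines(tg2))   # bit-identical
  tg3 <- track(odf, dom, trackingParams(seed = 4L))
  expect_false(identical(streamlines(tg1), streamlines(tg3)))
})

test_that("retained lengths and step sizes respect the parameters", {
  ph <- tubePhantom()
  tg <- track(tubeOdf(), makePropagationDomain(ph$wmMask, 1L),
              trackingParams(seed = 3L))
  len <- vapply(streamlines(tg), streamlineLength, numeric(1))
  expect_true(all(len >= 1.25 & len <= 300))
  steps <- unlist(lapply(streamlines(tg)[1:20], function(s)
    sqrt(rowSums(diff(s)^2))))
  expect_true(all(abs(steps - 0.3) < 0.3 * 0.2))
})

test_that("streamlines follow a straight fiber and span the tube", {
  ph <- tubePhantom()
  tg <- track(tubeOdf(), makePropagationDomain(ph$wmMask, 1L),
              trackingParams(seed = 3L))
  len <- vapply(streamlines(tg), streamlineLength, numeric(1))
  segs <- do.call(rbind, lapply(streamlines(tg)[len > 5], function(s)
    diff(s) / sqrt(rowSums(diff(s)^2))))
  expect_lt(mean(axialAngleDeg(segs, c(1, 0, 0))), 15)   # < aperture / 2
  ep <- t(vapply(streamlines(tg), function(s) range(s[, 1]), numeric(2)))
  span <- mean(ep[, 1] <= 2.5 & ep[, 2] >= 23.75 - 2.5)
  expect_gt(span, 0.5)
})

test_that("both bundles of a crossing receive crossing streamlines", {
  gt <- smallGtab()
  b1 <- tubeBundle("x", lineCurve(c(0, 8.125, 8.125), c(16.25, 8.125, 8.125)),
                   radius = 2)
  b2 <- tubeBundle("y", lineCurve(c(8.125, 0, 8.125), c(8.125, 16.25, 8.125)),
                   radius = 2)
  ph <- buildPhantom(phantomSpec(gridShape = c(14L, 14L, 14L),
                                 bundles = list(b1, b2), noiseSigma = 0,
                                 crossingMode = TRUE), gt)
  odf <- fitCsaOdf(ph$dwi, gt, ph$wmMask, shOrder = 8L, affine = ph$affine)
  tg <- track(odf, makePropagationDomain(ph$wmMask, 1L),
              trackingParams(seed = 5L))
  # streamlines traversing the crossing region along each axis
  mid <- 8.125
  traversed <- vapply(streamlines(tg), function(s) {
    nearCross <- any(abs(s[, 1] - mid) < 2.5 & abs(s[, 2] - mid) < 2.5)
    if (!nearCross) return(0L)
    d <- abs(s[nrow(s), ] - s[1, ])
    if (d[1] > 2 * d[2]) 1L else if (d[2] > 2 * d[1]) 2L else 0L
  }, integer(1))
  expect_gt(sum(traversed == 1L), 0)
  expect_gt(sum(traversed == 2L), 0)
})

test_that("an empty domain warns and returns an empty tractogram", {
  odf <- tubeOdf()
  dom <- array(FALSE, dim(shCoefficients(odf))[1:3])
  expect_warning(tg <- track(odf, dom), "empty")
  expect_equal(nStreamlines(tg), 0L)
})
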