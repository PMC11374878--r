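test_that("the full protocol scheme has the right shell structure", {
  gt <- fullGtab()
  expect_length(bValues(gt), 276L)        # 3 x 90 + 6
  expect_equal(sum(shellIds(gt) == 0L), 6L)
  expect_equal(unname(shellBValues(gt)), c(1000, 2000, 3000))
  expect_equal(as.vector(table(shellIds(gt)[shellIds(gt) != 0L])),
               rep(90L, 3L))
  # non-b0 directions are unit vectors
  dw <- shellIds(gt) != 0L
  expect_true(all(abs(sqrt(colSums(bVectors(gt)[, dw]^2)) - 1) < 1e-6))
})

test_that("a minimal scheme has 7 entries with 6 unit vectors", {
  gt <- makeGradientTable(6, 1000, 1L, seed = 0L)
  expect_length(bValues(gt), 7L)
  dw <- shellIds(gt) != 0L
  expect_equal(sum(dw), 6L)
  expect_true(all(abs(sqrt(colSums(bVectors(gt)[, dw]^2)) - 1) < 1e-6))
})

test_that("per-shell directions are spread: minimal pairwise angle > 10 deg", {
  gt <- fullGtab()
  for (s in 1:3) {
    g <- t(bVectors(gt)[, shellIds(gt) == s])
    # brute-force pairwise axial angle scan
    C <- abs(g %*% t(g))
    minAngle <- min(acos(pmin(1, C[upper.tri(C)]))) * 180 / pi
    expect_gt(minAngle, 10)
  }
})

test_that("the scheme is deterministic for a fixed seed and varies by seed", {
  a <- makeGradientTable(30, c(1000, 2000), 2L, seed = 5L)
  b <- makeGradientTable(30, c(1000, 2000), 2L, seed = 5L)
  c <- makeGradientTable(30, c(1000, 2000), 2L, seed = 6L)
  expect_identical(bVectors(a), bVectors(b))
  expect_false(identical(bVectors(a), bVectors(c)))
})

test_that("invalid schemes are rejected", {
  expect_error(makeGradientTable(5, 1000, 1L), "dirsPerShell")
  expect_error(makeGradientTable(6, c(1000, -5), 1L), "positive")
  expect_error(makeGradientTable(6, c(1000, 1000), 1L), "distinct")
  expect_error(makeGradientTable(6, 1000, 0L), "b = 0")
})

test_that("shell detection clusters jittered b-values", {
  bv <- c(0, 5, 995, 1005, 2990, 3010)
  ids <- tractometry:::detectShells(bv)
  expect_equal(ids[1:2], c(0L, 0L))
  expect_equal(ids[3], ids[4])
  expect_equal(ids[5], ids[6])
  expect_false(ids[3] == ids[5])
})
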