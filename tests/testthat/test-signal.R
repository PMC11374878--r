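test_that("tensor signal matches the closed form", {
  gt <- gradientTable(c(0, 1000, 1000), cbind(c(0, 0, 0), c(1, 0, 0),
                                              c(0, 1, 0)))
  D <- diag(c(1.7e-3, 0.3e-3, 0.3e-3))
  s <- simulateSignalTensor(D, gt, 1)
  expect_equal(s[1], 1)                      # b = 0 entry returns s0
  expect_equal(s[2], exp(-1.7), tolerance = 1e-12)
  expect_equal(s[3], exp(-0.3), tolerance = 1e-12)
})

test_that("isotropic tensor decay is direction independent", {
  gt <- smallGtab()
  s <- simulateSignalTensor(diag(rep(1e-3, 3)), gt, 2)
  sh1 <- s[shellIds(gt) == 1L]
  expect_true(all(abs(sh1 - 2 * exp(-1)) < 1e-12))
  expect_true(all(s[shellIds(gt) == 0L] == 2))
})

test_that("non-PSD tensors are rejected", {
  gt <- smallGtab()
  expect_error(simulateSignalTensor(diag(c(1e-3, 1e-3, -1e-4)), gt),
               "semi-definite")
})

test_that("NODDI signal limits behave like single compartments", {
  gt <- smallGtab()
  # pure free water: mono-exponential isotropic decay on every shell
  s <- simulateSignalNoddi(0.5, 1, 4, c(0, 0, 1), gt)
  for (sh in 1:3) {
    b <- unname(shellBValues(gt)[sh])
    expect_true(all(abs(s[shellIds(gt) == sh] - exp(-b * 3.0e-3)) < 1e-12))
  }
  # b0 entries return s0 exactly for arbitrary parameters
  for (p in list(c(0.1, 0.2, 0.5), c(0.9, 0.05, 16))) {
    s <- simulateSignalNoddi(p[1], p[2], p[3], c(1, 1, 1) / sqrt(3), gt,
                             s0 = 7)
    expect_true(all(s[shellIds(gt) == 0L] == 7))
  }
})

test_that("a high-concentration stick barely attenuates across the fiber", {
  # kappa = 64: near-parallel sticks; perpendicular signal stays near s0
  gt <- gradientTable(c(0, 1000), cbind(c(0, 0, 0), c(1, 0, 0)))
  s <- simulateSignalNoddi(1, 0, 64, c(0, 0, 1), gt)
  expect_gt(s[2], 0.98)
})

test_that("noddi fractions outside [0,1] are rejected", {
  gt <- smallGtab()
  expect_error(simulateSignalNoddi(1.2, 0, 4, c(0, 0, 1), gt), "fraction")
  expect_error(simulateSignalNoddi(0.5, -0.1, 4, c(0, 0, 1), gt),
               "fraction")
  expect_error(simulateSignalNoddi(0.5, 0.1, 0, c(0, 0, 1), gt), "kappa")
})

test_that("ODI is a decreasing map of kappa with the right limits", {
  k <- c(0.01, 0.25, 1, 4, 64, 1e6)
  o <- odiFromKappa(k)
  expect_true(all(diff(o) < 0))
  expect_equal(odiFromKappa(1), 0.5)          # (2/pi) atan(1)
  expect_lt(o[length(o)], 1e-5)
  expect_gt(o[1], 0.99)
})

test_that("the Watson average respects its analytic second moment limits", {
  # tau1 = E[(mu.n)^2]: 1/3 for uniform (kappa -> 0), 1 for parallel
  expect_equal(tractometry:::watsonTau1(1e-6), 1 / 3, tolerance = 1e-3)
  expect_gt(tractometry:::watsonTau1(512), 0.99)
})
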