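test_that("the Bonferroni threshold is alpha over m", {
  expect_equal(bonferroniThreshold(0.05, 772), 0.05 / 772)
  expect_equal(signif(bonferroniThreshold(0.05, 772), 8), 6.4766839e-05)
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  expect_equal(bonferroniThreshold(0.01, 10), 0.001)
  expect_error(bonferroniThreshold(0.05, 0), "m must be")
  expect_error(bonferroniThreshold(1.2, 10), "alpha")
})

test_that("Cohen's d reproduces published group-summary effect sizes", {
  # corpus callosum genu, percent of TBV
  expect_equal(round(cohensD(2.06, 0.27, 490, 2.21, 0.27, 575), 2), -0.56)
  # total brain volume in cm^3
  expect_equal(round(cohensD(1290, 102, 490, 1128, 90, 575), 1), 1.7)
  # left middle cortico-cerebellar and right lenticular-frontal tracts
  expect_equal(round(cohensD(2.17, 0.46, 490, 1.97, 0.46, 575), 2), 0.43)
  expect_equal(round(cohensD(1.10, 0.42, 490, 0.90, 0.41, 575), 2), 0.48)
  expect_equal(cohensD(5, 1, 10, 5, 1, 10), 0)
  expect_error(cohensD(1, 0, 10, 1, 0, 10), "pooled")
})

test_that("Cohen's d is antisymmetric and matches raw-sample computation", {
  set.seed(4)
  x <- rnorm(40, 1, 2); y <- rnorm(55, 0.4, 1.8)
  d1 <- cohensD(mean(x), sd(x), 40, mean(y), sd(y), 55)
  d2 <- cohensD(mean(y), sd(y), 55, mean(x), sd(x), 40)
  expect_equal(d1, -d2, tolerance = 1e-12)
  # t from summary stats equals t.test on the raw samples
  tt <- t.test(x, y, var.equal = TRUE)
  sp <- sqrt(((40 - 1) * var(x) + (55 - 1) * var(y)) / (40 + 55 - 2))
  tSummary <- (mean(x) - mean(y)) / (sp * sqrt(1 / 40 + 1 / 55))
  expect_equal(unname(tt$statistic), tSummary, tolerance = 1e-10)
})

test_that("effect bins follow the |d| cutpoints with upward boundaries", {
  expect_equal(effectBin(c(-0.56, 1.7, 0, 0.3, -1.2)),
               c("medium", "large", "negligible", "small", "large"))
  expect_equal(effectBin(c(0.2, 0.5, 0.8)), c("small", "medium", "large"))
  expect_error(effectBin(NA_real_), "finite")
})

test_that("relative differences use the men-group denominator", {
  expect_equal(round(relativeDifference(1290, 1128), 1), 12.6)
  expect_equal(round(relativeDifference(2.06, 2.21), 1), -7.3)
  expect_equal(relativeDifference(3, 3), 0)
  expect_error(relativeDifference(0, 1), "zero")
})

test_that("groupCompare fills a consistent comparison row", {
  set.seed(8)
  x <- rnorm(50, 10, 2); y <- rnorm(60, 9, 2)
  row <- groupCompare(x, y, bonferroniAlpha = 0.01, measure = "demo")
  expect_equal(row$n_m, 50); expect_equal(row$n_f, 60)
  expect_equal(row$significant, row$p < 0.01)
  expect_equal(row$cohens_d,
               cohensD(mean(x), sd(x), 50, mean(y), sd(y), 60))
  expect_equal(row$effect_bin, effectBin(row$cohens_d))
  expect_true(is.finite(row$shapiro_p_m) && is.finite(row$levene_p))
  # identical samples: t = 0, p = 1, d = 0
  z <- rnorm(20)
  row0 <- groupCompare(z, z)
  expect_equal(row0$t, 0, tolerance = 1e-12)
  expect_equal(row0$p, 1, tolerance = 1e-12)
  expect_equal(row0$cohens_d, 0)
  expect_false(row0$significant)
  expect_error(groupCompare(rnorm(2), rnorm(10)), "insufficient")
})

test_that("the comparison family is tracts x 10 + 2 with the derived threshold", {
  co <- nullCohort(n = 10L, seed = 2L)
  res <- runFullComparison(co)
  expect_equal(nrow(res), 3L * 10L + 2L)
  expect_equal(attr(res, "familySize"), 32L)
  expect_equal(res$bonferroni_alpha[1], 0.05 / 32)
  expect_equal(res$measure[1:2], c("TBV", "WMV"))
  # row order of the input cohort does not matter
  perm <- co[sample.int(nrow(co)), ]
  res2 <- runFullComparison(perm)
  expect_equal(res, res2, ignore_attr = TRUE)
  # single-sex cohorts are rejected
  expect_error(runFullComparison(co[co$sex == "M", ]), "both sexes")
})

test_that("TBV and WMV group gaps in a realistic cohort are large effects", {
  co <- simulateCohort(cohortSpec(490, 575, "t1", seed = 31L))
  res <- runFullComparison(co)
  tbv <- res[res$measure == "TBV", ]
  expect_equal(tbv$effect_bin, "large")
  expect_true(tbv$significant)
  expect_lt(abs(tbv$cohens_d - 1.69), 0.25)
  expect_lt(abs(tbv$relative_difference_pct - 12.6), 2)
})

test_that("regression and ANCOVA recover exact linear structure", {
  co <- nullCohort(n = 20L, seed = 6L)
  # overwrite with exact linear data: same slope in both sexes
  co$vol_pct_tbv <- 0.002 * co$tbv_cm3 + 1
  sub <- co[co$tract == "a", ]
  reg <- suppressWarnings(volumeVsTbvRegression(sub, "a"))
  expect_equal(reg$slopes$r_squared, c(1, 1), tolerance = 1e-9)
  expect_equal(reg$slopes$slope, c(0.002, 0.002), tolerance = 1e-9)
  # distinct slopes produce a significant interaction
  men <- sub$sex == "M"
  sub$vol_pct_tbv[men] <- 0.004 * sub$tbv_cm3[men] + 0.5 +
    rnorm(sum(men), 0, 1e-4)
  sub$vol_pct_tbv[!men] <- 0.001 * sub$tbv_cm3[!men] + 2 +
    rnorm(sum(!men), 0, 1e-4)
  reg2 <- volumeVsTbvRegression(sub, "a")
  expect_lt(reg2$ancova$p, 1e-6)
  expect_error(volumeVsTbvRegression(sub, "zz"), "not in the cohort")
})
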