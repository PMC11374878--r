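#' @include AllClasses.R
NULL

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate, in (0, 1) (default 0.05).
#' @param m number of comparisons in the family (>= 1).
#' @return `alpha / m`.
#' @examples
#' bonferroniThreshold(0.05, 772)  # 6.476684e-05
#' @export
bonferroniThreshold <- function(alpha = 0.05, m) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (length(m) != 1L || !is.finite(m) || m < 1) stop("m must be >= 1")
  alpha / m
}

#' Cohen's d from group summary statistics
#'
#' Classic two-sample Cohen's d with the df-weighted pooled standard
#' deviation:
#' `d = (mean_m - mean_f) / sqrt(((n_m-1) sd_m^2 + (n_f-1) sd_f^2) / (n_m+n_f-2))`.
#' Positive values mean the first (men) group is larger.
#'
#' @param meanM,sdM,nM first-group mean, SD, size.
#' @param meanF,sdF,nF second-group mean, SD, size.
#' @return Cohen's d.
#' @examples
#' cohensD(2.06, 0.27, 490, 2.21, 0.27, 575)  # -0.556
#' @export
cohensD <- function(meanM, sdM, nM, meanF, sdF, nF) {
  if (any(c(sdM, sdF) < 0) || any(c(nM, nF) < 2))
    stop("need sds >= 0 and group sizes >= 2")
  sp <- sqrt(((nM - 1) * sdM^2 + (nF - 1) * sdF^2) / (nM + nF - 2))
  if (sp == 0) stop("pooled standard deviation is zero; effect size undefined")
  (meanM - meanF) / sp
}

#' Effect-size bin for Cohen's d
#'
#' `|d| < 0.2` negligible, `0.2 - 0.5` small, `0.5 - 0.8` medium,
#' `> 0.8` large; boundary values go to the higher bin.
#'
#' @param d Cohen's d (finite; vectorized).
#' @return character vector of bins.
#' @export
effectBin <- function(d) {
  if (any(!is.finite(d))) stop("d must be finite")
  a <- abs(d)
  ifelse(a < 0.2, "negligible",
         ifelse(a < 0.5, "small", ifelse(a < 0.8, "medium", "large")))
}

#' Relative group difference in percent
#'
#' `100 * (mean_m - mean_f) / mean_m` (first-group denominator); positive
#' means the first (men) group is larger.
#'
#' @param meanM,meanF group means; `meanM` must be non-zero.
#' @return percentage.
#' @export
relativeDifference <- function(meanM, meanF) {
  if (any(meanM == 0)) stop("the men-group mean is zero; undefined")
  100 * (meanM - meanF) / meanM
}

#' Two-group comparison of one measure
#'
#' Shapiro-Wilk normality per group and Levene's test (center = mean) for
#' homogeneity of variance are computed and recorded as QC columns; the
#' reported p-value always comes from the two-sided pooled-variance
#' Student's t-test. Cohen's d, its bin, the relative difference and the
#' Bonferroni significance flag are filled in.
#'
#' @param valuesM,valuesF numeric samples (n >= 3 each).
#' @param bonferroniAlpha corrected significance threshold the p-value is
#'   compared against (default 0.05).
#' @param measure measure name carried into the result.
#' @return one-row data.frame with columns `measure`, `n_m`, `n_f`,
#'   `mean_m`, `sd_m`, `mean_f`, `sd_f`, `shapiro_p_m`, `shapiro_p_f`,
#'   `levene_p`, `t`, `p`, `bonferroni_alpha`, `significant`, `cohens_d`,
#'   `effect_bin`, `relative_difference_pct`.
#' @export
groupCompare <- function(valuesM, valuesF, bonferroniAlpha = 0.05,
                         measure = "measure") {
  valuesM <- valuesM[is.finite(valuesM)]
  valuesF <- valuesF[is.finite(valuesF)]
  if (length(valuesM) < 3L || length(valuesF) < 3L)
    stop("insufficient data: each group needs at least 3 values")
  shp <- function(x) {
    if (stats::sd(x) == 0) return(NA_real_)
    if (length(x) > 5000) x <- x[round(seq(1, length(x), length.out = 5000))]
    tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
  }
  lev <- tryCatch({
    g <- factor(rep(c("M", "F"), c(length(valuesM), length(valuesF))))
    car::leveneTest(c(valuesM, valuesF), g, center = mean)[1, "Pr(>F)"]
  }, error = function(e) NA_real_)
  tt <- stats::t.test(valuesM, valuesF, var.equal = TRUE)
  d <- if (stats::sd(valuesM) == 0 && stats::sd(valuesF) == 0) 0 else
    cohensD(mean(valuesM), stats::sd(valuesM), length(valuesM),
            mean(valuesF), stats::sd(valuesF), length(valuesF))
  p <- tt$p.value
  data.frame(measure = measure, n_m = length(valuesM), n_f = length(valuesF),
             mean_m = mean(valuesM), sd_m = stats::sd(valuesM),
             mean_f = mean(valuesF), sd_f = stats::sd(valuesF),
             shapiro_p_m = shp(valuesM), shapiro_p_f = shp(valuesF),
             levene_p = lev, t = unname(tt$statistic), p = p,
             bonferroni_alpha = bonferroniAlpha,
             significant = p < bonferroniAlpha, cohens_d = d,
             effect_bin = effectBin(d),
             relative_difference_pct =
               if (mean(valuesM) != 0)
                 relativeDifference(mean(valuesM), mean(valuesF))
               else NA_real_,
             stringsAsFactors = FALSE)
}

# The per-tract measures entering the comparison family, in report order.
TRACT_MEASURES <- c("vol_pct_tbv", "vol_pct_wmv", "fa", "md", "ad", "rd",
                    "gfa", "ndi", "iwvf", "odi")

#' Full two-group comparison over a cohort of subject measures
#'
#' Runs [groupCompare()] for every measure in the family: per tract the two
#' normalized volumes and the eight microstructural metrics, plus the
#' subject-level TBV and WMV — a family of `10 * n_tracts + 2` comparisons
#' (772 for a 77-tract atlas). The Bonferroni threshold is `alpha` divided
#' by that family size, computed from the cohort's tract set, never
#' hard-coded. Measure ordering is stable (TBV, WMV, then tracts in sorted
#' order) regardless of input row order.
#'
#' @param cohort data.frame as produced by [simulateCohort()] or by
#'   stacking [measureSubject()] rows: one row per (subject, tract) with
#'   `sex` ("M"/"F"), `tbv_cm3`, `wmv_cm3` and the ten per-tract measures.
#' @param alpha family-wise error rate before correction (default 0.05).
#' @return data.frame of [groupCompare()] rows, one per measure, with
#'   measure names `TBV`, `WMV` and `<tract>:<measure>`.
#' @export
runFullComparison <- function(cohort, alpha = 0.05) {
  need <- c("subject", "sex", "tbv_cm3", "wmv_cm3", "tract", TRACT_MEASURES)
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop(paste("cohort lacks columns:", paste(miss, collapse = ", ")))
  if (length(setdiff(c("M", "F"), unique(cohort$sex))))
    stop("the cohort must contain both sexes")
  tracts <- sort(unique(cohort$tract))
  m <- length(tracts) * length(TRACT_MEASURES) + 2L
  thr <- bonferroniThreshold(alpha, m)

  subj <- cohort[!duplicated(cohort$subject),
                 c("subject", "sex", "tbv_cm3", "wmv_cm3")]
  subj <- subj[order(subj$subject), ]
  men <- subj$sex == "M"
  res <- list(
    groupCompare(subj$tbv_cm3[men], subj$tbv_cm3[!men], thr, "TBV"),
    groupCompare(subj$wmv_cm3[men], subj$wmv_cm3[!men], thr, "WMV"))
  for (tr in tracts) {
    sub <- cohort[cohort$tract == tr, ]
    sub <- sub[order(sub$subject), ]
    menT <- sub$sex == "M"
    for (ms in TRACT_MEASURES) {
      res[[length(res) + 1L]] <-
        groupCompare(sub[[ms]][menT], sub[[ms]][!menT], thr,
                     paste(tr, ms, sep = ":"))
    }
  }
  out <- do.call(rbind, res)
  attr(out, "familySize") <- m
  attr(out, "alpha") <- alpha
  out
}

#' Per-sex regression of normalized tract volume on TBV, with ANCOVA
#'
#' Fits `vol_pct_tbv ~ tbv_cm3` separately in men and women by least
#' squares, and an ANCOVA `vol_pct_tbv ~ tbv_cm3 * sex` on the pooled
#' cohort; the sex-by-TBV interaction F statistic and p-value test whether
#' the two slopes differ.
#'
#' @param cohort data.frame as in [runFullComparison()].
#' @param tract tract name to analyse.
#' @return list with `slopes` (data.frame per sex: slope, intercept,
#'   r_squared, n) and `ancova` (data.frame: interaction F, p, df).
#' @export
volumeVsTbvRegression <- function(cohort, tract) {
  sub <- cohort[cohort$tract == tract, ]
  if (!nrow(sub)) stop(sprintf("tract '%s' not in the cohort", tract))
  if (min(table(sub$sex)) < 3L) stop("need at least 3 subjects per sex")
  perSex <- do.call(rbind, lapply(c("M", "F"), function(sx) {
    dd <- sub[sub$sex == sx, ]
    fit <- stats::lm(vol_pct_tbv ~ tbv_cm3, data = dd)
    data.frame(sex = sx, slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = summary(fit)$r.squared, n = nrow(dd),
               stringsAsFactors = FALSE)
  }))
  sub$sex <- factor(sub$sex)
  full <- stats::lm(vol_pct_tbv ~ tbv_cm3 * sex, data = sub)
  an <- stats::anova(full)
  irow <- grep(":", rownames(an))
  list(slopes = perSex,
       ancova = data.frame(F = an$`F value`[irow], p = an$`Pr(>F)`[irow],
                           df1 = an$Df[irow],
                           df2 = an$Df[nrow(an)]))
}
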