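#' @include AllClasses.R utils.R
NULL

# Per-tract measure baselines for simulated cohorts: values at the scale of
# healthy adult deep white matter (volumes as percent of TBV, diffusivities
# in mm^2/s).
MEASURE_BASELINES <- data.frame(
  measure = c("vol_pct_tbv", "fa", "md", "ad", "rd", "gfa", "ndi",
              "iwvf", "odi"),
  mean = c(2.06, 0.45, 0.75e-3, 1.20e-3, 0.55e-3, 0.20, 0.60, 0.10, 0.25),
  sd   = c(0.27, 0.03, 0.03e-3, 0.05e-3, 0.03e-3, 0.02, 0.04, 0.03, 0.03),
  stringsAsFactors = FALSE)

#' Specify a simulated two-group cohort
#'
#' Builds a [CohortSpec-class] with one row of group means/SDs per
#' (tract, measure). Baselines are identical between the sexes; `effects`
#' plants standardized group differences (Cohen's d, positive = larger in
#' men) on selected measures by shifting the women's mean by `-d * sd`.
#'
#' @param nMen,nWomen group sizes.
#' @param tractNames character vector of tract names.
#' @param effects named list: `effects[[tract]][[measure]] = d`.
#' @param tbv,wmv c(mean_m, sd_m, mean_f, sd_f) in cm^3; defaults are
#'   healthy-young-adult scale values (TBV 1290 +/- 102 vs 1128 +/- 90,
#'   WMV 476 +/- 49 vs 409 +/- 42).
#' @param seed RNG seed.
#' @return A [CohortSpec-class].
#' @export
cohortSpec <- function(nMen, nWomen, tractNames,
                       effects = list(),
                       tbv = c(1290, 102, 1128, 90),
                       wmv = c(476, 49, 409, 42),
                       seed = 1L) {
  base <- MEASURE_BASELINES
  tracts <- do.call(rbind, lapply(tractNames, function(tr) {
    data.frame(tract = tr, measure = base$measure,
               mean_m = base$mean, sd_m = base$sd,
               mean_f = base$mean, sd_f = base$sd,
               stringsAsFactors = FALSE)
  }))
  for (tr in names(effects)) {
    for (ms in names(effects[[tr]])) {
      row <- tracts$tract == tr & tracts$measure == ms
      if (!any(row)) stop(sprintf("unknown tract/measure: %s/%s", tr, ms))
      tracts$mean_f[row] <- tracts$mean_m[row] -
        effects[[tr]][[ms]] * tracts$sd_m[row]
    }
  }
  new("CohortSpec", nMen = as.integer(nMen), nWomen = as.integer(nWomen),
      tbv = tbv, wmv = wmv, tracts = tracts, seed = as.integer(seed))
}

#' Set explicit group parameters for one measure
#'
#' Convenience editor for a [CohortSpec-class]: overwrite mean/SD for one
#' (tract, measure) pair with explicit men/women values.
#'
#' @param spec a [CohortSpec-class].
#' @param tract,measure which row to set.
#' @param mean_m,sd_m,mean_f,sd_f group parameters.
#' @return The modified spec.
#' @export
setCohortMeasure <- function(spec, tract, measure, mean_m, sd_m, mean_f,
                             sd_f) {
  row <- spec@tracts$tract == tract & spec@tracts$measure == measure
  if (!any(row)) stop(sprintf("unknown tract/measure: %s/%s", tract, measure))
  spec@tracts$mean_m[row] <- mean_m; spec@tracts$sd_m[row] <- sd_m
  spec@tracts$mean_f[row] <- mean_f; spec@tracts$sd_f[row] <- sd_f
  validObject(spec)
  spec
}

#' Simulate a cohort of per-subject tract measures
#'
#' Draws every measure from its group normal distribution. The percent-of-TBV
#' volume is the generative primitive; raw volume and percent-of-WMV are
#' derived per subject (`volume = pct_tbv * TBV / 100`,
#' `pct_wmv = 100 * volume / WMV`), so the normalization identities hold by
#' construction. Deterministic for a fixed spec seed.
#'
#' @param spec a [CohortSpec-class].
#' @return data.frame with one row per (subject, tract): columns `subject`,
#'   `sex` ("M"/"F"), `tbv_cm3`, `wmv_cm3`, `tract`, `volume_cm3`,
#'   `vol_pct_tbv`, `vol_pct_wmv`, `fa`, `md`, `ad`, `rd`, `gfa`, `ndi`,
#'   `iwvf`, `odi`.
#' @export
simulateCohort <- function(spec) {
  validObject(spec)
  withSeed(spec@seed, {
    n <- spec@nMen + spec@nWomen
    sex <- rep(c("M", "F"), c(spec@nMen, spec@nWomen))
    subject <- sprintf("sub-%03d", seq_len(n))
    men <- sex == "M"
    tbv <- numeric(n); wmv <- numeric(n)
    tbv[men] <- stats::rnorm(sum(men), spec@tbv[1], spec@tbv[2])
    tbv[!men] <- stats::rnorm(sum(!men), spec@tbv[3], spec@tbv[4])
    wmv[men] <- stats::rnorm(sum(men), spec@wmv[1], spec@wmv[2])
    wmv[!men] <- stats::rnorm(sum(!men), spec@wmv[3], spec@wmv[4])

    tractNames <- unique(spec@tracts$tract)
    rows <- list()
    for (tr in tractNames) {
      par <- spec@tracts[spec@tracts$tract == tr, ]
      draw <- function(ms) {
        p <- par[par$measure == ms, ]
        v <- numeric(n)
        v[men] <- stats::rnorm(sum(men), p$mean_m, p$sd_m)
        v[!men] <- stats::rnorm(sum(!men), p$mean_f, p$sd_f)
        v
      }
      pctTbv <- draw("vol_pct_tbv")
      volume <- pctTbv * tbv / 100
      rows[[tr]] <- data.frame(
        subject = subject, sex = sex, tbv_cm3 = tbv, wmv_cm3 = wmv,
        tract = tr, volume_cm3 = volume, vol_pct_tbv = pctTbv,
        vol_pct_wmv = 100 * volume / wmv,
        fa = draw("fa"), md = draw("md"), ad = draw("ad"), rd = draw("rd"),
        gfa = draw("gfa"), ndi = draw("ndi"), iwvf = draw("iwvf"),
        odi = draw("odi"), stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$subject, out$tract), ]
    rownames(out) <- NULL
    out
  })
}
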