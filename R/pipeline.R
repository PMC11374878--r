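#' @include phantom.R dti.R csa.R noddi.R tracking.R bundles.R stats.R io.R cohort.R
NULL

#' Fit all local models and return the eight scalar maps
#'
#' DTI metrics come from the b = 1000 shell only; the constant-solid-angle
#' ODF field, GFA and NODDI use all shells.
#'
#' @param dwi 4D signal array.
#' @param gtab a [GradientTable-class].
#' @param mask 3D fit mask.
#' @param affine voxel-to-world matrix.
#' @param shOrder spherical-harmonic order for the ODF fit.
#' @param noddiRefine run the NODDI nonlinear refinement (TRUE) or stop at
#'   the dictionary optimum (FALSE, faster).
#' @return list with `maps` (named list fa, md, ad, rd, gfa, ndi, iwvf,
#'   odi), `odf` (the [ODFField-class]) and `fit` (the [TensorFit-class]).
#' @export
fitLocalModels <- function(dwi, gtab, mask, affine, shOrder = 8L,
                           noddiRefine = TRUE) {
  fit <- fitDti(dwi, gtab, mask, affine)
  sc <- tensorScalars(fit)
  odf <- fitCsaOdf(dwi, gtab, mask, shOrder = shOrder, affine = affine)
  g <- gfa(odf)
  nd <- fitNoddi(dwi, gtab, mask, affine, refine = noddiRefine)
  list(maps = list(fa = sc$fa, md = sc$md, ad = sc$ad, rd = sc$rd,
                   gfa = g, ndi = nd$ndi, iwvf = nd$iwvf, odi = nd$odi),
       odf = odf, fit = fit)
}

#' Per-subject tractometry pipeline
#'
#' The individual analysis chain on one acquisition: local model fitting,
#' probabilistic tractography over the dilated white-matter domain, atlas
#' labeling and per-tract measurement.
#'
#' @param dwi,gtab,affine the acquisition.
#' @param brainMask,wmMask 3D masks.
#' @param atlas a [BundleAtlas-class] in the subject frame.
#' @param params a [TrackingParams-class].
#' @param subject,sex subject metadata.
#' @param shOrder SH order for the ODF fit.
#' @param noddiRefine see [fitLocalModels()].
#' @param dilationVoxels propagation-domain dilation (default 1).
#' @return list with `measures` (the [measureSubject()] table), `labeled`
#'   ([LabeledTractogram-class]), `maps`, `odf`.
#' @export
runSubjectPipeline <- function(dwi, gtab, affine, brainMask, wmMask, atlas,
                               params = trackingParams(),
                               subject = "sub-001", sex = NA_character_,
                               shOrder = 8L, noddiRefine = TRUE,
                               dilationVoxels = 1L) {
  lm <- fitLocalModels(dwi, gtab, wmMask, affine, shOrder = shOrder,
                       noddiRefine = noddiRefine)
  domain <- makePropagationDomain(wmMask, dilationVoxels)
  tg <- track(lm$odf, domain, params)
  labeled <- labelTractogram(tg, atlas)
  meas <- measureSubject(labeled, lm$maps, brainMask, wmMask, affine, atlas,
                         subject = subject, sex = sex)
  list(measures = meas, labeled = labeled, maps = lm$maps, odf = lm$odf)
}

#' End-to-end demonstration pipeline
#'
#' Runs the whole analysis at desk scale, deterministically per seed:
#' (1) builds a noisy three-bundle phantom whose tube centerlines are the
#' toy atlas centroids, runs the per-subject imaging chain on it
#' (fit, track, label, measure); (2) simulates a two-group cohort of
#' per-subject tract measures over the same three tracts, with a planted
#' genu-like volumetric deficit in men on the `cc_genu` tract
#' (men 2.06 +/- 0.27 vs women 2.21 +/- 0.27 percent of TBV, a true
#' Cohen's d of -0.56); and (3) runs the full Bonferroni-controlled group
#' comparison plus the TBV regression/ANCOVA on the planted tract.
#'
#' @param seed integer seed driving phantom noise, tracking and the cohort
#'   draw.
#' @param outDir optional output directory; when given, the cohort table,
#'   comparison table, exemplar subject measures, labeled bundle TCKs and a
#'   JSON run manifest are written there.
#' @param nMen,nWomen cohort group sizes (default 10 each).
#' @param gridShape phantom grid (default 16^3).
#' @param dirsPerShell phantom acquisition directions per shell (default
#'   30; three shells at b = 1000/2000/3000 plus 6 b0 as in the emulated
#'   protocol geometry).
#' @param snr b0 signal-to-noise ratio of the phantom (default 30).
#' @param imaging run the imaging stage (default TRUE; FALSE runs only the
#'   cohort statistics stage).
#' @return list with `comparison`, `regression`, `cohort`,
#'   `subjectMeasures`, `atlas`, `plantedTract`, `plantedD`, `seed`.
#' @export
runDemoPipeline <- function(seed = 1L, outDir = NULL, nMen = 10L,
                            nWomen = 10L, gridShape = c(16L, 16L, 16L),
                            dirsPerShell = 30L, snr = 30,
                            imaging = TRUE) {
  seed <- as.integer(seed)
  vs <- 1.25
  atlas <- makeToyAtlas(voxelSize = vs, gridShape = gridShape)

  subjectMeasures <- NULL
  labeled <- NULL
  if (imaging) {
    gtab <- makeGradientTable(dirsPerShell, c(1000, 2000, 3000), 6L,
                              seed = 0L)
    s0 <- 100
    bundles <- lapply(seq_along(atlasLabels(atlas)), function(i)
      tubeBundle(atlasLabels(atlas)[i], atlasCentroids(atlas)[[i]],
                 radius = 2.0))
    spec <- phantomSpec(gridShape = gridShape, voxelSize = vs,
                        bundles = bundles, s0 = s0,
                        noiseSigma = s0 / snr, noiseModel = "rician",
                        signalModel = "tensor", crossingMode = TRUE,
                        seed = seed)
    ph <- buildPhantom(spec, gtab)
    sub <- runSubjectPipeline(ph$dwi, gtab, ph$affine, ph$brainMask,
                              ph$wmMask, atlas,
                              params = trackingParams(seed = seed + 1L),
                              subject = "demo-001", sex = "M",
                              shOrder = 6L, noddiRefine = FALSE)
    subjectMeasures <- sub$measures
    labeled <- sub$labeled
  }

  cs <- cohortSpec(nMen, nWomen, atlasLabels(atlas), seed = seed + 2L)
  cs <- setCohortMeasure(cs, "cc_genu", "vol_pct_tbv",
                         mean_m = 2.06, sd_m = 0.27,
                         mean_f = 2.21, sd_f = 0.27)
  cohort <- simulateCohort(cs)
  comparison <- runFullComparison(cohort)
  regression <- volumeVsTbvRegression(cohort, "cc_genu")

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeTsv(cohort, file.path(outDir, "cohort.tsv"))
    writeTsv(comparison, file.path(outDir, "comparison.tsv"))
    if (!is.null(subjectMeasures))
      writeTsv(subjectMeasures, file.path(outDir, "subject_measures.tsv"))
    if (!is.null(labeled))
      writeStreamlines(labeled, file.path(outDir, "tractogram.tck"))
    writeBundleAtlas(atlas, file.path(outDir, "atlas.tck"),
                     file.path(outDir, "atlas.tsv"))
    writeManifest(file.path(outDir, "manifest.json"),
                  config = list(nMen = nMen, nWomen = nWomen,
                                gridShape = gridShape,
                                dirsPerShell = dirsPerShell, snr = snr,
                                plantedTract = "cc_genu",
                                plantedD = -0.56, imaging = imaging),
                  seed = seed)
  }

  list(comparison = comparison, regression = regression, cohort = cohort,
       subjectMeasures = subjectMeasures, atlas = atlas,
       plantedTract = "cc_genu", plantedD = -0.56, seed = seed)
}
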