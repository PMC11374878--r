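#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("arrayOrNULL", c("array", "NULL"))

#' Multi-shell q-space sampling scheme
#'
#' One entry per acquired volume: a b-value in s/mm^2, a unit gradient
#' direction (the zero vector for b = 0 volumes) and an integer shell id
#' (0 for the b = 0 shell).
#'
#' @slot bvals numeric vector of b-values, s/mm^2.
#' @slot bvecs 3 x n matrix of gradient directions (columns).
#' @slot shellIds integer shell membership per volume; 0 marks b = 0.
#' @exportClass GradientTable
setClass("GradientTable",
  representation(bvals = "numeric", bvecs = "matrix", shellIds = "integer"))

setValidity("GradientTable", function(object) {
  n <- length(object@bvals)
  if (!is.numeric(object@bvecs) || nrow(object@bvecs) != 3L ||
      ncol(object@bvecs) != n)
    return("bvecs must be a 3 x n numeric matrix matching length(bvals)")
  if (length(object@shellIds) != n)
    return("shellIds must have one entry per volume")
  if (any(object@bvals < 0)) return("b-values must be non-negative")
  dw <- object@shellIds != 0L
  if (!any(!dw)) return("at least one b = 0 entry is required")
  if (any(object@bvals[!dw] > 50))
    return("shell id 0 entries must have b close to 0")
  nrm <- sqrt(colSums(object@bvecs[, dw, drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-6))
    return("non-b0 directions must have unit norm (within 1e-6)")
  TRUE
})

#' Voxelwise quantitative scalar map
#'
#' @slot data 3D numeric array.
#' @slot affine 4 x 4 voxel-to-world (RAS mm) matrix; voxel (1,1,1) maps
#'   through index (0,0,0).
#' @slot metric metric name, one of FA, MD, AD, RD, GFA, NDI, IWVF, ODI
#'   (free names allowed for derived maps).
#' @slot units "mm^2/s" for diffusivities, "1" for dimensionless indices.
#' @exportClass ScalarMap
setClass("ScalarMap",
  representation(data = "array", affine = "matrix", metric = "character",
                 units = "character"))

setValidity("ScalarMap", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3D array")
  if (!all(dim(object@affine) == c(4L, 4L))) return("affine must be 4 x 4")
  TRUE
})

#' Voxelwise ODF field in the real even spherical-harmonic basis
#'
#' @slot coefficients 4D array (x, y, z, coefficient); coefficient count is
#'   (shOrder+1)(shOrder+2)/2.
#' @slot shOrder even spherical-harmonic order.
#' @slot affine 4 x 4 voxel-to-world matrix.
#' @exportClass ODFField
setClass("ODFField",
  representation(coefficients = "array", shOrder = "integer",
                 affine = "matrix"))

setValidity("ODFField", function(object) {
  if (length(dim(object@coefficients)) != 4L)
    return("coefficients must be a 4D array")
  L <- object@shOrder
  if (L %% 2L != 0L || L < 0L) return("shOrder must be a non-negative even integer")
  nc <- (L + 1L) * (L + 2L) / 2L
  if (dim(object@coefficients)[4L] != nc)
    return(sprintf("expected %d coefficients for shOrder %d", nc, L))
  TRUE
})

#' Voxelwise diffusion tensor fit
#'
#' @slot tensor 4D array (x, y, z, 6): unique tensor elements
#'   Dxx, Dyy, Dzz, Dxy, Dxz, Dyz in mm^2/s.
#' @slot evals 4D array (x, y, z, 3): eigenvalues sorted descending,
#'   negative values clamped to zero (clamp count in `qc`).
#' @slot evec1 4D array (x, y, z, 3): principal eigenvector.
#' @slot s0 3D array of estimated non-diffusion-weighted signal.
#' @slot mask 3D logical array of fitted voxels.
#' @slot affine 4 x 4 voxel-to-world matrix.
#' @slot qc list with counts of clamped signals / eigenvalues.
#' @exportClass TensorFit
setClass("TensorFit",
  representation(tensor = "array", evals = "array", evec1 = "array",
                 s0 = "array", mask = "array", affine = "matrix",
                 qc = "list"))

#' Streamline set in world (mm) coordinates
#'
#' @slot streamlines list of n_i x 3 matrices of ordered points, mm.
#' @slot seedVoxel integer linear index of the seed voxel per streamline
#'   (NA when unknown, e.g. after file round-trips).
#' @slot nSeedsAttempted number of seeds attempted by the tracker.
#' @exportClass Tractogram
setClass("Tractogram",
  representation(streamlines = "list", seedVoxel = "integer",
                 nSeedsAttempted = "integer"),
  prototype(streamlines = list(), seedVoxel = integer(),
            nSeedsAttempted = NA_integer_))

setValidity("Tractogram", function(object) {
  ok <- vapply(object@streamlines, function(s)
    is.matrix(s) && ncol(s) == 3L && nrow(s) >= 2L, logical(1))
  if (length(ok) && !all(ok))
    return("every streamline must be an n x 3 matrix with n >= 2")
  if (length(object@seedVoxel) &&
      length(object@seedVoxel) != length(object@streamlines))
    return("seedVoxel must match the number of streamlines")
  TRUE
})

#' Streamline set with per-streamline bundle labels
#'
#' @slot labels character label per streamline; "UNLABELED" when no atlas
#'   tract accepted the streamline. Each streamline carries exactly one label.
#' @exportClass LabeledTractogram
setClass("LabeledTractogram", contains = "Tractogram",
  representation(labels = "character"))

setValidity("LabeledTractogram", function(object) {
  if (length(object@labels) != length(object@streamlines))
    return("labels must have one entry per streamline")
  TRUE
})

#' Bundle atlas of labeled centroid streamlines
#'
#' @slot labels unique tract names.
#' @slot centroids list of n x 3 centroid point matrices (atlas mm space).
#' @slot thresholds per-tract distance threshold, mm.
#' @slot category per-tract category: association, projection,
#'   interhemispheric or other.
#' @slot hemisphere "left", "right" or "both".
#' @exportClass BundleAtlas
setClass("BundleAtlas",
  representation(labels = "character", centroids = "list",
                 thresholds = "numeric", category = "character",
                 hemisphere = "character"))

setValidity("BundleAtlas", function(object) {
  n <- length(object@labels)
  if (anyDuplicated(object@labels)) return("atlas labels must be unique")
  if (length(object@centroids) != n || length(object@thresholds) != n ||
      length(object@category) != n || length(object@hemisphere) != n)
    return("labels, centroids, thresholds, category, hemisphere lengths differ")
  if (n && any(object@thresholds <= 0)) return("thresholds must be > 0")
  bad <- setdiff(unique(object@category),
                 c("association", "projection", "interhemispheric", "other"))
  if (length(bad)) return(paste("unknown category:", paste(bad, collapse = ", ")))
  TRUE
})

#' Voxelwise ground-truth microstructure field of a phantom
#'
#' @slot orientation 4D (x, y, z, 3) primary fiber orientation (unit vectors,
#'   zero in isotropic voxels).
#' @slot orientation2 second orientation in crossing voxels, or NULL.
#' @slot evals 4D (x, y, z, 3) tensor eigenvalues mm^2/s.
#' @slot nuIc,nuIso,kappa 3D arrays of NODDI ground truth.
#' @slot label 3D integer array: 0 background, k = bundle k, -1 crossing.
#' @slot affine 4 x 4 voxel-to-world matrix.
#' @exportClass MicrostructureField
setClass("MicrostructureField",
  representation(orientation = "array", orientation2 = "arrayOrNULL",
                 evals = "array", nuIc = "array", nuIso = "array",
                 kappa = "array", label = "array", affine = "matrix"))

#' Phantom acquisition specification
#'
#' Parametric tube bundles on a regular grid with per-compartment ground
#' truth, an isotropic background, and Rician or Gaussian measurement noise.
#'
#' @slot gridShape 3 integers.
#' @slot voxelSize isotropic voxel size, mm (default 1.25 as acquired by
#'   connectome-style protocols).
#' @slot bundles list of bundle geometries from [tubeBundle()].
#' @slot background list(diffusivity, nuIso) for out-of-tube voxels.
#' @slot s0 baseline signal.
#' @slot noiseSigma noise standard deviation (0 = noiseless).
#' @slot noiseModel "rician" (magnitude MRI, default) or "gaussian".
#' @slot signalModel "tensor" or "noddi" forward model inside tubes.
#' @slot crossingMode allow overlapping tubes as two-orientation voxels.
#' @slot seed RNG seed.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(gridShape = "integer", voxelSize = "numeric",
                 bundles = "list", background = "list", s0 = "numeric",
                 noiseSigma = "numeric", noiseModel = "character",
                 signalModel = "character", crossingMode = "logical",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    return("gridShape must be 3 positive integers")
  if (object@voxelSize <= 0) return("voxelSize must be > 0")
  if (!object@noiseModel %in% c("rician", "gaussian"))
    return("noiseModel must be 'rician' or 'gaussian'")
  if (!object@signalModel %in% c("tensor", "noddi"))
    return("signalModel must be 'tensor' or 'noddi'")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  for (b in object@bundles) {
    if (any(b$evals < 0)) return("tensor eigenvalues must be >= 0")
    if (b$nuIc < 0 || b$nuIc > 1 || b$nuIso < 0 || b$nuIso > 1)
      return("nuIc and nuIso must lie in [0, 1]")
    if (b$kappa <= 0) return("kappa must be > 0")
  }
  TRUE
})

#' Two-group cohort specification
#'
#' Per-measure group means and standard deviations for a simulated
#' men/women cohort of per-subject tract measures.
#'
#' @slot nMen,nWomen group sizes (>= 2).
#' @slot tbv,wmv numeric length-4 vectors c(mean_m, sd_m, mean_f, sd_f), cm^3.
#' @slot tracts data.frame with columns tract, measure, mean_m, sd_m,
#'   mean_f, sd_f; one row per (tract, measure) pair. Volumes are
#'   parameterized through the measure `vol_pct_tbv` (percent of TBV); raw
#'   volume and percent-of-WMV are derived per subject.
#' @slot seed RNG seed.
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(nMen = "integer", nWomen = "integer", tbv = "numeric",
                 wmv = "numeric", tracts = "data.frame", seed = "integer"))

setValidity("CohortSpec", function(object) {
  if (object@nMen < 2L || object@nWomen < 2L)
    return("group sizes must be >= 2")
  if (length(object@tbv) != 4L || length(object@wmv) != 4L)
    return("tbv and wmv must be c(mean_m, sd_m, mean_f, sd_f)")
  if (any(c(object@tbv[c(2, 4)], object@wmv[c(2, 4)]) <= 0))
    return("standard deviations must be > 0")
  need <- c("tract", "measure", "mean_m", "sd_m", "mean_f", "sd_f")
  if (!all(need %in% names(object@tracts)))
    return(paste("tracts needs columns:", paste(need, collapse = ", ")))
  if (nrow(object@tracts) && any(c(object@tracts$sd_m, object@tracts$sd_f) <= 0))
    return("standard deviations must be > 0")
  TRUE
})

#' Probabilistic tracking parameters
#'
#' Defaults follow the acquisition-scale protocol: 8 seeds per voxel,
#' 30 degree aperture, 0.3 mm step, 1.25-300 mm retained length range and
#' unit sampler temperature.
#'
#' @slot seedsPerVoxel seeds per propagation-domain voxel.
#' @slot apertureDeg half-angle of the candidate cone, degrees.
#' @slot stepMm integration step, mm (forward and backward).
#' @slot minLenMm,maxLenMm retained streamline length range, mm.
#' @slot temperature Gibbs sampler temperature T; candidate directions are
#'   drawn with probability proportional to odf^(1/T).
#' @slot seed RNG seed.
#' @exportClass TrackingParams
setClass("TrackingParams",
  representation(seedsPerVoxel = "integer", apertureDeg = "numeric",
                 stepMm = "numeric", minLenMm = "numeric",
                 maxLenMm = "numeric", temperature = "numeric",
                 seed = "integer"))

setValidity("TrackingParams", function(object) {
  if (object@stepMm <= 0 || object@stepMm >= object@minLenMm)
    return("need 0 < stepMm < minLenMm")
  if (object@apertureDeg <= 0 || object@apertureDeg >= 90)
    return("need 0 < apertureDeg < 90")
  if (object@temperature <= 0) return("temperature must be > 0")
  if (object@minLenMm >= object@maxLenMm)
    return("need minLenMm < maxLenMm")
  if (object@seedsPerVoxel < 1L) return("seedsPerVoxel must be >= 1")
  TRUE
})
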