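#' @include AllClasses.R
NULL

#' Accessors for tractometry objects
#'
#' Small accessor generics: `bValues`, `bVectors`, `shellIds` for
#' [GradientTable-class]; `streamlines`, `nStreamlines`, `streamlineLabels`
#' for tractograms; `shCoefficients`, `shOrder` for [ODFField-class];
#' `mapData`, `mapAffine`, `metricName` for [ScalarMap-class]; `atlasLabels`,
#' `atlasCentroids`, `atlasThresholds` for [BundleAtlas-class].
#'
#' @param object an object of the matching class.
#' @return The slot contents.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("bValues", function(object) standardGeneric("bValues"))
#' @rdname accessors
#' @export
setGeneric("bVectors", function(object) standardGeneric("bVectors"))
#' @rdname accessors
#' @export
setGeneric("shellIds", function(object) standardGeneric("shellIds"))
#' @rdname accessors
#' @export
setGeneric("streamlines", function(object) standardGeneric("streamlines"))
#' @rdname accessors
#' @export
setGeneric("nStreamlines", function(object) standardGeneric("nStreamlines"))
#' @rdname accessors
#' @export
setGeneric("streamlineLabels",
           function(object) standardGeneric("streamlineLabels"))
#' @rdname accessors
#' @export
setGeneric("shCoefficients",
           function(object) standardGeneric("shCoefficients"))
#' @rdname accessors
#' @export
setGeneric("shOrder", function(object) standardGeneric("shOrder"))
#' @rdname accessors
#' @export
setGeneric("mapData", function(object) standardGeneric("mapData"))
#' @rdname accessors
#' @export
setGeneric("mapAffine", function(object) standardGeneric("mapAffine"))
#' @rdname accessors
#' @export
setGeneric("metricName", function(object) standardGeneric("metricName"))
#' @rdname accessors
#' @export
setGeneric("atlasLabels", function(object) standardGeneric("atlasLabels"))
#' @rdname accessors
#' @export
setGeneric("atlasCentroids",
           function(object) standardGeneric("atlasCentroids"))
#' @rdname accessors
#' @export
setGeneric("atlasThresholds",
           function(object) standardGeneric("atlasThresholds"))

#' @rdname accessors
setMethod("bValues", "GradientTable", function(object) object@bvals)
#' @rdname accessors
setMethod("bVectors", "GradientTable", function(object) object@bvecs)
#' @rdname accessors
setMethod("shellIds", "GradientTable", function(object) object@shellIds)
#' @rdname accessors
setMethod("streamlines", "Tractogram", function(object) object@streamlines)
#' @rdname accessors
setMethod("nStreamlines", "Tractogram",
          function(object) length(object@streamlines))
#' @rdname accessors
setMethod("streamlineLabels", "LabeledTractogram",
          function(object) object@labels)
#' @rdname accessors
setMethod("shCoefficients", "ODFField", function(object) object@coefficients)
#' @rdname accessors
setMethod("shOrder", "ODFField", function(object) object@shOrder)
#' @rdname accessors
setMethod("mapData", "ScalarMap", function(object) object@data)
#' @rdname accessors
setMethod("mapAffine", "ScalarMap", function(object) object@affine)
#' @rdname accessors
setMethod("metricName", "ScalarMap", function(object) object@metric)
#' @rdname accessors
setMethod("atlasLabels", "BundleAtlas", function(object) object@labels)
#' @rdname accessors
setMethod("atlasCentroids", "BundleAtlas", function(object) object@centroids)
#' @rdname accessors
setMethod("atlasThresholds", "BundleAtlas", function(object) object@thresholds)

setMethod("show", "GradientTable", function(object) {
  sh <- split(object@bvals, object@shellIds)
  cat("GradientTable with", length(object@bvals), "volumes\n")
  for (s in names(sh))
    cat(sprintf("  shell %s: %d volumes, b ~ %.0f s/mm^2\n",
                s, length(sh[[s]]), mean(sh[[s]])))
})

setMethod("show", "Tractogram", function(object) {
  n <- length(object@streamlines)
  cat("Tractogram with", n, "streamlines")
  if (!is.na(object@nSeedsAttempted))
    cat(" (", object@nSeedsAttempted, " seeds attempted)", sep = "")
  cat("\n")
  if (n) {
    len <- vapply(object@streamlines, streamlineLength, numeric(1))
    cat(sprintf("  length: %.1f-%.1f mm (median %.1f)\n",
                min(len), max(len), stats::median(len)))
  }
})

setMethod("show", "LabeledTractogram", function(object) {
  callNextMethod()
  tab <- table(object@labels)
  for (l in names(tab)) cat(sprintf("  %s: %d\n", l, tab[[l]]))
})

setMethod("show", "ODFField", function(object) {
  d <- dim(object@coefficients)
  cat(sprintf("ODFField %dx%dx%d, SH order %d (%d coefficients)\n",
              d[1], d[2], d[3], object@shOrder, d[4]))
})

setMethod("show", "ScalarMap", function(object) {
  d <- dim(object@data)
  v <- object@data[is.finite(object@data)]
  cat(sprintf("ScalarMap '%s' [%s] %dx%dx%d, range %.4g..%.4g\n",
              object@metric, object@units, d[1], d[2], d[3],
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
})

setMethod("show", "BundleAtlas", function(object) {
  cat("BundleAtlas with", length(object@labels), "tracts\n")
  tab <- table(object@category)
  for (l in names(tab)) cat(sprintf("  %s: %d\n", l, tab[[l]]))
})
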