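#' @include streamlines.R AllClasses.R
NULL

#' Construct a bundle atlas
#'
#' @param labels unique tract names.
#' @param centroids list of n x 3 centroid point matrices (mm).
#' @param thresholds per-tract assignment distance threshold, mm
#'   (recycled; default 10).
#' @param category per-tract category (association, projection,
#'   interhemispheric, other; recycled).
#' @param hemisphere per-tract hemisphere: left, right or both (recycled).
#' @return A [BundleAtlas-class].
#' @export
bundleAtlas <- function(labels, centroids, thresholds = 10,
                        category = "other", hemisphere = "both") {
  n <- length(labels)
  centroids <- lapply(centroids, function(m) {
    m <- as.matrix(m); dimnames(m) <- NULL; m
  })
  new("BundleAtlas", labels = labels, centroids = centroids,
      thresholds = rep_len(thresholds, n),
      category = rep_len(category, n),
      hemisphere = rep_len(hemisphere, n))
}

#' Toy three-tract bundle atlas
#'
#' A miniature atlas mirroring the category structure of a deep white
#' matter atlas: one interhemispheric arc (a genu-like anterior
#' interhemispheric tract), one left association tract and one right
#' projection tract, with centroid geometry that fits the default phantom
#' grid.
#'
#' @param voxelSize grid voxel size, mm (default 1.25).
#' @param gridShape grid the atlas should fit (default c(20, 20, 20)).
#' @param threshold assignment threshold, mm (default 10).
#' @return A [BundleAtlas-class] with 3 tracts.
#' @export
makeToyAtlas <- function(voxelSize = 1.25, gridShape = c(20L, 20L, 20L),
                         threshold = 10) {
  ext <- (gridShape - 1) * voxelSize
  mid <- ext / 2
  genu <- arcCurve(center = c(mid[1], ext[2] * 0.55, mid[3]),
                   arcRadius = ext[1] * 0.3, angles = c(pi / 6, pi - pi / 6),
                   plane = "xy")
  assoc <- lineCurve(c(ext[1] * 0.2, ext[2] * 0.15, mid[3] * 0.6),
                     c(ext[1] * 0.2, ext[2] * 0.85, mid[3] * 0.6))
  proj <- lineCurve(c(ext[1] * 0.8, mid[2], ext[3] * 0.1),
                    c(ext[1] * 0.8, mid[2], ext[3] * 0.9))
  bundleAtlas(
    labels = c("cc_genu", "left_association", "right_projection"),
    centroids = list(genu, assoc, proj),
    thresholds = threshold,
    category = c("interhemispheric", "association", "projection"),
    hemisphere = c("both", "left", "right"))
}

#' Label a tractogram against a centroid atlas
#'
#' For each streamline, the flip-symmetrized maximum corresponding-point
#' distance (see [streamlineDistance()]) to every atlas centroid is
#' computed on `nPoints` resampled points. Among tracts whose distance
#' threshold is satisfied, the streamline is assigned to the closest one;
#' otherwise it is left "UNLABELED". Each streamline receives exactly one
#' label, so labels partition the tractogram.
#'
#' @param tractogram a [Tractogram-class].
#' @param atlas a [BundleAtlas-class] in the same spatial frame (apply any
#'   rigid/affine pre-alignment with [transformTractogram()] first).
#' @param nPoints resampling points for the distance (default 21).
#' @return A [LabeledTractogram-class].
#' @export
labelTractogram <- function(tractogram, atlas, nPoints = 21L) {
  if (!length(atlasLabels(atlas))) stop("the atlas is empty")
  sl <- streamlines(tractogram)
  n <- length(sl)
  if (!n)
    return(new("LabeledTractogram", streamlines = list(),
               seedVoxel = integer(), labels = character(),
               nSeedsAttempted = tractogram@nSeedsAttempted))
  R <- vapply(sl, function(s) as.numeric(resampleStreamlineN(s, nPoints)),
              numeric(3L * nPoints))          # (3*nPoints) x n, column-major
  R <- t(R)                                    # n x (nPoints*3)
  cents <- atlasCentroids(atlas)
  D <- matrix(Inf, n, length(cents))
  for (ci in seq_along(cents)) {
    cc <- resampleStreamlineN(cents[[ci]], nPoints)
    for (flip in c(FALSE, TRUE)) {
      b <- if (flip) cc[nPoints:1, , drop = FALSE] else cc
      sq <- matrix(0, n, nPoints)
      for (ax in 1:3) {
        cols <- (ax - 1L) * nPoints + seq_len(nPoints)
        sq <- sq + (R[, cols, drop = FALSE] -
                    matrix(b[, ax], n, nPoints, byrow = TRUE))^2
      }
      dmax <- sqrt(apply(sq, 1, max))
      D[, ci] <- pmin(D[, ci], dmax)
    }
  }
  ok <- sweep(D, 2, atlasThresholds(atlas), "<=")
  Dok <- D
  Dok[!ok] <- Inf
  pick <- max.col(-Dok, ties.method = "first")
  lab <- ifelse(is.finite(Dok[cbind(seq_len(n), pick)]),
                atlasLabels(atlas)[pick], "UNLABELED")
  new("LabeledTractogram", streamlines = sl,
      seedVoxel = tractogram@seedVoxel,
      nSeedsAttempted = tractogram@nSeedsAttempted, labels = lab)
}

#' Apply a rigid/affine transform to streamlines
#'
#' @param tractogram a [Tractogram-class] (or [BundleAtlas-class]).
#' @param matrix44 4 x 4 transform applied to every point (mm to mm).
#' @return The transformed object.
#' @export
transformTractogram <- function(tractogram, matrix44) {
  tf <- function(p) t(matrix44 %*% rbind(t(p), 1))[, 1:3, drop = FALSE]
  if (is(tractogram, "BundleAtlas")) {
    tractogram@centroids <- lapply(tractogram@centroids, tf)
    return(tractogram)
  }
  tractogram@streamlines <- lapply(tractogram@streamlines, tf)
  tractogram
}

#' Bundle density mask
#'
#' Counts, per voxel, the number of DISTINCT streamlines with at least one
#' resampled point inside the voxel (streamlines are resampled to
#' `resampleStep` mm first, so point density cannot inflate the count), and
#' thresholds at `minFibers`.
#'
#' @param bundle list of streamline matrices (or a [Tractogram-class]).
#' @param dim 3D grid dimensions.
#' @param affine 4 x 4 voxel-to-world matrix of the grid.
#' @param minFibers minimum distinct streamlines per voxel (default 5).
#' @param resampleStep resampling step, mm (default 0.1).
#' @return 3D logical mask.
#' @export
densityMask <- function(bundle, dim, affine, minFibers = 5L,
                        resampleStep = 0.1) {
  if (is(bundle, "Tractogram")) bundle <- streamlines(bundle)
  if (minFibers < 1L) stop("minFibers must be >= 1")
  counts <- array(0L, dim)
  if (!length(bundle)) return(counts >= minFibers)
  inv <- solve(affine)
  for (s in bundle) {
    p <- resampleStreamline(s, resampleStep)
    v <- round(t(inv %*% rbind(t(p), 1))[, 1:3, drop = FALSE]) + 1
    keep <- v[, 1] >= 1 & v[, 1] <= dim[1] & v[, 2] >= 1 & v[, 2] <= dim[2] &
            v[, 3] >= 1 & v[, 3] <= dim[3]
    if (!any(keep)) next
    lin <- unique((v[keep, 1] - 1) + dim[1] * ((v[keep, 2] - 1) +
                  dim[2] * (v[keep, 3] - 1)) + 1)
    counts[lin] <- counts[lin] + 1L
  }
  counts >= minFibers
}

#' Volume of a binary mask in cm^3
#'
#' @param mask 3D logical/0-1 array.
#' @param voxelSize isotropic voxel size in mm (or a length-3 vector).
#' @return volume in cm^3.
#' @export
bundleVolume <- function(mask, voxelSize) {
  stopifnotPositive(voxelSize, "voxel size")
  sum(mask != 0) * prod(rep_len(voxelSize, 3L)) / 1000
}

#' Normalize a volume to a reference volume
#'
#' @param raw volume, cm^3.
#' @param reference reference volume (TBV or WMV), cm^3; must be > 0.
#' @return percentage `100 * raw / reference`.
#' @export
normalizeVolume <- function(raw, reference) {
  if (any(!is.finite(reference)) || any(reference <= 0))
    stop("reference volume must be positive")
  100 * raw / reference
}

#' Along-tract mean of a quantitative map
#'
#' Every streamline is resampled to `step` mm; the map is interpolated
#' trilinearly at every resampled point; the mean over all points of all
#' streamlines is returned (point-weighted: longer streamlines contribute
#' more points). A Shapiro-Wilk normality check of the pooled values
#' (subsampled to 5000 points when larger) is attached as attribute
#' `shapiroP`; it is recorded, never used to alter the mean.
#'
#' @param bundle list of streamline matrices (or a [Tractogram-class]).
#' @param map a [ScalarMap-class] covering the bundle extent.
#' @param step resampling step, mm (default 0.1).
#' @return the pooled mean (numeric scalar) with attribute `shapiroP`.
#' @export
tractMetricMean <- function(bundle, map, step = 0.1) {
  if (is(bundle, "Tractogram")) bundle <- streamlines(bundle)
  if (!length(bundle)) return(structure(NA_real_, shapiroP = NA_real_))
  inv <- solve(mapAffine(map))
  vals <- unlist(lapply(bundle, function(s) {
    p <- resampleStreamline(s, step)
    v <- t(inv %*% rbind(t(p), 1))[, 1:3, drop = FALSE] + 1
    trilinear(mapData(map), v, outside = "error")
  }))
  sp <- NA_real_
  if (length(vals) >= 3 && stats::sd(vals) > 0) {
    sub <- if (length(vals) > 5000)
      vals[round(seq(1, length(vals), length.out = 5000))] else vals
    sp <- tryCatch(stats::shapiro.test(sub)$p.value,
                   error = function(e) NA_real_)
  }
  structure(mean(vals), shapiroP = sp)
}

#' Per-subject tract measures
#'
#' Computes the full tractometry row set for one subject: total brain and
#' white matter volumes from the masks, and per atlas tract the density-mask
#' volume (raw cm^3, percent of TBV, percent of WMV) plus the along-tract
#' mean of every supplied quantitative map. Tracts with no labeled
#' streamlines get volume 0 and missing (NA) metric means.
#'
#' @param labeled a [LabeledTractogram-class].
#' @param maps named list of [ScalarMap-class] maps (canonically fa, md,
#'   ad, rd, gfa, ndi, iwvf, odi) on one common grid.
#' @param brainMask,wmMask 3D masks on the same grid.
#' @param affine 4 x 4 voxel-to-world matrix of that grid.
#' @param atlas the [BundleAtlas-class] used for labeling (defines the row
#'   set).
#' @param subject subject id string.
#' @param sex "M" or "F" (or NA).
#' @param minFibers density-mask threshold (default 5 fibers/voxel).
#' @param step metric resampling step, mm (default 0.1).
#' @return data.frame, one row per atlas tract, with columns `subject`,
#'   `sex`, `tbv_cm3`, `wmv_cm3`, `tract`, `n_streamlines`, `volume_cm3`,
#'   `vol_pct_tbv`, `vol_pct_wmv`, one column per map and one
#'   `shapiro_p_<map>` QC column per map.
#' @export
measureSubject <- function(labeled, maps, brainMask, wmMask, affine, atlas,
                           subject = "sub-001", sex = NA_character_,
                           minFibers = 5L, step = 0.1) {
  d <- dim(brainMask)
  if (!all(dim(wmMask) == d) ||
      !all(vapply(maps, function(m) all(dim(mapData(m)) == d), logical(1))))
    stop("masks and maps must share one grid")
  voxVol <- abs(det(affine[1:3, 1:3]))
  tbv <- sum(brainMask != 0) * voxVol / 1000
  wmv <- sum(wmMask != 0) * voxVol / 1000
  sl <- streamlines(labeled)
  labs <- streamlineLabels(labeled)
  inv <- solve(affine)
  rows <- lapply(atlasLabels(atlas), function(tr) {
    bun <- sl[labs == tr]
    vol <- 0
    mets <- stats::setNames(rep(NA_real_, length(maps)), names(maps))
    shp <- stats::setNames(rep(NA_real_, length(maps)),
                           paste0("shapiro_p_", names(maps)))
    if (length(bun)) {
      # resample each streamline once; share the points between the
      # density mask and all metric means
      res <- lapply(bun, resampleStreamline, step = step)
      vox <- lapply(res, function(p)
        t(inv %*% rbind(t(p), 1))[, 1:3, drop = FALSE] + 1)
      counts <- array(0L, d)
      for (v in vox) {
        vr <- round(v)
        keep <- vr[, 1] >= 1 & vr[, 1] <= d[1] & vr[, 2] >= 1 &
                vr[, 2] <= d[2] & vr[, 3] >= 1 & vr[, 3] <= d[3]
        if (!any(keep)) next
        lin <- unique((vr[keep, 1] - 1) + d[1] * ((vr[keep, 2] - 1) +
                      d[2] * (vr[keep, 3] - 1)) + 1)
        counts[lin] <- counts[lin] + 1L
      }
      mask <- counts >= minFibers
      vol <- bundleVolume(mask, abs(det(affine[1:3, 1:3]))^(1 / 3))
      allVox <- do.call(rbind, vox)
      for (mn in names(maps)) {
        vals <- trilinear(mapData(maps[[mn]]), allVox, outside = "error")
        mets[mn] <- mean(vals)
        if (length(vals) >= 3 && stats::sd(vals) > 0) {
          sub <- if (length(vals) > 5000)
            vals[round(seq(1, length(vals), length.out = 5000))] else vals
          shp[paste0("shapiro_p_", mn)] <-
            tryCatch(stats::shapiro.test(sub)$p.value,
                     error = function(e) NA_real_)
        }
      }
    }
    cbind(data.frame(subject = subject, sex = sex, tbv_cm3 = tbv,
                     wmv_cm3 = wmv, tract = tr,
                     n_streamlines = length(bun), volume_cm3 = vol,
                     vol_pct_tbv = normalizeVolume(vol, tbv),
                     vol_pct_wmv = normalizeVolume(vol, wmv),
                     stringsAsFactors = FALSE),
          as.data.frame(t(mets)), as.data.frame(t(shp)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
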