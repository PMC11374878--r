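#' @include csa.R streamlines.R
NULL

#' Probabilistic tracking parameters
#'
#' Constructor for [TrackingParams-class] with the standard defaults:
#' 8 seeds per voxel, 30 degree aperture, 0.3 mm step, 1.25-300 mm retained
#' length range, temperature 1.
#'
#' @param seedsPerVoxel,apertureDeg,stepMm,minLenMm,maxLenMm,temperature,seed
#'   see [TrackingParams-class].
#' @return A [TrackingParams-class].
#' @export
trackingParams <- function(seedsPerVoxel = 8L, apertureDeg = 30,
                           stepMm = 0.3, minLenMm = 1.25, maxLenMm = 300,
                           temperature = 1, seed = 1L) {
  new("TrackingParams", seedsPerVoxel = as.integer(seedsPerVoxel),
      apertureDeg = apertureDeg, stepMm = stepMm, minLenMm = minLenMm,
      maxLenMm = maxLenMm, temperature = temperature,
      seed = as.integer(seed))
}

#' Build the tractography propagation domain
#'
#' Morphological dilation of the white-matter mask by `dilationVoxels`
#' steps of 6-connected dilation. The result is always a superset of the
#' input mask.
#'
#' @param wmMask 3D logical array (non-empty).
#' @param dilationVoxels number of dilation steps (default 1).
#' @return 3D logical array.
#' @export
makePropagationDomain <- function(wmMask, dilationVoxels = 1L) {
  if (!any(wmMask)) stop("the white matter mask is empty")
  m <- wmMask
  d <- dim(m)
  shift <- function(a, ax, by) {
    out <- array(FALSE, d)
    src <- lapply(d, seq_len)
    dst <- src
    if (by > 0) { dst[[ax]] <- (1 + by):d[ax]; src[[ax]] <- 1:(d[ax] - by) }
    else { dst[[ax]] <- 1:(d[ax] + by); src[[ax]] <- (1 - by):d[ax] }
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (it in seq_len(dilationVoxels)) {
    grown <- m
    for (ax in 1:3) {
      if (d[ax] > 1L) grown <- grown | shift(m, ax, 1L) | shift(m, ax, -1L)
    }
    m <- grown
  }
  m
}

#' Whole-volume regularized probabilistic tractography
#'
#' Seeds `seedsPerVoxel` uniformly jittered positions in every propagation
#' domain voxel. The initial direction is drawn over the whole sphere with
#' probability proportional to `odf^(1/T)`; each subsequent direction is
#' drawn the same way but restricted to the aperture cone around the
#' previous step. Trajectories grow forward and backward from the seed in
#' steps of `stepMm`, stop when they leave the domain (or grid) or no
#' candidate direction carries positive ODF mass, and are retained only if
#' their arc length lies within `[minLenMm, maxLenMm]`. Deterministic for a
#' fixed `params@seed`.
#'
#' @param odf an [ODFField-class].
#' @param domain 3D logical propagation domain (see
#'   [makePropagationDomain()]).
#' @param params a [TrackingParams-class].
#' @param nSphere size of the direction tessellation (default 724).
#' @return A [Tractogram-class]; `nSeedsAttempted` records
#'   `seedsPerVoxel * sum(domain)`. An empty domain yields an empty
#'   tractogram with a warning.
#' @export
track <- function(odf, domain, params = trackingParams(),
                  nSphere = 724L, sharpening = 6) {
  validObject(params)
  cf <- shCoefficients(odf)
  d <- dim(cf)[1:3]
  stopifnot(all(dim(domain) == d))
  vox <- which(domain)
  if (!length(vox)) {
    warning("empty propagation domain; returning an empty tractogram")
    return(new("Tractogram", streamlines = list(), seedVoxel = integer(),
               nSeedsAttempted = 0L))
  }
  dirs <- sphereDirections(nSphere)
  basis <- shBasis(dirs, shOrder(odf))
  invA <- solve(odf@affine)

  # Voxelwise ODF minimum for Tuch-style min-max normalization of the
  # sampling law: probabilities are proportional to
  # (odf - odf_min)^(1/T), which sharpens the broad constant-solid-angle
  # profile without changing its maxima.
  nc4 <- dim(cf)[4]
  M <- matrix(cf, prod(d), nc4)
  odfMin <- array(0, d)
  nz <- which(rowSums(abs(M)) > 0)
  if (length(nz)) {
    V <- M[nz, , drop = FALSE] %*% t(basis)
    odfMin[nz] <- pmax(apply(V, 1, min), 0)
  }

  idx <- arrayInd(vox, d)
  nSeeds <- length(vox) * params@seedsPerVoxel
  res <- withSeed(params@seed, {
    jitter <- matrix(stats::runif(nSeeds * 3L) - 0.5, nSeeds, 3L)
    idx0 <- idx[rep(seq_along(vox), each = params@seedsPerVoxel), ,
                drop = FALSE] - 1L
    seedsWorld <- t(odf@affine %*% rbind(t(idx0 + jitter), 1))[, 1:3,
                                                               drop = FALSE]
    .trackStreamlines(as.numeric(cf), as.numeric(odfMin),
                      as.integer(c(d, dim(cf)[4])),
                      as.integer(domain), invA, dirs, basis, seedsWorld,
                      params@stepMm, params@apertureDeg,
                      params@temperature, params@minLenMm, params@maxLenMm,
                      sharpening)
  })
  seedVoxLin <- vox[rep(seq_along(vox), each = params@seedsPerVoxel)]
  new("Tractogram", streamlines = res$streamlines,
      seedVoxel = as.integer(seedVoxLin[res$seedIndex]),
      nSeedsAttempted = as.integer(nSeeds))
}
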