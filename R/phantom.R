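#' @include signal.R
NULL

#' Tube bundle geometry with ground-truth microstructure
#'
#' A bundle is a centerline polyline (mm, world coordinates) swept by a tube
#' of constant radius. Voxels whose center falls inside the tube carry the
#' bundle's anisotropic ground truth oriented along the local tangent.
#'
#' @param name bundle name.
#' @param points n x 3 centerline points in mm (use [lineCurve()] /
#'   [arcCurve()]).
#' @param radius tube radius, mm.
#' @param evals tensor eigenvalues (lambda1 >= lambda2 >= lambda3), mm^2/s.
#' @param nuIc,nuIso,kappa NODDI ground truth of the tube tissue.
#' @return A list describing the bundle, for [phantomSpec()].
#' @export
tubeBundle <- function(name, points, radius = 2.5,
                       evals = c(1.7e-3, 0.3e-3, 0.3e-3),
                       nuIc = 0.6, nuIso = 0.1, kappa = 4) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L, nrow(points) >= 2L, radius > 0)
  list(name = name, points = points, radius = radius, evals = evals,
       nuIc = nuIc, nuIso = nuIso, kappa = kappa)
}

#' @rdname tubeBundle
#' @param from,to segment endpoints, mm.
#' @param n number of polyline points.
#' @export
lineCurve <- function(from, to, n = 64L) {
  t <- seq(0, 1, length.out = n)
  cbind(from[1] + t * (to[1] - from[1]),
        from[2] + t * (to[2] - from[2]),
        from[3] + t * (to[3] - from[3]))
}

#' @rdname tubeBundle
#' @param center arc center, mm.
#' @param arcRadius arc radius, mm.
#' @param angles c(start, end) angle, radians.
#' @param plane "xy", "xz" or "yz".
#' @export
arcCurve <- function(center, arcRadius, angles = c(0, pi), plane = "xy",
                     n = 96L) {
  a <- seq(angles[1], angles[2], length.out = n)
  u <- arcRadius * cos(a); v <- arcRadius * sin(a)
  p <- switch(plane,
    xy = cbind(u, v, 0), xz = cbind(u, 0, v), yz = cbind(0, u, v),
    stop("plane must be xy, xz or yz"))
  sweep(p, 2, center, "+")
}

#' Phantom specification
#'
#' @param gridShape 3 integers (default 20 x 20 x 20).
#' @param voxelSize isotropic voxel size, mm (default 1.25).
#' @param bundles list of [tubeBundle()] geometries.
#' @param background list with `diffusivity` (mm^2/s) for the isotropic
#'   out-of-tube signal; background ground truth is free water
#'   (`nuIso = 1`).
#' @param s0 baseline signal (default 100).
#' @param noiseSigma noise SD in signal units (default 0, noiseless).
#' @param noiseModel "rician" (default) or "gaussian".
#' @param signalModel "tensor" (default) or "noddi" forward model in tubes.
#' @param crossingMode allow overlapping tubes (two-orientation voxels).
#' @param seed RNG seed for the noise draw.
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(gridShape = c(20L, 20L, 20L), voxelSize = 1.25,
                        bundles = list(), background = list(diffusivity = 3.0e-3),
                        s0 = 100, noiseSigma = 0,
                        noiseModel = c("rician", "gaussian"),
                        signalModel = c("tensor", "noddi"),
                        crossingMode = FALSE, seed = 1L) {
  new("PhantomSpec", gridShape = as.integer(gridShape),
      voxelSize = voxelSize, bundles = bundles, background = background,
      s0 = s0, noiseSigma = noiseSigma,
      noiseModel = match.arg(noiseModel),
      signalModel = match.arg(signalModel),
      crossingMode = crossingMode, seed = as.integer(seed))
}

#' Build a synthetic multi-shell acquisition from a phantom specification
#'
#' Rasterizes the tube bundles onto the grid, simulates the diffusion signal
#' voxelwise with the chosen forward model, adds seeded noise, and returns
#' the acquisition together with its ground truth, masks and true bundle
#' tractograms.
#'
#' @param spec a [PhantomSpec-class].
#' @param gtab a [GradientTable-class].
#' @param streamsPerBundle number of true streamlines per bundle (the
#'   centerline plus parallel offset copies inside the tube).
#' @return list with elements `dwi` (4D array), `gtab`, `affine`, `truth`
#'   ([MicrostructureField-class]), `brainMask`, `wmMask` (3D logical),
#'   and `bundles` (named list of [Tractogram-class] true bundles).
#' @export
buildPhantom <- function(spec, gtab, streamsPerBundle = 9L) {
  d <- spec@gridShape
  vs <- spec@voxelSize
  A <- defaultAffine(vs)
  nvol <- length(bValues(gtab))
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  centers <- voxelToWorld(A, idx)
  nvox <- nrow(centers)

  label <- integer(nvox)
  orient1 <- matrix(0, nvox, 3)
  orient2 <- matrix(NA_real_, nvox, 3)
  hitCount <- integer(nvox)

  # densify each centerline and find member voxels
  curves <- vector("list", length(spec@bundles))
  for (b in seq_along(spec@bundles)) {
    bun <- spec@bundles[[b]]
    crv <- resamplePolyline(bun$points, step = vs / 4)
    curves[[b]] <- crv
    lims <- apply(crv, 2, range)
    if (any(lims[1, ] < -vs / 2) ||
        any(lims[2, ] > (d - 0.5) * vs))
      stop(sprintf("bundle '%s' does not fit inside the grid", bun$name))
    dmat <- distToPoints(centers, crv)    # nvox: min distance + nearest index
    inside <- dmat$dist <= bun$radius
    tang <- polylineTangents(crv)
    hitCount[inside] <- hitCount[inside] + 1L
    first <- inside & hitCount == 1L
    second <- inside & hitCount == 2L
    if (any(inside & hitCount > 2L))
      stop("more than two overlapping tubes in one voxel is not supported")
    label[first] <- b
    orient1[first, ] <- tang[dmat$nearest[first], , drop = FALSE]
    if (any(second)) {
      if (!spec@crossingMode)
        stop("overlapping tubes with contradictory ground truth; enable crossingMode")
      label[second] <- -1L
      orient2[second, ] <- tang[dmat$nearest[second], , drop = FALSE]
    }
  }

  # per-voxel signal
  dwi <- matrix(0, nvox, nvol)
  bg <- simulateSignalTensor(diag(rep(spec@background$diffusivity, 3)),
                             gtab, spec@s0)
  bgVox <- label == 0L
  dwi[bgVox, ] <- matrix(bg, sum(bgVox), nvol, byrow = TRUE)
  for (b in seq_along(spec@bundles)) {
    bun <- spec@bundles[[b]]
    vox <- which(label == b)
    if (!length(vox)) next
    dwi[vox, ] <- bundleSignal(bun, orient1[vox, , drop = FALSE], gtab,
                               spec@s0, spec@signalModel)
  }
  cross <- which(label == -1L)
  if (length(cross)) {
    # equal-fraction mixture of the two member bundles' single-fiber signals
    memb <- crossingMembers(centers[cross, , drop = FALSE], curves,
                            spec@bundles)
    s1 <- matrix(0, length(cross), nvol); s2 <- s1
    for (b in seq_along(spec@bundles)) {
      bun <- spec@bundles[[b]]
      i1 <- memb$first == b
      if (any(i1)) s1[i1, ] <- bundleSignal(bun,
        orient1[cross[i1], , drop = FALSE], gtab, spec@s0, spec@signalModel)
      i2 <- memb$second == b
      if (any(i2)) s2[i2, ] <- bundleSignal(bun,
        orient2[cross[i2], , drop = FALSE], gtab, spec@s0, spec@signalModel)
    }
    dwi[cross, ] <- (s1 + s2) / 2
  }

  dwi <- withSeed(spec@seed,
                  addNoise(dwi, spec@noiseSigma, spec@noiseModel))

  arr4 <- array(dwi, c(d, nvol))
  toVol <- function(x) array(x, d)
  evals <- array(0, c(d, 3L))
  nuIc <- toVol(0); nuIso <- toVol(0); kap <- toVol(0)
  nuIso[] <- 1; kap[] <- 1e6   # background: free water, no neurites
  evals[, , , ] <- spec@background$diffusivity
  for (b in seq_along(spec@bundles)) {
    bun <- spec@bundles[[b]]
    vox <- label == b | label == -1L   # crossing voxels carry tube tissue
    for (q in 1:3) {
      ev <- array(evals[, , , q], d); ev[vox] <- bun$evals[q]
      evals[, , , q] <- ev
    }
    nuIc[vox] <- bun$nuIc; nuIso[vox] <- bun$nuIso; kap[vox] <- bun$kappa
  }
  orientArr <- array(orient1, c(d, 3L))
  orient2Arr <- if (length(cross)) array(orient2, c(d, 3L)) else NULL
  truth <- new("MicrostructureField", orientation = orientArr,
               orientation2 = orient2Arr, evals = evals, nuIc = nuIc,
               nuIso = nuIso, kappa = kap, label = array(label, d),
               affine = A)

  bundles <- list()
  for (b in seq_along(spec@bundles)) {
    bun <- spec@bundles[[b]]
    bundles[[bun$name]] <- trueBundleTractogram(curves[[b]], bun$radius,
                                                streamsPerBundle)
  }

  list(dwi = arr4, gtab = gtab, affine = A, truth = truth,
       brainMask = array(TRUE, d), wmMask = array(label != 0L, d),
       bundles = bundles)
}

# Signal of a single-bundle voxel set (rows of `orient` are tangents).
bundleSignal <- function(bun, orient, gtab, s0, model) {
  nvol <- length(bValues(gtab))
  out <- matrix(0, nrow(orient), nvol)
  key <- apply(round(orient, 6), 1, paste, collapse = ",")
  for (k in unique(key)) {
    rows <- which(key == k)
    axis <- orient[rows[1], ]
    s <- if (model == "tensor")
      simulateSignalTensor(axialTensor(bun$evals, axis), gtab, s0)
    else
      simulateSignalNoddi(bun$nuIc, bun$nuIso, bun$kappa, axis, gtab, s0)
    out[rows, ] <- matrix(s, length(rows), nvol, byrow = TRUE)
  }
  out
}

# Identify which two bundles claim each crossing voxel (by tube membership).
crossingMembers <- function(pts, curves, bundles) {
  first <- integer(nrow(pts)); second <- integer(nrow(pts))
  for (b in seq_along(bundles)) {
    dmat <- distToPoints(pts, curves[[b]])
    inside <- dmat$dist <= bundles[[b]]$radius
    newFirst <- inside & first == 0L
    first[newFirst] <- b
    second[inside & !newFirst & second == 0L & first != b] <- b
  }
  list(first = first, second = second)
}

# Min distance (and index of nearest point) from each row of `pts` to a
# point cloud `cloud`, chunked to bound memory.
distToPoints <- function(pts, cloud, chunk = 4096L) {
  n <- nrow(pts)
  dist <- numeric(n); nearest <- integer(n)
  cn2 <- rowSums(cloud^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    P <- pts[s:e, , drop = FALSE]
    D2 <- outer(rowSums(P^2), cn2, "+") - 2 * P %*% t(cloud)
    j <- max.col(-D2, ties.method = "first")
    nearest[s:e] <- j
    dist[s:e] <- sqrt(pmax(0, D2[cbind(seq_len(nrow(P)), j)]))
  }
  list(dist = dist, nearest = nearest)
}

# Unit tangents of a polyline (central differences).
polylineTangents <- function(p) {
  n <- nrow(p)
  t <- rbind(p[2, ] - p[1, ],
             p[3:n, , drop = FALSE] - p[1:(n - 2), , drop = FALSE],
             p[n, ] - p[n - 1, ])
  t / sqrt(rowSums(t^2))
}

# Resample a polyline to roughly equidistant points with spacing `step`.
resamplePolyline <- function(p, step) {
  L <- sum(sqrt(rowSums(diff(p)^2)))
  n <- max(2L, ceiling(L / step) + 1L)
  resampleStreamlineN(p, n)
}

# Centerline plus parallel copies filling the tube cross-section on a
# sunflower (golden-angle) pattern, so the true bundle covers the tube
# roughly uniformly.
trueBundleTractogram <- function(curve, radius, nStreams) {
  sl <- list(curve)
  if (nStreams > 1L) {
    tang <- polylineTangents(curve)
    # frame normal to the mean tangent
    m <- colMeans(tang); m <- m / sqrt(sum(m^2))
    u <- if (abs(m[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- u - sum(u * m) * m; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(m[2] * e1[3] - m[3] * e1[2], m[3] * e1[1] - m[1] * e1[3],
            m[1] * e1[2] - m[2] * e1[1])
    nOff <- nStreams - 1L
    i <- seq_len(nOff)
    rr <- 0.95 * radius * sqrt(i / nOff)
    ang <- pi * (1 + sqrt(5)) * i
    for (a in i) {
      off <- rr[a] * (cos(ang[a]) * e1 + sin(ang[a]) * e2)
      sl[[a + 1L]] <- sweep(curve, 2, off, "+")
    }
  }
  new("Tractogram", streamlines = sl,
      seedVoxel = rep(NA_integer_, length(sl)))
}
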