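#' @include gradient.R utils.R
NULL

# Real even spherical-harmonic basis evaluated at unit directions.
# Index order: l = 0, 2, ..., L; within l, m = -l..l. Normalized so the
# basis is orthonormal on the sphere.
shBasis <- function(dirs, L) {
  dirs <- as.matrix(dirs)
  theta <- acos(pmin(1, pmax(-1, dirs[, 3])))
  phi <- atan2(dirs[, 2], dirs[, 1])
  n <- nrow(dirs)
  nc <- (L + 1) * (L + 2) / 2
  B <- matrix(0, n, nc)
  j <- 1L
  ct <- cos(theta)
  for (l in seq(0L, L, by = 2L)) {
    P <- pracma::legendre(l, ct)           # (l+1) x n, m = 0..l rows
    if (is.null(dim(P))) P <- matrix(P, 1L, n)
    for (m in -l:l) {
      am <- abs(m)
      N <- sqrt((2 * l + 1) / (4 * pi) *
                exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      Plm <- P[am + 1L, ]
      B[, j] <- if (m < 0) sqrt(2) * N * Plm * cos(am * phi)
                else if (m == 0) N * Plm
                else sqrt(2) * N * Plm * sin(m * phi)
      j <- j + 1L
    }
  }
  B
}

# Degree of each basis coefficient.
shDegrees <- function(L) {
  unlist(lapply(seq(0L, L, by = 2L), function(l) rep(l, 2L * l + 1L)))
}

# Legendre polynomial at zero: P_l(0) = (-1)^(l/2) (l-1)!! / l!! for even l.
legendreAtZero <- function(l) {
  if (l == 0L) return(1)
  k <- l / 2
  (-1)^k * exp(lgamma(l + 1) - 2 * k * log(2) - 2 * lgamma(k + 1))
}

#' Fit constant-solid-angle Q-ball ODFs
#'
#' Analytical Q-ball reconstruction in constant solid angle: per shell, the
#' normalized signal E is clamped to `[delta, 1 - delta]`, the double-log
#' transform `log(-log(E))` is expanded in the real even spherical-harmonic
#' basis with Laplace-Beltrami regularization, and the ODF coefficients
#' follow from the Funk-Radon transform (Legendre eigenvalues) combined
#' with the spherical Laplacian. Multi-shell acquisitions are combined by
#' averaging the per-shell ODF coefficients with equal weights.
#'
#' @param dwi 4D signal array.
#' @param gtab a [GradientTable-class]; each shell needs at least
#'   `(shOrder+1)(shOrder+2)/2` directions.
#' @param mask 3D logical array (default: all voxels).
#' @param shOrder even spherical-harmonic order, 4-8 (default 8).
#' @param affine 4 x 4 voxel-to-world matrix.
#' @param lambda Laplace-Beltrami regularization weight (default 0.006).
#' @param delta signal clamp for the double-log transform (default 1e-3).
#' @return An [ODFField-class]. ODF values integrate to 1 over the sphere
#'   (constant-solid-angle normalization); sampling and per-direction
#'   normalization are provided by [sampleOdf()].
#' @export
fitCsaOdf <- function(dwi, gtab, mask = NULL, shOrder = 8L,
                      affine = defaultAffine(1.25), lambda = 0.006,
                      delta = 1e-3) {
  shOrder <- as.integer(shOrder)
  if (shOrder %% 2L != 0L || shOrder < 2L || shOrder > 12L)
    stop("shOrder must be an even integer between 2 and 12")
  d <- dim(dwi)[1:3]
  if (is.null(mask)) mask <- array(TRUE, d)
  nc <- (shOrder + 1L) * (shOrder + 2L) / 2L
  degs <- shDegrees(shOrder)
  lb <- degs * (degs + 1)

  ids <- shellIds(gtab)
  shells <- sort(unique(ids[ids != 0L]))
  vox <- which(mask)
  S <- matrix(aperm(dwi, c(4, 1, 2, 3)), nrow = dim(dwi)[4])[, vox,
                                                             drop = FALSE]
  b0 <- colMeans(S[ids == 0L, , drop = FALSE])
  b0 <- pmax(b0, .Machine$double.eps)

  # ODF transform per degree: FRT (2 pi P_l(0)) and Laplacian (-l(l+1)),
  # scaled by 1/(16 pi^2); constant term 1/(2 sqrt(pi)).
  odfScale <- vapply(degs, function(l)
    if (l == 0L) 0 else -1 / (8 * pi) * legendreAtZero(l) * l * (l + 1),
    numeric(1))

  coefSum <- matrix(0, nc, length(vox))
  for (s in shells) {
    sel <- ids == s
    if (sum(sel) < nc)
      stop(sprintf("shell %d has %d directions; need >= %d for shOrder %d",
                   s, sum(sel), nc, shOrder))
    B <- shBasis(t(bVectors(gtab)[, sel, drop = FALSE]), shOrder)
    fitMat <- solve(crossprod(B) + lambda * diag(lb^2), t(B))
    E <- sweep(S[sel, , drop = FALSE], 2, b0, "/")
    E <- pmin(pmax(E, delta), 1 - delta)
    y <- log(-log(E))
    cf <- fitMat %*% y
    cf <- cf * odfScale
    cf[1, ] <- 1 / (2 * sqrt(pi))
    coefSum <- coefSum + cf
  }
  coefSum <- coefSum / length(shells)

  coefs <- array(0, c(d, nc))
  for (q in seq_len(nc)) {
    v <- array(0, d); v[vox] <- coefSum[q, ]; coefs[, , , q] <- v
  }
  new("ODFField", coefficients = coefs, shOrder = shOrder, affine = affine)
}

#' Sample an ODF field on a direction set
#'
#' Evaluates the spherical-harmonic expansion at the given directions,
#' clamps negative lobes to zero, and (optionally) normalizes each voxel's
#' samples to sum to 1.
#'
#' @param odf an [ODFField-class], or a numeric coefficient vector for a
#'   single voxel.
#' @param dirs m x 3 unit direction matrix (default: 724-point spherical
#'   Fibonacci set).
#' @param normalize divide each voxel's samples by their sum (default TRUE).
#' @return For a field: nvox x m matrix (voxels in array order, restricted
#'   to voxels with any non-zero coefficient... all voxels are returned).
#'   For a single coefficient vector: length-m numeric vector.
#' @export
sampleOdf <- function(odf, dirs = sphereDirections(724L), normalize = TRUE) {
  if (is.numeric(odf) && is.null(dim(odf))) {
    L <- shOrderFromCount(length(odf))
    v <- as.numeric(shBasis(dirs, L) %*% odf)
    v <- pmax(v, 0)
    if (normalize && sum(v) > 0) v <- v / sum(v)
    return(v)
  }
  cf <- shCoefficients(odf)
  d <- dim(cf)
  M <- matrix(cf, prod(d[1:3]), d[4])
  V <- M %*% t(shBasis(dirs, shOrder(odf)))
  V <- pmax(V, 0)
  if (normalize) {
    rs <- rowSums(V)
    rs[rs == 0] <- 1
    V <- V / rs
  }
  V
}

shOrderFromCount <- function(nc) {
  L <- (sqrt(8 * nc + 1) - 3) / 2
  if (abs(L - round(L)) > 1e-9) stop("invalid SH coefficient count")
  as.integer(round(L))
}

#' Generalized fractional anisotropy of an ODF field
#'
#' `GFA = std(psi) / rms(psi)` over the sampled ODF values per voxel
#' (population standard deviation), 0 for a uniform or all-zero ODF and
#' approaching 1 for a one-hot ODF.
#'
#' @param odf an [ODFField-class].
#' @param dirs sampling direction set (>= 60 directions; default 724).
#' @return A [ScalarMap-class] named "GFA" with values in `[0, 1]`.
#' @export
gfa <- function(odf, dirs = sphereDirections(724L)) {
  if (nrow(dirs) < 60L) stop("GFA needs a direction set with >= 60 points")
  V <- sampleOdf(odf, dirs, normalize = TRUE)
  n <- ncol(V)
  mu <- rowMeans(V)
  varp <- rowMeans(V^2) - mu^2
  rms2 <- rowMeans(V^2)
  g <- ifelse(rms2 > 0, sqrt(pmax(0, varp) / rms2), 0)
  d <- dim(shCoefficients(odf))[1:3]
  new("ScalarMap", data = array(g, d), affine = odf@affine,
      metric = "GFA", units = "1")
}

#' ODF peak directions of a single voxel
#'
#' Dense-sampling local maxima: directions whose sampled value is maximal
#' within `minSeparation` degrees and at least `relThreshold` of the global
#' maximum. Antipodal duplicates are merged.
#'
#' @param coeffs SH coefficient vector of one voxel.
#' @param dirs dense sampling set (default 724 directions).
#' @param relThreshold relative peak threshold (default 0.5).
#' @param minSeparation minimum angular separation in degrees (default 25).
#' @return matrix of peak directions (rows), strongest first.
#' @export
odfPeaks <- function(coeffs, dirs = sphereDirections(724L),
                     relThreshold = 0.5, minSeparation = 25) {
  v <- sampleOdf(coeffs, dirs, normalize = FALSE)
  ord <- order(v, decreasing = TRUE)
  peaks <- integer(0)
  for (i in ord) {
    if (v[i] < relThreshold * v[ord[1]]) break
    if (length(peaks)) {
      ang <- axialAngleDeg(dirs[peaks, , drop = FALSE], dirs[i, ])
      if (any(ang < minSeparation)) next
    }
    peaks <- c(peaks, i)
  }
  dirs[peaks, , drop = FALSE]
}
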