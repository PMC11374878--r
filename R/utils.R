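#' @include AllClasses.R
NULL

# Run `expr` under a private RNG stream, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Default phantom affine: RAS mm, voxel (1,1,1) center at the origin.
defaultAffine <- function(voxelSize) {
  A <- diag(c(rep(voxelSize, 3L), 1))
  A
}

# 1-based voxel indices (n x 3) -> world mm (n x 3).
voxelToWorld <- function(affine, idx) {
  idx <- rbind(t(idx - 1), 1)
  t(affine %*% idx)[, 1:3, drop = FALSE]
}

# world mm (n x 3) -> continuous 1-based voxel coordinates (n x 3).
worldToVoxel <- function(affine, pts) {
  pts <- rbind(t(pts), 1)
  t(solve(affine) %*% pts)[, 1:3, drop = FALSE] + 1
}

#' Spherical Fibonacci direction set
#'
#' `n` approximately uniformly distributed unit vectors on the sphere from
#' the golden-angle spiral, optionally rotated by a seeded random rotation
#' (so repeated calls with different seeds give distinct but equally uniform
#' sets).
#'
#' @param n number of directions.
#' @param seed optional integer; when given, the set is rotated by a random
#'   rotation drawn deterministically from this seed.
#' @return n x 3 matrix of unit row vectors.
#' @export
sphereDirections <- function(n, seed = NULL) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  if (!is.null(seed)) {
    R <- withSeed(seed, randomRotation())
    dirs <- dirs %*% t(R)
  }
  dirs
}

# Hemisphere Fibonacci spiral: n directions with z > 0, approximately
# uniform as *axial* directions (diffusion gradients are antipodally
# symmetric, so sampling designs live on the hemisphere).
hemisphereDirections <- function(n, seed = NULL) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - i / n
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  if (!is.null(seed)) {
    R <- withSeed(seed, randomRotation())
    dirs <- dirs %*% t(R)
  }
  dirs
}

# Uniform random rotation matrix (QR of a Gaussian matrix, det +1).
randomRotation <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Trilinear interpolation of a 3D array at continuous 1-based voxel
# coordinates (n x 3). Out-of-grid points are clamped to the edge voxel
# centers unless `outside = "error"`.
trilinear <- function(vol, vox, outside = c("clamp", "error")) {
  outside <- match.arg(outside)
  d <- dim(vol)
  if (outside == "error") {
    # tolerate the outer half-voxel rim (inside the field of view, beyond
    # the last voxel center); values there clamp to the edge
    bad <- vox[, 1] < 0.5 | vox[, 1] > d[1] + 0.5 |
           vox[, 2] < 0.5 | vox[, 2] > d[2] + 0.5 |
           vox[, 3] < 0.5 | vox[, 3] > d[3] + 0.5
    if (any(bad)) {
      ex <- apply(vox[bad, , drop = FALSE], 2, range)
      stop(sprintf(
        "points outside map support: x %.2f..%.2f, y %.2f..%.2f, z %.2f..%.2f (grid %dx%dx%d)",
        ex[1, 1], ex[2, 1], ex[1, 2], ex[2, 2], ex[1, 3], ex[2, 3],
        d[1], d[2], d[3]))
    }
  }
  x <- pmin(pmax(vox[, 1], 1), d[1])
  y <- pmin(pmax(vox[, 2], 1), d[2])
  z <- pmin(pmax(vox[, 3], 1), d[3])
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L)
  z0 <- pmin(floor(z), d[3] - 1L)
  if (d[1] == 1L) x0 <- rep(1, length(x))
  if (d[2] == 1L) y0 <- rep(1, length(y))
  if (d[3] == 1L) z0 <- rep(1, length(z))
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
  at <- function(i, j, k) vol[cbind(i, j, k)]
  v000 <- at(x0, y0, z0); v100 <- at(x1, y0, z0)
  v010 <- at(x0, y1, z0); v110 <- at(x1, y1, z0)
  v001 <- at(x0, y0, z1); v101 <- at(x1, y0, z1)
  v011 <- at(x0, y1, z1); v111 <- at(x1, y1, z1)
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
  (v010 * (1 - fx) + v110 * fx) * fy * (1 - fz) +
  (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
  (v011 * (1 - fx) + v111 * fx) * fy * fz
}

# Angle in degrees between unit vectors a (n x 3) and b (3-vector or n x 3),
# folded to [0, 90] (fiber orientations are axial).
axialAngleDeg <- function(a, b) {
  if (is.null(dim(b))) b <- matrix(b, nrow(a), 3, byrow = TRUE)
  d <- abs(rowSums(a * b))
  acos(pmin(1, d)) * 180 / pi
}

stopifnotPositive <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("%s must be positive", what), call. = FALSE)
}
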