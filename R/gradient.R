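#' @include AllClasses.R utils.R
NULL

#' Construct a gradient table
#'
#' @param bvals numeric b-values, s/mm^2.
#' @param bvecs 3 x n (or n x 3) matrix of directions; b = 0 entries may be
#'   zero vectors. Non-zero vectors are normalized to unit length.
#' @param b0Threshold b-values at or below this are treated as b = 0
#'   (default 50 s/mm^2).
#' @param shellTolerance b-values within this of a shell center belong to
#'   that shell (default 50 s/mm^2).
#' @return A [GradientTable-class].
#' @export
gradientTable <- function(bvals, bvecs, b0Threshold = 50,
                          shellTolerance = 50) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L && ncol(bvecs) == 3L) bvecs <- t(bvecs)
  if (nrow(bvecs) != 3L) stop("bvecs must be 3 x n or n x 3")
  if (ncol(bvecs) != length(bvals))
    stop(sprintf("gradient count mismatch: %d b-values vs %d vectors",
                 length(bvals), ncol(bvecs)))
  if (any(bvals < 0)) stop("b-values must be non-negative")
  nrm <- sqrt(colSums(bvecs^2))
  nz <- nrm > 0
  bvecs[, nz] <- sweep(bvecs[, nz, drop = FALSE], 2, nrm[nz], "/")
  ids <- detectShells(bvals, b0Threshold, shellTolerance)
  bvecs[, ids == 0L] <- 0
  new("GradientTable", bvals = bvals, bvecs = bvecs, shellIds = ids)
}

# Cluster b-values into shells by tolerance; shell 0 is b <= b0Threshold.
detectShells <- function(bvals, b0Threshold = 50, tol = 50) {
  ids <- integer(length(bvals))
  dw <- which(bvals > b0Threshold)
  if (length(dw)) {
    centers <- numeric(0)
    ord <- dw[order(bvals[dw])]
    for (i in ord) {
      hit <- which(abs(centers - bvals[i]) <= tol)
      if (length(hit)) {
        ids[i] <- hit[1]
      } else {
        centers <- c(centers, bvals[i])
        ids[i] <- length(centers)
      }
    }
  }
  ids
}

# Mean b-value per shell id (named numeric, excluding the b0 shell).
shellBValues <- function(gtab) {
  dw <- shellIds(gtab) != 0L
  vapply(split(bValues(gtab)[dw], shellIds(gtab)[dw]), mean, numeric(1))
}

#' Generate a multi-shell acquisition scheme
#'
#' Builds a gradient table with `nB0` non-diffusion-weighted volumes followed
#' by `dirsPerShell` approximately uniformly distributed directions for each
#' requested shell. Directions come from a spherical Fibonacci set with a
#' seeded random rotation per shell, so sets are reproducible and distinct
#' across shells.
#'
#' @param dirsPerShell directions per shell (>= 6).
#' @param shellBvalues distinct positive b-values, s/mm^2.
#' @param nB0 number of b = 0 volumes (>= 1).
#' @param seed RNG seed for the per-shell rotations.
#' @return A [GradientTable-class] with `nB0 + dirsPerShell * length(shellBvalues)`
#'   entries.
#' @examples
#' gtab <- makeGradientTable(90, c(1000, 2000, 3000), 6, seed = 0)
#' length(bValues(gtab))  # 276
#' @export
makeGradientTable <- function(dirsPerShell, shellBvalues, nB0 = 6L,
                              seed = 0L) {
  if (dirsPerShell < 6L) stop("dirsPerShell must be >= 6")
  if (nB0 < 1L) stop("at least one b = 0 volume is required")
  stopifnotPositive(shellBvalues, "shell b-values")
  if (anyDuplicated(shellBvalues)) stop("shell b-values must be distinct")
  bvals <- rep(0, nB0)
  bvecs <- matrix(0, 3, nB0)
  for (k in seq_along(shellBvalues)) {
    dirs <- hemisphereDirections(dirsPerShell, seed = as.integer(seed) + k)
    bvals <- c(bvals, rep(shellBvalues[k], dirsPerShell))
    bvecs <- cbind(bvecs, t(dirs))
  }
  gradientTable(bvals, bvecs)
}
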