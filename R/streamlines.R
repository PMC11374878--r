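#' @include utils.R
NULL

#' Streamline arc length
#'
#' Sum of consecutive Euclidean point distances, mm.
#'
#' @param s n x 3 matrix of ordered points (n >= 2).
#' @return length in mm.
#' @export
streamlineLength <- function(s) {
  s <- as.matrix(s)
  if (nrow(s) < 2L) stop("a streamline needs at least 2 points")
  sum(sqrt(rowSums(diff(s)^2)))
}

# Cumulative arc length per point (starting at 0).
cumArcLength <- function(s) c(0, cumsum(sqrt(rowSums(diff(s)^2))))

# Linear interpolation of a polyline at arc-length positions `at`.
interpAtArc <- function(s, at) {
  cl <- cumArcLength(s)
  cbind(stats::approx(cl, s[, 1], xout = at, rule = 2)$y,
        stats::approx(cl, s[, 2], xout = at, rule = 2)$y,
        stats::approx(cl, s[, 3], xout = at, rule = 2)$y)
}

#' Resample a streamline at a fixed arc-length step
#'
#' Equidistant arc-length resampling. Points are placed at 0, step,
#' 2*step, ... along the streamline; the original end point is always kept,
#' so arc length is preserved to within one step and both endpoints are
#' exact.
#'
#' @param s n x 3 point matrix (n >= 2).
#' @param step sampling step, mm (default 0.1, the along-tract metric
#'   sampling step).
#' @return m x 3 matrix of resampled points.
#' @export
resampleStreamline <- function(s, step = 0.1) {
  s <- as.matrix(s)
  if (step <= 0) stop("step must be > 0")
  if (nrow(s) < 2L) stop("a streamline needs at least 2 points")
  L <- streamlineLength(s)
  if (L <= 0) stop("degenerate zero-length streamline")
  at <- seq(0, L, by = step)
  if (at[length(at)] < L - 1e-9) at <- c(at, L)
  out <- interpAtArc(s, at)
  out[1, ] <- s[1, ]
  out[nrow(out), ] <- s[nrow(s), ]
  out
}

# Resample to exactly n equidistant points (endpoints preserved).
resampleStreamlineN <- function(s, n) {
  s <- as.matrix(s)
  L <- streamlineLength(s)
  out <- interpAtArc(s, seq(0, L, length.out = n))
  out[1, ] <- s[1, ]
  out[n, ] <- s[nrow(s), ]
  out
}

#' Flip-symmetrized maximum corresponding-point streamline distance
#'
#' Both streamlines are resampled to `nPoints` equidistant points; the
#' distance is the maximum over corresponding points of the Euclidean
#' distance, taken in direct and flipped point order, and the smaller of the
#' two is returned. This is symmetric, non-negative, and zero exactly when
#' the resampled point sequences coincide up to orientation.
#'
#' @param a,b point matrices (n x 3).
#' @param nPoints number of resampled points (default 21).
#' @param resample set to FALSE when both inputs already have exactly
#'   `nPoints` points (they are then compared as given).
#' @return distance in mm.
#' @export
streamlineDistance <- function(a, b, nPoints = 21L, resample = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (resample) {
    a <- resampleStreamlineN(a, nPoints)
    b <- resampleStreamlineN(b, nPoints)
  } else if (nrow(a) != nPoints || nrow(b) != nPoints) {
    stop(sprintf("point counts (%d, %d) do not match nPoints = %d",
                 nrow(a), nrow(b), nPoints))
  }
  dDirect <- max(sqrt(rowSums((a - b)^2)))
  dFlip <- max(sqrt(rowSums((a - b[nPoints:1, , drop = FALSE])^2)))
  min(dDirect, dFlip)
}
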