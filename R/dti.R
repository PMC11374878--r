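#' @include gradient.R utils.R
NULL

#' Fit the diffusion tensor model
#'
#' Weighted linear least squares on the log signal (one IRLS pass with
#' squared-predicted-signal weights on top of an ordinary LLS start),
#' restricted to the b = 0 and b = 1000 s/mm^2 volumes: quantitative tensor
#' metrics are computed from the innermost shell only, whatever else was
#' acquired. Non-positive signals are clamped to a small fraction of the
#' voxel b0 before the log (counted in `qc`).
#'
#' @param dwi 4D signal array (x, y, z, volume).
#' @param gtab a [GradientTable-class].
#' @param mask 3D logical array of voxels to fit (default: all).
#' @param affine 4 x 4 voxel-to-world matrix.
#' @param shellB b-value of the shell used for the fit (default 1000
#'   s/mm^2; matched within +/- 50).
#' @return A [TensorFit-class].
#' @export
fitDti <- function(dwi, gtab, mask = NULL, affine = defaultAffine(1.25),
                   shellB = 1000) {
  d <- dim(dwi)[1:3]
  if (is.null(mask)) mask <- array(TRUE, d)
  b <- bValues(gtab)
  use <- shellIds(gtab) == 0L | abs(b - shellB) <= 50
  if (!any(shellIds(gtab)[use] != 0L))
    stop(sprintf("no b = %g shell in the gradient table", shellB))
  if (sum(use & shellIds(gtab) != 0L) < 6L)
    stop("insufficient data: need at least 6 diffusion-weighted directions")
  b <- b[use]
  g <- bVectors(gtab)[, use, drop = FALSE]
  b[shellIds(gtab)[use] == 0L] <- 0
  # log S = log S0 - b g' D g ; design over (log S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
  X <- cbind(1, -b * g[1, ]^2, -b * g[2, ]^2, -b * g[3, ]^2,
             -2 * b * g[1, ] * g[2, ], -2 * b * g[1, ] * g[3, ],
             -2 * b * g[2, ] * g[3, ])

  vox <- which(mask)
  nvox <- length(vox)
  S <- matrix(aperm(dwi, c(4, 1, 2, 3)), nrow = dim(dwi)[4])[use, vox,
                                                             drop = FALSE]
  clamped <- 0L
  b0ref <- pmax(colMeans(S[b == 0, , drop = FALSE]), .Machine$double.eps)
  floorS <- matrix(1e-6 * b0ref, nrow(S), ncol(S), byrow = TRUE)
  bad <- S <= 0
  clamped <- sum(bad)
  S[bad] <- floorS[bad]
  Y <- log(S)

  XtXinv <- solve(crossprod(X))
  beta <- XtXinv %*% crossprod(X, Y)            # OLS start, all voxels at once
  # one IRLS pass: weights = predicted squared signal
  tensor <- matrix(0, nvox, 6L)
  s0 <- numeric(nvox)
  evals <- matrix(0, nvox, 3L)
  evec1 <- matrix(0, nvox, 3L)
  negClamped <- 0L
  for (i in seq_len(nvox)) {
    w <- exp(2 * (X %*% beta[, i]))
    XtW <- t(X * as.numeric(w))
    bb <- tryCatch(solve(XtW %*% X, XtW %*% Y[, i]),
                   error = function(e) beta[, i])
    s0[i] <- exp(bb[1])
    tensor[i, ] <- bb[2:7]
    D <- matrix(c(bb[2], bb[5], bb[6],
                  bb[5], bb[3], bb[7],
                  bb[6], bb[7], bb[4]), 3, 3)
    e <- eigen(D, symmetric = TRUE)
    ev <- e$values
    if (any(ev < 0)) negClamped <- negClamped + 1L
    evals[i, ] <- pmax(ev, 0)
    evec1[i, ] <- e$vectors[, 1]
  }

  pack <- function(m) {
    out <- array(0, c(d, ncol(m)))
    for (q in seq_len(ncol(m))) {
      v <- array(0, d); v[vox] <- m[, q]; out[, , , q] <- v
    }
    out
  }
  s0v <- array(0, d); s0v[vox] <- s0
  new("TensorFit", tensor = pack(tensor), evals = pack(evals),
      evec1 = pack(evec1), s0 = s0v, mask = mask, affine = affine,
      qc = list(clampedSignals = clamped, clampedEigenvalues = negClamped,
                shellB = shellB))
}

#' Scalar maps from a tensor fit
#'
#' Computes the four tensor-derived maps from the (clamped) eigenvalues:
#' mean diffusivity `MD = (l1+l2+l3)/3`, axial diffusivity `AD = l1`,
#' radial diffusivity `RD = (l2+l3)/2`, and fractional anisotropy
#' `FA = sqrt(3/2 * sum((li - MD)^2) / sum(li^2))` (0 for an all-zero
#' tensor).
#'
#' @param fit a [TensorFit-class].
#' @return named list of four [ScalarMap-class] objects: `fa`, `md`, `ad`,
#'   `rd`.
#' @export
tensorScalars <- function(fit) {
  d <- dim(fit@evals)[1:3]
  l1 <- array(fit@evals[, , , 1], d)
  l2 <- array(fit@evals[, , , 2], d)
  l3 <- array(fit@evals[, , , 3], d)
  md <- (l1 + l2 + l3) / 3
  ad <- l1
  rd <- (l2 + l3) / 2
  ss <- l1^2 + l2^2 + l3^2
  num <- (l1 - md)^2 + (l2 - md)^2 + (l3 - md)^2
  fa <- ifelse(ss > 0, sqrt(1.5 * num / ss), 0)
  mk <- function(x, nm, un) new("ScalarMap", data = x, affine = fit@affine,
                                metric = nm, units = un)
  list(fa = mk(fa, "FA", "1"), md = mk(md, "MD", "mm^2/s"),
       ad = mk(ad, "AD", "mm^2/s"), rd = mk(rd, "RD", "mm^2/s"))
}
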