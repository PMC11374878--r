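#' @include gradient.R
NULL

# Fixed NODDI diffusivities (mm^2/s), the conventional in-vivo values.
NODDI_D_PAR <- 1.7e-3
NODDI_D_ISO <- 3.0e-3

# Quadrature set for Watson orientation averages, built once per session.
watsonQuadCache <- new.env(parent = emptyenv())
watsonQuadrature <- function(n = 3072L) {
  key <- as.character(n)
  if (is.null(watsonQuadCache[[key]]))
    watsonQuadCache[[key]] <- sphereDirections(n)
  watsonQuadCache[[key]]
}

# Watson weights on a direction set: w_j proportional to exp(kappa (mu.n_j)^2),
# normalized to sum to 1 (equal-area quadrature).
watsonWeights <- function(mu, kappa, dirs) {
  c2 <- as.numeric(dirs %*% mu)^2
  w <- exp(kappa * (c2 - max(c2)))   # stable at large kappa
  w / sum(w)
}

# Watson second moment tau1 = E[(mu.n)^2].
watsonTau1 <- function(kappa, dirs = watsonQuadrature()) {
  mu <- c(0, 0, 1)
  w <- watsonWeights(mu, kappa, dirs)
  sum(w * dirs[, 3]^2)
}

#' Diffusion tensor forward signal
#'
#' Single-tensor signal law `S_i = s0 * exp(-b_i g_i' D g_i)`; b = 0 entries
#' return `s0` exactly.
#'
#' @param tensor symmetric 3 x 3 diffusion tensor, mm^2/s; must be positive
#'   semi-definite.
#' @param gtab a [GradientTable-class].
#' @param s0 non-diffusion-weighted signal (default 1).
#' @return numeric signal vector, one value per gradient entry.
#' @export
simulateSignalTensor <- function(tensor, gtab, s0 = 1) {
  tensor <- as.matrix(tensor)
  if (!all(dim(tensor) == c(3L, 3L)) || any(abs(tensor - t(tensor)) > 1e-12))
    stop("tensor must be a symmetric 3 x 3 matrix")
  ev <- eigen(tensor, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-12 * max(abs(ev), 1e-30)))
    stop("tensor must be positive semi-definite (negative eigenvalue)")
  g <- bVectors(gtab)
  q <- colSums(g * (tensor %*% g))     # g' D g per volume
  s <- s0 * exp(-bValues(gtab) * q)
  s[shellIds(gtab) == 0L] <- s0
  s
}

#' NODDI three-compartment forward signal
#'
#' Watson-dispersed sticks (intracellular), a tortuosity-coupled zeppelin
#' (extracellular, `d_perp = d_par * (1 - nuIc)`) averaged over the same
#' Watson distribution, and an isotropic ball (free water):
#' `S = s0 * (nuIso * ball + (1 - nuIso) * (nuIc * stick + (1 - nuIc) * zeppelin))`.
#' The stick orientation average is computed by spherical quadrature; the
#' zeppelin average uses the Watson second moment (dispersion-averaged
#' tensor). b = 0 entries return `s0` exactly.
#'
#' @param nuIc intracellular (neurite) volume fraction of the tissue
#'   compartment, in `[0, 1]`.
#' @param nuIso isotropic (free water) volume fraction, in `[0, 1]`.
#' @param kappa Watson concentration, > 0.
#' @param mu mean neurite orientation (unit 3-vector).
#' @param gtab a [GradientTable-class].
#' @param s0 baseline signal (default 1).
#' @param dPar intrinsic parallel diffusivity, mm^2/s.
#' @param dIso free water diffusivity, mm^2/s.
#' @param nQuad Watson quadrature size (default 3072 directions).
#' @return numeric signal vector, one value per gradient entry.
#' @export
simulateSignalNoddi <- function(nuIc, nuIso, kappa, mu, gtab, s0 = 1,
                                dPar = NODDI_D_PAR, dIso = NODDI_D_ISO,
                                nQuad = 3072L) {
  if (nuIc < 0 || nuIc > 1 || nuIso < 0 || nuIso > 1)
    stop("volume fractions must lie in [0, 1]")
  if (kappa <= 0) stop("kappa must be > 0")
  mu <- mu / sqrt(sum(mu^2))
  b <- bValues(gtab)
  g <- t(bVectors(gtab))               # n x 3
  dirs <- watsonQuadrature(nQuad)
  w <- watsonWeights(mu, kappa, dirs)

  # intracellular: Watson-averaged stick
  C2 <- (g %*% t(dirs))^2              # n x nQuad, (g.n)^2
  stick <- as.numeric(exp(-outer(b, rep(dPar, nrow(dirs))) * C2) %*% w)

  # extracellular: zeppelin with tortuosity, Watson-averaged tensor
  dPerp <- dPar * (1 - nuIc)
  tau1 <- sum(w * as.numeric(dirs %*% mu)^2)
  # <nn'> = tau1 mu mu' + (1 - tau1)/2 (I - mu mu')
  gmu2 <- as.numeric(g %*% mu)^2
  meanC2 <- tau1 * gmu2 + (1 - tau1) / 2 * (1 - gmu2)
  zeppelin <- exp(-b * (dPerp + (dPar - dPerp) * meanC2))

  ball <- exp(-b * dIso)
  s <- s0 * (nuIso * ball + (1 - nuIso) * (nuIc * stick + (1 - nuIc) * zeppelin))
  s[shellIds(gtab) == 0L] <- s0
  s
}

#' Orientation dispersion index from the Watson concentration
#'
#' `ODI = (2/pi) * atan(1/kappa)`: 0 for perfectly parallel neurites
#' (kappa -> Inf), 1 for fully dispersed ones (kappa -> 0).
#'
#' @param kappa Watson concentration(s), > 0.
#' @return ODI in `[0, 1]`.
#' @export
odiFromKappa <- function(kappa) (2 / pi) * atan(1 / kappa)

# Axially symmetric tensor with given eigenvalues (lambda1 along `axis`).
axialTensor <- function(evals, axis) {
  axis <- axis / sqrt(sum(axis^2))
  P <- outer(axis, axis)
  evals[1] * P + (evals[2] + evals[3]) / 2 * (diag(3) - P)
}

# Add seeded measurement noise to a signal array (last dim = volumes).
addNoise <- function(signal, sigma, model = c("rician", "gaussian")) {
  model <- match.arg(model)
  if (sigma == 0) return(signal)
  n <- length(signal)
  if (model == "gaussian") {
    signal + stats::rnorm(n, 0, sigma)
  } else {
    sqrt((signal + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  }
}
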