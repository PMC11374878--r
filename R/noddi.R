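#' @include signal.R
NULL

# NODDI fitting grids (coarse search stage).
NODDI_GRID_NU <- seq(0, 1, by = 0.1)
NODDI_GRID_KAPPA <- c(0.25, 0.5, 1, 2, 4, 8, 16, 32, 64)
NODDI_GRID_NMU <- 30L

noddiCache <- new.env(parent = emptyenv())

gtabKey <- function(gtab) {
  paste(length(bValues(gtab)), signif(sum(bValues(gtab)), 10),
        signif(sum(abs(bVectors(gtab))), 10), sep = "|")
}

# Precomputed machinery for one gradient table: the stick kernel over the
# Watson quadrature set, the tortuosity-zeppelin pieces and the signal
# dictionary over the coarse grid. Cached per gradient table.
noddiWorkspace <- function(gtab, nQuad = 3072L) {
  key <- gtabKey(gtab)
  if (!is.null(noddiCache[[key]])) return(noddiCache[[key]])
  b <- bValues(gtab)
  b[shellIds(gtab) == 0L] <- 0
  g <- t(bVectors(gtab))                       # nvol x 3
  quad <- watsonQuadrature(nQuad)
  C2 <- (g %*% t(quad))^2                      # nvol x nQuad
  A <- exp(-b * NODDI_D_PAR * C2)              # stick kernel (recycles b by col)
  ball <- exp(-b * NODDI_D_ISO)
  muSet <- sphereDirections(NODDI_GRID_NMU)
  gmu2 <- (g %*% t(muSet))^2                   # nvol x nmu

  tau1 <- vapply(NODDI_GRID_KAPPA, function(k) {
    w <- watsonWeights(c(0, 0, 1), k, quad); sum(w * quad[, 3]^2)
  }, numeric(1))

  # Watson-averaged stick per (kappa, mu)
  W <- matrix(0, nQuad, length(NODDI_GRID_KAPPA) * NODDI_GRID_NMU)
  cnt <- 0L
  for (k in NODDI_GRID_KAPPA) for (m in seq_len(NODDI_GRID_NMU)) {
    cnt <- cnt + 1L
    W[, cnt] <- watsonWeights(muSet[m, ], k, quad)
  }
  stick <- A %*% W                             # nvol x (nkappa*nmu)

  nk <- length(NODDI_GRID_KAPPA); nm <- NODDI_GRID_NMU
  nnu <- length(NODDI_GRID_NU)
  atoms <- matrix(0, length(b), nnu * nnu * nk * nm)
  par <- matrix(0, nnu * nnu * nk * nm, 4L)    # nuIc, nuIso, kappaIdx, muIdx
  col <- 0L
  for (ic in seq_len(nnu)) {
    nuIc <- NODDI_GRID_NU[ic]
    dPerp <- NODDI_D_PAR * (1 - nuIc)
    for (km in seq_len(nk)) {
      meanC2 <- tau1[km] * gmu2 + (1 - tau1[km]) / 2 * (1 - gmu2)
      zep <- exp(-b * (dPerp + (NODDI_D_PAR - dPerp) * meanC2)) # nvol x nmu
      stickBlk <- stick[, ((km - 1L) * nm + 1L):(km * nm), drop = FALSE]
      tissue <- nuIc * stickBlk + (1 - nuIc) * zep
      for (io in seq_len(nnu)) {
        nuIso <- NODDI_GRID_NU[io]
        blk <- nuIso * ball + (1 - nuIso) * tissue
        cols <- col + seq_len(nm)
        atoms[, cols] <- blk
        par[cols, ] <- cbind(nuIc, nuIso, km, seq_len(nm))
        col <- col + nm
      }
    }
  }
  ws <- list(b = b, g = g, quad = quad, A = A, ball = ball, muSet = muSet,
             atoms = atoms, atomNorm2 = colSums(atoms^2), par = par,
             b0sel = shellIds(gtab) == 0L)
  noddiCache[[key]] <- ws
  ws
}

# Forward model using the cached workspace (s0 = 1); identical to
# simulateSignalNoddi with the same quadrature set.
noddiForward <- function(ws, nuIc, nuIso, kappa, mu) {
  w <- watsonWeights(mu, kappa, ws$quad)
  stick <- as.numeric(ws$A %*% w)
  tau1 <- sum(w * as.numeric(ws$quad %*% mu)^2)
  dPerp <- NODDI_D_PAR * (1 - nuIc)
  gmu2 <- as.numeric(ws$g %*% mu)^2
  meanC2 <- tau1 * gmu2 + (1 - tau1) / 2 * (1 - gmu2)
  zep <- exp(-ws$b * (dPerp + (NODDI_D_PAR - dPerp) * meanC2))
  s <- nuIso * ws$ball + (1 - nuIso) * (nuIc * stick + (1 - nuIc) * zep)
  s[ws$b0sel] <- 1
  s
}

#' Fit the NODDI three-compartment model
#'
#' Per voxel: the signal is normalized by its mean b = 0 value, a coarse
#' grid search over (nuIc, nuIso, kappa, mu) against a precomputed signal
#' dictionary picks a starting point, and bounded nonlinear least squares
#' (L-BFGS-B on the sum of squared residuals of the same forward model used
#' by [simulateSignalNoddi()]) refines it. Voxels where refinement fails to
#' improve on the grid fall back to the grid optimum and are flagged in the
#' QC mask.
#'
#' @param dwi 4D signal array.
#' @param gtab a [GradientTable-class] with at least 2 non-zero shells.
#' @param mask 3D logical array (default: all voxels).
#' @param affine 4 x 4 voxel-to-world matrix.
#' @param refine run the nonlinear refinement (default TRUE; FALSE returns
#'   the grid-search optimum, useful for quick passes).
#' @return named list of [ScalarMap-class] maps `ndi` (neurite density,
#'   = nuIc), `iwvf` (isotropic water volume fraction, = nuIso) and `odi`
#'   (orientation dispersion, `(2/pi) atan(1/kappa)`), plus `qcMask`
#'   (3D logical; TRUE where refinement fell back to the grid).
#' @export
fitNoddi <- function(dwi, gtab, mask = NULL, affine = defaultAffine(1.25),
                     refine = TRUE) {
  d <- dim(dwi)[1:3]
  if (is.null(mask)) mask <- array(TRUE, d)
  if (length(unique(shellIds(gtab)[shellIds(gtab) != 0L])) < 2L)
    stop("NODDI needs at least 2 non-zero shells")
  ws <- noddiWorkspace(gtab)
  vox <- which(mask)
  S <- matrix(aperm(dwi, c(4, 1, 2, 3)), nrow = dim(dwi)[4])[, vox,
                                                             drop = FALSE]
  b0 <- pmax(colMeans(S[ws$b0sel, , drop = FALSE]), .Machine$double.eps)
  E <- sweep(S, 2, b0, "/")
  nvox <- length(vox)

  # coarse dictionary search, chunked over voxels
  best <- integer(nvox)
  chunk <- max(1L, floor(2e7 / ncol(ws$atoms)))
  for (s in seq(1L, nvox, by = chunk)) {
    e <- min(s + chunk - 1L, nvox)
    cross <- crossprod(E[, s:e, drop = FALSE], ws$atoms)   # nv x natoms
    sse <- sweep(-2 * cross, 2, ws$atomNorm2, "+")
    best[s:e] <- max.col(-sse, ties.method = "first")
  }

  nuIc <- ws$par[best, 1]; nuIso <- ws$par[best, 2]
  kappa <- NODDI_GRID_KAPPA[ws$par[best, 3]]
  mus <- ws$muSet[ws$par[best, 4], , drop = FALSE]
  qc <- logical(nvox)

  if (refine) {
    for (i in seq_len(nvox)) {
      y <- E[, i]
      gridSse <- sum((noddiForward(ws, nuIc[i], nuIso[i], kappa[i],
                                   mus[i, ]) - y)^2)
      th0 <- acos(pmin(1, pmax(-1, mus[i, 3])))
      ph0 <- atan2(mus[i, 2], mus[i, 1])
      obj <- function(x) {
        mu <- c(sin(x[4]) * cos(x[5]), sin(x[4]) * sin(x[5]), cos(x[4]))
        sum((noddiForward(ws, x[1], x[2], exp(x[3]), mu) - y)^2)
      }
      res <- tryCatch(
        stats::optim(c(nuIc[i], nuIso[i], log(kappa[i]), th0, ph0), obj,
                     method = "L-BFGS-B",
                     lower = c(0, 0, log(0.05), th0 - pi / 2, ph0 - pi / 2),
                     upper = c(1, 1, log(128), th0 + pi / 2, ph0 + pi / 2),
                     control = list(maxit = 50)),
        error = function(e) NULL)
      if (!is.null(res) && res$value <= gridSse) {
        nuIc[i] <- res$par[1]; nuIso[i] <- res$par[2]
        kappa[i] <- exp(res$par[3])
      } else {
        qc[i] <- TRUE
      }
    }
  }

  toMap <- function(v, nm) {
    a <- array(0, d); a[vox] <- v
    new("ScalarMap", data = a, affine = affine, metric = nm, units = "1")
  }
  qcArr <- array(FALSE, d); qcArr[vox] <- qc
  list(ndi = toMap(pmin(pmax(nuIc, 0), 1), "NDI"),
       iwvf = toMap(pmin(pmax(nuIso, 0), 1), "IWVF"),
       odi = toMap(odiFromKappa(kappa), "ODI"),
       qcMask = qcArr)
}
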