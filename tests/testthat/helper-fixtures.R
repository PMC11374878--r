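# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# Full-protocol gradient table: 3 shells x 90 directions + 6 b0.
fullGtab <- function() fixture("fullGtab", function()
  makeGradientTable(90, c(1000, 2000, 3000), 6L, seed = 0L))

# Lighter 3-shell table for fitting tests.
smallGtab <- function() fixture("smallGtab", function()
  makeGradientTable(60, c(1000, 2000, 3000), 6L, seed = 0L))

# Wrap a per-voxel signal vector as a 1x1x1 acquisition.
voxelDwi <- function(signal) array(signal, c(1L, 1L, 1L, length(signal)))

# Noiseless straight tube along x: 20 x 8 x 8 grid, 1.25 mm, radius 2.2 mm.
tubePhantom <- function() fixture("tubePhantom", function() {
  b <- tubeBundle("tube",
                  lineCurve(c(0, 3.75, 3.75), c(23.75, 3.75, 3.75)),
                  radius = 2.2)
  buildPhantom(phantomSpec(gridShape = c(20L, 8L, 8L), bundles = list(b),
                           noiseSigma = 0, seed = 1L), smallGtab())
})

# CSA ODF field of the tube phantom (fit inside the white matter mask).
tubeOdf <- function() fixture("tubeOdf", function() {
  ph <- tubePhantom()
  fitCsaOdf(ph$dwi, smallGtab(), mask = ph$wmMask, shOrder = 8L,
            affine = ph$affine)
})

# A toy cohort with no true group differences.
nullCohort <- function(n = 15L, seed = 1L, tracts = c("a", "b", "c")) {
  simulateCohort(cohortSpec(n, n, tracts, seed = seed))
}

# Random smooth streamline for property tests.
randomStreamline <- function(nPts = 12L, scale = 10) {
  p <- matrix(stats::rnorm(3L * nPts), ncol = 3L)
  apply(p, 2, cumsum) * scale / nPts
}
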