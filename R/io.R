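#' @include gradient.R AllClasses.R
NULL

#' Read / write NIfTI volumes
#'
#' Thin wrappers over RNifti keeping the voxel-to-world affine (RAS mm,
#' 0-based voxel indices) alongside the data array.
#'
#' @param data numeric array (3D or 4D).
#' @param affine 4 x 4 voxel-to-world matrix.
#' @param path file path (.nii or .nii.gz).
#' @return `readVolume` returns `list(data, affine)`; `writeVolume` returns
#'   the path invisibly.
#' @export
writeVolume <- function(data, affine, path) {
  img <- RNifti::asNifti(data, pixdim = sqrt(colSums(affine[1:3, 1:3]^2)))
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  list(data = array(as.numeric(img), dim(img)), affine = unclass(aff))
}

#' Read / write FSL-style gradient tables
#'
#' bval: one whitespace-separated row of b-values; bvec: three rows (x, y,
#' z components).
#'
#' @param gtab a [GradientTable-class].
#' @param bvalPath,bvecPath file paths.
#' @return `readBvalBvec` returns a [GradientTable-class] (non-unit vectors
#'   are normalized with a warning).
#' @export
writeBvalBvec <- function(gtab, bvalPath, bvecPath) {
  writeLines(paste(format(bValues(gtab), trim = TRUE, scientific = FALSE),
                   collapse = " "), bvalPath)
  v <- bVectors(gtab)
  writeLines(apply(v, 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvecPath)
  invisible(NULL)
}

#' @rdname writeBvalBvec
#' @export
readBvalBvec <- function(bvalPath, bvecPath) {
  bvals <- scan(bvalPath, quiet = TRUE)
  bv <- as.matrix(utils::read.table(bvecPath))
  if (nrow(bv) != 3L && ncol(bv) == 3L) bv <- t(bv)
  if (ncol(bv) != length(bvals))
    stop(sprintf("gradient count mismatch: %d b-values vs %d vectors",
                 length(bvals), ncol(bv)))
  nrm <- sqrt(colSums(bv^2))
  nz <- nrm > 0
  if (any(abs(nrm[nz] - 1) > 1e-3))
    warning("non-unit gradient vectors found; normalizing")
  gradientTable(bvals, bv)
}

#' Read a diffusion-weighted acquisition
#'
#' Loads a 4D NIfTI together with its FSL bval/bvec files; shells are
#' auto-detected by clustering b-values within +/- 50 s/mm^2.
#'
#' @param niftiPath 4D NIfTI path.
#' @param bvalPath,bvecPath gradient table paths.
#' @return list with `dwi` (4D array), `affine`, `gtab`.
#' @export
readDwi <- function(niftiPath, bvalPath, bvecPath) {
  vol <- readVolume(niftiPath)
  gtab <- readBvalBvec(bvalPath, bvecPath)
  nvol <- if (length(dim(vol$data)) == 4L) dim(vol$data)[4] else 1L
  if (nvol != length(bValues(gtab)))
    stop(sprintf("volume count (%d) does not match gradient count (%d)",
                 nvol, length(bValues(gtab))))
  list(dwi = vol$data, affine = vol$affine, gtab = gtab)
}

#' @rdname readDwi
#' @param dwi 4D array.
#' @param affine 4 x 4 voxel-to-world matrix.
#' @param gtab a [GradientTable-class].
#' @param prefix output path prefix; writes `<prefix>.nii.gz`,
#'   `<prefix>.bval`, `<prefix>.bvec`.
#' @export
writeDwi <- function(dwi, affine, gtab, prefix) {
  writeVolume(dwi, affine, paste0(prefix, ".nii.gz"))
  writeBvalBvec(gtab, paste0(prefix, ".bval"), paste0(prefix, ".bvec"))
  invisible(prefix)
}

#' Read / write streamline files (TCK and TRK)
#'
#' `writeStreamlines` dispatches on the file extension: `.tck` writes the
#' MRtrix track format, `.trk` the TrackVis format (version 2).
#' Coordinates are world mm (RAS) in both cases; TRK additionally stores
#' (and on reading, undoes) its corner-based voxel-mm convention through
#' the `vox_to_ras` header.
#'
#' @param tractogram a [Tractogram-class].
#' @param path output file (.tck or .trk).
#' @param affine voxel-to-world matrix (TRK only; default 1.25 mm
#'   isotropic).
#' @param dim grid dimensions (TRK only).
#' @return `readStreamlines` returns a [Tractogram-class].
#' @export
writeStreamlines <- function(tractogram, path,
                             affine = defaultAffine(1.25),
                             dim = c(1L, 1L, 1L)) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tck = writeTck(tractogram, path),
         trk = writeTrk(tractogram, path, affine, dim),
         stop(sprintf("unknown streamline format '.%s' (use .tck or .trk)",
                      ext)))
}

#' @rdname writeStreamlines
#' @export
readStreamlines <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tck = readTck(path),
         trk = readTrk(path),
         stop(sprintf("unknown streamline format '.%s' (use .tck or .trk)",
                      ext)))
}

writeTck <- function(tractogram, path) {
  sl <- streamlines(tractogram)
  hdr1 <- "mrtrix tracks"
  lines <- c(sprintf("count: %d", length(sl)), "datatype: Float32LE")
  # compute offset: header lines + "file: . NNN" + END marker
  base <- nchar(hdr1) + 1L + sum(nchar(lines) + 1L) + nchar("END") + 1L
  fileLine <- function(off) sprintf("file: . %d", off)
  off <- base
  repeat {
    total <- base + nchar(fileLine(off)) + 1L
    if (total == off) break
    off <- total
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(c(hdr1, lines, fileLine(off), "END"),
                         collapse = "\n"), "\n"), con, eos = NULL)
  for (s in sl) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(path)
}

readTck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!startsWith(magic, "mrtrix tracks")) stop("not a TCK file")
  off <- NA_integer_
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln) || ln == "END") break
    if (startsWith(ln, "file:"))
      off <- as.integer(sub(".*\\. *", "", ln))
  }
  if (is.na(off)) stop("TCK header lacks a file offset")
  seek(con, off)
  raw <- readBin(con, "numeric", n = file.size(path), size = 4L,
                 endian = "little")
  pts <- matrix(raw, ncol = 3L, byrow = TRUE)
  isNan <- rowSums(is.na(pts)) > 0
  isInf <- is.infinite(pts[, 1])
  sl <- list()
  cur <- integer(0)
  for (i in seq_len(nrow(pts))) {
    if (isInf[i]) break
    if (isNan[i]) {
      if (length(cur) >= 2L)
        sl[[length(sl) + 1L]] <- pts[cur, , drop = FALSE]
      cur <- integer(0)
    } else cur <- c(cur, i)
  }
  if (length(cur) >= 2L) sl[[length(sl) + 1L]] <- pts[cur, , drop = FALSE]
  new("Tractogram", streamlines = sl,
      seedVoxel = rep(NA_integer_, length(sl)))
}

writeTrk <- function(tractogram, path, affine, dim) {
  sl <- streamlines(tractogram)
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  inv <- solve(affine)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("TRACK", con, nchars = 5L, eos = NULL)
  writeBin(raw(1L), con)                             # id_string pad
  writeBin(as.integer(dim), con, size = 2L, endian = "little")
  writeBin(as.numeric(vs), con, size = 4L, endian = "little")
  writeBin(rep(0, 3), con, size = 4L, endian = "little")   # origin
  writeBin(0L, con, size = 2L, endian = "little")          # n_scalars
  writeBin(raw(200L), con)                                 # scalar names
  writeBin(0L, con, size = 2L, endian = "little")          # n_properties
  writeBin(raw(200L), con)                                 # property names
  writeBin(as.numeric(t(affine)), con, size = 4L, endian = "little")
  writeBin(raw(444L), con)                                 # reserved
  writeChar("RAS", con, nchars = 3L, eos = NULL)
  writeBin(raw(1L), con)
  writeBin(raw(4L), con)                                   # pad2
  writeBin(rep(0, 6), con, size = 4L, endian = "little")   # image orient
  writeBin(raw(2L), con)                                   # pad1
  writeBin(raw(6L), con)                                   # invert/swap
  writeBin(length(sl), con, size = 4L, endian = "little")  # n_count
  writeBin(2L, con, size = 4L, endian = "little")          # version
  writeBin(1000L, con, size = 4L, endian = "little")       # hdr_size
  for (s in sl) {
    writeBin(nrow(s), con, size = 4L, endian = "little")
    vox <- t(inv %*% rbind(t(s), 1))[, 1:3, drop = FALSE]  # 0-based voxels
    vmm <- sweep(vox + 0.5, 2, vs, "*")                    # corner voxel-mm
    writeBin(as.numeric(t(vmm)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

readTrk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 5L, useBytes = TRUE)
  if (magic != "TRACK") stop("not a TRK file")
  seek(con, 12L)
  vs <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
  seek(con, 24L)
  readBin(con, "integer", 1L, size = 2L, endian = "little")
  seek(con, 440L)
  M <- matrix(readBin(con, "numeric", 16L, size = 4L, endian = "little"),
              4L, 4L, byrow = TRUE)
  seek(con, 988L)
  nCount <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  version <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdrSize <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (hdrSize != 1000L) stop("unsupported TRK header size")
  if (all(M == 0)) M <- diag(4)
  seek(con, 1000L)
  sl <- list()
  repeat {
    np <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (!length(np)) break
    pts <- matrix(readBin(con, "numeric", np * 3L, size = 4L,
                          endian = "little"), ncol = 3L, byrow = TRUE)
    vox <- sweep(pts, 2, vs, "/") - 0.5
    wld <- t(M %*% rbind(t(vox), 1))[, 1:3, drop = FALSE]
    if (np >= 2L) sl[[length(sl) + 1L]] <- wld
    if (nCount > 0L && length(sl) >= nCount) break
  }
  new("Tractogram", streamlines = sl,
      seedVoxel = rep(NA_integer_, length(sl)))
}

#' Read / write a bundle atlas on disk
#'
#' An atlas is stored as a TCK file of centroid streamlines plus a TSV
#' table with columns `label`, `category`, `hemisphere`, `threshold_mm`
#' (row order matches the TCK).
#'
#' @param atlas a [BundleAtlas-class].
#' @param tckPath,tsvPath file paths.
#' @return `readBundleAtlas` returns a [BundleAtlas-class].
#' @export
writeBundleAtlas <- function(atlas, tckPath, tsvPath) {
  writeTck(new("Tractogram", streamlines = atlasCentroids(atlas),
               seedVoxel = rep(NA_integer_, length(atlasLabels(atlas)))),
           tckPath)
  writeTsv(data.frame(label = atlasLabels(atlas),
                      category = atlas@category,
                      hemisphere = atlas@hemisphere,
                      threshold_mm = atlasThresholds(atlas),
                      stringsAsFactors = FALSE), tsvPath)
  invisible(NULL)
}

#' @rdname writeBundleAtlas
#' @export
readBundleAtlas <- function(tckPath, tsvPath) {
  tab <- readTsv(tsvPath)
  cents <- streamlines(readTck(tckPath))
  if (length(cents) != nrow(tab))
    stop("atlas TCK and TSV disagree on the number of tracts")
  bundleAtlas(tab$label, cents, tab$threshold_mm, tab$category,
              tab$hemisphere)
}

#' Read / write TSV tables
#'
#' Tab-separated tables with a header row, the cohort and comparison
#' interchange format.
#'
#' @param x data.frame.
#' @param path file path.
#' @return `readTsv` returns a data.frame.
#' @export
writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

# Run manifest: package version, configuration, seed and input hashes.
writeManifest <- function(path, config, seed, inputs = character()) {
  hashes <- if (length(inputs))
    as.list(tools::md5sum(inputs[file.exists(inputs)])) else list()
  jsonlite::write_json(
    list(package = "tractometry",
         version = as.character(utils::packageVersion("tractometry")),
         seed = seed, config = config, input_md5 = hashes),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
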