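# Binary crystallographic map (CCP4/MRC) and reflection (MTZ) file I/O.
# Implemented against the published format specifications with readBin /
# writeBin; little-endian IEEE floats throughout (the formats' machine
# stamps are written accordingly and checked on read).

#' Read a CCP4/MRC density map
#'
#' Supports mode-2 (float32) maps whose grid covers exactly one full unit
#' cell along each axis; arbitrary axis orders (MAPC/MAPR/MAPS) and section
#' starts are handled by permutation and cyclic shift. Partial-cell maps are
#' rejected rather than mis-wrapped.
#'
#' @param path file path
#' @return an (unscaled) [DensityMap-class]
#' @export
readCCP4Map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdrInt <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdrFlt <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  ncrs <- hdrInt[1:3]
  mode <- hdrInt[4]
  if (mode != 2L) stop("unsupported map mode: ", mode, " (need 2, float32)")
  start <- hdrInt[5:7]
  nxyz <- hdrInt[8:10]
  cell <- hdrFlt[11:16]
  mapcrs <- hdrInt[17:19]
  nsymbt <- hdrInt[24]
  if (any(sort(mapcrs) != 1:3)) stop("bad axis order in map header")
  if (any(ncrs != nxyz[mapcrs]))
    stop("map grid does not cover a full unit cell")
  seek(con, 1024 + nsymbt)
  dat <- readBin(con, "numeric", n = prod(ncrs), size = 4, endian = "little")
  if (length(dat) < prod(ncrs)) stop("truncated map data")
  g <- array(dat, dim = ncrs)
  # permute from (col,row,sec) storage to (x,y,z)
  perm <- match(1:3, mapcrs)
  g <- aperm(g, perm)
  startXYZ <- start[perm]
  # cyclic shift so index 1 is fractional coordinate 0
  for (ax in 1:3) {
    s <- startXYZ[ax] %% nxyz[ax]
    if (s != 0) {
      idx <- ((seq_len(nxyz[ax]) - 1L - s) %% nxyz[ax]) + 1L
      g <- switch(ax, g[idx, , , drop = FALSE], g[, idx, , drop = FALSE],
                  g[, , idx, drop = FALSE])
    }
  }
  densityMap(g, cell)
}

#' Write a density map as CCP4/MRC (mode 2)
#'
#' Writes the full-cell grid with axis order x, y, z and zero start indices.
#'
#' @param m a [DensityMap-class]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeCCP4Map <- function(m, path) {
  stopifnot(is(m, "DensityMap"))
  g <- m@grid
  n <- dim(g)
  con <- file(path, "wb")
  on.exit(close(con))
  wInt <- function(x) writeBin(as.integer(x), con, size = 4,
                               endian = "little")
  wFlt <- function(x) writeBin(as.numeric(x), con, size = 4,
                               endian = "little")
  wInt(n); wInt(2L); wInt(c(0L, 0L, 0L)); wInt(n)
  wFlt(m@cell); wInt(1:3)
  wFlt(c(min(g), max(g), mean(g)))
  wInt(1L)                       # ISPG (P1)
  wInt(0L)                       # NSYMBT
  wInt(rep(0L, 25))              # LSKFLG + skew + extra (words 25-49)
  wFlt(c(0, 0, 0))               # ORIGIN (words 50-52)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # little-endian stamp
  wFlt(stats::sd(as.vector(g)))
  wInt(1L)                       # NLABL
  lab <- sprintf("%-80s", "multiconf density map")
  writeChar(lab, con, nchars = 80, eos = NULL)
  writeChar(paste(rep(" ", 80 * 9), collapse = ""), con, nchars = 720,
            eos = NULL)
  wFlt(as.vector(g))
  invisible(path)
}

#' Read map coefficients from an MTZ file
#'
#' Parses the binary MTZ reflection format (header records at the tail,
#' float32 data records) and extracts one amplitude/phase column pair as
#' 2Fo-Fc-style map coefficients. Column labels are auto-detected among
#' common dialects (`2FOFCWT`/`PH2FOFCWT`, `FWT`/`PHWT`, `FC`/`PHIC`) unless
#' `labels` overrides them.
#'
#' @param path file path
#' @param labels optional character(2): amplitude and phase column labels
#' @return a [MapCoefficients-class]
#' @export
readMTZ <- function(path, labels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "MTZ ")) stop("not an MTZ file: ", path)
  headerPos <- readBin(con, "integer", 1, size = 4, endian = "little")
  sz <- file.size(path)
  seek(con, (headerPos - 1) * 4)
  nrec <- floor((sz - (headerPos - 1) * 4) / 80)
  recs <- vapply(seq_len(nrec),
                 function(i) readChar(con, 80, useBytes = TRUE), "")
  recs <- trimws(recs, "right")
  getRec <- function(key) grep(paste0("^", key, "\\b"), recs, value = TRUE)
  ncolRec <- getRec("NCOL")
  if (!length(ncolRec)) stop("MTZ header lacks NCOL record")
  ncolVals <- as.numeric(strsplit(trimws(sub("^NCOL", "", ncolRec[1])),
                                  "\\s+")[[1]])
  ncol <- ncolVals[1]; nrefl <- ncolVals[2]
  cellRec <- getRec("CELL")
  cell <- as.numeric(strsplit(trimws(sub("^CELL", "", cellRec[1])),
                              "\\s+")[[1]])
  colRecs <- getRec("COLUMN")
  colLab <- vapply(colRecs, function(r)
    strsplit(trimws(sub("^COLUMN", "", r)), "\\s+")[[1]][1], "")
  names(colLab) <- NULL
  resRec <- getRec("RESO")
  reso <- c(NA_real_, NA_real_)
  if (length(resRec)) {
    rv <- as.numeric(strsplit(trimws(sub("^RESO", "", resRec[1])),
                              "\\s+")[[1]])
    reso <- rev(sort(1 / sqrt(rv)))   # stored as 1/d^2
  }
  seek(con, 80)
  dat <- readBin(con, "numeric", n = ncol * nrefl, size = 4,
                 endian = "little")
  dat <- matrix(dat, ncol = ncol, byrow = TRUE)
  colnames(dat) <- colLab
  need <- c("H", "K", "L")
  if (!all(need %in% colLab)) stop("MTZ lacks H/K/L columns")
  if (is.null(labels)) {
    dialects <- list(c("2FOFCWT", "PH2FOFCWT"), c("FWT", "PHWT"),
                     c("FC", "PHIC"))
    hit <- Filter(function(d) all(d %in% colLab), dialects)
    if (!length(hit))
      stop("no recognized amplitude/phase column pair; available: ",
           paste(colLab, collapse = ", "))
    labels <- hit[[1]]
  }
  if (!all(labels %in% colLab))
    stop("requested columns not in file: ", paste(labels, collapse = "/"))
  mapCoefficients(dat[, need, drop = FALSE], dat[, labels[1]],
                  dat[, labels[2]], cell, resolution = reso)
}

#' Write map coefficients to an MTZ file
#'
#' Writes a minimal single-dataset MTZ with H, K, L and one amplitude/phase
#' column pair. Round-trips through [readMTZ()].
#'
#' @param coeffs a [MapCoefficients-class]
#' @param path output file path
#' @param labels character(2) amplitude/phase column labels
#'   (default `FWT`/`PHWT`)
#' @return `path`, invisibly
#' @export
writeMTZ <- function(coeffs, path, labels = c("FWT", "PHWT")) {
  stopifnot(is(coeffs, "MapCoefficients"), length(labels) == 2)
  n <- nrow(coeffs@hkl)
  dat <- cbind(coeffs@hkl, coeffs@amplitude, coeffs@phase)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("MTZ ", con, nchars = 4, eos = NULL)
  headerPos <- 20L + n * 5L + 1L           # 1-based word index
  writeBin(headerPos, con, size = 4, endian = "little")
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)
  writeBin(raw(80 - 12), con)              # pad to data start (word 21)
  writeBin(as.numeric(t(dat)), con, size = 4, endian = "little")
  dmin <- .resolutionOf(coeffs)
  rec <- function(s) writeChar(sprintf("%-80s", s), con, nchars = 80,
                               eos = NULL)
  rec("VERS MTZ:V1.1")
  rec("TITLE multiconf map coefficients")
  rec(sprintf("NCOL %d %d 0", 5L, n))
  rec(sprintf("CELL %10.4f%10.4f%10.4f%10.4f%10.4f%10.4f",
              coeffs@cell[1], coeffs@cell[2], coeffs@cell[3],
              coeffs@cell[4], coeffs@cell[5], coeffs@cell[6]))
  rec("SORT 1 2 3 0 0")
  rec("SYMINF 1 1 P 1 1 'P 1' PG1")
  rec("SYM X, Y, Z")
  rec(sprintf("RESO %12.8f %12.8f", dmin[1], dmin[2]))
  cols <- data.frame(lab = c("H", "K", "L", labels),
                     type = c("H", "H", "H", "F", "P"))
  for (i in seq_len(nrow(cols)))
    rec(sprintf("COLUMN %-30s %s %16.4f %16.4f 1", cols$lab[i],
                cols$type[i], min(dat[, i]), max(dat[, i])))
  rec("END")
  rec("MTZENDOFHEADERS")
  invisible(path)
}

# low/high resolution as 1/d^2 range for the RESO record
.resolutionOf <- function(coeffs) {
  M <- orthoMatrix(coeffs@cell)
  recip <- t(solve(M))                       # reciprocal basis (columns)
  s <- coeffs@hkl %*% t(recip)
  s2 <- rowSums(s^2)
  s2 <- s2[s2 > 0]
  if (!length(s2)) return(c(0, 0))
  range(s2)
}

#' Load a density map from any supported source
#'
#' Convenience dispatcher: a CCP4/MRC map file is read directly; an MTZ file
#' is read as coefficients and Fourier-synthesized. If both are supplied the
#' map file wins. The returned map is always sigma-scaled.
#'
#' @param map optional CCP4/MRC path
#' @param mtz optional MTZ path
#' @param mtzLabels optional character(2) column override for the MTZ
#' @param gridSpacing grid spacing for coefficient synthesis (see
#'   [mapFromCoefficients()])
#' @return a sigma-scaled [DensityMap-class]
#' @export
loadDensity <- function(map = NULL, mtz = NULL, mtzLabels = NULL,
                        gridSpacing = NULL) {
  if (!is.null(map)) return(sigmaScale(readCCP4Map(map)))
  if (!is.null(mtz))
    return(mapFromCoefficients(readMTZ(mtz, labels = mtzLabels),
                               gridSpacing = gridSpacing))
  stop("supply a map file or an MTZ file")
}
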