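#' Orthogonalization matrix of a unit cell
#'
#' Columns are the cell basis vectors in Cartesian Angstrom (PDB convention:
#' a along x, b in the xy plane). Multiplying fractional coordinates by this
#' matrix gives Cartesian coordinates; its inverse fractionalizes.
#'
#' @param cell numeric(6): a, b, c (Angstrom), alpha, beta, gamma (degrees)
#' @return 3x3 numeric matrix
#' @export
orthoMatrix <- function(cell) {
  stopifnot(length(cell) == 6, all(cell[1:3] > 0))
  ab <- cell[1:3]
  ang <- cell[4:6] * pi / 180
  ca <- cos(ang[1]); cb <- cos(ang[2]); cg <- cos(ang[3]); sg <- sin(ang[3])
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  matrix(c(ab[1], 0, 0,
           ab[2] * cg, ab[2] * sg, 0,
           ab[3] * cb, ab[3] * (ca - cb * cg) / sg, ab[3] * v / sg),
         nrow = 3)
}

#' Construct a DensityMap from a grid and cell
#'
#' @param grid 3-D numeric array covering one full unit cell
#' @param cell numeric(6) cell parameters
#' @param spacegroup space-group symbol (default "P 1")
#' @return a [DensityMap-class] (unscaled)
#' @export
densityMap <- function(grid, cell, spacegroup = "P 1") {
  methods::new("DensityMap", grid = grid, cell = as.numeric(cell),
               spacegroup = spacegroup)
}

#' @rdname sigmaScale
#' @details Each voxel is replaced by `(value - mean) / sd` where mean and sd
#'   are taken over the whole grid; the statistics are recorded on the
#'   returned object. A constant (zero-variance) grid is an error. The
#'   operation is idempotent to floating-point precision.
#' @export
setMethod("sigmaScale", "DensityMap", function(x) {
  g <- x@grid
  m <- mean(g)
  s <- sqrt(mean((g - m)^2))          # population (RMS) sigma
  if (!is.finite(s) || s < 1e-12 * max(1, abs(m)))
    stop("constant map: cannot sigma-scale a zero-variance grid")
  x@grid <- (g - m) / s
  x@mean <- m
  x@sd <- s
  x@scaled <- TRUE
  methods::validObject(x)
  x
})

#' Interpolate map density at Cartesian points
#'
#' Points are fractionalized against the cell, wrapped into the unit cell by
#' lattice translation (mod 1) and interpolated trilinearly from the 8
#' surrounding grid nodes with periodic wrapping at the cell edges. Values
#' are in the grid's units (sigma units for a scaled map).
#'
#' @param m a [DensityMap-class]
#' @param points numeric vector of length 3 or an N x 3 matrix of Cartesian
#'   coordinates (Angstrom)
#' @return numeric vector of interpolated densities
#' @export
interpolateMap <- function(m, points) {
  stopifnot(is(m, "DensityMap"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  n <- dim(m@grid)
  frac <- points %*% t(solve(orthoMatrix(m@cell)))
  frac <- frac - floor(frac)          # lattice wrap
  g <- sweep(frac, 2, n, `*`)
  i0 <- floor(g)
  t <- g - i0
  val <- numeric(nrow(points))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- (i0[, 1] + dx) %% n[1] + 1L
    iy <- (i0[, 2] + dy) %% n[2] + 1L
    iz <- (i0[, 3] + dz) %% n[3] + 1L
    w <- (if (dx) t[, 1] else 1 - t[, 1]) *
         (if (dy) t[, 2] else 1 - t[, 2]) *
         (if (dz) t[, 3] else 1 - t[, 3])
    val <- val + w * m@grid[cbind(ix, iy, iz)]
  }
  val
}

#' Map coefficients constructor
#'
#' @param hkl integer matrix (N x 3) of Miller indices
#' @param amplitude,phase numeric vectors (phase in degrees)
#' @param cell numeric(6) cell parameters
#' @param spacegroup space-group symbol
#' @param resolution numeric(2) low/high limits in Angstrom (optional)
#' @return a [MapCoefficients-class]
#' @export
mapCoefficients <- function(hkl, amplitude, phase, cell,
                            spacegroup = "P 1",
                            resolution = c(NA_real_, NA_real_)) {
  hkl <- matrix(as.integer(hkl), ncol = 3)
  methods::new("MapCoefficients", hkl = hkl,
               amplitude = as.numeric(amplitude),
               phase = as.numeric(phase), cell = as.numeric(cell),
               spacegroup = spacegroup, resolution = as.numeric(resolution))
}

#' Synthesize a sigma-scaled density map from map coefficients
#'
#' Performs the inverse Fourier synthesis
#' `rho(x) = (1/V) * sum_h F_h * exp(-2 pi i h.x)` on a grid whose spacing is
#' at most `gridSpacing` along each cell axis (and fine enough to hold the
#' highest-index reflection without aliasing), then sigma-scales the result.
#' Friedel mates are generated internally, so only unique reflections need to
#' be supplied.
#'
#' @param coeffs a [MapCoefficients-class]
#' @param gridSpacing maximum grid spacing in Angstrom (default: high
#'   resolution limit / 4 when known, else 0.5)
#' @return a sigma-scaled [DensityMap-class]
#' @export
mapFromCoefficients <- function(coeffs, gridSpacing = NULL) {
  stopifnot(is(coeffs, "MapCoefficients"))
  nref <- nrow(coeffs@hkl)
  if (!nref) stop("empty reflection list")
  if (is.null(gridSpacing)) {
    gridSpacing <- if (is.finite(coeffs@resolution[2]))
      coeffs@resolution[2] / 4 else 0.5
  }
  stopifnot(gridSpacing > 0)
  cell <- coeffs@cell
  hmax <- apply(abs(coeffs@hkl), 2, max)
  n <- pmax(ceiling(cell[1:3] / gridSpacing), 2L * hmax + 2L, 4L)
  Farr <- array(complex(real = 0), dim = n)
  F <- coeffs@amplitude * exp(1i * coeffs@phase * pi / 180)
  idx <- sweep(coeffs@hkl, 2, n, `%%`) + 1L
  idxF <- sweep(-coeffs@hkl, 2, n, `%%`) + 1L
  lin <- (idx[, 3] - 1L) * n[1] * n[2] + (idx[, 2] - 1L) * n[1] + idx[, 1]
  linF <- (idxF[, 3] - 1L) * n[1] * n[2] + (idxF[, 2] - 1L) * n[1] + idxF[, 1]
  for (i in seq_len(nref)) {
    if (lin[i] == linF[i]) {
      Farr[lin[i]] <- Farr[lin[i]] + Re(F[i])
    } else {
      Farr[lin[i]] <- Farr[lin[i]] + F[i]
      Farr[linF[i]] <- Farr[linF[i]] + Conj(F[i])
    }
  }
  # forward DFT sum_h z_h exp(-2 pi i h k / n) matches the synthesis sign
  rho <- Re(stats::fft(Farr))
  m <- densityMap(rho, cell, coeffs@spacegroup)
  sigmaScale(m)
}

#' Structure factors of a density grid (Fourier analysis)
#'
#' The inverse operation of [mapFromCoefficients()]: computes
#' `F_h = (V/N) * sum_k rho_k * exp(+2 pi i h.k/n)` for all Miller indices up
#' to `hmax`, returning the unique half-set (h >= 0, with the usual boundary
#' deduplication). Mainly used to round-trip synthetic maps through the
#' coefficient path.
#'
#' @param m a [DensityMap-class]
#' @param hmax integer(3) (or scalar) maximum |h|, |k|, |l|
#' @return a [MapCoefficients-class]
#' @export
structureFactors <- function(m, hmax) {
  stopifnot(is(m, "DensityMap"))
  n <- dim(m@grid)
  hmax <- rep_len(as.integer(hmax), 3L)
  stopifnot(all(2L * hmax < n))
  V <- abs(det(orthoMatrix(m@cell)))
  Fall <- stats::fft(m@grid, inverse = TRUE) * (V / prod(n))
  hs <- expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                    l = -hmax[3]:hmax[3])
  # keep one of each Friedel pair: first nonzero index positive
  keep <- hs$h > 0 | (hs$h == 0 & (hs$k > 0 | (hs$k == 0 & hs$l >= 0)))
  hs <- as.matrix(hs[keep, , drop = FALSE])
  idx <- sweep(hs, 2, n, `%%`) + 1L
  F <- Fall[cbind(idx[, 1], idx[, 2], idx[, 3])]
  mapCoefficients(hs, Mod(F), Arg(F) * 180 / pi, m@cell, m@spacegroup)
}
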