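# Synthetic ground-truth fixtures: an extended peptide with planted rotamer
# ensembles and a density map computed from the full ensemble with
# Gaussian atoms on a P1 grid.

# NeRF atom placement: position D so |CD| = bond, angle(B,C,D) = ang (deg)
# and torsion(A,B,C,D) = tors (deg).
.nerf <- function(A, B, C, bond, ang, tors) {
  ang <- ang * pi / 180
  tors <- tors * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- .cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tors),
         bond * sin(ang) * sin(tors))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# Backbone geometry (Engh-Huber-like) used by the peptide builder.
.BB <- list(nca = 1.458, cac = 1.525, cn = 1.329, co = 1.231,
            ang_ncac = 111.2, ang_cacn = 116.2, ang_cnca = 121.7,
            ang_caco = 120.8)

# Side-chain internal coordinates per supported residue type. Each atom is
# placed by NeRF from three reference atoms; `tors` is either a fixed
# number or list(chi = k, offset = deg).
.SC_GEOM <- list(
  ALA = list(list("CB", c("N", "C", "CA"), 1.521, 110.4, 122.6)),
  SER = list(list("CB", c("N", "C", "CA"), 1.530, 110.5, 122.6),
             list("OG", c("N", "CA", "CB"), 1.417, 110.8,
                  list(chi = 1, offset = 0))),
  CYS = list(list("CB", c("N", "C", "CA"), 1.530, 110.5, 122.6),
             list("SG", c("N", "CA", "CB"), 1.808, 114.2,
                  list(chi = 1, offset = 0))),
  THR = list(list("CB", c("N", "C", "CA"), 1.540, 111.5, 122.6),
             list("OG1", c("N", "CA", "CB"), 1.433, 109.6,
                  list(chi = 1, offset = 0)),
             list("CG2", c("N", "CA", "CB"), 1.521, 110.5,
                  list(chi = 1, offset = -120))),
  VAL = list(list("CB", c("N", "C", "CA"), 1.540, 111.5, 122.6),
             list("CG1", c("N", "CA", "CB"), 1.521, 110.5,
                  list(chi = 1, offset = 0)),
             list("CG2", c("N", "CA", "CB"), 1.521, 110.5,
                  list(chi = 1, offset = 122))),
  LEU = list(list("CB", c("N", "C", "CA"), 1.530, 110.5, 122.6),
             list("CG", c("N", "CA", "CB"), 1.530, 116.3,
                  list(chi = 1, offset = 0)),
             list("CD1", c("CA", "CB", "CG"), 1.521, 110.7,
                  list(chi = 2, offset = 0)),
             list("CD2", c("CA", "CB", "CG"), 1.521, 110.7,
                  list(chi = 2, offset = 122))),
  ILE = list(list("CB", c("N", "C", "CA"), 1.540, 111.5, 122.6),
             list("CG1", c("N", "CA", "CB"), 1.530, 110.4,
                  list(chi = 1, offset = 0)),
             list("CG2", c("N", "CA", "CB"), 1.521, 110.5,
                  list(chi = 1, offset = -122)),
             list("CD1", c("CA", "CB", "CG1"), 1.513, 113.8,
                  list(chi = 2, offset = 0))),
  ASP = list(list("CB", c("N", "C", "CA"), 1.530, 110.5, 122.6),
             list("CG", c("N", "CA", "CB"), 1.516, 112.6,
                  list(chi = 1, offset = 0)),
             list("OD1", c("CA", "CB", "CG"), 1.249, 118.4,
                  list(chi = 2, offset = 0)),
             list("OD2", c("CA", "CB", "CG"), 1.249, 118.4,
                  list(chi = 2, offset = 180))),
  ASN = list(list("CB", c("N", "C", "CA"), 1.530, 110.5, 122.6),
             list("CG", c("N", "CA", "CB"), 1.516, 112.6,
                  list(chi = 1, offset = 0)),
             list("OD1", c("CA", "CB", "CG"), 1.231, 120.8,
                  list(chi = 2, offset = 0)),
             list("ND2", c("CA", "CB", "CG"), 1.328, 116.4,
                  list(chi = 2, offset = 180))),
  GLU = list(list("CB", c("N", "C", "CA"), 1.530, 110.5, 122.6),
             list("CG", c("N", "CA", "CB"), 1.530, 114.1,
                  list(chi = 1, offset = 0)),
             list("CD", c("CA", "CB", "CG"), 1.516, 112.6,
                  list(chi = 2, offset = 0)),
             list("OE1", c("CB", "CG", "CD"), 1.249, 118.4,
                  list(chi = 3, offset = 0)),
             list("OE2", c("CB", "CG", "CD"), 1.249, 118.4,
                  list(chi = 3, offset = 180))),
  GLN = list(list("CB", c("N", "C", "CA"), 1.530, 110.5, 122.6),
             list("CG", c("N", "CA", "CB"), 1.530, 114.1,
                  list(chi = 1, offset = 0)),
             list("CD", c("CA", "CB", "CG"), 1.516, 112.6,
                  list(chi = 2, offset = 0)),
             list("OE1", c("CB", "CG", "CD"), 1.231, 120.8,
                  list(chi = 3, offset = 0)),
             list("NE2", c("CB", "CG", "CD"), 1.328, 116.4,
                  list(chi = 3, offset = 180))),
  LYS = list(list("CB", c("N", "C", "CA"), 1.530, 110.5, 122.6),
             list("CG", c("N", "CA", "CB"), 1.530, 114.1,
                  list(chi = 1, offset = 0)),
             list("CD", c("CA", "CB", "CG"), 1.520, 111.3,
                  list(chi = 2, offset = 0)),
             list("CE", c("CB", "CG", "CD"), 1.520, 111.3,
                  list(chi = 3, offset = 0)),
             list("NZ", c("CG", "CD", "CE"), 1.489, 111.9,
                  list(chi = 4, offset = 0))),
  MET = list(list("CB", c("N", "C", "CA"), 1.530, 110.5, 122.6),
             list("CG", c("N", "CA", "CB"), 1.530, 114.1,
                  list(chi = 1, offset = 0)),
             list("SD", c("CA", "CB", "CG"), 1.803, 112.7,
                  list(chi = 2, offset = 0)),
             list("CE", c("CB", "CG", "SD"), 1.791, 100.9,
                  list(chi = 3, offset = 0))),
  GLY = list())

.FIXTURE_TYPES <- names(.SC_GEOM)

# electron counts for the Gaussian atom model
.ELECTRONS <- c(C = 6, N = 7, O = 8, S = 16)

.elementOf <- function(elety) {
  first <- substr(gsub("[0-9]", "", elety), 1, 1)
  if (!first %in% names(.ELECTRONS)) stop("unknown element for ", elety)
  first
}

#' Build an extended peptide with chosen side-chain chi angles
#'
#' Constructs backbone and side chains from standard internal coordinates
#' (extended conformation, phi = psi = omega = 180 degrees). Supported
#' residue types: GLY, ALA, SER, CYS, THR, VAL, LEU, ILE, ASP, ASN, GLU,
#' GLN, LYS, MET.
#'
#' @param sequence character vector of 3-letter codes
#' @param chis list (one element per residue) of numeric chi vectors;
#'   NULL entries get all chis at 180 degrees
#' @param chain chain identifier (default "A")
#' @return a [ProteinModel-class]
#' @export
buildPeptide <- function(sequence, chis = NULL, chain = "A") {
  sequence <- toupper(sequence)
  bad <- setdiff(sequence, .FIXTURE_TYPES)
  if (length(bad))
    stop("unsupported fixture residue type(s): ", paste(bad, collapse = ", "))
  nres <- length(sequence)
  if (is.null(chis)) chis <- vector("list", nres)
  rows <- list()
  bb <- .BB
  prev <- NULL
  for (i in seq_len(nres)) {
    if (is.null(prev)) {
      N <- c(0, 0, 0)
      CA <- c(bb$nca, 0, 0)
      a <- bb$ang_ncac * pi / 180
      C <- CA + bb$cac * c(-cos(a), sin(a), 0)
    } else {
      N <- .nerf(prev$N, prev$CA, prev$C, bb$cn, bb$ang_cacn, 180)  # psi
      CA <- .nerf(prev$CA, prev$C, N, bb$nca, bb$ang_cnca, 180)     # omega
      C <- .nerf(prev$C, N, CA, bb$cac, bb$ang_ncac, 180)           # phi
    }
    coords <- rbind(N = N, CA = CA, C = C)
    geom <- .SC_GEOM[[sequence[i]]]
    chiv <- chis[[i]]
    nchi <- length(chiDefinitions(sequence[i]))
    if (is.null(chiv)) chiv <- rep(180, max(nchi, 1))
    chiv <- chiv %% 360
    for (g in geom) {
      tors <- g[[5]]
      if (is.list(tors)) tors <- chiv[tors$chi] + tors$offset
      coords <- rbind(coords,
                      .nerf(coords[g[[2]][1], ], coords[g[[2]][2], ],
                            coords[g[[2]][3], ], g[[3]], g[[4]], tors))
      rownames(coords)[nrow(coords)] <- g[[1]]
    }
    # carbonyl O last (after next-residue psi is fixed at 180)
    coords <- rbind(coords, O = .nerf(N, CA, C, bb$co, bb$ang_caco, 0))
    ord <- c("N", "CA", "C", "O",
             setdiff(rownames(coords), c("N", "CA", "C", "O")))
    coords <- coords[ord, , drop = FALSE]
    rows[[i]] <- data.frame(
      type = "ATOM", eleno = 0L, elety = rownames(coords), alt = "",
      resid = sequence[i], chain = chain, resno = i, insert = "",
      x = coords[, 1], y = coords[, 2], z = coords[, 3], o = 1, b = 15,
      elesy = vapply(rownames(coords), .elementOf, ""))
    prev <- list(N = N, CA = CA, C = C)
  }
  a <- do.call(rbind, rows)
  a$eleno <- seq_len(nrow(a))
  rownames(a) <- NULL
  methods::new("ProteinModel", atoms = a)
}

#' Compute a Gaussian-atom density map from a model
#'
#' Places an isotropic Gaussian (amplitude proportional to the element's
#' electron count, occupancy-weighted) at every atom on a P1 grid spanning
#' the given cell. Optional seeded white noise (standard deviation expressed
#' in units of the noise-free grid's sd) is added before sigma scaling.
#'
#' @param x a [ProteinModel-class] whose atoms all lie inside the cell
#' @param cell numeric(3) orthogonal P1 box edge lengths in Angstrom (or
#'   numeric(6) full cell; must be orthogonal)
#' @param spacing grid spacing in Angstrom (default 0.5)
#' @param width Gaussian width (sd) in Angstrom (default 0.5, a typical
#'   effective atomic width at ~1.5 Angstrom resolution)
#' @param noiseSd white-noise sd in units of the signal grid's sd
#'   (default 0 = noise-free)
#' @param seed RNG seed for the noise (required when noiseSd > 0)
#' @return a sigma-scaled [DensityMap-class]
#' @export
gaussianDensityMap <- function(x, cell, spacing = 0.5, width = 0.5,
                               noiseSd = 0, seed = NULL) {
  stopifnot(is(x, "ProteinModel"))
  if (length(cell) == 3) cell <- c(cell, 90, 90, 90)
  stopifnot(all(cell[4:6] == 90))
  n <- pmax(4L, ceiling(cell[1:3] / spacing))
  g <- array(0, dim = n)
  d <- cell[1:3] / n                    # voxel size per axis
  a <- x@atoms
  cutoff <- 4 * width
  for (i in seq_len(nrow(a))) {
    z <- .ELECTRONS[[.elementOf(a$elety[i])]] * a$o[i]
    ctr <- c(a$x[i], a$y[i], a$z[i])
    lo <- floor((ctr - cutoff) / d)
    hi <- ceiling((ctr + cutoff) / d)
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    dx2 <- (ix * d[1] - ctr[1])^2
    dy2 <- (iy * d[2] - ctr[2])^2
    dz2 <- (iz * d[3] - ctr[3])^2
    blk <- z * exp(-(outer(outer(dx2, dy2, `+`), dz2, `+`)) /
                     (2 * width^2))
    idx <- cbind(rep(ix %% n[1] + 1L, times = length(iy) * length(iz)),
                 rep(rep(iy %% n[2] + 1L, each = length(ix)),
                     times = length(iz)),
                 rep(iz %% n[3] + 1L, each = length(ix) * length(iy)))
    g[idx] <- g[idx] + as.vector(blk)
  }
  if (noiseSd > 0) {
    if (is.null(seed)) stop("noise requires a seed for reproducibility")
    s0 <- stats::sd(as.vector(g))
    set.seed(seed)
    g <- g + array(stats::rnorm(prod(n), 0, noiseSd * s0), dim = n)
  }
  sigmaScale(densityMap(g, cell))
}

#' Generate a ground-truth fixture: peptide, planted rotamers and map
#'
#' Builds an extended peptide, plants the named rotamers (ideal library chi
#' means) at the target residues as altloc conformers with the given
#' occupancies, computes the ensemble density map (occupancy-weighted
#' Gaussian atoms, optional seeded noise) and returns the ground-truth
#' multi-conformer structure, its single-conformer reduction (highest
#' occupancy conformer per residue) and the sigma-scaled map.
#'
#' @param sequence character vector of 3-letter codes (3-10 residues)
#' @param planted named list: names are residue indices (as characters),
#'   values are named numeric vectors of occupancies by rotamer name, e.g.
#'   `list("2" = c(m = 0.6, p = 0.4))`; occupancies must sum to 1
#' @param spacing,width,noiseSd,seed map parameters, see
#'   [gaussianDensityMap()]
#' @param padding box padding around the model in Angstrom (default 4,
#'   at least twice the Gaussian width)
#' @param library a [RotamerLibrary-class] (default: packaged library)
#' @return list with `truth`, `single` ([ProteinModel-class]), `map`
#'   ([DensityMap-class]) and `cell`
#' @export
generateFixture <- function(sequence, planted = list(), spacing = 0.5,
                            width = 0.5, noiseSd = 0, seed = NULL,
                            padding = 4, library = NULL) {
  stopifnot(length(sequence) >= 1, padding >= 2 * width)
  if (is.null(library)) library <- rotamerLibrary()
  base <- buildPeptide(sequence)
  a <- base@atoms
  ensemble <- list()
  for (key in as.character(seq_along(sequence))) {
    sel <- a$resno == as.integer(key)
    res <- a[sel, , drop = FALSE]
    if (!key %in% names(planted)) {
      ensemble[[key]] <- res
      next
    }
    occs <- planted[[key]]
    if (abs(sum(occs) - 1) > 1e-9)
      stop("occupancies for residue ", key, " must sum to 1")
    resid <- sequence[as.integer(key)]
    defs <- chiDefinitions(resid)
    lib <- library@entries[library@entries$resid == resid, , drop = FALSE]
    coords <- as.matrix(res[, c("x", "y", "z")])
    rownames(coords) <- res$elety
    confs <- list()
    for (k in seq_along(occs)) {
      rname <- names(occs)[k]
      hit <- lib[lib$rotamer == rname, , drop = FALSE]
      if (!nrow(hit))
        stop("unknown rotamer name for ", resid, ": ", rname)
      ck <- coords
      for (j in seq_along(defs))
        ck <- setChi(ck, defs[[j]], hit[[paste0("chi", j)]][1] %% 360)
      conf <- res
      conf$alt <- if (length(occs) > 1) LETTERS[k] else ""
      conf$o <- occs[k]
      conf[, c("x", "y", "z")] <- ck[conf$elety, , drop = FALSE]
      confs[[k]] <- conf
    }
    ensemble[[key]] <- do.call(rbind, confs)
  }
  truth <- do.call(rbind, ensemble)
  # shift into a padded P1 box
  mins <- apply(truth[, c("x", "y", "z")], 2, min)
  maxs <- apply(truth[, c("x", "y", "z")], 2, max)
  shift <- padding - mins
  truth[, c("x", "y", "z")] <- sweep(truth[, c("x", "y", "z")], 2, shift,
                                     `+`)
  cell <- as.numeric(maxs - mins + 2 * padding)
  truth$eleno <- seq_len(nrow(truth))
  rownames(truth) <- NULL
  truthModel <- methods::new("ProteinModel", atoms = truth)
  map <- gaussianDensityMap(truthModel, cell, spacing = spacing,
                            width = width, noiseSd = noiseSd, seed = seed)
  list(truth = truthModel, single = stripAltConfs(truthModel), map = map,
       cell = cell)
}
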