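#' @import methods
NULL

.STD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
             "TYR", "VAL")

.ATOM_COLS <- c("type", "eleno", "elety", "alt", "resid", "chain", "resno",
                "insert", "x", "y", "z", "o", "b", "elesy")

#' ProteinModel: an atomic model with alternate-location bookkeeping
#'
#' A thin S4 container around a per-atom table. Each row is one atom with its
#' chain, residue (3-letter code, number, insertion code), atom name, altloc
#' label (`""` for blank), Cartesian position in Angstrom, occupancy in
#' \[0, 1\] and isotropic B factor. Atom names must be unique within a
#' (residue, altloc) pair and occupancies must lie in \[0, 1\].
#'
#' @slot atoms data.frame with columns `type`, `eleno`, `elety`, `alt`,
#'   `resid`, `chain`, `resno`, `insert`, `x`, `y`, `z`, `o`, `b`, `elesy`.
#' @export
setClass("ProteinModel", representation(atoms = "data.frame"))

setValidity("ProteinModel", function(object) {
  a <- object@atoms
  miss <- setdiff(.ATOM_COLS, names(a))
  if (length(miss))
    return(paste("missing atom columns:", paste(miss, collapse = ", ")))
  if (nrow(a)) {
    if (any(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z)))
      return("non-finite coordinates")
    if (any(a$o < 0 | a$o > 1, na.rm = TRUE))
      return("occupancies must lie in [0, 1]")
    key <- paste(a$chain, a$resno, a$insert, a$alt, a$elety)
    if (anyDuplicated(key))
      return("duplicate atom name within a (residue, altloc) pair")
  }
  TRUE
})

#' DensityMap: a sigma-scalable density grid on a crystallographic cell
#'
#' Holds a 3-D array of density values sampled on a grid covering one full
#' unit cell (grid point `[i, j, k]` sits at fractional coordinate
#' `((i-1)/nx, (j-1)/ny, (k-1)/nz)`), together with the cell parameters and
#' space-group label. `mean` and `sd` record the grid statistics used for
#' sigma scaling; `scaled` marks whether the grid is currently in sigma units
#' (zero mean, unit standard deviation).
#'
#' @slot grid 3-D numeric array of density values.
#' @slot cell numeric(6): a, b, c (Angstrom), alpha, beta, gamma (degrees).
#' @slot spacegroup character space-group symbol (fixtures use "P 1").
#' @slot mean,sd numeric grid statistics recorded at scaling time.
#' @slot scaled logical: TRUE once the grid is in sigma units.
#' @export
setClass("DensityMap", representation(grid = "array", cell = "numeric",
                                      spacegroup = "character",
                                      mean = "numeric", sd = "numeric",
                                      scaled = "logical"),
         prototype(spacegroup = "P 1", mean = NA_real_, sd = NA_real_,
                   scaled = FALSE))

setValidity("DensityMap", function(object) {
  if (length(dim(object@grid)) != 3L) return("grid must be a 3-D array")
  if (length(object@cell) != 6L) return("cell must have 6 parameters")
  if (any(object@cell[1:3] <= 0)) return("cell lengths must be positive")
  if (any(object@cell[4:6] <= 0 | object@cell[4:6] >= 180))
    return("cell angles must lie in (0, 180)")
  if (isTRUE(object@scaled)) {
    g <- object@grid
    if (abs(mean(g)) > 1e-6 || abs(sqrt(mean((g - mean(g))^2)) - 1) > 1e-6)
      return("scaled grid must have mean ~0 and rms ~1")
  }
  TRUE
})

#' MapCoefficients: amplitude/phase reflections for Fourier map synthesis
#'
#' A reflection list (h, k, l, amplitude, phase in degrees) for a
#' 2Fo-Fc-style map, with the cell and space group needed to synthesize a
#' density grid. Duplicate Miller indices and negative amplitudes are
#' rejected.
#'
#' @slot hkl integer matrix, one row per reflection, columns h, k, l.
#' @slot amplitude,phase numeric vectors parallel to the rows of `hkl`
#'   (phase in degrees).
#' @slot cell numeric(6) cell parameters.
#' @slot spacegroup character symbol.
#' @slot resolution numeric(2) low/high resolution limits in Angstrom
#'   (may be NA).
#' @export
setClass("MapCoefficients",
         representation(hkl = "matrix", amplitude = "numeric",
                        phase = "numeric", cell = "numeric",
                        spacegroup = "character", resolution = "numeric"),
         prototype(spacegroup = "P 1", resolution = c(NA_real_, NA_real_)))

setValidity("MapCoefficients", function(object) {
  n <- nrow(object@hkl)
  if (ncol(object@hkl) != 3L) return("hkl must have 3 columns")
  if (length(object@amplitude) != n || length(object@phase) != n)
    return("amplitude/phase length must match reflection count")
  if (n && any(object@amplitude < 0)) return("amplitudes must be >= 0")
  if (n && anyDuplicated(paste(object@hkl[, 1], object@hkl[, 2],
                               object@hkl[, 3])))
    return("duplicate (h,k,l)")
  if (length(object@cell) != 6L) return("cell must have 6 parameters")
  TRUE
})

#' DihedralTrace: density sampled around one chi dihedral
#'
#' The Ringer-style scan of one side-chain chi angle: density values (sigma
#' units) at angles 0, step, ..., 360 - step. The sample step must divide
#' 360 exactly.
#'
#' @slot chain,resno,insert,resid residue identity.
#' @slot chi integer chi index (1-4).
#' @slot step numeric sample step in degrees.
#' @slot densities numeric vector of length 360/step.
#' @export
setClass("DihedralTrace",
         representation(chain = "character", resno = "integer",
                        insert = "character", resid = "character",
                        chi = "integer", step = "numeric",
                        densities = "numeric"))

setValidity("DihedralTrace", function(object) {
  if (object@step <= 0 || (360 %% object@step) != 0)
    return("step must divide 360")
  if (length(object@densities) != 360 / object@step)
    return("densities length must equal 360/step")
  if (!object@chi %in% 1:4) return("chi index must be 1-4")
  TRUE
})

#' RotamerLibrary: ideal rotamer table (names, chi means, frequencies)
#'
#' A validated table of ideal rotamers: residue type, rotamer name (the
#' p/t/m naming convention), mean chi angles (degrees, one per chi of the
#' residue type) and the population frequency of the rotamer among
#' high-quality structures. Within a residue type, rotamer names are unique
#' and all entries carry the same number of chi angles.
#'
#' @slot entries data.frame with columns `resid`, `rotamer`, `chi1`..`chi4`
#'   (NA for unused chis) and `frequency`.
#' @export
setClass("RotamerLibrary", representation(entries = "data.frame"))

setValidity("RotamerLibrary", function(object) {
  e <- object@entries
  need <- c("resid", "rotamer", "chi1", "chi2", "chi3", "chi4", "frequency")
  miss <- setdiff(need, names(e))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(paste(e$resid, e$rotamer)))
    return("duplicate (residue type, rotamer name)")
  if (any(e$frequency <= 0 | e$frequency > 1))
    return("frequencies must lie in (0, 1]")
  chim <- as.matrix(e[, c("chi1", "chi2", "chi3", "chi4")])
  nchi <- rowSums(!is.na(chim))
  if (any(nchi == 0)) return("every entry needs at least one chi mean")
  # chi angles must be contiguous from chi1
  filled <- t(apply(chim, 1, function(r) !is.na(r)))
  if (any(filled != (col(filled) <= nchi)))
    return("chi means must be contiguous from chi1")
  byres <- tapply(nchi, e$resid, function(v) length(unique(v)))
  if (any(byres != 1))
    return("inconsistent chi count within a residue type")
  TRUE
})

#' FlexibilityCensus: per-residue conformer counts for one model
#'
#' Summarizes how flexible a model is: the number of distinct altloc labels
#' per protein residue (blank-only residues count 1), the set of flexible
#' residues (>= 2 conformers) and the flexible fraction of all standard
#' amino-acid residues. Waters, ligands and ions are excluded from the
#' denominator.
#'
#' @slot counts data.frame with columns `chain`, `resno`, `insert`, `resid`,
#'   `conformers`.
#' @slot flexible character vector of residue keys ("chain:resno:insert")
#'   with >= 2 conformers.
#' @slot fraction numeric flexible fraction in \[0, 1\].
#' @export
setClass("FlexibilityCensus",
         representation(counts = "data.frame", flexible = "character",
                        fraction = "numeric"))

setValidity("FlexibilityCensus", function(object) {
  if (object@fraction < 0 || object@fraction > 1)
    return("fraction must lie in [0, 1]")
  if (nrow(object@counts) && any(object@counts$conformers < 1))
    return("conformer counts must be >= 1")
  TRUE
})
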