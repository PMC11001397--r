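# Side-chain chi dihedral topology and rigid-rotation kinematics.
#
# .CHI_TABLE lists, for each chi-bearing residue type, the IUPAC atom
# quadruple defining each chi and the set of atoms distal to the rotated
# bond (everything that moves rigidly with the 4th atom). Density is
# measured at the 4th (moving) atom of each quadruple, the Ringer
# convention; branched residues use the IUPAC-priority branch (Val CG1,
# Thr OG1, Ile CG1). PRO is excluded (ring-constrained); GLY/ALA have no chi.

.CHI_TABLE <- list(
  SER = list(list(atoms = c("N", "CA", "CB", "OG"), moves = "OG")),
  CYS = list(list(atoms = c("N", "CA", "CB", "SG"), moves = "SG")),
  THR = list(list(atoms = c("N", "CA", "CB", "OG1"),
                  moves = c("OG1", "CG2"))),
  VAL = list(list(atoms = c("N", "CA", "CB", "CG1"),
                  moves = c("CG1", "CG2"))),
  LEU = list(list(atoms = c("N", "CA", "CB", "CG"),
                  moves = c("CG", "CD1", "CD2")),
             list(atoms = c("CA", "CB", "CG", "CD1"),
                  moves = c("CD1", "CD2"))),
  ILE = list(list(atoms = c("N", "CA", "CB", "CG1"),
                  moves = c("CG1", "CG2", "CD1")),
             list(atoms = c("CA", "CB", "CG1", "CD1"), moves = "CD1")),
  MET = list(list(atoms = c("N", "CA", "CB", "CG"),
                  moves = c("CG", "SD", "CE")),
             list(atoms = c("CA", "CB", "CG", "SD"), moves = c("SD", "CE")),
             list(atoms = c("CB", "CG", "SD", "CE"), moves = "CE")),
  ASP = list(list(atoms = c("N", "CA", "CB", "CG"),
                  moves = c("CG", "OD1", "OD2")),
             list(atoms = c("CA", "CB", "CG", "OD1"),
                  moves = c("OD1", "OD2"))),
  ASN = list(list(atoms = c("N", "CA", "CB", "CG"),
                  moves = c("CG", "OD1", "ND2")),
             list(atoms = c("CA", "CB", "CG", "OD1"),
                  moves = c("OD1", "ND2"))),
  GLU = list(list(atoms = c("N", "CA", "CB", "CG"),
                  moves = c("CG", "CD", "OE1", "OE2")),
             list(atoms = c("CA", "CB", "CG", "CD"),
                  moves = c("CD", "OE1", "OE2")),
             list(atoms = c("CB", "CG", "CD", "OE1"),
                  moves = c("OE1", "OE2"))),
  GLN = list(list(atoms = c("N", "CA", "CB", "CG"),
                  moves = c("CG", "CD", "OE1", "NE2")),
             list(atoms = c("CA", "CB", "CG", "CD"),
                  moves = c("CD", "OE1", "NE2")),
             list(atoms = c("CB", "CG", "CD", "OE1"),
                  moves = c("OE1", "NE2"))),
  LYS = list(list(atoms = c("N", "CA", "CB", "CG"),
                  moves = c("CG", "CD", "CE", "NZ")),
             list(atoms = c("CA", "CB", "CG", "CD"),
                  moves = c("CD", "CE", "NZ")),
             list(atoms = c("CB", "CG", "CD", "CE"), moves = c("CE", "NZ")),
             list(atoms = c("CG", "CD", "CE", "NZ"), moves = "NZ")),
  ARG = list(list(atoms = c("N", "CA", "CB", "CG"),
                  moves = c("CG", "CD", "NE", "CZ", "NH1", "NH2")),
             list(atoms = c("CA", "CB", "CG", "CD"),
                  moves = c("CD", "NE", "CZ", "NH1", "NH2")),
             list(atoms = c("CB", "CG", "CD", "NE"),
                  moves = c("NE", "CZ", "NH1", "NH2")),
             list(atoms = c("CG", "CD", "NE", "CZ"),
                  moves = c("CZ", "NH1", "NH2"))),
  HIS = list(list(atoms = c("N", "CA", "CB", "CG"),
                  moves = c("CG", "ND1", "CD2", "CE1", "NE2")),
             list(atoms = c("CA", "CB", "CG", "ND1"),
                  moves = c("ND1", "CD2", "CE1", "NE2"))),
  PHE = list(list(atoms = c("N", "CA", "CB", "CG"),
                  moves = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
             list(atoms = c("CA", "CB", "CG", "CD1"),
                  moves = c("CD1", "CD2", "CE1", "CE2", "CZ"))),
  TYR = list(list(atoms = c("N", "CA", "CB", "CG"),
                  moves = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH")),
             list(atoms = c("CA", "CB", "CG", "CD1"),
                  moves = c("CD1", "CD2", "CE1", "CE2", "CZ", "OH"))),
  TRP = list(list(atoms = c("N", "CA", "CB", "CG"),
                  moves = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3",
                            "CZ2", "CZ3", "CH2")),
             list(atoms = c("CA", "CB", "CG", "CD1"),
                  moves = c("CD1", "CD2", "NE1", "CE2", "CE3",
                            "CZ2", "CZ3", "CH2"))))

# chis whose terminal group is 2-fold symmetric: compared modulo 180 deg
.SYMMETRIC_CHI <- list(PHE = 2L, TYR = 2L, ASP = 2L, GLU = 3L)

#' Chi dihedral definitions for a residue type
#'
#' Returns the IUPAC-standard chi atom quadruples for a standard amino-acid
#' type, ordered chi1, chi2, ... GLY and ALA return an empty list; PRO is
#' excluded as ring-constrained and also returns an empty list.
#'
#' @param resid 3-letter residue code
#' @return list of definitions, each with elements `atoms` (the four
#'   dihedral atom names; the 4th is the moving atom where density is
#'   measured) and `moves` (all atoms rotated rigidly with it)
#' @export
chiDefinitions <- function(resid) {
  resid <- toupper(resid)
  if (!resid %in% .STD_AA) stop("unknown residue type: ", resid)
  if (resid %in% c("GLY", "ALA", "PRO")) return(list())
  .CHI_TABLE[[resid]]
}

#' Measure a dihedral angle
#'
#' @param p1,p2,p3,p4 numeric(3) Cartesian positions
#' @return angle in degrees in \[0, 360)
#' @export
measureDihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(.cross3(n1, n2) * b2) / sqrt(sum(b2^2))
  r <- (atan2(y, x) * 180 / pi) %% 360
  if (r >= 360) 0 else r      # guard the float edge at exactly 360
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rodrigues rotation matrix about unit axis u by theta (radians)
.rotMat <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Set a chi dihedral by rigid rotation
#'
#' Rotates the moving atom and all atoms distal to the rotated bond about
#' the bond axis so the measured dihedral equals `angle`. Bond lengths and
#' angles are unchanged (pure rigid rotation of the distal set).
#'
#' @param coords named numeric matrix (rows = atom names of one residue
#'   conformer, columns x, y, z)
#' @param chi one element of [chiDefinitions()]
#' @param angle target dihedral in degrees
#' @return the coordinate matrix with the distal atoms rotated
#' @export
setChi <- function(coords, chi, angle) {
  need <- chi$atoms
  if (!all(need %in% rownames(coords)))
    stop("missing dihedral atoms: ",
         paste(setdiff(need, rownames(coords)), collapse = ", "))
  p <- coords[need, , drop = FALSE]
  cur <- measureDihedral(p[1, ], p[2, ], p[3, ], p[4, ])
  delta <- ((angle - cur + 180) %% 360 - 180) * pi / 180
  if (abs(delta) < 1e-12) return(coords)
  axis <- p[3, ] - p[2, ]
  R <- .rotMat(axis, delta)
  mov <- intersect(chi$moves, rownames(coords))
  shifted <- sweep(coords[mov, , drop = FALSE], 2, p[3, ])
  coords[mov, ] <- sweep(shifted %*% t(R), 2, p[3, ], `+`)
  coords
}

#' Measure a residue's chi angles
#'
#' @param coords named coordinate matrix of one residue conformer
#' @param resid 3-letter residue code
#' @return numeric vector of chi angles in degrees (\[0, 360)), length equal
#'   to the residue type's chi count; NA where atoms are missing
#' @export
measureChis <- function(coords, resid) {
  defs <- chiDefinitions(resid)
  vapply(defs, function(d) {
    if (!all(d$atoms %in% rownames(coords))) return(NA_real_)
    p <- coords[d$atoms, , drop = FALSE]
    measureDihedral(p[1, ], p[2, ], p[3, ], p[4, ])
  }, numeric(1))
}
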