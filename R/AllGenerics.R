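#' Atom table accessor
#'
#' @param x a [ProteinModel-class]
#' @return the per-atom data.frame
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
#' @export
setMethod("atoms", "ProteinModel", function(x) x@atoms)

#' Grid values accessor
#'
#' @param x a [DensityMap-class]
#' @return the 3-D density array
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname gridValues
#' @export
setMethod("gridValues", "DensityMap", function(x) x@grid)

#' Unit-cell parameters accessor
#'
#' @param x a [DensityMap-class] or [MapCoefficients-class]
#' @return numeric(6): a, b, c, alpha, beta, gamma
#' @export
setGeneric("cellParams", function(x) standardGeneric("cellParams"))

#' @rdname cellParams
#' @export
setMethod("cellParams", "DensityMap", function(x) x@cell)

#' @rdname cellParams
#' @export
setMethod("cellParams", "MapCoefficients", function(x) x@cell)

#' Is the map in sigma units?
#'
#' @param x a [DensityMap-class]
#' @return logical
#' @export
setGeneric("isScaled", function(x) standardGeneric("isScaled"))

#' @rdname isScaled
#' @export
setMethod("isScaled", "DensityMap", function(x) x@scaled)

#' Scale a density grid to sigma units (zero mean, unit sd)
#'
#' @param x a [DensityMap-class]
#' @return a sigma-scaled [DensityMap-class]; errors on a constant grid
#' @export
setGeneric("sigmaScale", function(x) standardGeneric("sigmaScale"))

#' Remove alternate conformations, keeping the strongest conformer
#'
#' @param x a [ProteinModel-class]
#' @return a [ProteinModel-class] with blank altlocs only
#' @export
setGeneric("stripAltConfs", function(x) standardGeneric("stripAltConfs"))

#' Rotamer-library entry table accessor
#'
#' @param x a [RotamerLibrary-class]
#' @return data.frame of entries
#' @export
setGeneric("libraryEntries", function(x) standardGeneric("libraryEntries"))

#' @rdname libraryEntries
#' @export
setMethod("libraryEntries", "RotamerLibrary", function(x) x@entries)

#' Trace density accessor
#'
#' @param x a [DihedralTrace-class]
#' @return numeric vector of densities at angles 0, step, ..., 360 - step
#' @export
setGeneric("traceDensities", function(x) standardGeneric("traceDensities"))

#' @rdname traceDensities
#' @export
setMethod("traceDensities", "DihedralTrace", function(x) x@densities)

setMethod("show", "ProteinModel", function(object) {
  a <- object@atoms
  nres <- nrow(unique(a[a$resid %in% .STD_AA,
                        c("chain", "resno", "insert")]))
  nalt <- sum(a$alt != "")
  cat("ProteinModel:", nrow(a), "atoms,", nres, "protein residues,",
      nalt, "altloc atoms\n")
})

setMethod("show", "DensityMap", function(object) {
  d <- dim(object@grid)
  cat(sprintf("DensityMap: %d x %d x %d grid, cell %.2f %.2f %.2f A, %s%s\n",
              d[1], d[2], d[3], object@cell[1], object@cell[2],
              object@cell[3], object@spacegroup,
              if (isTRUE(object@scaled)) " (sigma-scaled)" else ""))
})

setMethod("show", "RotamerLibrary", function(object) {
  e <- object@entries
  cat("RotamerLibrary:", nrow(e), "rotamers across",
      length(unique(e$resid)), "residue types\n")
})

setMethod("show", "DihedralTrace", function(object) {
  cat(sprintf("DihedralTrace: %s %s%d%s chi%d, step %g deg, %d samples\n",
              object@resid, object@chain, object@resno, object@insert,
              object@chi, object@step, length(object@densities)))
})

setMethod("show", "FlexibilityCensus", function(object) {
  cat(sprintf("FlexibilityCensus: %d residues, %d flexible (%.1f%%)\n",
              nrow(object@counts), length(object@flexible),
              100 * object@fraction))
})
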