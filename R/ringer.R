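# Ringer-style scans: rotate each chi through 360 degrees and record the
# interpolated map density at the moving (4th dihedral) atom.

# coordinate matrix (rows named by atom) of one residue's blank-altloc atoms
.residueCoords <- function(a, chain, resno, insert) {
  sel <- a$chain == chain & a$resno == resno & a$insert == insert &
    a$alt == ""
  r <- a[sel, , drop = FALSE]
  r <- r[!grepl("^H|^\\dH", r$elety), , drop = FALSE]   # ignore hydrogens
  m <- as.matrix(r[, c("x", "y", "z")])
  rownames(m) <- r$elety
  m
}

#' Sample a density trace around one chi dihedral
#'
#' Rotates the chi through 0, step, ..., 360 - step degrees and records the
#' interpolated density (sigma units) at the moving atom at each angle. The
#' input coordinates are untouched: rotation happens on a copy.
#'
#' @param coords named coordinate matrix of the residue (see [setChi()])
#' @param map a sigma-scaled [DensityMap-class]
#' @param chi one element of [chiDefinitions()]
#' @param step sample step in degrees; must divide 360 (default 5)
#' @param id list with chain, resno, insert, resid, chiIndex for labelling
#' @return a [DihedralTrace-class]
#' @export
sampleTrace <- function(coords, map, chi, step = 5,
                        id = list(chain = "A", resno = 1L, insert = "",
                                  resid = "UNK", chiIndex = 1L)) {
  stopifnot(step > 0, 360 %% step == 0)
  angles <- seq(0, 360 - step, by = step)
  moving <- chi$atoms[4]
  pts <- matrix(NA_real_, nrow = length(angles), ncol = 3)
  for (i in seq_along(angles)) {
    rot <- setChi(coords, chi, angles[i])
    pts[i, ] <- rot[moving, ]
  }
  methods::new("DihedralTrace", chain = id$chain,
               resno = as.integer(id$resno), insert = id$insert,
               resid = id$resid, chi = as.integer(id$chiIndex),
               step = step, densities = interpolateMap(map, pts))
}

#' Sample traces for every eligible side chain in a model
#'
#' Walks all standard amino-acid residues, skipping GLY/ALA/PRO and (with a
#' warning) residues missing any chi-defining atom, and scans each chi with
#' all other dihedrals held at their modeled values.
#'
#' @param x a [ProteinModel-class] (single-conformer; alternate
#'   conformations are stripped first if present)
#' @param map a sigma-scaled [DensityMap-class]
#' @param step sample step in degrees (default 5)
#' @return list of [DihedralTrace-class]
#' @export
sampleTraces <- function(x, map, step = 5) {
  stopifnot(is(x, "ProteinModel"), is(map, "DensityMap"))
  if (any(x@atoms$alt != "")) x <- stripAltConfs(x)
  a <- x@atoms
  res <- .proteinResidues(a)
  out <- list()
  for (i in seq_len(nrow(res))) {
    defs <- chiDefinitions(res$resid[i])
    if (!length(defs)) next
    coords <- .residueCoords(a, res$chain[i], res$resno[i], res$insert[i])
    need <- unique(unlist(lapply(defs, `[[`, "atoms")))
    if (!all(need %in% rownames(coords))) {
      warning(sprintf("skipping %s %s%d%s: missing side-chain atoms (%s)",
                      res$resid[i], res$chain[i], res$resno[i],
                      res$insert[i],
                      paste(setdiff(need, rownames(coords)),
                            collapse = ", ")))
      next
    }
    for (k in seq_along(defs)) {
      out[[length(out) + 1L]] <- sampleTrace(
        coords, map, defs[[k]], step = step,
        id = list(chain = res$chain[i], resno = res$resno[i],
                  insert = res$insert[i], resid = res$resid[i],
                  chiIndex = k))
    }
  }
  out
}

#' Write dihedral traces to CSV
#'
#' One row per (residue, chi): identifying columns `chain`, `resnum`,
#' `icode`, `restype`, `chi`, `step`, then the 360/step density values at
#' successive angles.
#'
#' @param traces list of [DihedralTrace-class]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
writeTraceCSV <- function(traces, path) {
  stopifnot(length(traces) > 0)
  step <- traces[[1]]@step
  n <- 360 / step
  rows <- lapply(traces, function(tr) {
    stopifnot(tr@step == step)
    data.frame(chain = tr@chain, resnum = tr@resno, icode = tr@insert,
               restype = tr@resid, chi = tr@chi, step = tr@step,
               t(tr@densities))
  })
  df <- do.call(rbind, rows)
  names(df)[-(1:6)] <- paste0("d", seq(0, 360 - step, by = step))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read dihedral traces from CSV
#'
#' Accepts the layout written by [writeTraceCSV()] and also a joined-label
#' dialect where the identifying fields are a single first column like
#' `"A SER 12"` or `"SER A 12"` followed by `chi`, `step` and densities.
#'
#' @param path CSV path
#' @return list of [DihedralTrace-class] (empty list for a header-only file)
#' @export
readTraceCSV <- function(path) {
  df <- tryCatch(utils::read.csv(path, check.names = FALSE,
                                 stringsAsFactors = FALSE),
                 error = function(e) stop("malformed trace CSV: ",
                                          conditionMessage(e)))
  if (!nrow(df)) return(list())
  if (!all(c("chain", "resnum", "icode", "restype") %in% names(df))) {
    # joined-label shim: first column holds "chain restype resnum"-ish label
    lab <- strsplit(as.character(df[[1]]), "[ _:]+")
    parts <- lapply(lab, function(p) {
      resno <- suppressWarnings(as.integer(p[grepl("^[0-9]+$", p)][1]))
      restype <- p[toupper(p) %in% .STD_AA][1]
      chain <- setdiff(p, c(resno, restype))[1]
      if (is.na(resno) || is.na(restype))
        stop("cannot parse trace label: ", df[[1]][1])
      list(chain = chain, resno = resno, restype = toupper(restype))
    })
    df <- cbind(data.frame(chain = vapply(parts, `[[`, "", "chain"),
                           resnum = vapply(parts, function(p)
                             as.integer(p$resno), 1L),
                           icode = "",
                           restype = vapply(parts, `[[`, "", "restype")),
                df[, -1, drop = FALSE])
  }
  df$icode[is.na(df$icode)] <- ""
  lapply(seq_len(nrow(df)), function(i) {
    step <- df$step[i]
    dens <- as.numeric(df[i, -(1:6)])
    dens <- dens[!is.na(dens)]
    if (step <= 0 || 360 %% step != 0 || length(dens) != 360 / step)
      stop(sprintf("row %d: expected %s density values at step %s, got %d",
                   i, ifelse(step > 0, 360 / step, NA), step, length(dens)))
    methods::new("DihedralTrace", chain = as.character(df$chain[i]),
                 resno = as.integer(df$resnum[i]),
                 insert = as.character(df$icode[i]),
                 resid = as.character(df$restype[i]),
                 chi = as.integer(df$chi[i]), step = step,
                 densities = dens)
  })
}

#' Plot a dihedral trace with threshold line and detected peaks
#'
#' @param trace a [DihedralTrace-class]
#' @param threshold detection threshold in sigma units (dotted line)
#' @param peaks optional data.frame from [detectPeaks()] to mark
#' @param ... passed to [graphics::plot()]
#' @return invisibly, NULL
#' @export
plotTrace <- function(trace, threshold = 0.3, peaks = NULL, ...) {
  ang <- seq(0, 360 - trace@step, by = trace@step)
  graphics::plot(ang, trace@densities, type = "l", xlab = "dihedral (deg)",
                 ylab = "density (sigma)",
                 main = sprintf("%s %s%d chi%d", trace@resid, trace@chain,
                                trace@resno, trace@chi), ...)
  graphics::abline(h = threshold, lty = 3)
  if (!is.null(peaks) && nrow(peaks))
    graphics::points(peaks$angle, peaks$height, pch = 8, col = "red")
  invisible(NULL)
}
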