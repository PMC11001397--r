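# Altloc plan construction and multi-conformer building.

#' Plan which rotamers to build for a residue
#'
#' Truncates the ranked candidate list to `maxAlts`. When one or zero
#' candidates remain the plan is empty: the residue stays single-conformer
#' with a blank altloc, so alternates are only built where at least two
#' rotamer wells have density support. `maxAlts = 1` therefore always yields
#' an empty plan.
#'
#' @param ranked data.frame from [rankCandidates()]
#' @param maxAlts maximum number of conformers per residue (default 3)
#' @param mode build mode, `"ALL"` (duplicate every residue atom) or
#'   `"SIDECHAIN"` (duplicate from the CA atom outward)
#' @return list with elements `rotamers` (the truncated data.frame; zero
#'   rows for an empty plan), `mode` and `maxAlts`
#' @export
makePlan <- function(ranked, maxAlts = 3, mode = c("ALL", "SIDECHAIN")) {
  mode <- match.arg(toupper(mode[1]), c("ALL", "SIDECHAIN"))
  stopifnot(maxAlts >= 1)
  kept <- utils::head(ranked, maxAlts)
  if (nrow(kept) <= 1L) kept <- kept[0, , drop = FALSE]
  list(rotamers = kept, mode = mode, maxAlts = maxAlts)
}

# occupancies 1/n rounded to PDB precision; first conformer absorbs the
# remainder so the column sums to exactly 1.00
.splitOccupancy <- function(n) {
  base <- floor(100 / n) / 100
  occ <- rep(base, n)
  occ[1] <- 1 - base * (n - 1)
  occ
}

#' Build planned alternate conformations into a structure
#'
#' For each planned rotamer (in signal order) the residue's side chain is
#' regenerated from its current internal geometry by setting every chi to
#' the rotamer's ideal library mean, and inserted with altloc label A, B,
#' ... In `ALL` mode every atom of the residue is duplicated per conformer
#' (backbone copies start at identical coordinates); in `SIDECHAIN` mode CA
#' and all side-chain atoms carry altlocs while N, C, O (and OXT) remain
#' blank and shared. Occupancies split the unit budget equally (first
#' conformer absorbs rounding so the sum is exactly 1.00); B factors are
#' inherited from the atoms being replaced.
#'
#' @param x a [ProteinModel-class] (blank-altloc at the target residue)
#' @param chain,resno,insert residue identity
#' @param plan a plan from [makePlan()] with at least 2 rotamers
#' @return the modified [ProteinModel-class]
#' @export
buildAlternates <- function(x, chain, resno, insert = "", plan) {
  stopifnot(is(x, "ProteinModel"))
  n <- nrow(plan$rotamers)
  if (n < 2L) return(x)
  a <- x@atoms
  sel <- which(a$chain == chain & a$resno == resno & a$insert == insert &
                 a$alt == "")
  if (!length(sel)) stop("residue not found: ", chain, resno, insert)
  res <- a[sel, , drop = FALSE]
  resid <- res$resid[1]
  if (!all(c("N", "CA", "C", "O") %in% res$elety)) {
    warning(sprintf("skipping %s %s%d%s: incomplete backbone", resid, chain,
                    resno, insert))
    return(x)
  }
  defs <- chiDefinitions(resid)
  coords <- as.matrix(res[, c("x", "y", "z")])
  rownames(coords) <- res$elety
  dupNames <- if (plan$mode == "ALL") res$elety
    else setdiff(res$elety, c("N", "C", "O", "OXT"))
  occ <- .splitOccupancy(n)
  pieces <- list()
  shared <- res[!res$elety %in% dupNames, , drop = FALSE]
  if (nrow(shared)) {
    shared$o <- 1
    pieces[[1]] <- shared
  }
  for (k in seq_len(n)) {
    ck <- coords
    for (j in seq_along(defs))
      ck <- setChi(ck, defs[[j]],
                   plan$rotamers[[paste0("ideal_chi", j)]][k] %% 360)
    conf <- res[res$elety %in% dupNames, , drop = FALSE]
    conf$alt <- LETTERS[k]
    conf$o <- occ[k]
    conf[, c("x", "y", "z")] <- ck[conf$elety, , drop = FALSE]
    pieces[[length(pieces) + 1L]] <- conf
  }
  block <- do.call(rbind, pieces)
  before <- if (sel[1] > 1) a[seq_len(sel[1] - 1L), , drop = FALSE]
    else a[0, , drop = FALSE]
  after <- if (max(sel) < nrow(a)) a[(max(sel) + 1L):nrow(a), , drop = FALSE]
    else a[0, , drop = FALSE]
  out <- rbind(before, block, after)
  out$eleno <- seq_len(nrow(out))
  rownames(out) <- NULL
  methods::new("ProteinModel", atoms = out)
}

#' Run the full multi-conformer building pipeline
#'
#' Orchestrates the whole workflow on one model and one sigma-scaled map:
#' strip alternate conformations, scan every eligible chi (or consume
#' pre-computed traces), detect peaks above the threshold, assemble and
#' library-match candidate rotamers, rank them by signal, and build the
#' per-residue plans into the model. Returns the multi-conformer model, a
#' companion single-conformer model (strongest conformer only, blank
#' altlocs) and a per-residue decision report.
#'
#' @param x a [ProteinModel-class]
#' @param map a [DensityMap-class] (sigma-scaled; scaled automatically if
#'   not)
#' @param threshold peak-detection threshold in sigma units (default 0.3)
#' @param maxAlts maximum conformers per residue (default 3)
#' @param mode `"ALL"` or `"SIDECHAIN"` (default `"ALL"`)
#' @param step sampling step in degrees (default 5)
#' @param tolerance rotamer-matching tolerance in degrees (default 30)
#' @param minSeparation peak separation in degrees (default 30)
#' @param library a [RotamerLibrary-class] (default: packaged library)
#' @param traces optional list of [DihedralTrace-class] replacing the
#'   sampling stage (e.g. from [readTraceCSV()])
#' @return list with elements `multi`, `single` (both
#'   [ProteinModel-class]), `report` (data.frame: one row per scanned
#'   residue with peak counts, candidate/match counts, built rotamers,
#'   signals, peak angles and altlocs) and `traces`
#' @export
buildMultiConformerModel <- function(x, map, threshold = 0.3, maxAlts = 3,
                                     mode = "ALL", step = 5, tolerance = 30,
                                     minSeparation = 30, library = NULL,
                                     traces = NULL) {
  stopifnot(is(x, "ProteinModel"), is(map, "DensityMap"))
  if (!isTRUE(map@scaled)) map <- sigmaScale(map)
  if (is.null(library)) library <- rotamerLibrary()
  single0 <- stripAltConfs(x)
  if (is.null(traces)) traces <- sampleTraces(single0, map, step = step)
  traceKey <- vapply(traces, function(tr)
    paste(tr@chain, tr@resno, tr@insert, sep = ":"), "")
  multi <- single0
  rpt <- list()
  for (key in unique(traceKey)) {
    trs <- traces[traceKey == key]
    trs <- trs[order(vapply(trs, function(t) t@chi, 1L))]
    resid <- trs[[1]]@resid
    nchi <- length(chiDefinitions(resid))
    row <- data.frame(chain = trs[[1]]@chain, resno = trs[[1]]@resno,
                      insert = trs[[1]]@insert, resid = resid, nchi = nchi,
                      peaks = NA_character_, ncand = 0L, nmatch = 0L,
                      built = "", rotamers = "", signals = "",
                      peak_angles = "", altlocs = "")
    if (length(trs) < nchi) {           # partially sampled residue: skip
      rpt[[key]] <- row
      next
    }
    peaksets <- lapply(trs, detectPeaks, threshold = threshold,
                       minSeparation = minSeparation)
    row$peaks <- paste(vapply(peaksets, nrow, 1L), collapse = "/")
    cand <- enumerateCandidates(peaksets)
    row$ncand <- nrow(cand)
    if (nrow(cand)) {
      matched <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i) {
        m <- matchRotamer(as.numeric(cand[i, paste0("chi", seq_len(nchi))]),
                          resid, library, tolerance = tolerance)
        if (!nrow(m)) return(NULL)
        m$signal <- cand$signal[i]
        m$peaks <- paste(round(as.numeric(
          cand[i, paste0("chi", seq_len(nchi))]), 1), collapse = ";")
        m
      }))
      if (!is.null(matched) && nrow(matched)) {
        ranked <- rankCandidates(matched)
        row$nmatch <- nrow(ranked)
        plan <- makePlan(ranked, maxAlts = maxAlts, mode = mode)
        built <- plan$rotamers
        row$rotamers <- paste(ranked$rotamer, collapse = ";")
        row$signals <- paste(round(ranked$signal, 4), collapse = ";")
        row$peak_angles <- paste(ranked$peaks, collapse = "|")
        if (nrow(built) >= 2L) {
          multi <- buildAlternates(multi, trs[[1]]@chain, trs[[1]]@resno,
                                   trs[[1]]@insert, plan)
          row$built <- paste(built$rotamer, collapse = ";")
          row$altlocs <- paste(LETTERS[seq_len(nrow(built))],
                               collapse = ";")
        } else if (nrow(ranked) >= 1L) {
          row$built <- ranked$rotamer[1]   # single-state call, no altloc
        }
      }
    }
    rpt[[key]] <- row
  }
  report <- if (length(rpt)) do.call(rbind, rpt)
    else data.frame()
  rownames(report) <- NULL
  single <- .reduceToSingle(multi)
  list(multi = multi, single = single, report = report, traces = traces)
}

# single-conformer companion: keep blank + altloc A atoms, blank the labels
.reduceToSingle <- function(x) {
  a <- x@atoms
  a <- a[a$alt %in% c("", "A"), , drop = FALSE]
  a$alt <- ""
  a$o <- 1
  a$eleno <- seq_len(nrow(a))
  rownames(a) <- NULL
  methods::new("ProteinModel", atoms = a)
}
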