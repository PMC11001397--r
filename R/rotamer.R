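# Candidate rotamer assembly, library matching and signal ranking.

#' Load a rotamer library
#'
#' Reads a CSV with columns `resid`, `rotamer`, `chi1`..`chi4` (blank/NA for
#' unused chis) and `frequency` (population fraction in (0, 1\]). The
#' packaged default transcribes the ideal rotamer wells and frequencies of
#' the penultimate rotamer library (Lovell et al. 2000): one row per named
#' rotamer of each of the 18 chi-bearing standard residue types.
#'
#' @param path CSV path; default is the packaged library
#' @return a [RotamerLibrary-class]
#' @export
rotamerLibrary <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rotamer_library.csv",
                        package = "multiconf", mustWork = TRUE)
  e <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("resid", "rotamer", "chi1", "chi2", "chi3", "chi4", "frequency")
  if (!all(need %in% names(e)))
    stop("rotamer library must have columns: ", paste(need, collapse = ", "))
  bad <- which(is.na(e$chi1) | is.na(e$frequency) | !nzchar(e$rotamer))
  if (length(bad))
    stop("malformed rotamer library row ", bad[1])
  e$rotamer <- as.character(e$rotamer)
  methods::new("RotamerLibrary", entries = e[, need])
}

# circular absolute difference in degrees; symmetric groups compare mod 180
.circDiff <- function(a, b, period = 360) {
  h <- period / 2
  abs((a - b + h) %% period - h)
}

#' Chi count of a residue type in a library
#'
#' @param library a [RotamerLibrary-class]
#' @param resid 3-letter residue code
#' @return integer chi count
#' @export
libraryChiCount <- function(library, resid) {
  e <- library@entries[library@entries$resid == toupper(resid), ,
                       drop = FALSE]
  if (!nrow(e)) stop("residue type absent from library: ", resid)
  sum(!is.na(as.numeric(e[1, c("chi1", "chi2", "chi3", "chi4")])))
}

#' Assemble candidate rotamers from per-chi peak sets
#'
#' Takes one [detectPeaks()] data.frame per chi of a residue and forms the
#' Cartesian product of peaks across chis. Each candidate carries the angle
#' tuple, the per-chi relative intensities and the signal score (sum of
#' relative intensities). A residue yields candidates only when every chi
#' has at least one peak; otherwise the result has zero rows.
#'
#' @param peaksets list of data.frames (one per chi, in chi order)
#' @return data.frame with columns `chi1`..`chi<n>` (angles), `signal` and a
#'   list-column `relints`
#' @export
enumerateCandidates <- function(peaksets) {
  stopifnot(length(peaksets) >= 1)
  nchi <- length(peaksets)
  if (any(vapply(peaksets, nrow, 1L) == 0L))
    return(data.frame(matrix(numeric(0), ncol = nchi,
                             dimnames = list(NULL, paste0("chi", 1:nchi))),
                      signal = numeric(0)))
  idx <- expand.grid(lapply(peaksets, function(p) seq_len(nrow(p))))
  ang <- mapply(function(p, i) p$angle[i], peaksets, idx)
  rel <- mapply(function(p, i) p$relint[i], peaksets, idx)
  if (is.null(dim(ang))) {                 # single candidate
    ang <- matrix(ang, nrow = 1)
    rel <- matrix(rel, nrow = 1)
  }
  out <- as.data.frame(ang)
  names(out) <- paste0("chi", seq_len(nchi))
  out$signal <- rowSums(rel)
  out$relints <- lapply(seq_len(nrow(rel)), function(i) rel[i, ])
  out
}

#' Match a candidate angle tuple against the rotamer library
#'
#' An entry matches when, for every chi, the circular difference between the
#' candidate angle and the entry's mean is at most `tolerance`. For chis
#' whose terminal group is 2-fold symmetric (PHE/TYR chi2, ASP chi2,
#' GLU chi3) the comparison is modulo 180 degrees (switchable). Among
#' multiple matches the entry with the highest library frequency wins (ties:
#' lexicographically smallest name, for determinism).
#'
#' @param angles numeric vector of candidate chi angles (degrees)
#' @param resid 3-letter residue code
#' @param library a [RotamerLibrary-class]
#' @param tolerance per-chi tolerance in degrees (default 30)
#' @param symmetryAware compare symmetric terminal chis modulo 180
#'   (default TRUE)
#' @return one-row data.frame with `rotamer`, `frequency`, `maxdev` and the
#'   entry's ideal chi means, or a zero-row frame when nothing matches
#' @export
matchRotamer <- function(angles, resid, library, tolerance = 30,
                         symmetryAware = TRUE) {
  resid <- toupper(resid)
  e <- library@entries[library@entries$resid == resid, , drop = FALSE]
  if (!nrow(e)) stop("residue type absent from library: ", resid)
  nchi <- libraryChiCount(library, resid)
  stopifnot(length(angles) == nchi)
  symChi <- if (symmetryAware && resid %in% names(.SYMMETRIC_CHI))
    .SYMMETRIC_CHI[[resid]] else 0L
  devs <- vapply(seq_len(nrow(e)), function(i) {
    mu <- as.numeric(e[i, paste0("chi", seq_len(nchi))])
    d <- vapply(seq_len(nchi), function(k)
      .circDiff(angles[k], mu[k],
                period = if (k == symChi) 180 else 360), numeric(1))
    max(d)
  }, numeric(1))
  ok <- which(devs <= tolerance)
  if (!length(ok))
    return(data.frame(rotamer = character(0), frequency = numeric(0),
                      maxdev = numeric(0)))
  best <- ok[order(-e$frequency[ok], e$rotamer[ok])][1]
  out <- data.frame(rotamer = e$rotamer[best], frequency = e$frequency[best],
                    maxdev = devs[best])
  for (k in seq_len(nchi))
    out[[paste0("ideal_chi", k)]] <- e[[paste0("chi", k)]][best]
  out
}

#' Rank matched candidates and deduplicate by rotamer name
#'
#' Candidates matched to the same rotamer name keep only the highest-signal
#' instance. The result is sorted by descending signal, ties broken by
#' descending library frequency, then rotamer name lexicographically.
#'
#' @param matched data.frame with at least `rotamer`, `frequency`, `signal`
#'   columns (one row per matched candidate)
#' @return the deduplicated, ordered data.frame
#' @export
rankCandidates <- function(matched) {
  if (!nrow(matched)) return(matched)
  o <- order(-matched$signal, -matched$frequency, matched$rotamer)
  matched <- matched[o, , drop = FALSE]
  matched <- matched[!duplicated(matched$rotamer), , drop = FALSE]
  rownames(matched) <- NULL
  matched
}
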