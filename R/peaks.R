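#' Detect peaks in a circular density trace
#'
#' A sample is a peak when its density is at or above `threshold` and it is
#' a strict local maximum on the circularly wrapped trace. Plateaus (runs of
#' equal values higher than both flanking values) yield one peak at the
#' run's leftmost sample. Peaks closer than `minSeparation` (circular
#' distance) are thinned greedily, tallest first (ties: smaller angle wins),
#' keeping only peaks at least `minSeparation` from every already-kept peak.
#' Relative intensities are heights divided by the tallest surviving peak's
#' height.
#'
#' @param trace a [DihedralTrace-class] or a plain numeric vector of
#'   densities at angles 0, step, ..., 360 - step
#' @param threshold detection threshold in sigma units (default 0.3)
#' @param minSeparation minimum circular separation between peaks in
#'   degrees (default 30, matching the rotamer-matching tolerance)
#' @param step sample step in degrees (taken from the trace when one is
#'   supplied)
#' @return data.frame with columns `angle`, `height`, `relint`, sorted by
#'   descending height; zero rows when nothing clears the threshold
#' @export
detectPeaks <- function(trace, threshold = 0.3, minSeparation = 30,
                        step = NULL) {
  if (is(trace, "DihedralTrace")) {
    d <- trace@densities
    step <- trace@step
  } else {
    d <- as.numeric(trace)
    if (is.null(step)) step <- 360 / length(d)
  }
  n <- length(d)
  stopifnot(n > 0, isTRUE(all.equal(step * n, 360)))
  empty <- data.frame(angle = numeric(0), height = numeric(0),
                      relint = numeric(0))
  if (all(d == d[1])) return(empty)      # constant trace: no local maxima

  # split the circular trace into runs of equal values, starting the scan
  # at a value change so no run straddles the scan origin
  start <- which(d != c(d[n], d[-n]))[1]
  ord <- ((start - 1L + seq_len(n) - 1L) %% n) + 1L   # circular scan order
  v <- d[ord]
  runId <- cumsum(c(TRUE, v[-1] != v[-n]))
  runFirst <- ord[!duplicated(runId)]
  runVal <- v[!duplicated(runId)]
  k <- length(runVal)
  prevVal <- runVal[c(k, seq_len(k - 1))]
  nextVal <- runVal[c(seq_len(k - 1) + 1, 1)]
  isPk <- runVal >= threshold & runVal > prevVal & runVal > nextVal
  if (!any(isPk)) return(empty)
  ang <- (runFirst[isPk] - 1) * step
  hgt <- runVal[isPk]

  # greedy circular non-maximum suppression, tallest first
  o <- order(-hgt, ang)
  ang <- ang[o]; hgt <- hgt[o]
  keep <- logical(length(ang))
  for (i in seq_along(ang)) {
    cd <- abs((ang[keep] - ang[i] + 180) %% 360 - 180)
    if (!length(cd) || all(cd >= minSeparation)) keep[i] <- TRUE
  }
  ang <- ang[keep]; hgt <- hgt[keep]
  data.frame(angle = ang, height = hgt, relint = hgt / max(hgt))
}
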