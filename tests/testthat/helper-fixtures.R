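# Shared fixtures and independent oracles for the test suite.

popSd <- function(g) sqrt(mean((g - mean(g))^2))   # crystallographic RMS

# the standard two-state fixture: SER 60% m / 40% p in a GLY-SER-GLY peptide
serFixture <- function(noiseSd = 0, seed = NULL) {
  generateFixture(c("GLY", "SER", "GLY"),
                  planted = list("2" = c(m = 0.6, p = 0.4)),
                  noiseSd = noiseSd, seed = seed)
}

residueCoordMatrix <- function(model, resno, alt = "") {
  a <- atoms(model)
  r <- a[a$resno == resno & a$alt %in% c("", alt), , drop = FALSE]
  # prefer the requested conformer where duplicated
  r <- r[order(r$elety, r$alt != alt), , drop = FALSE]
  r <- r[!duplicated(r$elety), , drop = FALSE]
  m <- as.matrix(r[, c("x", "y", "z")])
  rownames(m) <- r$elety
  m
}

# Independent peak-finding oracle: scans every sample of the circularly
# wrapped trace against its nearest differing neighbours in each direction
# (plateau -> run-start sample wins), thresholds, then greedily keeps the
# tallest peaks at >= minSep circular separation.
oraclePeaks <- function(d, threshold = 0.3, minSep = 30,
                        step = 360 / length(d)) {
  n <- length(d)
  if (all(d == d[1]))
    return(data.frame(angle = numeric(0), height = numeric(0),
                      relint = numeric(0)))
  cand <- list()
  for (i in seq_len(n)) {
    if (d[i] < threshold) next
    left1 <- if (i == 1) n else i - 1
    if (d[left1] == d[i]) next      # plateau: only the run-start sample
    if (d[left1] > d[i]) next
    # left flank differs and is lower; check the right flank (walk past
    # any plateau to the nearest differing value)
    k <- i
    repeat {
      k <- if (k == n) 1 else k + 1
      if (d[k] != d[i] || k == i) break
    }
    if (d[k] >= d[i]) next
    cand[[length(cand) + 1]] <- c(angle = (i - 1) * step, height = d[i])
  }
  if (!length(cand))
    return(data.frame(angle = numeric(0), height = numeric(0),
                      relint = numeric(0)))
  p <- as.data.frame(do.call(rbind, cand))
  p <- p[order(-p$height, p$angle), , drop = FALSE]
  kept <- p[0, , drop = FALSE]
  for (i in seq_len(nrow(p))) {
    dd <- abs((kept$angle - p$angle[i] + 180) %% 360 - 180)
    if (!nrow(kept) || all(dd >= minSep)) kept <- rbind(kept, p[i, ])
  }
  kept$relint <- kept$height / max(kept$height)
  rownames(kept) <- NULL
  kept
}

# Independent rotamer-matching oracle: exhaustive scan of the library for
# the residue type, computing the max per-chi circular deviation (symmetric
# terminal chis modulo 180), filtering at the tolerance and taking the
# highest-frequency survivor (ties: first name alphabetically).
oracleMatch <- function(angles, resid, lib, tol = 30) {
  e <- libraryEntries(lib)
  e <- e[e$resid == resid, , drop = FALSE]
  sym <- c(PHE = 2, TYR = 2, ASP = 2, GLU = 3)[resid]
  best <- NULL
  for (i in seq_len(nrow(e))) {
    dev <- 0
    for (k in seq_along(angles)) {
      mu <- e[[paste0("chi", k)]][i]
      per <- if (!is.na(sym) && k == sym) 180 else 360
      dk <- abs(angles[k] - mu) %% per
      dk <- min(dk, per - dk)
      dev <- max(dev, dk)
    }
    if (dev <= tol) {
      if (is.null(best) || e$frequency[i] > best$frequency ||
          (e$frequency[i] == best$frequency && e$rotamer[i] < best$rotamer))
        best <- list(rotamer = e$rotamer[i], frequency = e$frequency[i])
    }
  }
  if (is.null(best)) NA_character_ else best$rotamer
}

# random circular traces, some smooth, some with seam-straddling bumps
randomTrace <- function(n = 72) {
  kind <- sample(3, 1)
  if (kind == 1) {
    as.numeric(stats::filter(rnorm(n, 0, 0.5), rep(1 / 5, 5),
                             circular = TRUE))
  } else if (kind == 2) {
    ang <- seq(0, 360 - 360 / n, by = 360 / n)
    ctr <- runif(1, 0, 360)       # bump may straddle the 0/360 seam
    dd <- abs((ang - ctr + 180) %% 360 - 180)
    runif(1, 0.3, 2) * pmax(0, 1 - dd / runif(1, 20, 60)) +
      rnorm(n, 0, 0.05)
  } else {
    round(rnorm(n, 0.2, 0.4), 1)  # coarse values force plateaus and ties
  }
}
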