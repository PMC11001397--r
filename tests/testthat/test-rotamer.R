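lib <- rotamerLibrary()

test_that("the packaged library covers all 18 chi-bearing residue types", {
  e <- libraryEntries(lib)
  chiBearing <- setdiff(c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                          "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                          "PRO", "SER", "THR", "TRP", "TYR", "VAL"),
                        c("GLY", "ALA"))
  expect_setequal(unique(e$resid), chiBearing)
  expect_true(all(table(e$resid) >= 1))
  # threonine's three ideal rotamers are named p, t and m
  expect_setequal(e$rotamer[e$resid == "THR"], c("p", "t", "m"))
  expect_true(all(e$frequency > 0 & e$frequency <= 1))
})

test_that("malformed library tables are rejected with the row number", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("resid,rotamer,chi1,chi2,chi3,chi4,frequency",
               "SER,p,62,,,,0.48", "SER,,183,,,,0.2"), f)
  expect_error(rotamerLibrary(f), "row 2")
  writeLines(c("resid,rotamer,chi1,chi2,chi3,chi4,frequency",
               "SER,p,62,,,,0.48", "SER,p,-65,,,,0.3"), f)
  expect_error(rotamerLibrary(f), "duplicate")
  writeLines(c("resid,rotamer,chi1,chi2,chi3,chi4,frequency",
               "SER,p,62,,,,0.48", "SER,t,183,99,,,0.2"), f)
  expect_error(rotamerLibrary(f), "chi count")
})

test_that("candidate enumeration is the Cartesian product of per-chi peaks", {
  pk <- function(...) {
    a <- c(...)
    data.frame(angle = a, height = seq_along(a),
               relint = seq_along(a) / length(a))
  }
  two <- pk(60, 180); three <- pk(60, 180, 300)
  expect_equal(nrow(enumerateCandidates(list(two, three))), 6L)
  expect_equal(nrow(enumerateCandidates(list(two, pk()))), 0L)
  one <- enumerateCandidates(list(pk(60), pk(300)))
  expect_equal(nrow(one), 1L)
  expect_equal(one$chi1, 60)
  expect_equal(one$chi2, 300)
  # signal = sum of per-chi relative intensities, bounded by the chi count
  cands <- enumerateCandidates(list(two, three))
  expect_true(all(cands$signal > 0 & cands$signal <= 2))
  expect_equal(max(cands$signal), 2)     # tallest peak on both chis
})

test_that("exact library means match with zero deviation", {
  m <- matchRotamer(62, "THR", lib)
  expect_equal(m$rotamer, "p")
  expect_equal(m$maxdev, 0)
})

test_that("candidates beyond the 30-degree tolerance are rejected", {
  e <- libraryEntries(lib)
  serMeans <- e$chi1[e$resid == "SER"]
  probe <- 120   # 58 from p(62), 58 from t(178), 175 from m(-65)
  expect_true(all(pmin(abs(probe - serMeans) %% 360,
                       360 - abs(probe - serMeans) %% 360) > 30))
  expect_equal(nrow(matchRotamer(probe, "SER", lib)), 0L)
  # the boundary itself is inclusive
  expect_equal(matchRotamer(92, "SER", lib, tolerance = 30)$rotamer, "p")
  expect_equal(nrow(matchRotamer(93, "SER", lib, tolerance = 30)), 0L)
})

test_that("multiple matches resolve to the highest-frequency entry", {
  # THR p (0.49) vs m (0.43): -1.5 = 358.5 is within 30 of neither;
  # probe halfway between p (62) and m (-65 = 295): circularly ~63.5 from
  # both at tolerance 70 -> both match, p wins on frequency
  m <- matchRotamer(358.5, "THR", lib, tolerance = 70)
  expect_equal(m$rotamer, "p")
})

test_that("symmetric terminal chis match modulo 180 degrees", {
  e <- libraryEntries(lib)
  asp <- e[e$resid == "ASP" & e$rotamer == "m-20", ]
  flipped <- c(asp$chi1, asp$chi2 + 180)
  m <- matchRotamer(flipped %% 360, "ASP", lib)
  expect_equal(m$rotamer, "m-20")
  off <- matchRotamer(flipped %% 360, "ASP", lib, symmetryAware = FALSE)
  expect_false(identical(off$rotamer, "m-20") && off$maxdev == asp$maxdev)
})

test_that("matching agrees with the exhaustive library-scan oracle", {
  set.seed(21)
  types <- unique(libraryEntries(lib)$resid)
  for (resid in types) {
    nchi <- libraryChiCount(lib, resid)
    for (i in 1:100) {
      ang <- runif(nchi, 0, 360)
      got <- matchRotamer(ang, resid, lib)
      want <- oracleMatch(ang, resid, lib)
      if (is.na(want)) expect_equal(nrow(got), 0L)
      else expect_equal(got$rotamer, want)
    }
  }
})

test_that("the matched set grows monotonically with tolerance", {
  set.seed(22)
  for (i in 1:200) {
    ang <- runif(1, 0, 360)
    atTol <- nrow(matchRotamer(ang, "SER", lib, tolerance = 20))
    atBig <- nrow(matchRotamer(ang, "SER", lib, tolerance = 45))
    expect_gte(atBig, atTol)
  }
})

test_that("ranking dedupes by rotamer name and orders by signal then frequency", {
  md <- data.frame(rotamer = c("mt", "mt", "tp", "tt"),
                   frequency = c(0.59, 0.59, 0.29, 0.02),
                   signal = c(1.2, 1.8, 1.5, 0.9))
  r <- rankCandidates(md)
  expect_equal(r$rotamer, c("mt", "tp", "tt"))
  expect_equal(r$signal, c(1.8, 1.5, 0.9))
  # equal signals: higher frequency first
  md2 <- data.frame(rotamer = c("a", "b"), frequency = c(0.1, 0.4),
                    signal = c(1, 1))
  expect_equal(rankCandidates(md2)$rotamer, c("b", "a"))
  expect_lte(nrow(rankCandidates(md)), nrow(md))
})
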