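rankedFrame <- function(n, resid = "SER") {
  lib <- libraryEntries(rotamerLibrary())
  e <- lib[lib$resid == resid, ][seq_len(n), ]
  data.frame(rotamer = e$rotamer, frequency = e$frequency,
             signal = rev(seq_len(n)), ideal_chi1 = e$chi1)
}

test_that("plans truncate at maxAlts and collapse to empty below two", {
  expect_equal(nrow(makePlan(rankedFrame(3), maxAlts = 3)$rotamers), 3L)
  expect_equal(nrow(makePlan(rankedFrame(3), maxAlts = 2)$rotamers), 2L)
  expect_equal(nrow(makePlan(rankedFrame(1), maxAlts = 3)$rotamers), 0L)
  # a cap of 1 always means single-conformer output
  expect_equal(nrow(makePlan(rankedFrame(3), maxAlts = 1)$rotamers), 0L)
})

test_that("occupancies split equally and sum to exactly 1.00 at PDB precision", {
  expect_equal(multiconf:::.splitOccupancy(2), c(0.5, 0.5))
  expect_equal(multiconf:::.splitOccupancy(3), c(0.34, 0.33, 0.33))
  expect_equal(multiconf:::.splitOccupancy(4), c(0.25, 0.25, 0.25, 0.25))
  for (n in 2:6) expect_equal(sum(multiconf:::.splitOccupancy(n)), 1)
})

test_that("ALL mode duplicates every atom; SIDECHAIN shares N, C, O", {
  fx <- serFixture()
  plan2 <- makePlan(rankedFrame(2), maxAlts = 3, mode = "ALL")
  m <- buildAlternates(fx$single, "A", 2, "", plan2)
  a <- atoms(m)[atoms(m)$resno == 2, ]
  for (nm in c("N", "CA", "C", "O", "CB", "OG"))
    expect_setequal(a$alt[a$elety == nm], c("A", "B"))
  # duplicated backbone copies start at identical coordinates
  bbA <- a[a$elety == "N" & a$alt == "A", c("x", "y", "z")]
  bbB <- a[a$elety == "N" & a$alt == "B", c("x", "y", "z")]
  expect_equal(unlist(bbA), unlist(bbB), ignore_attr = TRUE)
  expect_equal(sort(a$o[a$elety == "OG"]), c(0.5, 0.5))

  side <- buildAlternates(fx$single, "A", 2, "",
                          makePlan(rankedFrame(2), mode = "SIDECHAIN"))
  as <- atoms(side)[atoms(side)$resno == 2, ]
  for (nm in c("N", "C", "O")) {
    expect_equal(as$alt[as$elety == nm], "")
    expect_equal(as$o[as$elety == nm], 1)
  }
  # "starting at the CA atom": CA carries altlocs too
  expect_setequal(as$alt[as$elety == "CA"], c("A", "B"))
  expect_setequal(as$alt[as$elety == "OG"], c("A", "B"))
})

test_that("three alternates get occupancies 0.34/0.33/0.33 in signal order", {
  fx <- generateFixture(c("GLY", "SER", "GLY"),
                        planted = list("2" = c(m = 0.45, p = 0.35,
                                               t = 0.20)))
  res <- buildMultiConformerModel(fx$single, fx$map)
  a <- atoms(res$multi)[atoms(res$multi)$resno == 2, ]
  og <- a[a$elety == "OG", ]
  expect_equal(og$alt, c("A", "B", "C"))
  expect_equal(og$o, c(0.34, 0.33, 0.33))
  expect_equal(sum(og$o), 1)
})

test_that("built side chains sit at ideal library chi means with unchanged bonds", {
  fx <- serFixture()
  res <- buildMultiConformerModel(fx$single, fx$map)
  lib <- libraryEntries(rotamerLibrary())
  for (alt in c("A", "B")) {
    co <- residueCoordMatrix(res$multi, 2, alt = alt)
    chi <- measureChis(co, "SER")[1]
    rot <- strsplit(res$report$built, ";")[[1]][match(alt, c("A", "B"))]
    mu <- lib$chi1[lib$resid == "SER" & lib$rotamer == rot] %% 360
    expect_lt(abs((chi - mu + 180) %% 360 - 180), 1e-6)
    # rotamer building changes only dihedrals, never bond lengths
    expect_equal(sqrt(sum((co["CB", ] - co["OG", ])^2)),
                 sqrt(sum((residueCoordMatrix(fx$single, 2)["CB", ] -
                           residueCoordMatrix(fx$single, 2)["OG", ])^2)),
                 tolerance = 1e-6)
  }
})

test_that("the 60/40 fixture rebuilds both rotamers with A = the major state", {
  fx <- serFixture()
  res <- buildMultiConformerModel(fx$single, fx$map)
  expect_equal(res$report$built, "m;p")
  expect_equal(res$report$altlocs, "A;B")
  a <- atoms(res$multi)
  expect_setequal(setdiff(unique(a$alt[a$resno == 2]), ""), c("A", "B"))
  # single-conformer companion keeps only the strongest rotamer, blank labels
  s <- atoms(res$single)
  expect_true(all(s$alt == ""))
  coS <- residueCoordMatrix(res$single, 2)
  coA <- residueCoordMatrix(res$multi, 2, alt = "A")
  expect_lt(max(abs(coS - coA)), 1e-12)
})

test_that("a zero map yields no alternates and an unchanged stripped model", {
  fx <- serFixture()
  flat <- fx$map
  set.seed(99)                         # tiny noise so the map is scalable
  flat@grid[] <- rnorm(length(flat@grid), 0, 1e-8)
  flat <- sigmaScale(densityMap(flat@grid, cellParams(fx$map)))
  res <- buildMultiConformerModel(fx$single, flat, threshold = 10)
  expect_identical(atoms(res$multi)[, c("x", "y", "z", "alt", "o")],
                   atoms(fx$single)[, c("x", "y", "z", "alt", "o")])
})

test_that("a three-state fixture capped at two keeps the two strongest states", {
  fx <- generateFixture(c("GLY", "SER", "GLY"),
                        planted = list("2" = c(m = 0.45, p = 0.35,
                                               t = 0.20)))
  res <- buildMultiConformerModel(fx$single, fx$map, maxAlts = 2)
  expect_equal(res$report$built, "m;p")     # the two highest occupancies
  a <- atoms(res$multi)
  expect_setequal(setdiff(unique(a$alt[a$resno == 2]), ""), c("A", "B"))
})

test_that("rerunning on the single-state output reproduces the rotamer calls", {
  fx <- serFixture()
  res1 <- buildMultiConformerModel(fx$single, fx$map)
  res2 <- buildMultiConformerModel(res1$single, fx$map)
  expect_equal(res2$report$built, res1$report$built)
  expect_equal(res2$report$rotamers, res1$report$rotamers)
})

test_that("pre-computed traces give results identical to in-memory sampling", {
  fx <- serFixture()
  res1 <- buildMultiConformerModel(fx$single, fx$map)
  f <- withr::local_tempfile(fileext = ".csv")
  writeTraceCSV(res1$traces, f)
  res2 <- buildMultiConformerModel(fx$single, fx$map,
                                   traces = readTraceCSV(f))
  expect_equal(atoms(res2$multi)[, c("x", "y", "z", "alt", "o")],
               atoms(res1$multi)[, c("x", "y", "z", "alt", "o")],
               tolerance = 1e-9)
})
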