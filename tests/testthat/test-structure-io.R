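test_that("a minimal one-atom PDB reads as one chain/residue/atom", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(paste0("ATOM      1  N   SER A   1       1.000   2.000",
                      "   3.000  1.00 10.00           N"), "END"), f)
  s <- readStructure(f)
  a <- atoms(s)
  expect_equal(nrow(a), 1L)
  expect_equal(a$elety, "N")
  expect_equal(unname(unlist(a[, c("x", "y", "z")])), c(1, 2, 3))
  expect_equal(a$alt, "")
})

test_that("altloc labels survive reading exactly as on disk", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CB  SER A   1       0.000   0.000   0.000  1.00 10.00           C",
    "ATOM      2  OG ASER A   1       1.400   0.000   0.000  0.60 10.00           O",
    "ATOM      3  OG BSER A   1       0.000   1.400   0.000  0.40 10.00           O",
    "END"), f)
  a <- atoms(readStructure(f))
  og <- a[a$elety == "OG", ]
  expect_equal(nrow(og), 2L)
  expect_equal(og$alt, c("A", "B"))
  expect_equal(og$o, c(0.6, 0.4))
})

test_that("empty or garbled files raise parse errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(character(0), f)
  expect_error(readStructure(f), "empty")
  writeLines(c("this is", "not a model"), f)
  expect_error(readStructure(f), "parse error")
  expect_error(readStructure("/nonexistent/file.pdb"), "no such file")
})

test_that("altloc stripping keeps the highest-occupancy conformer at occ 1", {
  fx <- serFixture()
  st <- stripAltConfs(fx$truth)
  a <- atoms(st)
  expect_true(all(a$alt == ""))
  expect_true(all(a$o == 1))
  # the kept OG must be the 60% "m" conformer's coordinates
  truthA <- atoms(fx$truth)
  ogA <- truthA[truthA$elety == "OG" & truthA$alt == "A", ]
  ogKept <- a[a$elety == "OG", ]
  expect_equal(unlist(ogKept[, c("x", "y", "z")]),
               unlist(ogA[, c("x", "y", "z")]), ignore_attr = TRUE)
})

test_that("stripping is idempotent and a no-op without altlocs", {
  fx <- serFixture()
  once <- stripAltConfs(fx$truth)
  twice <- stripAltConfs(once)
  expect_identical(atoms(once), atoms(twice))
  expect_identical(atoms(stripAltConfs(fx$single)), atoms(fx$single))
})

test_that("occupancy ties break toward the alphabetically earliest altloc", {
  fx <- generateFixture(c("GLY", "SER", "GLY"),
                        planted = list("2" = c(p = 0.5, m = 0.5)))
  a <- atoms(fx$truth)
  st <- atoms(stripAltConfs(fx$truth))
  ogA <- a[a$elety == "OG" & a$alt == "A", ]   # A was planted first (= p)
  ogKept <- st[st$elety == "OG", ]
  expect_equal(unlist(ogKept[, c("x", "y", "z")]),
               unlist(ogA[, c("x", "y", "z")]), ignore_attr = TRUE)
})

test_that("PDB round-trip preserves coordinates, altlocs and occupancies", {
  fx <- serFixture()
  f <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(fx$truth, f)
  back <- readStructure(f)
  a1 <- atoms(fx$truth); a2 <- atoms(back)
  expect_lt(max(abs(as.matrix(a1[, c("x", "y", "z")]) -
                    as.matrix(a2[, c("x", "y", "z")]))), 1e-3)
  expect_identical(a1$alt, a2$alt)
  expect_equal(a1$o, a2$o)
  # write -> read -> write is byte-stable
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("mmCIF round-trip preserves the same fields", {
  fx <- serFixture()
  f <- withr::local_tempfile(fileext = ".cif")
  writeStructure(fx$truth, f, format = "mmcif")
  back <- readStructure(f)
  a1 <- atoms(fx$truth); a2 <- atoms(back)
  expect_lt(max(abs(as.matrix(a1[, c("x", "y", "z")]) -
                    as.matrix(a2[, c("x", "y", "z")]))), 1e-3)
  expect_identical(a1$alt, a2$alt)
  expect_equal(a1$o, a2$o)
})

test_that("PDB fixed columns round occupancy to two decimals", {
  fx <- serFixture()
  a <- atoms(fx$single)
  a$o[1] <- 0.333
  m <- new("ProteinModel", atoms = a)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(m, f)
  expect_equal(atoms(readStructure(f))$o[1], 0.33)
})
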