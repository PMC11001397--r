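test_that("sigma scaling gives mean 0 / sd 1, records stats, errors on a constant grid", {
  set.seed(1)
  g <- array(runif(4 * 5 * 6, 0, 7), dim = c(4, 5, 6))
  m <- sigmaScale(densityMap(g, c(10, 12, 14, 90, 90, 90)))
  expect_lt(abs(mean(gridValues(m))), 1e-10)
  expect_lt(abs(popSd(gridValues(m)) - 1), 1e-10)
  expect_equal(m@mean, mean(g))
  expect_equal(m@sd, popSd(g))
  expect_error(sigmaScale(densityMap(array(3, dim = c(4, 4, 4)),
                                     c(10, 10, 10, 90, 90, 90))),
               "constant map")
})

test_that("a two-valued grid z-scores to -1/+1 and rescaling is idempotent", {
  g <- array(rep(c(0, 2), 32), dim = c(4, 4, 4))
  m <- sigmaScale(densityMap(g, c(8, 8, 8, 90, 90, 90)))
  v <- sort(unique(as.vector(gridValues(m))))
  expect_equal(v, c(-1, 1), tolerance = 1e-12)
  again <- sigmaScale(m)
  expect_lt(max(abs(gridValues(again) - gridValues(m))), 1e-10)
})

test_that("interpolation reproduces node values and respects lattice periodicity", {
  set.seed(2)
  n <- c(5, 6, 7)
  cell <- c(10, 12, 14, 90, 90, 90)
  m <- densityMap(array(rnorm(prod(n)), dim = n), cell)
  # grid node (i,j,k) sits at fractional ((i-1)/nx, ...)
  for (node in list(c(1, 1, 1), c(3, 4, 2), c(5, 6, 7))) {
    p <- (node - 1) / n * cell[1:3]
    expect_equal(interpolateMap(m, p), gridValues(m)[rbind(node)])
  }
  pts <- matrix(runif(30, -5, 25), ncol = 3)
  shift <- sweep(pts, 2, cell[1:3] * c(1, -2, 3), `+`)
  expect_equal(interpolateMap(m, pts), interpolateMap(m, shift),
               tolerance = 1e-9)
})

test_that("midpoint interpolation averages wrapped neighbours (P1)", {
  n <- c(4, 4, 4)
  cell <- c(8, 8, 8, 90, 90, 90)
  g <- array(0, dim = n)
  g[1, 1, 1] <- 1; g[2, 1, 1] <- 3
  m <- densityMap(g, cell)
  # halfway between nodes 1 and 2 along x
  expect_equal(interpolateMap(m, c(1, 0, 0)), 2)
  # halfway between the last node and the wrapped first node
  g2 <- array(0, dim = n); g2[4, 1, 1] <- 1; g2[1, 1, 1] <- 5
  m2 <- densityMap(g2, cell)
  expect_equal(interpolateMap(m2, c(7, 0, 0)), 3)
})

test_that("single-reflection synthesis is a cosine wave peaking at the origin plane", {
  cc <- mapCoefficients(matrix(c(1L, 0L, 0L), 1), 1, 0,
                        c(10, 10, 10, 90, 90, 90))
  m <- mapFromCoefficients(cc, gridSpacing = 0.5)
  g <- gridValues(m)
  prof <- g[, 1, 1]
  nx <- dim(g)[1]
  # closed form: proportional to cos(2 pi x / a); maximum on the x = 0 plane
  expect_equal(cor(prof, cos(2 * pi * (seq_len(nx) - 1) / nx)), 1,
               tolerance = 1e-10)
  expect_equal(which.max(prof), 1L)
  expect_true(all(abs(g[1, , ] - max(g)) < 1e-9))
})

test_that("an F000-only coefficient set is rejected as a constant map", {
  cc <- mapCoefficients(matrix(c(0L, 0L, 0L), 1), 100, 0,
                        c(10, 10, 10, 90, 90, 90))
  expect_error(mapFromCoefficients(cc), "constant map")
  expect_error(mapFromCoefficients(mapCoefficients(
    matrix(integer(0), ncol = 3), numeric(0), numeric(0),
    c(10, 10, 10, 90, 90, 90))), "empty")
})

test_that("coefficient round-trip reproduces the Gaussian fixture map", {
  fx <- serFixture()
  # analyse to just below the grid's Nyquist band and resynthesize on the
  # same grid: the residual is only the discarded top-band content
  sf <- structureFactors(fx$map, c(15, 13, 9))
  m2 <- mapFromCoefficients(sf, gridSpacing = 0.5)
  expect_equal(dim(gridValues(m2)), dim(gridValues(fx$map)))
  expect_gt(cor(as.vector(gridValues(m2)), as.vector(gridValues(fx$map))),
            0.999)
  expect_lt(max(abs(gridValues(m2) - gridValues(fx$map))), 0.2)
})

test_that("CCP4 map files round-trip grid and cell", {
  fx <- serFixture()
  f <- withr::local_tempfile(fileext = ".ccp4")
  writeCCP4Map(fx$map, f)
  back <- readCCP4Map(f)
  expect_lt(max(abs(gridValues(back) - gridValues(fx$map))), 1e-5)
  expect_lt(max(abs(cellParams(back) - cellParams(fx$map))), 1e-4)
})

test_that("MTZ files round-trip reflections and support label dialects", {
  fx <- serFixture()
  sf <- structureFactors(fx$map, c(6, 6, 5))
  f <- withr::local_tempfile(fileext = ".mtz")
  writeMTZ(sf, f, labels = c("2FOFCWT", "PH2FOFCWT"))
  back <- readMTZ(f)                       # auto-detected dialect
  expect_equal(nrow(back@hkl), nrow(sf@hkl))
  expect_lt(max(abs(back@amplitude - sf@amplitude)), 1e-3)
  expect_lt(max(abs((back@phase - sf@phase + 180) %% 360 - 180)), 1e-3)
  expect_identical(back@hkl, sf@hkl)
  back2 <- readMTZ(f, labels = c("2FOFCWT", "PH2FOFCWT"))
  expect_equal(back2@amplitude, back@amplitude)
  expect_error(readMTZ(f, labels = c("NOPE", "PHNOPE")), "not in file")
})

test_that("loadDensity prefers the map file over MTZ and always sigma-scales", {
  fx <- serFixture()
  fmap <- withr::local_tempfile(fileext = ".ccp4")
  writeCCP4Map(fx$map, fmap)
  sf <- structureFactors(fx$map, c(4, 4, 4))
  fmtz <- withr::local_tempfile(fileext = ".mtz")
  writeMTZ(sf, fmtz)
  both <- loadDensity(map = fmap, mtz = fmtz)
  expect_equal(dim(gridValues(both)), dim(gridValues(fx$map)))
  expect_true(isScaled(both))
  expect_error(loadDensity(), "supply")
})
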