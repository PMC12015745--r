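test_that("Gi* matches the exhaustive formula evaluation", {
  # 9x9 zero field with a 3x3 block of ones: the centre is the peak
  m <- matrix(0, 9, 9); m[4:6, 4:6] <- 1
  g <- grid(m, cellSize = 0.1, yll = 30)
  hs <- giStar(g, radius = 1)
  z <- gridValues(hs$z)
  expect_equal(which.max(z), which(seq_along(m) == (5 - 1) * 9 + 5))
  expect_gt(z[5, 5], 0)
  oracle <- giStarOracle(m, 1)
  expect_lt(max(abs(z - oracle)), 1e-9)

  # random fields with NODATA, radii 1-3, up to 20x20
  for (s in 1:4) {
    set.seed(s + 30)
    nr <- sample(6:20, 1); nc <- sample(6:20, 1)
    x <- matrix(rnorm(nr * nc), nr, nc)
    x[sample(nr * nc, 5)] <- NA
    rad <- sample(1:3, 1)
    gg <- grid(x, cellSize = 0.1, yll = 30)
    zz <- gridValues(giStar(gg, rad)$z)
    oo <- giStarOracle(x, rad)
    expect_lt(max(abs(zz - oo), na.rm = TRUE), 1e-9)
    expect_equal(is.na(zz), is.na(oo))
  }
})

test_that("Gi* degenerate and limiting cases are handled", {
  # constant field: all z = 0 with warning
  gC <- grid(matrix(5, 6, 6), cellSize = 0.1, yll = 30)
  expect_warning(hsC <- giStar(gC, 2), "constant")
  expect_true(all(gridValues(hsC$z) == 0))
  expect_true(all(gridValues(hsC$bin) == 0))
  # radius covering the whole grid: every window is the full field, z
  # degenerates to 0 everywhere and the z field sums to 0
  set.seed(35)
  gF <- grid(matrix(rnorm(25), 5, 5), cellSize = 0.1, yll = 30)
  hsF <- giStar(gF, radius = 10)
  expect_equal(sum(gridValues(hsF$z)), 0)
})

test_that("hot-spot bins reflect corrected significance and hot neighbourhoods", {
  w <- smallWorld(60, seed = 17, nOcc = 100)
  hs <- giStar(w$suitability, radius = 3)
  z <- gridValues(hs$z); p <- gridValues(hs$p); b <- gridValues(hs$bin)
  ok <- !is.na(b)
  # bin 3 <=> corrected p < 0.01 with positive z
  expect_true(all((b[ok] == 3) == (p[ok] < 0.01 & z[ok] > 0)))
  expect_true(all((abs(b[ok]) >= 2) == (p[ok] < 0.05)))
  # hot cells have neighbourhood mass above the global mean: z > 0 there
  expect_true(all(z[ok][b[ok] == 3] > 0))
  # hotspot area is a positive subset of the study area
  expect_gt(hotspotAreaKm2(hs), 0)
  a <- cellAreaMatrix(w$suitability)
  expect_lt(hotspotAreaKm2(hs), sum(a, na.rm = TRUE))
})

test_that("habitat centroid is the area-weighted balance point", {
  # single cell: its centre
  m <- matrix(0, 4, 4); m[2, 3] <- 1
  g <- grid(m, xll = 10, yll = 40, cellSize = 1)
  cen <- habitatCentroid(g)
  expect_equal(unname(cen["lon"]), 12.5)
  expect_equal(unname(cen["lat"]), 42.5)
  # two equal-latitude cells: midpoint longitude
  m2 <- matrix(0, 4, 4); m2[2, 1] <- 1; m2[2, 4] <- 1
  cen2 <- habitatCentroid(grid(m2, xll = 10, yll = 40, cellSize = 1))
  expect_equal(unname(cen2["lon"]), 12)
  expect_equal(unname(cen2["lat"]), 42.5)
  # symmetric cross: geometric centre
  m3 <- matrix(0, 5, 5); m3[3, ] <- 1; m3[, 3] <- 1
  cen3 <- habitatCentroid(grid(m3, xll = 0, yll = 0, cellSize = 1))
  expect_equal(unname(cen3["lon"]), 2.5)
  expect_equal(unname(cen3["lat"]), 2.5, tolerance = 1e-3)
  expect_error(habitatCentroid(grid(matrix(0, 3, 3))), "empty")
})

test_that("centroid shifts use haversine distance and initial bearing", {
  trk <- centroidTrack(data.frame(
    scenario = c("current", "A", "A"), period = c("now", "2050s", "2050s"),
    lon = c(90, 90, 90), lat = c(30, 31, 31)))
  sh <- centroidShift(trk)
  # 1 degree of latitude on a 6371-km sphere
  expect_equal(sh$distanceKm[1], 6371 * pi / 180, tolerance = 1e-6)
  expect_equal(sh$distanceKm[1], 111.19, tolerance = 1e-3)
  expect_equal(sh$bearingDeg[1], 0)
  # identical consecutive states
  expect_equal(sh$distanceKm[2], 0)
  expect_equal(sh$bearingDeg[2], 0)
  # symmetry under swap: same distance, reversed bearing
  trkR <- centroidTrack(data.frame(
    scenario = c("A", "current"), period = c("2050s", "now"),
    lon = c(90, 90), lat = c(31, 30)))
  shR <- centroidShift(trkR)
  expect_equal(shR$distanceKm[1], sh$distanceKm[1])
  expect_equal((sh$bearingDeg[1] - shR$bearingDeg[1]) %% 360, 180)
  expect_error(centroidShift(trk[1, ]), "2 states")
})

test_that("centroid climate annotation reads the right layers", {
  # constant 348-mm precipitation field annotates as 348
  b18 <- grid(matrix(348, 5, 5), xll = 88, yll = 29, cellSize = 0.5)
  b11 <- grid(matrix(-11, 5, 5), xll = 88, yll = 29, cellSize = 0.5)
  trk <- centroidTrack(data.frame(scenario = "current", period = "now",
                                  lon = 89, lat = 30))
  ann <- centroidClimate(trk, list(b11), list(b18))
  expect_equal(ann$bio18, 348)
  expect_equal(ann$bio11, -11)
  # empty track stays empty
  e <- centroidClimate(centroidTrack(data.frame(
    scenario = character(0), period = character(0),
    lon = numeric(0), lat = numeric(0))), list(), list())
  expect_equal(nrow(e), 0)
  # NODATA at the centroid resolves to the nearest valid cell within 3
  v <- matrix(348, 5, 5); v[3, 3] <- NA
  b18na <- grid(v, xll = 88, yll = 29, cellSize = 0.5)
  trkC <- centroidTrack(data.frame(scenario = "c", period = "n",
                                   lon = 89.25, lat = 30.25))
  annNA <- centroidClimate(trkC, list(b11), list(b18na))
  expect_equal(annNA$bio18, 348)
})
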