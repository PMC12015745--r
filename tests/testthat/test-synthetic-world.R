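test_that("environment generation is deterministic and ecologically shaped", {
  a <- generateEnvironment(worldGeometry(40, 40), seed = 9)
  b <- generateEnvironment(worldGeometry(40, 40), seed = 9)
  for (nm in layerNames(a))
    expect_identical(gridValues(getLayer(a, nm)), gridValues(getLayer(b, nm)))

  # the nine canonical predictors, tagged with their four families
  expect_setequal(layerNames(a),
                  c("Bio11", "Bio18", "T_SILT", "T_OC", "T_PH_H2O",
                    "ELE", "SLOP", "HV", "NT"))
  expect_setequal(unique(unname(a@roles)),
                  c("bioclimatic", "soil", "terrain", "land_cover"))

  # lapse rate: temperature decreases with elevation
  expect_lt(cor(as.vector(gridValues(getLayer(a, "ELE"))),
                as.vector(gridValues(getLayer(a, "Bio11")))), 0)
  # elevation span covers the alpine belt
  ele <- gridValues(getLayer(a, "ELE"))
  expect_lt(min(ele), 3000)
  expect_gt(max(ele), 5000)

  expect_error(generateEnvironment(worldGeometry(0, 10)), "degenerate")
})

test_that("truth suitability follows its closed form", {
  tr <- truthParams()
  # all weights zero: constant logistic(intercept)
  tr0 <- truthParams(weights = c(ELE = 0, Bio18 = 0, Bio11 = 0, HV = 0),
                     intercept = -1)
  stk <- constantStack(list(Bio11 = -6, Bio18 = 200, ELE = 4200, HV = 60))
  s0 <- computeTrueSuitability(stk, tr0)
  expect_equal(unique(as.vector(gridValues(s0))), plogis(-1))

  # at the joint optimum suitability is high
  sOpt <- computeTrueSuitability(stk, tr)
  expect_gt(gridValues(sOpt)[1, 1], 0.9)
  # closed-form check at a non-optimal point
  stk2 <- constantStack(list(Bio11 = -2, Bio18 = 150, ELE = 3800, HV = 20))
  s2 <- computeTrueSuitability(stk2, tr)
  eta <- tr$intercept +
    tr$weights[["ELE"]] * exp(-(3800 - tr$eleOpt)^2 / (2 * tr$eleBreadth^2)) +
    tr$weights[["Bio18"]] *
      exp(-(150 - tr$bio18Opt)^2 / (2 * tr$bio18Breadth^2)) +
    tr$weights[["Bio11"]] *
      exp(-(-2 - tr$bio11Opt)^2 / (2 * tr$bio11Breadth^2)) +
    tr$weights[["HV"]] * plogis((20 - tr$hvThreshold) / tr$hvScale)
  expect_equal(gridValues(s2)[1, 1], plogis(eta), tolerance = 1e-12)

  # unimodal along an elevation transect, everything else at optimum
  eles <- seq(3000, 5400, by = 100)
  nr <- 1; nc <- length(eles)
  mk <- function(v, nm) grid(matrix(v, nr, nc), cellSize = 1, name = nm)
  trans <- envStack(list(Bio11 = mk(-6, "Bio11"), Bio18 = mk(200, "Bio18"),
                         ELE = mk(eles, "ELE"), HV = mk(60, "HV")),
                    c("bioclimatic", "bioclimatic", "terrain", "land_cover"))
  st <- as.vector(gridValues(computeTrueSuitability(trans, tr)))
  expect_equal(eles[which.max(st)], tr$eleOpt)

  # missing variable named in the error
  stk3 <- constantStack(list(Bio11 = -6, Bio18 = 200, ELE = 4200))
  expect_error(computeTrueSuitability(stk3, tr), "HV")
})

test_that("occurrence sampling tracks suitability", {
  # concentrated suitability: all points land in the hot cell
  m <- matrix(1e-12, 5, 5); m[3, 3] <- 1
  s <- grid(m, xll = 0, yll = 0, cellSize = 1)
  occ <- sampleOccurrences(s, 1, seed = 1)
  expect_true(occ$lon > 2 && occ$lon < 3 && occ$lat > 2 && occ$lat < 3)

  w <- smallWorld(60, seed = 2, nOcc = 150)
  occ1 <- sampleOccurrences(w$suitability, 100, seed = 5)
  occ2 <- sampleOccurrences(w$suitability, 100, seed = 5)
  expect_identical(occ1, occ2)

  expect_error(sampleOccurrences(s, 1000), "exceeds")

  # mean truth suitability at sampled points beats the field mean, 10 seeds
  v <- gridValues(w$suitability)
  fieldMean <- mean(v, na.rm = TRUE)
  hits <- vapply(1:10, function(sd) {
    pts <- sampleOccurrences(w$suitability, 100, seed = sd)
    ex <- extractAtPoints(w$stack, pts)
    s <- computeTrueSuitability(w$stack)
    pc <- gridValues(s)[cbind(
      yartsa:::pointToCell(s, pts$lon, pts$lat)$row,
      yartsa:::pointToCell(s, pts$lon, pts$lat)$col)]
    mean(pc, na.rm = TRUE)
  }, 0)
  expect_true(all(hits > fieldMean))
})

test_that("future scenarios perturb only the climate layers", {
  w <- smallWorld(40, seed = 3, nOcc = 100)
  stk <- w$stack
  # identity scenario reproduces the current stack
  id <- scenarioSpec("id", "now", bio11Offset = 0, bio18Multiplier = 1,
                     nGcms = 2, jitterSdT = 0, jitterSdP = 0)
  fut <- generateFutureScenario(stk, id)
  expect_equal(gridValues(getLayer(fut[[1]], "Bio11")),
               gridValues(getLayer(stk, "Bio11")))
  expect_equal(gridValues(getLayer(fut[[1]], "Bio18")),
               gridValues(getLayer(stk, "Bio18")))

  # +3 C exact shift with zero jitter; substrate untouched
  warm <- scenarioSpec("w", "2050s", bio11Offset = 3, bio18Multiplier = 1,
                       nGcms = 7, jitterSdT = 0, jitterSdP = 0)
  fw <- generateFutureScenario(stk, warm)
  expect_length(fw, 7)
  expect_equal(gridValues(getLayer(fw[[4]], "Bio11")),
               gridValues(getLayer(stk, "Bio11")) + 3)
  expect_identical(gridValues(getLayer(fw[[4]], "ELE")),
                   gridValues(getLayer(stk, "ELE")))
  expect_identical(gridValues(getLayer(fw[[4]], "T_OC")),
                   gridValues(getLayer(stk, "T_OC")))

  expect_error(scenarioSpec(nGcms = 0), "nGcms")
})

test_that("warming shifts the suitability-weighted mean elevation upward", {
  stk <- generateEnvironment(worldGeometry(60, 60), seed = 4)
  tr <- truthParams()
  cur <- computeTrueSuitability(stk, tr)
  warm <- scenarioSpec("w", "x", bio11Offset = 2, bio18Multiplier = 1,
                       nGcms = 1, jitterSdT = 0, jitterSdP = 0)
  stkW <- generateFutureScenario(stk, warm)[[1]]
  futS <- computeTrueSuitability(stkW, tr)
  ele <- gridValues(getLayer(stk, "ELE"))
  wm <- function(s) sum(ele * gridValues(s)) / sum(gridValues(s))
  expect_gt(wm(futS), wm(cur))
})

test_that("simulateWorld writes a complete readable world", {
  d <- withr::local_tempdir()
  files <- simulateWorld(d, worldGeometry(20, 20), nOccurrences = 30,
                         seed = 2)
  expect_true(all(file.exists(files)))
  g <- readAsciiGrid(file.path(d, "ELE.asc"))
  expect_equal(nRows(g), 20)
  occ <- read.csv(file.path(d, "occurrences.csv"))
  expect_equal(nrow(occ), 30)
  expect_true(any(grepl("^scenario\\.", readLines(file.path(d,
                                                            "manifest.txt")))))
})
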