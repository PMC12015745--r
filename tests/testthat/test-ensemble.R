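test_that("the run design produces the configured grid of runs, reproducibly", {
  w <- smallWorld(40, seed = 10, nOcc = 100)
  d1 <- runDesign(w$stack, w$occurrences, algorithms = "GLM", nPaSets = 1,
                  paSize = 200, nReps = 1, seed = 5, predictGrids = FALSE)
  expect_length(d1$runs, 1)
  d2 <- runDesign(w$stack, w$occurrences,
                  algorithms = c("GLM", "CTA", "MaxEnt"),
                  nPaSets = 2, paSize = 200, nReps = 2, seed = 5,
                  predictGrids = FALSE)
  expect_length(d2$runs, 12)
  # same master seed: identical evaluation tables
  d3 <- runDesign(w$stack, w$occurrences,
                  algorithms = c("GLM", "CTA", "MaxEnt"),
                  nPaSets = 2, paSize = 200, nReps = 2, seed = 5,
                  predictGrids = FALSE)
  expect_equal(vapply(d2$runs, runTss, 0), vapply(d3$runs, runTss, 0))
  expect_equal(vapply(d2$runs, runAuc, 0), vapply(d3$runs, runAuc, 0))
  # holdout disjoint from training happens inside splitTrainTest; here check
  # evaluation was computed on the 20% partition size
  nPres <- sum(occurrencePoints(w$occurrences)$label == 1)
  n <- nrow(d2$runs[[1]]@holdout$features)
  expect_equal(n, (nPres - round(0.8 * nPres)) + (200 - round(0.8 * 200)))
})

test_that("TSS gating keeps qualifying runs and variables", {
  w <- smallWorld(40, seed = 11, nOcc = 100)
  d <- runDesign(w$stack, w$occurrences, algorithms = c("GLM", "MaxEnt"),
                 nPaSets = 1, paSize = 200, nReps = 2, seed = 6,
                 predictGrids = FALSE)
  runs <- d$runs
  # impose known TSS values
  tssVals <- c(0.6, 0.71, 0.9, 0.3)
  for (i in seq_along(runs)) runs[[i]]@evaluation$tss <- tssVals[i]
  sel <- selectRuns(runs, tssMin = 0.7, importanceMin = -1)
  expect_length(sel$runs, 2)
  expect_setequal(vapply(sel$runs, runTss, 0), c(0.71, 0.9))
  # gate 0 keeps everything with positive skill
  expect_length(selectRuns(runs, tssMin = 0, importanceMin = -1)$runs, 4)
  # all runs failing -> informative error
  expect_error(selectRuns(runs, tssMin = 0.95), "gate")
})

test_that("combiner arithmetic matches its definitions", {
  scoreMat <- matrix(c(0.2, 0.4, 0.9), 3, 1)
  expect_equal(yartsa:::combineScores(scoreMat, "EMmean", NULL, NULL)[1], 0.5)
  expect_equal(yartsa:::combineScores(scoreMat, "EMmedian", NULL, NULL)[1],
               0.4)
  # EMca: thresholds making votes {1, 1, 0}
  expect_equal(yartsa:::combineScores(scoreMat, "EMca",
                                      thresholds = c(0.1, 0.3, 0.95),
                                      NULL)[1], 2 / 3)
  # equal weights collapse EMwmean to EMmean
  expect_equal(yartsa:::combineScores(scoreMat, "EMwmean", NULL,
                                      weights = rep(1 / 3, 3))[1], 0.5)
  expect_error(yartsa:::combineScores(scoreMat, "EMxyz", NULL, NULL),
               "EMmean")
})

test_that("ensembles respect member bounds and EMca vote granularity", {
  w <- smallWorld(50, seed = 12, nOcc = 150)
  d <- runDesign(w$stack, w$occurrences,
                 algorithms = c("GLM", "CTA", "MaxEnt"), nPaSets = 1,
                 paSize = 300, nReps = 1, seed = 7)
  sel <- selectRuns(d$runs, tssMin = 0, importanceMin = -1)
  m <- length(sel$runs)
  vals <- lapply(sel$runs, function(r) gridValues(r@suitability))
  lo <- Reduce(pmin, vals); hi <- Reduce(pmax, vals)
  for (method in c("EMmean", "EMmedian", "EMwmean")) {
    ens <- combineRuns(sel$runs, method)
    v <- gridValues(ens@suitability)
    ok <- !is.na(v)
    expect_true(all(v[ok] >= lo[ok] - 1e-12 & v[ok] <= hi[ok] + 1e-12),
                label = paste(method, "bounded by members"))
  }
  ca <- combineRuns(sel$runs, "EMca")
  v <- gridValues(ca@suitability)
  expect_true(all(v[!is.na(v)] %in% ((0:m) / m)))
  expect_error(combineRuns(sel$runs, "EMbogus"), "valid")
})

test_that("binarization thresholds behave at the extremes and areas add up", {
  w <- smallWorld(40, seed = 13, nOcc = 100)
  suit <- w$suitability
  all1 <- binarizeMap(suit, 0)
  v1 <- gridValues(all1)
  expect_true(all(v1[!is.na(v1)] == 1))
  all0 <- binarizeMap(suit, max(gridValues(suit), na.rm = TRUE) + 0.1)
  expect_true(all(gridValues(all0) == 0, na.rm = TRUE))
  # area equals the independent sum over 1-cells
  bin <- binarizeMap(suit, 0.5)
  idx <- which(gridValues(bin) == 1, arr.ind = TRUE)
  manual <- sum(cellAreaKm2(bin, idx[, 1]))
  expect_equal(habitatAreaKm2(bin), manual)
})

test_that("ensemble ranking orders by TSS then AUC and beats its members", {
  w <- smallWorld(60, seed = 14, nOcc = 200)
  d <- runDesign(w$stack, w$occurrences,
                 algorithms = c("GLM", "CTA", "MaxEnt", "RF"), nPaSets = 1,
                 paSize = 400, nReps = 2, seed = 8, predictGrids = FALSE)
  sel <- selectRuns(d$runs, tssMin = 0.5, importanceMin = -1)
  rk <- rankEnsembles(sel$runs)
  tab <- rk$table
  expect_equal(tab$method[1], rk$best)
  expect_true(all(diff(tab$tss) <= 1e-12))
  # tie-break documented: equal TSS ordered by AUC
  ties <- which(abs(tab$tss - tab$tss[1]) < 1e-12)
  if (length(ties) > 1)
    expect_true(all(diff(tab$auc[ties]) <= 1e-12))
  # ensembling does not fall below the median member (the premise of
  # committee modelling)
  medMember <- median(vapply(sel$runs, runTss, 0))
  expect_gte(rk$table$tss[1], medMember)
})
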