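makeFeatures <- function(n, k = 2, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * k), n, k, dimnames = list(NULL, paste0("v", seq_len(k))))
}

test_that("SRE envelope equals presence quantiles and classifies containment", {
  x <- makeFeatures(40, 2, seed = 2)
  labels <- rep(c(1L, 0L), each = 20)
  # quantile 0: envelope is the presence min/max, training presences all 1
  sre0 <- fitSre(x, labels, quantile = 0)
  pres <- x[labels == 1, ]
  expect_equal(sre0@model$lo, apply(pres, 2, min))
  expect_equal(sre0@model$hi, apply(pres, 2, max))
  expect_true(all(predictSuitability(sre0, pres) == 1))
  # a point outside one envelope scores 0
  out <- matrix(c(max(pres[, 1]) + 10, mean(pres[, 2])), 1,
                dimnames = list(NULL, colnames(x)))
  expect_equal(predictSuitability(sre0, out), 0)

  # order-statistic oracle for interior quantiles (type-7 interpolation)
  set.seed(5)
  p20 <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("v1", "v2")))
  sre <- fitSre(p20, rep(1L, 20), quantile = 0.1)
  for (v in c("v1", "v2")) {
    s <- sort(p20[, v])
    h <- function(p) { hh <- (20 - 1) * p + 1
      s[floor(hh)] + (hh - floor(hh)) * (s[floor(hh) + 1] - s[floor(hh)]) }
    expect_equal(unname(sre@model$lo[v]), h(0.1), tolerance = 1e-12)
    expect_equal(unname(sre@model$hi[v]), h(0.9), tolerance = 1e-12)
  }
})

test_that("logistic GLM recovers a known slope and the null is flat", {
  set.seed(31)
  n <- 5000
  x <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "v1"))
  y <- rbinom(n, 1, plogis(0.8 * x[, 1]))
  fit <- fitGlmLogistic(x, y)
  # coefficient is on the z scale; undo the standardization
  slope <- unname(fit@model$coef[["v1"]] / fit@scale[[1]])
  expect_equal(slope, 0.8, tolerance = 0.1)

  # shuffled labels: held-out AUC ~ 0.5
  set.seed(32)
  ysh <- sample(y)
  fitN <- fitGlmLogistic(x[1:4000, , drop = FALSE], ysh[1:4000])
  aucN <- computeAuc(predictSuitability(fitN, x[4001:5000, , drop = FALSE]),
                     ysh[4001:5000])
  expect_lt(abs(aucN - 0.5), 0.05)

  # intercept-only information: 25% positives -> constant 0.25
  xc <- matrix(1, 400, 1, dimnames = list(NULL, "v1"))
  yc <- rep(c(1L, 0L, 0L, 0L), 100)
  fitC <- fitGlmLogistic(xc, yc)
  expect_equal(unique(round(predictSuitability(fitC, xc), 10)), 0.25)

  # perfect separation falls back to ridge with a warning
  xs <- matrix(c(-(10:1), 1:10), 20, 1, dimnames = list(NULL, "v1"))
  ys <- rep(c(0L, 1L), each = 10)
  expect_warning(fitS <- fitGlmLogistic(xs, ys), "separation")
  expect_true(fitS@meta$ridgeFallback)
  expect_true(all(predictSuitability(fitS, xs) >= 0 &
                    predictSuitability(fitS, xs) <= 1))
})

test_that("classification tree finds the separating split", {
  # separable 1-D data: split near 0, perfect training accuracy
  x <- matrix(seq(-1, 1, length.out = 100), 100, 1,
              dimnames = list(NULL, "v1"))
  y <- as.integer(x[, 1] > 0)
  fit <- fitCta(x, y, minLeaf = 1)
  sp <- fit@model$splits
  expect_lt(abs(sp[1, "index"]), 2 / 99 + 1e-9)  # within one grid point of 0
  expect_true(all((predictSuitability(fit, x) >= 0.5) == (y == 1)))

  # pure labels: single constant leaf
  fitP <- fitCta(x, rep(1L, 100))
  expect_equal(unique(predictSuitability(fitP, x)), 1)

  # first split matches an exhaustive Gini search on a 30-point fixture
  set.seed(41)
  x30 <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, "v1"))
  y30 <- rbinom(30, 1, plogis(2 * x30[, 1]))
  if (length(unique(y30)) == 2) {
    fit30 <- fitCta(x30, y30, minLeaf = 1)
    giniGain <- function(thr) {
      L <- y30[x30[, 1] < thr]; R <- y30[x30[, 1] >= thr]
      gini <- function(v) if (!length(v)) 0 else
        1 - mean(v)^2 - (1 - mean(v))^2
      gini(y30) - (length(L) * gini(L) + length(R) * gini(R)) / 30
    }
    s <- sort(x30[, 1])
    mids <- (s[-1] + s[-30]) / 2
    bestMid <- mids[which.max(vapply(mids, giniGain, 0))]
    expect_equal(unname(fit30@model$splits[1, "index"]), bestMid,
                 tolerance = 1e-9)
  }
})

test_that("MaxEnt-lite responds to contrast and regularization", {
  # background identical to presences: near-constant field
  set.seed(51)
  p <- makeFeatures(100, 2, seed = 51)
  feats <- rbind(p, p)
  labels <- rep(c(1L, 0L), each = 100)
  fit0 <- fitMaxentLite(feats, labels)
  expect_lt(sd(predictSuitability(fit0, p)), 0.02)

  # unimodal truth: transect response peaks near the optimum
  set.seed(52)
  n <- 800
  x <- matrix(runif(n, -3, 3), n, 1, dimnames = list(NULL, "v1"))
  s <- exp(-(x[, 1] - 0.5)^2 / (2 * 0.8^2))
  pres <- x[runif(n) < s, , drop = FALSE]
  bg <- matrix(runif(500, -3, 3), 500, 1, dimnames = list(NULL, "v1"))
  fitU <- fitMaxentLite(rbind(pres, bg),
                        c(rep(1L, nrow(pres)), rep(0L, 500)))
  grid1 <- matrix(seq(-3, 3, 0.05), ncol = 1,
                  dimnames = list(NULL, "v1"))
  resp <- predictSuitability(fitU, grid1)
  mode <- grid1[which.max(resp), 1]
  expect_lt(abs(mode - 0.5), 0.4)   # within breadth/2 of the optimum

  # heavy penalty flattens the model
  fitR <- fitMaxentLite(rbind(pres, bg),
                        c(rep(1L, nrow(pres)), rep(0L, 500)), reg = 100)
  expect_lt(sd(predictSuitability(fitR, grid1)), 1e-6)
})

test_that("prediction respects the learner contract across the registry", {
  w <- smallWorld(40, seed = 7, nOcc = 120)
  ex <- extractAtPoints(w$stack, occurrencePoints(w$occurrences))
  pf <- ex$features[ex$valid, , drop = FALSE]
  pa <- samplePseudoAbsences(w$stack, occurrencePoints(w$occurrences),
                             n = 150, seed = 2)
  bg <- extractAtPoints(w$stack, pa)$features
  feats <- rbind(pf, bg[!apply(is.na(bg), 1, any), , drop = FALSE])
  labels <- c(rep(1L, nrow(pf)), rep(0L, nrow(feats) - nrow(pf)))
  for (alg in listAlgorithms()) {
    fit <- fitLearner(alg, feats, labels, seed = 99)
    sc <- predictSuitability(fit, feats)
    expect_true(all(sc >= 0 & sc <= 1), label = paste(alg, "bounded"))
    # refit with the same seed reproduces predictions exactly
    fit2 <- fitLearner(alg, feats, labels, seed = 99)
    expect_identical(sc, predictSuitability(fit2, feats),
                     label = paste(alg, "deterministic"))
    # empty input -> empty output
    expect_length(predictSuitability(fit, feats[0, , drop = FALSE]), 0)
  }
  # schema mismatch names the columns
  fit <- fitLearner("GLM", feats, labels)
  bad <- feats; colnames(bad)[1] <- "XX"
  expect_error(predictSuitability(fit, bad), "columns")
})

test_that("GLM predictions equal the inverse-logit of stored coefficients", {
  x <- makeFeatures(200, 2, seed = 61)
  y <- rbinom(200, 1, plogis(x[, 1] - 0.5 * x[, 2]))
  fit <- fitGlmLogistic(x, y)
  rows <- x[1:3, , drop = FALSE]
  z <- sweep(sweep(rows, 2, fit@center), 2, fit@scale, "/")
  manual <- plogis(fit@model$coef["(Intercept)"] +
                     fit@model$coef["v1"] * z[, 1] +
                     fit@model$coef["v2"] * z[, 2] +
                     fit@model$coef["v1.sq"] * z[, 1]^2 +
                     fit@model$coef["v2.sq"] * z[, 2]^2)
  expect_equal(unname(predictSuitability(fit, rows)), unname(manual),
               tolerance = 1e-12)
})

test_that("native learners discriminate well and SRE trails the field", {
  aucs <- matrix(NA_real_, 5, 4,
                 dimnames = list(NULL, c("SRE", "GLM", "CTA", "MaxEnt")))
  for (s in 1:5) {
    w <- smallWorld(80, seed = s + 200, nOcc = 250)
    d <- runDesign(w$stack, w$occurrences,
                   algorithms = colnames(aucs), nPaSets = 1, paSize = 600,
                   nReps = 1, seed = s, predictGrids = FALSE)
    for (r in d$runs) aucs[s, r@algorithm] <- runAuc(r)
  }
  means <- colMeans(aucs)
  expect_true(all(means[c("GLM", "CTA", "MaxEnt")] > 0.8))
  expect_equal(names(which.min(means)), "SRE")
})
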