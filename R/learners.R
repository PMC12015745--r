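# Base-learner contract and the algorithm suite behind it.
#
# Four learners are implemented natively and fully specified (SRE envelope,
# logistic GLM, classification tree, MaxEnt-lite); the remaining slots of
# the ten-algorithm design (RF, GBM, GAM, ANN, FDA, MARS) are filled by
# contract-compliant fits built on established packages. Every learner
# returns suitability scores in [0, 1] and is deterministic after fitting.

#' @include grid.R
NULL

#' A fitted base learner
#'
#' @slot algorithm algorithm id (one of [listAlgorithms()])
#' @slot model fitted object, opaque per algorithm
#' @slot columns training feature column names (order matters)
#' @slot center,scale per-column standardization parameters (from training)
#' @slot meta list: seed, hyper-parameters, warnings recorded during fitting
#' @export
setClass("FittedLearner",
  representation(algorithm = "character", model = "ANY",
                 columns = "character", center = "numeric",
                 scale = "numeric", meta = "list"))

setMethod("show", "FittedLearner", function(object) {
  cat(sprintf("FittedLearner <%s> on %d variables: %s\n", object@algorithm,
              length(object@columns), paste(object@columns, collapse = ", ")))
})

## standardization helpers -------------------------------------------------

colStats <- function(features) {
  list(center = apply(features, 2, mean),
       scale = pmax(apply(features, 2, sd), 1e-9))
}

zScore <- function(features, center, scale) {
  sweep(sweep(features, 2, center), 2, scale, "/")
}

## z + z^2 design used by GLM and FDA
linQuad <- function(z) {
  q <- z^2
  colnames(q) <- paste0(colnames(z), ".sq")
  cbind(z, q)
}

## hinge basis: max(0, z - k) and max(0, k - z) at given knots (per column)
hingeBasis <- function(z, knots) {
  out <- list()
  for (v in colnames(z)) {
    for (i in seq_along(knots[[v]])) {
      k <- knots[[v]][i]
      out[[paste0(v, ".hp", i)]] <- pmax(z[, v] - k, 0)
      out[[paste0(v, ".hm", i)]] <- pmax(k - z[, v], 0)
    }
  }
  do.call(cbind, out)
}

newLearner <- function(algorithm, model, columns, center, scale, meta) {
  new("FittedLearner", algorithm = algorithm, model = model,
      columns = columns, center = center, scale = scale, meta = meta)
}

# ---------------------------------------------------------------------------
# Native learners

#' Surface range envelope (SRE)
#'
#' Per variable, the envelope is the `[q, 1-q]` presence quantile interval;
#' a point scores 1 if every variable lies inside its envelope (inclusive),
#' else 0. A variable constant across presences yields a zero-width envelope
#' that passes on equality.
#'
#' @param features numeric matrix with named columns
#' @param labels 0/1 vector; only presence rows are used
#' @param quantile tail mass trimmed per side, in `[0, 0.5)` (default 0.025)
#' @param seed unused (SRE is deterministic); kept for contract uniformity
#' @return a [FittedLearner-class]
#' @export
fitSre <- function(features, labels, quantile = 0.025, seed = 1) {
  stopifnot(quantile >= 0, quantile < 0.5)
  pres <- features[labels == 1, , drop = FALSE]
  if (nrow(pres) < 2) stop("SRE needs at least 2 presence records")
  env <- apply(pres, 2, function(x)
    stats::quantile(x, c(quantile, 1 - quantile), names = FALSE, type = 7))
  newLearner("SRE", list(lo = env[1, ], hi = env[2, ]),
             colnames(features), center = rep(0, ncol(features)),
             scale = rep(1, ncol(features)),
             meta = list(quantile = quantile, seed = seed))
}

#' Logistic GLM on linear + quadratic terms
#'
#' Maximum-likelihood logistic regression (IRLS via [stats::glm()]) on
#' standardized linear and quadratic terms. Under perfect separation the fit
#' falls back to a ridge-penalized solution (glmnet, `alpha = 0`) and the
#' fallback is recorded in the learner's metadata.
#'
#' @inheritParams fitSre
#' @param maxIter IRLS iteration cap
#' @param tol IRLS convergence tolerance
#' @return a [FittedLearner-class]
#' @export
fitGlmLogistic <- function(features, labels, maxIter = 100, tol = 1e-8,
                           seed = 1) {
  if (length(unique(labels)) < 2) stop("both classes required")
  st <- colStats(features)
  X <- linQuad(zScore(features, st$center, st$scale))
  sep <- FALSE
  fit <- withCallingHandlers(
    glm.fit(cbind(1, X), labels, family = binomial(),
            control = list(maxit = maxIter, epsilon = tol)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  bad <- isTRUE(sep) || isTRUE(any(abs(fit$coefficients) > 1e3))
  if (bad) {
    warning("perfect separation detected; using ridge fallback")
    keep <- apply(X, 2, sd) > 1e-12
    beta <- setNames(rep(0, 1 + ncol(X)), c("(Intercept)", colnames(X)))
    if (any(keep)) {
      rf <- glmnet::glmnet(X[, keep, drop = FALSE], labels,
                           family = "binomial", alpha = 0,
                           lambda = 1e-3, standardize = FALSE)
      beta[c(TRUE, keep)] <- as.numeric(coef(rf))
    } else {
      beta["(Intercept)"] <- qlogis(mean(labels))
    }
    model <- list(coef = beta, ridge = TRUE)
  } else {
    model <- list(coef = setNames(fit$coefficients,
                                  c("(Intercept)", colnames(X))),
                  ridge = FALSE)
  }
  model$coef[is.na(model$coef)] <- 0   # collinear/constant columns
  newLearner("GLM", model, colnames(features), st$center, st$scale,
             meta = list(seed = seed, ridgeFallback = bad))
}

#' Classification tree (CTA)
#'
#' Binary recursive partitioning by Gini impurity via rpart; leaves predict
#' the positive fraction of their training records.
#'
#' @inheritParams fitSre
#' @param maxDepth maximum tree depth
#' @param minLeaf minimum records per leaf
#' @return a [FittedLearner-class]
#' @export
fitCta <- function(features, labels, maxDepth = 8, minLeaf = 5, seed = 1) {
  if (length(unique(labels)) < 2) {
    # pure-label input: a single leaf predicting that label's probability
    return(newLearner("CTA", list(constant = mean(labels)),
                      colnames(features), rep(0, ncol(features)),
                      rep(1, ncol(features)),
                      meta = list(seed = seed, pure = TRUE)))
  }
  set.seed(seed)
  df <- data.frame(.y = factor(labels, levels = c(0, 1)), features,
                   check.names = FALSE)
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      control = rpart::rpart.control(
                        maxdepth = maxDepth, minbucket = minLeaf,
                        minsplit = max(2 * minLeaf, 4), cp = 1e-4,
                        xval = 0))
  newLearner("CTA", fit, colnames(features),
             center = rep(0, ncol(features)), scale = rep(1, ncol(features)),
             meta = list(seed = seed, maxDepth = maxDepth, minLeaf = minLeaf))
}

#' MaxEnt-lite: presence/background penalized logistic discrimination
#'
#' Approximates MaxEnt by logistic discrimination of presences against
#' background points on standardized linear + quadratic + hinge-at-median
#' features with an L1 penalty (glmnet). Output is the logistic response,
#' already in `[0, 1]`. As `reg` grows all penalized weights shrink to zero
#' and the prediction tends to a constant.
#'
#' @inheritParams fitSre
#' @param labels 0/1 vector; 1 = presence, 0 = background
#' @param reg L1 penalty (glmnet lambda)
#' @param maxIter optimizer iteration cap
#' @return a [FittedLearner-class]
#' @export
fitMaxentLite <- function(features, labels, reg = 1e-3, maxIter = 1e5,
                          seed = 1) {
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0)
    stop("presences and background must both be non-empty")
  set.seed(seed)
  st <- colStats(features)
  z <- zScore(features, st$center, st$scale)
  knots <- lapply(as.data.frame(z), function(x) median(x))
  names(knots) <- colnames(z)
  X <- cbind(linQuad(z), hingeBasis(z, knots))
  fit <- glmnet::glmnet(X, labels, family = "binomial", alpha = 1,
                        lambda = reg, standardize = FALSE,
                        maxit = maxIter)
  if (fit$jerr != 0) warning("MaxEnt-lite optimizer did not fully converge; ",
                             "returning best iterate")
  newLearner("MaxEnt", list(fit = fit, knots = knots), colnames(features),
             st$center, st$scale, meta = list(seed = seed, reg = reg))
}

# ---------------------------------------------------------------------------
# Contract-compliant suite fillers

fitRf <- function(features, labels, nTree = 100, seed = 1) {
  set.seed(seed)
  fit <- randomForest::randomForest(
    x = features, y = factor(labels, levels = c(0, 1)), ntree = nTree)
  newLearner("RF", fit, colnames(features), rep(0, ncol(features)),
             rep(1, ncol(features)), meta = list(seed = seed, nTree = nTree))
}

fitGbm <- function(features, labels, nRounds = 60, maxDepth = 3, eta = 0.1,
                   seed = 1) {
  set.seed(seed)
  fit <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = maxDepth,
                  eta = eta, nthread = 1),
    data = xgboost::xgb.DMatrix(features, label = labels, nthread = 1),
    nrounds = nRounds, verbose = 0)
  newLearner("GBM", fit, colnames(features), rep(0, ncol(features)),
             rep(1, ncol(features)), meta = list(seed = seed))
}

fitGam <- function(features, labels, k = 5, seed = 1) {
  set.seed(seed)
  df <- data.frame(.y = labels, features, check.names = FALSE)
  terms <- vapply(colnames(features), function(v)
    sprintf("s(`%s`, k = %d)", v, k), "")
  fit <- mgcv::gam(as.formula(paste(".y ~", paste(terms, collapse = " + "))),
                   data = df, family = binomial())
  newLearner("GAM", fit, colnames(features), rep(0, ncol(features)),
             rep(1, ncol(features)), meta = list(seed = seed, k = k))
}

fitAnn <- function(features, labels, size = 5, decay = 0.01, maxit = 200,
                   seed = 1) {
  set.seed(seed)
  st <- colStats(features)
  z <- zScore(features, st$center, st$scale)
  fit <- nnet::nnet(x = z, y = labels, size = size, decay = decay,
                    maxit = maxit, entropy = TRUE, trace = FALSE)
  newLearner("ANN", fit, colnames(features), st$center, st$scale,
             meta = list(seed = seed, size = size))
}

## FDA-lite: discriminant analysis on a quadratic basis (LDA posterior)
fitFda <- function(features, labels, seed = 1) {
  set.seed(seed)
  st <- colStats(features)
  X <- linQuad(zScore(features, st$center, st$scale))
  fit <- MASS::lda(X, grouping = factor(labels, levels = c(0, 1)))
  newLearner("FDA", fit, colnames(features), st$center, st$scale,
             meta = list(seed = seed))
}

## MARS-lite: logistic regression on a piecewise-linear hinge basis with
## knots at the training quartiles (ridge-stabilized)
fitMars <- function(features, labels, seed = 1) {
  set.seed(seed)
  st <- colStats(features)
  z <- zScore(features, st$center, st$scale)
  knots <- lapply(as.data.frame(z), function(x)
    unique(stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)))
  names(knots) <- colnames(z)
  X <- cbind(z, hingeBasis(z, knots))
  fit <- glmnet::glmnet(X, labels, family = "binomial", alpha = 0,
                        lambda = 1e-4, standardize = FALSE)
  newLearner("MARS", list(fit = fit, knots = knots), colnames(features),
             st$center, st$scale, meta = list(seed = seed))
}

# ---------------------------------------------------------------------------
# Registry

learnerRegistry <- new.env(parent = emptyenv())

#' Register a learner-fitting function
#'
#' A fit function has signature `function(features, labels, seed, ...)` and
#' must return a [FittedLearner-class] whose predictions lie in `[0, 1]`.
#'
#' @param id algorithm id string
#' @param fitFun fitting function
#' @export
registerLearner <- function(id, fitFun) {
  stopifnot(is.character(id), is.function(fitFun))
  assign(id, fitFun, envir = learnerRegistry)
  invisible(id)
}

#' List registered algorithm ids
#' @return character vector
#' @export
listAlgorithms <- function() sort(ls(learnerRegistry))

#' Fit a registered learner by algorithm id
#' @param id algorithm id (see [listAlgorithms()])
#' @param features,labels training data
#' @param seed integer seed
#' @param ... passed to the underlying fit function
#' @return a [FittedLearner-class]
#' @export
fitLearner <- function(id, features, labels, seed = 1, ...) {
  if (!exists(id, envir = learnerRegistry))
    stop("unknown algorithm '", id, "'; registered: ",
         paste(listAlgorithms(), collapse = ", "))
  get(id, envir = learnerRegistry)(features, labels, seed = seed, ...)
}

## populated at load time
registerDefaultLearners <- function() {
  registerLearner("SRE", fitSre)
  registerLearner("GLM", fitGlmLogistic)
  registerLearner("CTA", fitCta)
  registerLearner("MaxEnt", fitMaxentLite)
  registerLearner("RF", fitRf)
  registerLearner("GBM", fitGbm)
  registerLearner("GAM", fitGam)
  registerLearner("ANN", fitAnn)
  registerLearner("FDA", fitFda)
  registerLearner("MARS", fitMars)
}

.onLoad <- function(libname, pkgname) registerDefaultLearners()

# ---------------------------------------------------------------------------
# Prediction

#' Predict habitat suitability
#'
#' Vectorized, deterministic prediction in `[0, 1]`. Feature columns must
#' match the training columns by name; rows containing `NA` (NODATA) yield
#' `NA` scores.
#'
#' @param learner a [FittedLearner-class]
#' @param features numeric matrix with named columns
#' @return numeric vector of scores, `NA` for invalid rows
#' @export
predictSuitability <- function(learner, features) {
  stopifnot(is(learner, "FittedLearner"))
  if (is.null(dim(features)))
    features <- matrix(features, ncol = length(learner@columns),
                       dimnames = list(NULL, learner@columns))
  if (!identical(sort(colnames(features)), sort(learner@columns)))
    stop("feature columns do not match training columns; expected {",
         paste(learner@columns, collapse = ", "), "} got {",
         paste(colnames(features), collapse = ", "), "}")
  features <- features[, learner@columns, drop = FALSE]
  n <- nrow(features)
  if (n == 0) return(numeric(0))
  ok <- !apply(is.na(features), 1, any)
  out <- rep(NA_real_, n)
  if (!any(ok)) return(out)
  f <- features[ok, , drop = FALSE]
  z <- zScore(f, learner@center, learner@scale)
  p <- switch(learner@algorithm,
    SRE = {
      m <- learner@model
      inside <- rep(TRUE, nrow(f))
      for (v in learner@columns)
        inside <- inside & f[, v] >= m$lo[v] & f[, v] <= m$hi[v]
      as.numeric(inside)
    },
    GLM = {
      X <- cbind(1, linQuad(z))
      as.numeric(plogis(X %*% learner@model$coef))
    },
    CTA = {
      if (is.list(learner@model) && !is.null(learner@model$constant)) {
        rep(learner@model$constant, nrow(f))
      } else {
        df <- data.frame(f, check.names = FALSE)
        predict(learner@model, newdata = df, type = "prob")[, "1"]
      }
    },
    MaxEnt = {
      X <- cbind(linQuad(z), hingeBasis(z, learner@model$knots))
      as.numeric(predict(learner@model$fit, newx = X, type = "response"))
    },
    RF = predict(learner@model, newdata = f, type = "prob")[, "1"],
    GBM = as.numeric(predict(learner@model, newdata = f)),
    GAM = {
      df <- data.frame(f, check.names = FALSE)
      as.numeric(predict(learner@model, newdata = df, type = "response"))
    },
    ANN = as.numeric(predict(learner@model, newdata = z)),
    FDA = {
      X <- linQuad(z)
      predict(learner@model, newdata = X)$posterior[, "1"]
    },
    MARS = {
      X <- cbind(z, hingeBasis(z, learner@model$knots))
      as.numeric(predict(learner@model$fit, newx = X, type = "response"))
    },
    stop("no prediction rule for algorithm '", learner@algorithm, "'")
  )
  out[ok] <- pmin(pmax(p, 0), 1)
  out
}

#' Predict a suitability Grid from an environmental stack
#'
#' Applies a fitted learner to every valid cell of the stack.
#' @param learner a [FittedLearner-class]
#' @param stack an [EnvStack-class] containing the training variables
#' @return a [Grid-class] of scores (NODATA preserved)
#' @export
predictGrid <- function(learner, stack) {
  g1 <- stack@layers[[1]]
  mask <- validMask(stack)
  idx <- which(mask)
  feats <- vapply(learner@columns,
                  function(v) getLayer(stack, v)@values[idx],
                  numeric(length(idx)))
  if (length(idx) == 1) feats <- matrix(feats, 1)
  colnames(feats) <- learner@columns
  vals <- matrix(NA_real_, nRows(g1), nCols(g1))
  vals[idx] <- predictSuitability(learner, feats)
  grid(vals, xll = g1@xll, yll = g1@yll, cellSize = g1@cellSize,
       name = paste0("suitability_", learner@algorithm))
}
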