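# The multi-run single-model design, TSS-gated selection, the four ensemble
# combiners, pooled ensemble evaluation and aggregate variable importance.

#' @include grid.R learners.R evaluation.R occurrences.R
NULL

#' One single-model run
#'
#' A fitted learner on one pseudo-absence set and replicate, with its
#' holdout evaluation, permutation importance and (optionally) its
#' suitability surface. The holdout is disjoint from training by
#' construction of the stratified split.
#'
#' @slot learner a [FittedLearner-class]
#' @slot algorithm algorithm id
#' @slot paSet pseudo-absence set index
#' @slot replicate replicate index
#' @slot evaluation holdout [evaluateBinary()] result at the TSS-optimal
#'   threshold, plus `auc`
#' @slot importance [permutationImportance()] table
#' @slot suitability a [Grid-class] or `NULL`
#' @slot holdout list with `features`, `labels` of the 20 % test partition
#' @export
setClass("RunResult",
  representation(learner = "FittedLearner", algorithm = "character",
                 paSet = "integer", replicate = "integer",
                 evaluation = "list", importance = "data.frame",
                 suitability = "ANY", holdout = "list"))

setMethod("show", "RunResult", function(object) {
  cat(sprintf("RunResult %s (PA %d, rep %d): TSS %.3f, AUC %.3f\n",
              object@algorithm, object@paSet, object@replicate,
              object@evaluation$tss, object@evaluation$auc))
})

#' @describeIn runDesign holdout TSS of one run
#' @param run a `RunResult`
#' @export
runTss <- function(run) run@evaluation$tss

#' @describeIn runDesign holdout AUC of one run
#' @export
runAuc <- function(run) run@evaluation$auc

#' Run the multi-model design
#'
#' Executes `nPaSets x |algorithms| x nReps` single-model runs. Each
#' pseudo-absence set is drawn once; each replicate draws its own stratified
#' 80/20 train/test split; every run is evaluated on its holdout at the
#' TSS-optimal threshold and its permutation importance recorded. The
#' canonical design (2 pseudo-absence sets of 1000 points, 10 algorithms,
#' 5 replicates) yields 100 runs. A failing run is recorded and excluded;
#' the design continues. Fully reproducible from `seed`.
#'
#' @param stack an [EnvStack-class] restricted to the modelling variables
#' @param occurrences an [OccurrenceSet-class] (cleaned presences)
#' @param algorithms character vector of registered algorithm ids
#' @param nPaSets number of pseudo-absence sets (default 2)
#' @param paSize points per pseudo-absence set (default 1000)
#' @param nReps replicates per algorithm and set (default 5)
#' @param trainFraction training fraction (default 0.8)
#' @param seed master seed; per-(set, replicate, algorithm) seeds derive
#'   from it by fixed offsets
#' @param predictGrids if `TRUE`, each run also predicts its suitability
#'   surface over the stack (needed for map combiners)
#' @return list with `runs` (list of [RunResult-class]) and `failures`
#'   (data frame of recorded errors)
#' @export
runDesign <- function(stack, occurrences, algorithms = listAlgorithms(),
                      nPaSets = 2, paSize = 1000, nReps = 5,
                      trainFraction = 0.8, seed = 1, predictGrids = TRUE) {
  stopifnot(is(occurrences, "OccurrenceSet"), nPaSets >= 1, nReps >= 1)
  pres <- occurrencePoints(occurrences)
  set.seed(seed)
  paSeeds <- sample.int(.Machine$integer.max, nPaSets)
  splitSeeds <- matrix(sample.int(.Machine$integer.max, nPaSets * nReps),
                       nPaSets, nReps)
  fitSeeds <- array(sample.int(.Machine$integer.max,
                               nPaSets * nReps * length(algorithms)),
                    c(nPaSets, nReps, length(algorithms)))
  presX <- extractAtPoints(stack, pres)
  pf <- presX$features[presX$valid, , drop = FALSE]
  runs <- list()
  failures <- data.frame(algorithm = character(), paSet = integer(),
                         replicate = integer(), message = character())
  for (p in seq_len(nPaSets)) {
    pa <- samplePseudoAbsences(stack, pres, n = paSize, seed = paSeeds[p])
    paX <- extractAtPoints(stack, pa)
    bg <- paX$features[paX$valid, , drop = FALSE]
    feats <- rbind(pf, bg)
    labels <- c(rep(1L, nrow(pf)), rep(0L, nrow(bg)))
    for (r in seq_len(nReps)) {
      sp <- splitTrainTest(labels, fraction = trainFraction,
                           seed = splitSeeds[p, r])
      for (a in seq_along(algorithms)) {
        alg <- algorithms[a]
        res <- tryCatch({
          fit <- fitLearner(alg, feats[sp$train, , drop = FALSE],
                            labels[sp$train], seed = fitSeeds[p, r, a])
          testF <- feats[sp$test, , drop = FALSE]
          testL <- labels[sp$test]
          scores <- predictSuitability(fit, testF)
          opt <- findOptimalThreshold(scores, testL)
          ev <- opt$evaluation
          ev$auc <- computeAuc(scores, testL)
          imp <- permutationImportance(fit, feats[sp$train, , drop = FALSE],
                                       nPerm = 2, seed = fitSeeds[p, r, a])
          suit <- if (predictGrids) predictGrid(fit, stack) else NULL
          new("RunResult", learner = fit, algorithm = alg,
              paSet = as.integer(p), replicate = as.integer(r),
              evaluation = ev, importance = imp, suitability = suit,
              holdout = list(features = testF, labels = testL))
        }, error = function(e) e)
        if (inherits(res, "error")) {
          failures <- rbind(failures, data.frame(
            algorithm = alg, paSet = p, replicate = r,
            message = conditionMessage(res)))
        } else {
          runs[[length(runs) + 1]] <- res
        }
      }
    }
  }
  list(runs = runs, failures = failures)
}

#' TSS gate and variable retention
#'
#' Keeps runs whose holdout TSS exceeds `tssMin` (default 0.7), then keeps
#' variables whose mean permutation importance over the kept runs exceeds
#' `importanceMin` (default 0.1).
#'
#' @param runs list of [RunResult-class]
#' @param tssMin TSS gate
#' @param importanceMin mean-importance gate
#' @return list with `runs` (kept), `variables` (retained names),
#'   `meanImportance` (named vector)
#' @export
selectRuns <- function(runs, tssMin = 0.7, importanceMin = 0.1) {
  kept <- Filter(function(r) runTss(r) > tssMin, runs)
  if (!length(kept))
    stop("no run exceeds the TSS gate of ", tssMin,
         "; consider relaxing the gate")
  impTabs <- lapply(kept, function(r) r@importance)
  vars <- impTabs[[1]]$variable
  m <- sapply(impTabs, function(t) t$importance[match(vars, t$variable)])
  if (is.null(dim(m))) m <- matrix(m, nrow = length(vars))
  meanImp <- setNames(rowMeans(m), vars)
  list(runs = kept, variables = vars[meanImp > importanceMin],
       meanImportance = meanImp)
}

#' An ensemble of gated runs
#'
#' @slot runs gated member runs
#' @slot method combiner: `EMmean`, `EMmedian`, `EMca` or `EMwmean`
#' @slot suitability combined suitability [Grid-class] (or `NULL`)
#' @slot memberThresholds per-member TSS-optimal thresholds
#' @slot threshold ensemble binarization threshold (pooled holdout)
#' @slot evaluation pooled-holdout evaluation of the combined scores
#' @slot importance aggregate importance table (mean member shares,
#'   renormalized to 100 %)
#' @export
setClass("EnsembleModel",
  representation(runs = "list", method = "character", suitability = "ANY",
                 memberThresholds = "numeric", threshold = "numeric",
                 evaluation = "list", importance = "data.frame"))

setMethod("show", "EnsembleModel", function(object) {
  cat(sprintf("EnsembleModel <%s>: %d members, TSS %.3f, AUC %.3f, thr %.3f\n",
              object@method, length(object@runs), object@evaluation$tss,
              object@evaluation$auc, object@threshold))
})

#' @describeIn combineRuns pooled-holdout evaluation of an ensemble
#' @param x an `EnsembleModel`
#' @export
ensembleEvaluation <- function(x) x@evaluation

#' @describeIn combineRuns aggregate variable-importance table
#' @export
ensembleImportance <- function(x) x@importance

validCombiners <- c("EMmean", "EMmedian", "EMca", "EMwmean")

## combine a members x n score matrix into one ensemble score vector
combineScores <- function(scoreMat, method, thresholds, weights) {
  switch(method,
    EMmean = colMeans(scoreMat),
    EMmedian = apply(scoreMat, 2, median),
    EMca = colMeans(scoreMat >= thresholds),
    EMwmean = as.numeric(weights %*% scoreMat),
    stop("unknown combiner '", method, "'; valid: ",
         paste(validCombiners, collapse = ", ")))
}

#' Combine gated runs into an ensemble model
#'
#' Per cell, the combined score is the arithmetic mean of member scores
#' (`EMmean`), their median (`EMmedian`), the fraction of members voting
#' presence after each is binarized at its own TSS-optimal threshold
#' (`EMca`), or the TSS-weighted mean with weights `TSS_i / sum TSS`
#' (`EMwmean`). The ensemble is evaluated on the pooled member holdouts and
#' its binarization threshold re-optimized on that pool.
#'
#' @param runs gated list of [RunResult-class] (with suitability grids if a
#'   combined map is wanted)
#' @param method one of `EMmean`, `EMmedian`, `EMca`, `EMwmean`
#' @return an [EnsembleModel-class]
#' @export
combineRuns <- function(runs, method = "EMca") {
  if (!method %in% validCombiners)
    stop("unknown combiner '", method, "'; valid: ",
         paste(validCombiners, collapse = ", "))
  if (!length(runs)) stop("need at least one gated run")
  thresholds <- vapply(runs, function(r) r@evaluation$threshold, 0)
  tss <- vapply(runs, runTss, 0)
  weights <- if (sum(tss) > 0) tss / sum(tss) else rep(1 / length(tss),
                                                       length(tss))
  # combined suitability surface
  suit <- NULL
  if (!is.null(runs[[1]]@suitability)) {
    g1 <- runs[[1]]@suitability
    mask <- !is.na(g1@values)
    idx <- which(mask)
    scoreMat <- t(vapply(runs, function(r) r@suitability@values[idx],
                         numeric(length(idx))))
    comb <- combineScores(scoreMat, method, thresholds, weights)
    vals <- matrix(NA_real_, nRows(g1), nCols(g1))
    vals[idx] <- comb
    suit <- grid(vals, xll = g1@xll, yll = g1@yll, cellSize = g1@cellSize,
                 name = paste0("suitability_", method))
  }
  # pooled-holdout evaluation: every member scores every pooled point
  pooled <- poolHoldouts(runs)
  scoreMat <- t(vapply(runs, function(r)
    predictSuitability(r@learner, pooled$features),
    numeric(nrow(pooled$features))))
  scores <- combineScores(scoreMat, method, thresholds, weights)
  opt <- findOptimalThreshold(scores, pooled$labels)
  ev <- opt$evaluation
  ev$auc <- computeAuc(scores, pooled$labels)
  # aggregate importance: mean member share, renormalized
  vars <- runs[[1]]@importance$variable
  shareMat <- vapply(runs, function(r)
    r@importance$share[match(vars, r@importance$variable)],
    numeric(length(vars)))
  if (is.null(dim(shareMat))) shareMat <- matrix(shareMat, length(vars))
  mShare <- rowMeans(shareMat)
  mShare <- if (sum(mShare) > 0) 100 * mShare / sum(mShare) else mShare
  imp <- data.frame(variable = vars, share = mShare)
  new("EnsembleModel", runs = runs, method = method, suitability = suit,
      memberThresholds = thresholds, threshold = opt$threshold,
      evaluation = ev, importance = imp)
}

## deduplicated pooled holdout points across members
poolHoldouts <- function(runs) {
  feats <- do.call(rbind, lapply(runs, function(r) r@holdout$features))
  labels <- unlist(lapply(runs, function(r) r@holdout$labels))
  dup <- duplicated(feats)
  list(features = feats[!dup, , drop = FALSE], labels = labels[!dup])
}

#' Binarize a suitability map
#'
#' Cell = 1 iff `score >= threshold`; NODATA preserved.
#' @param suitability a [Grid-class]
#' @param threshold cut-off from [findOptimalThreshold()] on pooled holdout
#'   data
#' @return a 0/1 [Grid-class]
#' @export
binarizeMap <- function(suitability, threshold) {
  g <- suitability
  g@values <- (g@values >= threshold) * 1
  g@name <- paste0(suitability@name, "_bin")
  g
}

#' Rank the four ensemble combiners
#'
#' Builds all four ensembles from the same gated runs, tabulates their
#' pooled-holdout AUC/TSS/sensitivity/specificity, and picks the best by
#' TSS (ties broken by AUC, then by combiner order).
#'
#' @param runs gated list of [RunResult-class]
#' @param methods combiners to rank (default all four)
#' @return list with `table` (data frame), `best` (method id) and
#'   `models` (named list of [EnsembleModel-class])
#' @export
rankEnsembles <- function(runs, methods = validCombiners) {
  models <- lapply(methods, function(m) combineRuns(runs, m))
  names(models) <- methods
  tab <- do.call(rbind, lapply(methods, function(m) {
    ev <- models[[m]]@evaluation
    data.frame(method = m, auc = ev$auc, tss = ev$tss,
               sensitivity = ev$sensitivity, specificity = ev$specificity)
  }))
  ord <- order(-tab$tss, -tab$auc, match(tab$method, methods))
  list(table = tab[ord, ], best = tab$method[ord][1], models = models)
}
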