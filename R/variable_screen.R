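# Two-tier predictor selection: pairwise-correlation filtering and grouped
# contribution screening.

#' Greedy pairwise-correlation filter
#'
#' While any pair of retained variables has `|Pearson r| >= rMax`, the pair
#' with the largest `|r|` is located and its lower-priority member dropped.
#' The result contains no pair violating the threshold. Zero-variance
#' variables are dropped up front with a recorded warning.
#'
#' @param features numeric matrix with named columns
#' @param rMax correlation threshold (default 0.6)
#' @param priority named numeric vector, higher = kept preferentially
#'   (defaults to equal priority, ties broken by column order)
#' @return list with `retained` (character), `dropped`, `corMatrix`,
#'   `warnings`, and the thresholds used
#' @examples
#' x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
#' x[, 2] <- x[, 1] + rnorm(100, 0, 0.1)
#' correlationFilter(x, 0.6, c(a = 3, b = 2, c = 1))$retained
#' @export
correlationFilter <- function(features, rMax = 0.6, priority = NULL) {
  vars <- colnames(features)
  if (length(vars) < 2) stop("need at least 2 variables")
  if (is.null(priority))
    priority <- setNames(rev(seq_along(vars)) / length(vars), vars)
  warnings <- character()
  constant <- vars[apply(features, 2, function(x) sd(x) < 1e-12)]
  if (length(constant)) {
    warnings <- c(warnings, paste("dropped zero-variance variable(s):",
                                  paste(constant, collapse = ", ")))
    warning(warnings[length(warnings)])
  }
  keep <- setdiff(vars, constant)
  cm <- cor(features[, keep, drop = FALSE])
  full <- cor(features[, setdiff(vars, constant), drop = FALSE])
  dropped <- constant
  while (length(keep) >= 2) {
    sub <- abs(cm[keep, keep, drop = FALSE])
    diag(sub) <- 0
    if (max(sub) < rMax) break
    ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    pair <- c(keep[ij[1]], keep[ij[2]])
    # drop the lower-priority member; tie -> later column order
    loser <- if (priority[pair[1]] < priority[pair[2]]) pair[1]
             else if (priority[pair[2]] < priority[pair[1]]) pair[2]
             else pair[which.max(match(pair, vars))]
    keep <- setdiff(keep, loser)
    dropped <- c(dropped, loser)
  }
  list(retained = keep, dropped = dropped, corMatrix = full,
       rMax = rMax, priority = priority, warnings = warnings)
}

#' Grouped contribution screen
#'
#' Within each variable group (bioclimatic, soil, terrain, land cover), the
#' MaxEnt-lite learner is fitted `nReps` times against freshly resampled
#' pseudo-absences; a variable's contribution is its normalized permutation-
#' importance share (percent), averaged over repetitions. Variables with
#' mean contribution above `contributionMin` are retained, and the
#' correlation filter is then re-applied within each group using mean
#' contribution as the priority.
#'
#' @param stack an [EnvStack-class]
#' @param presences data frame of presence points (`lon`, `lat`)
#' @param nReps MaxEnt-lite repetitions per group (default 10)
#' @param contributionMin retention threshold in percent (default 15)
#' @param rMax correlation threshold for the within-group re-filter
#' @param paSize pseudo-absences drawn per repetition
#' @param seed integer seed
#' @return list with `retained`, per-variable `contribution` (percent),
#'   `byGroup` details and the thresholds used
#' @export
contributionScreen <- function(stack, presences, nReps = 10,
                               contributionMin = 15, rMax = 0.6,
                               paSize = 1000, seed = 1) {
  stopifnot(nReps >= 1)
  set.seed(seed)
  repSeeds <- sample.int(.Machine$integer.max, nReps)
  presX <- extractAtPoints(stack, presences)
  pf <- presX$features[presX$valid, , drop = FALSE]
  groups <- split(layerNames(stack), stack@roles[layerNames(stack)])
  contrib <- setNames(rep(NA_real_, length(layerNames(stack))),
                      layerNames(stack))
  byGroup <- list()
  retained <- character()
  for (gname in names(groups)) {
    gvars <- groups[[gname]]
    if (!length(gvars)) { warning("group '", gname, "' empty; skipped"); next }
    shares <- matrix(0, nReps, length(gvars),
                     dimnames = list(NULL, gvars))
    for (r in seq_len(nReps)) {
      pa <- samplePseudoAbsences(stack, presences, n = paSize,
                                 seed = repSeeds[r])
      paX <- extractAtPoints(stack, pa)
      bg <- paX$features[paX$valid, , drop = FALSE]
      feats <- rbind(pf[, gvars, drop = FALSE], bg[, gvars, drop = FALSE])
      labels <- c(rep(1L, nrow(pf)), rep(0L, nrow(bg)))
      if (length(gvars) == 1) {
        shares[r, ] <- 100
        next
      }
      fit <- fitMaxentLite(feats, labels, seed = repSeeds[r])
      imp <- permutationImportance(fit, feats, nPerm = 2, seed = repSeeds[r])
      shares[r, imp$variable] <- imp$share
    }
    mShare <- colMeans(shares)
    contrib[gvars] <- mShare
    # contributionMin <= 0 disables the screen entirely
    keep <- if (contributionMin <= 0) gvars else gvars[mShare > contributionMin]
    # re-apply the correlation filter within the group, contribution as
    # priority
    if (length(keep) >= 2) {
      cf <- correlationFilter(pf[, keep, drop = FALSE], rMax = rMax,
                              priority = mShare[keep])
      keep <- cf$retained
    }
    byGroup[[gname]] <- list(variables = gvars, contribution = mShare,
                             retained = keep)
    retained <- c(retained, keep)
  }
  list(retained = retained, contribution = contrib, byGroup = byGroup,
       contributionMin = contributionMin, rMax = rMax, nReps = nReps)
}
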