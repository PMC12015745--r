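# Confusion-matrix metrics, rank-based AUC, TSS-optimal thresholding and
# permutation variable importance.

#' Evaluate binary predictions at a threshold
#'
#' Predictions are `score >= threshold`. Sensitivity and specificity are
#' reported in percent; the true skill statistic is
#' `TSS = sensitivity/100 + specificity/100 - 1`.
#'
#' @param scores numeric scores in `[0, 1]` (finite)
#' @param labels 0/1 vector, both classes present
#' @param threshold cut-off in score units
#' @return list with `sensitivity`, `specificity` (percent), `tss`,
#'   `threshold` and counts `tp`, `fp`, `tn`, `fn`
#' @examples
#' evaluateBinary(c(.9, .8, .2, .1), c(1, 1, 0, 0), 0.5)$tss
#' @export
evaluateBinary <- function(scores, labels, threshold) {
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2)
    stop("labels must contain both classes 0 and 1")
  if (any(!is.finite(scores))) stop("scores must be finite")
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1); fn <- sum(!pred & labels == 1)
  tn <- sum(!pred & labels == 0); fp <- sum(pred & labels == 0)
  se <- tp / (tp + fn); sp <- tn / (tn + fp)
  list(sensitivity = 100 * se, specificity = 100 * sp,
       tss = se + sp - 1, threshold = threshold,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' True skill statistic from printed sensitivity/specificity
#'
#' Recovers `TSS = Se/100 + Sp/100 - 1` from percent values, as when
#' checking a published evaluation table.
#' @param sensitivity,specificity percent values
#' @return TSS in `[-1, 1]`
#' @export
tssFromRates <- function(sensitivity, specificity) {
  sensitivity / 100 + specificity / 100 - 1
}

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, ties counting one half.
#'
#' @inheritParams evaluateBinary
#' @return AUC in `[0, 1]`
#' @export
computeAuc <- function(scores, labels) {
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2)
    stop("labels must contain both classes 0 and 1")
  r <- rank(scores)          # midranks handle ties as 1/2
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' TSS-maximizing threshold
#'
#' Scans candidate thresholds at the midpoints of sorted unique scores
#' (for a single unique score, that score itself) and returns the one
#' maximizing TSS; ties break toward the lowest threshold. This is the
#' ROC-threshold used to binarize continuous suitability maps.
#'
#' @inheritParams evaluateBinary
#' @return list with `threshold` and the full [evaluateBinary()] result
#' @export
findOptimalThreshold <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- if (length(u) == 1) u else (u[-1] + u[-length(u)]) / 2
  best <- NULL
  for (th in cand) {
    ev <- evaluateBinary(scores, labels, th)
    if (is.null(best) || ev$tss > best$tss + 1e-12) best <- ev
  }
  list(threshold = best$threshold, evaluation = best)
}

#' Permutation variable importance
#'
#' For each variable: predict on the original features, then on features
#' with that column permuted; importance is `1 - cor(original, permuted)`,
#' averaged over `nPerm` permutations and floored at zero. Shares are
#' normalized to sum to 100 % over variables with nonzero importance.
#'
#' @param learner a fitted learner (see [predictSuitability()])
#' @param features numeric matrix with named columns matching training
#' @param nPerm permutations per variable
#' @param seed integer seed
#' @return data.frame with `variable`, `importance`, `share` (percent)
#' @export
permutationImportance <- function(learner, features, nPerm = 3, seed = 1) {
  set.seed(seed)
  base <- predictSuitability(learner, features)
  vars <- colnames(features)
  imp <- numeric(length(vars))
  if (sd(base) < 1e-12) {
    warning("constant predictions; importance undefined, returning zeros")
    return(data.frame(variable = vars, importance = 0, share = 0))
  }
  for (j in seq_along(vars)) {
    acc <- 0
    for (p in seq_len(nPerm)) {
      fp <- features
      fp[, j] <- fp[sample(nrow(fp)), j]
      prm <- predictSuitability(learner, fp)
      r <- if (sd(prm) < 1e-12) 0 else cor(base, prm)
      acc <- acc + (1 - r)
    }
    imp[j] <- max(acc / nPerm, 0)
  }
  tot <- sum(imp)
  data.frame(variable = vars, importance = imp,
             share = if (tot > 0) 100 * imp / tot else rep(0, length(imp)))
}
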