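# Shared fixtures, built in code and cached for the session.

.fixtures <- new.env(parent = emptyenv())

## small synthetic world + truth + occurrences, memoized by key
smallWorld <- function(n = 60, seed = 1, nOcc = 200) {
  key <- sprintf("w_%d_%d_%d", n, seed, nOcc)
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  stk <- generateEnvironment(worldGeometry(n, n), seed = seed)
  suit <- computeTrueSuitability(stk)
  occ <- cleanOccurrences(sampleOccurrences(suit, nOcc, seed = seed + 100))
  .fixtures[[key]] <- list(stack = stk, suitability = suit, occurrences = occ)
  .fixtures[[key]]
}

## tiny hand-made stack: one constant layer per variable, for closed-form
## checks
constantStack <- function(values, nr = 3, nc = 3, cellSize = 1) {
  roles <- c(Bio11 = "bioclimatic", Bio18 = "bioclimatic",
             T_SILT = "soil", T_OC = "soil", T_PH_H2O = "soil",
             ELE = "terrain", SLOP = "terrain",
             HV = "land_cover", NT = "land_cover")
  layers <- lapply(names(values), function(nm)
    grid(matrix(values[[nm]], nr, nc), xll = 0, yll = 0,
         cellSize = cellSize, name = nm))
  names(layers) <- names(values)
  envStack(layers, unname(roles[names(values)]))
}

## brute-force AUC by concordant-pair counting
aucOracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

## exhaustive Gi* evaluation by double loop (independent of the package path)
giStarOracle <- function(x, radius) {
  valid <- !is.na(x)
  n <- sum(valid)
  xbar <- mean(x[valid])
  S <- sqrt(sum(x[valid]^2) / n - xbar^2)
  nr <- nrow(x); nc <- ncol(x)
  z <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!valid[i, j]) next
    sw <- 0; sx <- 0
    for (a in seq_len(nr)) for (b in seq_len(nc)) {
      if (!valid[a, b]) next
      if (max(abs(a - i), abs(b - j)) <= radius) {
        sw <- sw + 1; sx <- sx + x[a, b]
      }
    }
    den <- S * sqrt(max(n * sw - sw^2, 0) / (n - 1))
    z[i, j] <- if (den < 1e-15) 0 else (sx - xbar * sw) / den
  }
  z
}

## all terminal retained sets reachable by priority-respecting elimination:
## at each step any violating pair may be chosen and its lower-priority
## member dropped
correlationFilterOracle <- function(features, rMax, priority) {
  vars <- colnames(features)
  cm <- abs(cor(features))
  results <- list()
  recurse <- function(keep) {
    sub <- cm[keep, keep, drop = FALSE]; diag(sub) <- 0
    viol <- which(sub >= rMax, arr.ind = TRUE)
    if (nrow(viol) == 0) {
      results[[paste(sort(keep), collapse = "|")]] <<- sort(keep)
      return(invisible())
    }
    for (k in seq_len(nrow(viol))) {
      pair <- c(keep[viol[k, 1]], keep[viol[k, 2]])
      loser <- if (priority[pair[1]] < priority[pair[2]]) pair[1]
               else if (priority[pair[2]] < priority[pair[1]]) pair[2]
               else pair[which.max(match(pair, vars))]
      recurse(setdiff(keep, loser))
    }
  }
  recurse(vars)
  results
}
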