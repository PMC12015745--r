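# Scenario projection: GCM consensus, habitat-change classification,
# elevation-band gain/loss accounting and per-region area summaries.

#' Majority consensus across GCM binary maps
#'
#' A cell is habitat in the consensus iff strictly more than half of the
#' input maps mark it habitat (4 of 7 passes; 3 of 6 fails). NODATA wherever
#' any input is NODATA.
#'
#' @param binaryMaps list of 0/1 [Grid-class] sharing one geometry
#' @return a 0/1 consensus [Grid-class]
#' @export
gcmConsensus <- function(binaryMaps) {
  stopifnot(length(binaryMaps) >= 1)
  g1 <- binaryMaps[[1]]
  for (g in binaryMaps[-1])
    if (!sameGeometry(g, g1)) stop("consensus inputs must share geometry")
  votes <- Reduce(`+`, lapply(binaryMaps, function(g) g@values))
  na <- Reduce(`|`, lapply(binaryMaps, function(g) is.na(g@values)))
  out <- (votes > length(binaryMaps) / 2) * 1
  out[na] <- NA
  grid(out, xll = g1@xll, yll = g1@yll, cellSize = g1@cellSize,
       name = "consensus")
}

#' Project an ensemble under one scenario
#'
#' Predicts and binarizes the ensemble on each pseudo-GCM future stack,
#' takes the strict-majority consensus, and (by default) intersects the
#' result with the current habitat — the no-dispersal constraint, under
#' which the species cannot colonize cells outside its current range. The
#' unconstrained consensus is returned alongside for diagnostics.
#'
#' @param ensemble an [EnsembleModel-class] (members carry fitted learners)
#' @param futureStacks list of per-GCM [EnvStack-class] from
#'   [generateFutureScenario()]
#' @param currentBinary current-habitat 0/1 [Grid-class]
#' @param noDispersal intersect future habitat with current (default TRUE)
#' @return list with `future` (headline 0/1 grid), `unconstrained`,
#'   and `perGcm` (list of 0/1 grids)
#' @export
projectEnsemble <- function(ensemble, futureStacks, currentBinary,
                            noDispersal = TRUE) {
  perGcm <- lapply(futureStacks, function(stk) {
    scoreMat <- NULL
    g1 <- stk@layers[[1]]
    mask <- validMask(stk)
    idx <- which(mask)
    feats <- vapply(ensemble@runs[[1]]@learner@columns,
                    function(v) getLayer(stk, v)@values[idx],
                    numeric(length(idx)))
    if (length(idx) == 1) feats <- matrix(feats, 1)
    colnames(feats) <- ensemble@runs[[1]]@learner@columns
    scoreMat <- t(vapply(ensemble@runs, function(r)
      predictSuitability(r@learner, feats), numeric(length(idx))))
    tss <- vapply(ensemble@runs, runTss, 0)
    weights <- if (sum(tss) > 0) tss / sum(tss) else
      rep(1 / length(tss), length(tss))
    comb <- combineScores(scoreMat, ensemble@method,
                          ensemble@memberThresholds, weights)
    vals <- matrix(NA_real_, nRows(g1), nCols(g1))
    vals[idx] <- comb
    suit <- grid(vals, xll = g1@xll, yll = g1@yll, cellSize = g1@cellSize)
    binarizeMap(suit, ensemble@threshold)
  })
  cons <- gcmConsensus(perGcm)
  future <- cons
  if (noDispersal) {
    future@values <- cons@values * currentBinary@values
    future@name <- "future_no_dispersal"
  }
  list(future = future, unconstrained = cons, perGcm = perGcm)
}

changeCategories <- c(absent = 0, stable_presence = 1, gain = 2, loss = 3)

#' Classify current-vs-future habitat change
#'
#' Per valid cell: (1,1) stable presence, (0,1) gain, (1,0) loss, (0,0)
#' absent; areas per category via [cellAreaKm2()]. The category areas
#' satisfy `stable + loss = current habitat area` and
#' `stable + gain = future habitat area`.
#'
#' @param currentBin,futureBin 0/1 [Grid-class] sharing geometry
#' @return list with `map` (coded [Grid-class]; 0 absent, 1 stable,
#'   2 gain, 3 loss), `areas` (named km^2 vector) and `codes`
#' @export
classifyChange <- function(currentBin, futureBin) {
  if (!sameGeometry(currentBin, futureBin))
    stop("current and future maps must share geometry")
  cur <- currentBin@values; fut <- futureBin@values
  code <- matrix(NA_real_, nrow(cur), ncol(cur))
  code[cur == 0 & fut == 0] <- changeCategories[["absent"]]
  code[cur == 1 & fut == 1] <- changeCategories[["stable_presence"]]
  code[cur == 0 & fut == 1] <- changeCategories[["gain"]]
  code[cur == 1 & fut == 0] <- changeCategories[["loss"]]
  map <- grid(code, xll = currentBin@xll, yll = currentBin@yll,
              cellSize = currentBin@cellSize, name = "change")
  a <- cellAreaMatrix(map)
  areas <- vapply(changeCategories, function(k)
    sum(a[which(code == k)], na.rm = TRUE), 0)
  list(map = map, areas = areas, codes = changeCategories)
}

#' Gain/loss accounting by elevation band
#'
#' Sums gain and loss areas within elevation bands and reports their ratio
#' (`NA` where a band has no loss). Default band edges follow the standard
#' 500-m ladder between 3000 and 5000 m with open tails.
#'
#' @param change result of [classifyChange()]
#' @param elevation elevation [Grid-class] sharing geometry
#' @param bandEdges strictly increasing numeric edges
#' @return data frame with `band`, `gainKm2`, `lossKm2`, `ratio`
#' @export
bandGainLoss <- function(change, elevation,
                         bandEdges = c(-Inf, 3000, 3500, 4000, 4500, 5000,
                                       Inf)) {
  if (!sameGeometry(change$map, elevation))
    stop("elevation grid must share the change-map geometry")
  if (any(diff(bandEdges) <= 0)) stop("band edges must be strictly increasing")
  code <- change$map@values
  a <- cellAreaMatrix(change$map)
  ele <- elevation@values
  band <- cut(ele, bandEdges, right = FALSE)
  lev <- levels(band)
  out <- data.frame(band = lev, gainKm2 = 0, lossKm2 = 0, ratio = NA_real_)
  for (i in seq_along(lev)) {
    inBand <- !is.na(band) & band == lev[i] & !is.na(code)
    out$gainKm2[i] <- sum(a[inBand & code == changeCategories[["gain"]]],
                          na.rm = TRUE)
    out$lossKm2[i] <- sum(a[inBand & code == changeCategories[["loss"]]],
                          na.rm = TRUE)
  }
  out$ratio <- ifelse(out$lossKm2 > 0, out$gainKm2 / out$lossKm2, NA_real_)
  out
}

#' Habitat area and share by region
#'
#' Sums habitat-cell areas within each region of an integer-labelled mask
#' and reports each region's share of the total habitat area (percent,
#' rounded to 1 decimal).
#'
#' @param binaryMap habitat 0/1 [Grid-class]
#' @param regionMask integer-labelled [Grid-class] sharing geometry
#' @param labels region labels to report (default: all labels in the mask);
#'   labels absent from the mask yield zero rows
#' @param regionNames optional names for `labels`
#' @return data frame with `region`, `areaKm2`, `sharePct`
#' @export
regionAreaSummary <- function(binaryMap, regionMask, labels = NULL,
                              regionNames = NULL) {
  if (!sameGeometry(binaryMap, regionMask))
    stop("region mask must share the habitat-map geometry")
  if (is.null(labels))
    labels <- sort(unique(regionMask@values[!is.na(regionMask@values)]))
  a <- cellAreaMatrix(binaryMap)
  hab <- binaryMap@values == 1
  areas <- vapply(labels, function(l)
    sum(a[which(hab & regionMask@values == l)], na.rm = TRUE), 0)
  total <- sum(areas)
  share <- if (total > 0) round(100 * areas / total, 1) else rep(0,
                                                                 length(areas))
  data.frame(
    region = if (is.null(regionNames)) as.character(labels) else regionNames,
    areaKm2 = areas, sharePct = share)
}

#' Shares from a printed per-region area table
#'
#' Convenience for checking published area accounting: given per-region
#' areas, returns each region's share of the total in percent, rounded to
#' 1 decimal.
#'
#' @param areas named numeric vector of areas (any consistent unit)
#' @return named numeric vector of percent shares
#' @examples
#' areaShares(c(China = 69.43, India = 2.37, Nepal = 2.20,
#'              Pakistan = 0.61, Bhutan = 0.58, Myanmar = 0.37))
#' @export
areaShares <- function(areas) {
  round(100 * areas / sum(areas), 1)
}
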