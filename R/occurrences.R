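# Occurrence cleaning, pseudo-absence sampling and train/test partitioning.

#' Cleaned occurrence set
#'
#' Presence points plus a cleaning report. The report satisfies
#' `retained = raw - duplicates - invalid`, where invalid records (non-finite
#' or out-of-bounds coordinates) are removed first and exact-coordinate
#' duplicates among the remaining records are then collapsed to one.
#'
#' @slot points data.frame with `lon`, `lat`, `label` (all 1) and optional
#'   `source`
#' @slot report named integer vector: `raw`, `invalid`, `duplicates`,
#'   `retained`
#' @export
setClass("OccurrenceSet",
  representation(points = "data.frame", report = "integer"))

setValidity("OccurrenceSet", function(object) {
  p <- object@points
  r <- object@report
  need <- c("raw", "invalid", "duplicates", "retained")
  if (!all(need %in% names(r))) return("report must carry raw/invalid/duplicates/retained")
  if (r[["retained"]] != r[["raw"]] - r[["duplicates"]] - r[["invalid"]])
    return("retained must equal raw - duplicates - invalid")
  if (nrow(p) != r[["retained"]]) return("points row count must equal retained")
  if (nrow(p) && anyDuplicated(p[, c("lon", "lat")]))
    return("no two retained records may share identical (lon, lat)")
  if (nrow(p) && (any(abs(p$lat) > 90) || any(abs(p$lon) > 180)))
    return("coordinates out of bounds")
  TRUE
})

setMethod("show", "OccurrenceSet", function(object) {
  r <- object@report
  cat(sprintf(
    "OccurrenceSet: %d retained (raw %d, duplicates %d, invalid %d)\n",
    r[["retained"]], r[["raw"]], r[["duplicates"]], r[["invalid"]]))
})

#' @describeIn cleanOccurrences retained presence points as a data frame
#' @param x an `OccurrenceSet`
#' @export
occurrencePoints <- function(x) x@points

#' @describeIn cleanOccurrences cleaning report counts
#' @export
cleaningReport <- function(x) x@report

#' Clean raw occurrence records
#'
#' Removes records with non-finite or out-of-bounds coordinates (invalid),
#' then collapses exact-coordinate duplicates to a single record. Cleaning is
#' idempotent. Duplicates are defined by exact `(lon, lat)` equality; no
#' spatial thinning is applied.
#'
#' @param raw data frame with columns `lon`, `lat` and optionally `source`
#' @param bounds study rectangle as `c(xmin, xmax, ymin, ymax)`; records
#'   outside it count as invalid. `NULL` restricts only to the valid
#'   geographic domain.
#' @return an [OccurrenceSet-class]
#' @examples
#' raw <- data.frame(lon = c(90, 90, 91), lat = c(30, 30, 31))
#' cleaningReport(cleanOccurrences(raw))
#' @export
cleanOccurrences <- function(raw, bounds = NULL) {
  if (is.null(raw) || nrow(raw) == 0) stop("no occurrence records to clean")
  stopifnot(all(c("lon", "lat") %in% names(raw)))
  nRaw <- nrow(raw)
  ok <- is.finite(raw$lon) & is.finite(raw$lat) &
    abs(raw$lat) <= 90 & raw$lon >= -180 & raw$lon <= 180
  if (!is.null(bounds)) {
    stopifnot(length(bounds) == 4)
    ok <- ok & raw$lon >= bounds[1] & raw$lon <= bounds[2] &
      raw$lat >= bounds[3] & raw$lat <= bounds[4]
  }
  ok[is.na(ok)] <- FALSE
  nInvalid <- sum(!ok)
  valid <- raw[ok, , drop = FALSE]
  dup <- duplicated(valid[, c("lon", "lat")])
  nDup <- sum(dup)
  kept <- valid[!dup, , drop = FALSE]
  if (nrow(kept) == 0) stop("cleaning removed every record; nothing to model")
  pts <- data.frame(lon = kept$lon, lat = kept$lat, label = 1L)
  if ("source" %in% names(kept)) pts$source <- kept$source
  rownames(pts) <- NULL
  new("OccurrenceSet", points = pts,
      report = c(raw = nRaw, invalid = nInvalid, duplicates = nDup,
                 retained = nrow(pts)))
}

#' Sample pseudo-absence points
#'
#' Draws `n` cells uniformly at random (without replacement) from the
#' non-NODATA cells of the stack, excluding any cell occupied by a presence,
#' and places one point jittered uniformly within each drawn cell. The
#' standard design uses two independent sets of 1000 points.
#'
#' @param stack an [EnvStack-class]
#' @param presences data frame of presence points (`lon`, `lat`)
#' @param n number of pseudo-absences (default 1000)
#' @param seed integer seed
#' @return data frame with `lon`, `lat`, `label` (= 0)
#' @export
samplePseudoAbsences <- function(stack, presences, n = 1000, seed = 1) {
  stopifnot(n >= 1)
  g1 <- stack@layers[[1]]
  mask <- validMask(stack)
  if (nrow(presences)) {
    pc <- pointToCell(g1, presences$lon, presences$lat)
    occIdx <- cbind(pc$row[pc$inBounds], pc$col[pc$inBounds])
    mask[occIdx] <- FALSE
  }
  eligible <- which(mask)
  if (length(eligible) < n)
    stop("need ", n, " eligible cells but only ", length(eligible),
         " available (deficit ", n - length(eligible), ")")
  set.seed(seed)
  cells <- if (length(eligible) == n) eligible else sample(eligible, n)
  nr <- nRows(g1); cs <- g1@cellSize
  row <- ((cells - 1) %% nr) + 1
  col <- ((cells - 1) %/% nr) + 1
  lon <- g1@xll + (col - 1) * cs + runif(n) * cs
  lat <- g1@yll + (nr - row) * cs + runif(n) * cs
  data.frame(lon = lon, lat = lat, label = 0L)
}

#' Stratified train/test split
#'
#' Splits a labelled dataset into train and test partitions, stratified by
#' label, with `round(fraction * n)` training records per class. The default
#' follows the 80/20 calibration/validation convention.
#'
#' @param labels 0/1 integer vector
#' @param fraction training fraction, strictly between 0 and 1
#' @param seed integer seed
#' @return list with integer index vectors `train` and `test`
#' @export
splitTrainTest <- function(labels, fraction = 0.8, seed = 1) {
  stopifnot(fraction > 0, fraction < 1)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  set.seed(seed)
  train <- integer(0)
  for (cls in c(0L, 1L)) {
    idx <- which(labels == cls)
    if (length(idx) < 2)
      stop("class ", cls, " has fewer than 2 records; cannot split")
    nTrain <- round(fraction * length(idx))
    nTrain <- min(max(nTrain, 1L), length(idx) - 1L)
    train <- c(train, sample(idx, nTrain))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}
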