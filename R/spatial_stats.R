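# Getis-Ord Gi* hotspot detection and habitat-centroid migration tracking.

#' Getis-Ord Gi* hotspot statistic
#'
#' For each valid cell i, with binary weights `w_ij = 1` for valid cells
#' within a Chebyshev (square-window) radius of i, self included:
#' \deqn{G_i^* = \frac{\sum_j w_{ij} x_j - \bar{X} \sum_j w_{ij}}
#'   {S \sqrt{[n \sum_j w_{ij}^2 - (\sum_j w_{ij})^2] / (n - 1)}}}
#' with \eqn{S = \sqrt{\sum_j x_j^2 / n - \bar{X}^2}} over the n valid
#' cells. Two-sided normal p-values are Benjamini-Hochberg corrected across
#' cells, and confidence bins assigned at corrected 0.10 / 0.05 / 0.01 with
#' the sign of z: `Gi_Bin = +-3` marks the 99 % hot/cold spots.
#'
#' @param valueGrid input [Grid-class] (typically the continuous ensemble
#'   suitability)
#' @param radius Chebyshev neighbourhood radius in cells (default 3)
#' @return list of [Grid-class]: `z`, `p` (BH-corrected), `bin`, plus `n`
#'   and `radius`
#' @export
giStar <- function(valueGrid, radius = 3) {
  stopifnot(radius >= 1)
  x <- valueGrid@values
  valid <- !is.na(x)
  n <- sum(valid)
  if (n < 2) stop("need at least 2 valid cells")
  xbar <- mean(x[valid])
  S <- sqrt(sum(x[valid]^2) / n - xbar^2)
  nr <- nrow(x); nc <- ncol(x)
  zmat <- matrix(NA_real_, nr, nc)
  if (S < 1e-12) {
    warning("constant field: all Gi* bins set to 0")
    zmat[valid] <- 0
    pmat <- zmat; pmat[valid] <- 1
    bin <- zmat
  } else {
    x0 <- x; x0[!valid] <- 0
    vmask <- valid * 1
    # neighbourhood sums via shifted-matrix accumulation (exact, fast)
    shift <- function(m, dr, dc) {
      out <- matrix(0, nr, nc)
      if (abs(dr) >= nr || abs(dc) >= nc) return(out)
      rs <- max(1, 1 + dr):min(nr, nr + dr)
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      out[rs, cs] <- m[rs - dr, cs - dc]
      out
    }
    sumX <- matrix(0, nr, nc); sumW <- matrix(0, nr, nc)
    for (dr in -radius:radius) for (dc in -radius:radius) {
      sumX <- sumX + shift(x0, dr, dc)
      sumW <- sumW + shift(vmask, dr, dc)
    }
    # binary weights: sum w^2 = sum w
    denom <- S * sqrt(pmax(n * sumW - sumW^2, 0) / (n - 1))
    z <- (sumX - xbar * sumW) / denom
    z[!valid] <- NA
    z[valid & !is.finite(z)] <- 0   # window covering all n cells
    zmat <- z
    praw <- 2 * pnorm(-abs(zmat[valid]))
    padj <- p.adjust(praw, method = "BH")
    pmat <- matrix(NA_real_, nr, nc)
    pmat[valid] <- padj
    bin <- matrix(NA_real_, nr, nc)
    b <- rep(0, n)
    b[padj < 0.10] <- 1
    b[padj < 0.05] <- 2
    b[padj < 0.01] <- 3
    bin[valid] <- b * sign(zmat[valid])
  }
  mk <- function(v, nm) grid(v, xll = valueGrid@xll, yll = valueGrid@yll,
                             cellSize = valueGrid@cellSize, name = nm)
  list(z = mk(zmat, "gi_z"), p = mk(pmat, "gi_p"), bin = mk(bin, "gi_bin"),
       n = n, radius = radius)
}

#' Hotspot area in km^2
#'
#' Area of cells with `Gi_Bin = 3` (99 % confidence hot spots).
#' @param hotspot result of [giStar()]
#' @return area in km^2
#' @export
hotspotAreaKm2 <- function(hotspot) {
  a <- cellAreaMatrix(hotspot$bin)
  sum(a[which(hotspot$bin@values == 3)], na.rm = TRUE)
}

#' Area-weighted habitat centroid
#'
#' The balance point of the mapped habitat: the mean of habitat cell-centre
#' coordinates weighted by [cellAreaKm2()] (cosine-latitude weights).
#' Longitude wraparound is unsupported (study areas far from +-180 deg).
#'
#' @param binaryMap habitat 0/1 [Grid-class]
#' @return named numeric `c(lon, lat)`
#' @export
habitatCentroid <- function(binaryMap) {
  idx <- which(binaryMap@values == 1, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty habitat: no cells equal 1")
  lon <- colLongitude(binaryMap, idx[, 2])
  lat <- rowLatitude(binaryMap, idx[, 1])
  w <- cellAreaKm2(binaryMap, idx[, 1])
  c(lon = sum(w * lon) / sum(w), lat = sum(w * lat) / sum(w))
}

#' Build a centroid track across scenarios
#'
#' @param states data frame with columns `scenario`, `period`, `lon`, `lat`
#'   (one row per state, in temporal order)
#' @return the same data frame with class `centroidTrack`
#' @export
centroidTrack <- function(states) {
  stopifnot(all(c("scenario", "period", "lon", "lat") %in% names(states)))
  structure(states, class = c("centroidTrack", "data.frame"))
}

#' Distances and bearings between consecutive centroids
#'
#' Haversine distance on a 6371-km sphere; initial bearing measured from
#' north, clockwise, in `[0, 360)`. Identical consecutive points give
#' distance 0 and bearing 0 by convention.
#'
#' @param track a [centroidTrack()] (>= 2 states)
#' @return data frame with `from`, `to`, `distanceKm`, `bearingDeg`
#' @export
centroidShift <- function(track) {
  if (nrow(track) < 2) stop("need at least 2 states")
  n <- nrow(track) - 1
  out <- data.frame(from = character(n), to = character(n),
                    distanceKm = 0, bearingDeg = 0)
  for (i in seq_len(n)) {
    p1 <- c(track$lon[i], track$lat[i])
    p2 <- c(track$lon[i + 1], track$lat[i + 1])
    lab <- function(j) paste(track$scenario[j], track$period[j])
    out$from[i] <- lab(i); out$to[i] <- lab(i + 1)
    if (isTRUE(all.equal(p1, p2))) {
      out$distanceKm[i] <- 0; out$bearingDeg[i] <- 0
    } else {
      out$distanceKm[i] <-
        geosphere::distHaversine(p1, p2, r = 6371000) / 1000
      out$bearingDeg[i] <- geosphere::bearing(p1, p2) %% 360
    }
  }
  out
}

#' Annotate a centroid track with climate values
#'
#' Reads Bio11 and Bio18 at each centroid from the period-appropriate
#' climate grids via [extractAtPoints()]. A centroid falling on NODATA is
#' resolved to the nearest valid cell within 3 cells; beyond that the value
#' is reported missing.
#'
#' @param track a [centroidTrack()]
#' @param bio11Grids,bio18Grids lists of [Grid-class], one per track state
#' @return the track with `bio11` (deg C) and `bio18` (mm) columns
#' @export
centroidClimate <- function(track, bio11Grids, bio18Grids) {
  if (nrow(track) == 0) {
    track$bio11 <- numeric(0); track$bio18 <- numeric(0)
    return(track)
  }
  stopifnot(length(bio11Grids) == nrow(track),
            length(bio18Grids) == nrow(track))
  readAt <- function(g, lon, lat) {
    pc <- pointToCell(g, lon, lat)
    if (!pc$inBounds[1]) return(NA_real_)
    v <- g@values[pc$row[1], pc$col[1]]
    if (!is.na(v)) return(v)
    # nearest valid cell within 3 cells (Chebyshev rings)
    for (rad in 1:3) {
      rows <- pmax(1, pc$row[1] - rad):pmin(nRows(g), pc$row[1] + rad)
      cols <- pmax(1, pc$col[1] - rad):pmin(nCols(g), pc$col[1] + rad)
      sub <- g@values[rows, cols, drop = FALSE]
      if (any(!is.na(sub))) {
        d <- outer(abs(rows - pc$row[1]), abs(cols - pc$col[1]), pmax)
        d[is.na(sub)] <- Inf
        k <- which(d == min(d), arr.ind = TRUE)[1, ]
        return(sub[k[1], k[2]])
      }
    }
    NA_real_
  }
  track$bio11 <- vapply(seq_len(nrow(track)), function(i)
    readAt(bio11Grids[[i]], track$lon[i], track$lat[i]), 0)
  track$bio18 <- vapply(seq_len(nrow(track)), function(i)
    readAt(bio18Grids[[i]], track$lon[i], track$lat[i]), 0)
  track
}
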