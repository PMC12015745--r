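# Synthetic environmental worlds with a known truth suitability, so every
# downstream stage (screening, learners, ensembling, futures, hotspots,
# centroids, economics) is testable without external rasters.

## smooth a matrix with a separable moving-average kernel applied `passes`
## times; repeated box filtering approximates a Gaussian kernel
smoothMatrix <- function(m, width = 7, passes = 3) {
  if (width <= 1) return(m)
  k <- rep(1 / width, width)
  pad <- (width - 1) %/% 2
  smooth1 <- function(x) {
    # reflect-pad so edges keep comparable variance
    xp <- c(rev(x[seq_len(pad)]), x, rev(x[seq(length(x) - pad + 1, length(x))]))
    as.numeric(stats::filter(xp, k, sides = 2))[(pad + 1):(pad + length(x))]
  }
  for (p in seq_len(passes)) {
    m <- apply(m, 2, smooth1)
    m <- t(apply(m, 1, smooth1))
  }
  m
}

## seeded, spatially autocorrelated field scaled to sd 1, mean 0
autocorrField <- function(nr, nc, width = 9, passes = 3) {
  m <- matrix(rnorm(nr * nc), nr, nc)
  m <- smoothMatrix(m, width = width, passes = passes)
  (m - mean(m)) / sd(m)
}

#' Default geometry of the synthetic world
#'
#' A 200 x 200 lattice of 0.05-degree cells with its lower-left corner at
#' (85 E, 28 N) — a Tibetan-Plateau-like extent small enough that every
#' pipeline stage runs in seconds.
#'
#' @param nRows,nCols lattice dimensions
#' @param xll,yll lower-left corner (degrees)
#' @param cellSize cell size (degrees)
#' @return a list usable as the `geometry` argument of
#'   [generateEnvironment()]
#' @export
worldGeometry <- function(nRows = 200, nCols = 200, xll = 85, yll = 28,
                          cellSize = 0.05) {
  list(nRows = as.integer(nRows), nCols = as.integer(nCols),
       xll = xll, yll = yll, cellSize = cellSize)
}

#' Generate a synthetic environmental stack
#'
#' Builds the nine predictor layers used throughout the workflow — Bio11
#' (mean temperature of the coldest quarter, deg C), Bio18 (precipitation of
#' the warmest quarter, mm), T_SILT, T_OC, T_PH_H2O (topsoil silt %, organic
#' carbon %, pH), ELE (elevation, m), SLOP (slope, degrees), HV and NT
#' (herbaceous-vegetation and needleleaf-tree cover, %). Elevation is a
#' smooth ridge plus autocorrelated noise spanning roughly 2500–5500 m;
#' Bio11 decreases with elevation (lapse-rate-like); Bio18 follows an
#' independent smooth gradient; HV is unimodal in elevation; soil layers are
#' weakly correlated autocorrelated noise. Deterministic given `seed`.
#'
#' @param geometry a list from [worldGeometry()]
#' @param seed integer seed
#' @param smoothWidth kernel width (cells) for the autocorrelation smoother
#' @return an [EnvStack-class] with nine named layers
#' @examples
#' stk <- generateEnvironment(worldGeometry(40, 40), seed = 1)
#' layerNames(stk)
#' @export
generateEnvironment <- function(geometry = worldGeometry(), seed = 1,
                                smoothWidth = 9) {
  nr <- geometry$nRows; nc <- geometry$nCols
  if (nr < 1 || nc < 1) stop("degenerate geometry: 0 cells")
  set.seed(seed)

  mk <- function(values, name) {
    grid(values, xll = geometry$xll, yll = geometry$yll,
         cellSize = geometry$cellSize, name = name)
  }

  # elevation: narrow diagonal ridge + autocorrelated relief, ~2500-5500 m
  rowf <- matrix(seq(0, 1, length.out = nr), nr, nc)
  colf <- matrix(seq(0, 1, length.out = nc), nr, nc, byrow = TRUE)
  ridge <- exp(-((rowf - colf)^2) / (2 * 0.16^2))   # high along the diagonal
  ele <- 2500 + 2700 * ridge + 450 * autocorrField(nr, nc, smoothWidth)
  ele <- pmax(ele, 2300)

  # coldest-quarter temperature: ~6.5 C/km lapse rate off elevation + noise
  bio11 <- 21 - 6.5 * (ele / 1000) + 1.5 * autocorrField(nr, nc, smoothWidth)

  # warmest-quarter precipitation: steep, independent west-east gradient
  bio18 <- 250 + 220 * (colf - 0.5) * 2 + 60 * autocorrField(nr, nc, smoothWidth)
  bio18 <- pmax(bio18, 10)

  # herbaceous cover: unimodal in elevation (alpine meadow belt)
  hv <- 75 * exp(-((ele - 4300)^2) / (2 * 900^2)) +
    8 * autocorrField(nr, nc, smoothWidth)
  hv <- pmin(pmax(hv, 0), 100)

  # needleleaf trees: low-elevation belt, mostly small cover values
  nt <- 30 * exp(-((ele - 2800)^2) / (2 * 600^2)) +
    5 * autocorrField(nr, nc, smoothWidth)
  nt <- pmin(pmax(nt, 0), 100)

  # slope: local elevation gradient magnitude (degrees, crude finite diff)
  cellM <- geometry$cellSize * 111195   # metres per cell, approx
  dy <- rbind(ele[1, , drop = FALSE], ele[-nr, , drop = FALSE]) - ele
  dx <- cbind(ele[, 1, drop = FALSE], ele[, -nc, drop = FALSE]) - ele
  slop <- atan(sqrt((dx / cellM)^2 + (dy / cellM)^2)) * 180 / pi

  # topsoil fields: weakly correlated autocorrelated noise
  silt <- pmin(pmax(35 + 12 * autocorrField(nr, nc, smoothWidth), 0), 100)
  toc <- pmax(1.2 + 0.6 * autocorrField(nr, nc, smoothWidth), 0.05)
  tph <- pmin(pmax(6.8 + 0.7 * autocorrField(nr, nc, smoothWidth), 4), 9.5)

  envStack(
    layers = list(
      Bio11 = mk(bio11, "Bio11"), Bio18 = mk(bio18, "Bio18"),
      T_SILT = mk(silt, "T_SILT"), T_OC = mk(toc, "T_OC"),
      T_PH_H2O = mk(tph, "T_PH_H2O"),
      ELE = mk(ele, "ELE"), SLOP = mk(slop, "SLOP"),
      HV = mk(hv, "HV"), NT = mk(nt, "NT")
    ),
    roles = c("bioclimatic", "bioclimatic", "soil", "soil", "soil",
              "terrain", "terrain", "land_cover", "land_cover")
  )
}

#' Truth-suitability parameters
#'
#' Defines the known habitat-suitability surface of the synthetic world on a
#' logistic scale: Gaussian (unimodal) responses for elevation, Bio18 and
#' Bio11, a saturating threshold response for herbaceous cover, an intercept
#' and per-variable weights. Default optima follow the response-curve shapes
#' the workflow is meant to recover: an elevation optimum in the alpine belt
#' (~4000 m), a moderate warm-season precipitation optimum (~200 mm), cold
#' winters (~-5 C), and herbaceous cover saturating above ~30 %.
#'
#' @param eleOpt,eleBreadth elevation optimum and breadth (m)
#' @param bio18Opt,bio18Breadth precipitation optimum and breadth (mm)
#' @param bio11Opt,bio11Breadth temperature optimum and breadth (deg C)
#' @param hvThreshold,hvScale herbaceous-cover threshold and softness (%)
#' @param weights named numeric weights on the logit scale
#'   (`ELE`, `Bio18`, `Bio11`, `HV`)
#' @param intercept logit-scale intercept
#' @param noiseSd sd of optional smooth logit-scale noise (0 = deterministic)
#' @return a `truthParams` list
#' @export
truthParams <- function(eleOpt = 4200, eleBreadth = 400,
                        bio18Opt = 200, bio18Breadth = 70,
                        bio11Opt = -6, bio11Breadth = 4,
                        hvThreshold = 30, hvScale = 8,
                        weights = c(ELE = 7.0, Bio18 = 4.5,
                                    Bio11 = 2.5, HV = 1.5),
                        intercept = -11.5, noiseSd = 0) {
  stopifnot(eleBreadth > 0, bio18Breadth > 0, bio11Breadth > 0, hvScale > 0,
            all(is.finite(weights)), noiseSd >= 0)
  structure(list(
    eleOpt = eleOpt, eleBreadth = eleBreadth,
    bio18Opt = bio18Opt, bio18Breadth = bio18Breadth,
    bio11Opt = bio11Opt, bio11Breadth = bio11Breadth,
    hvThreshold = hvThreshold, hvScale = hvScale,
    weights = weights, intercept = intercept, noiseSd = noiseSd
  ), class = "truthParams")
}

## per-variable response functions on [0, 1]
truthResponses <- function(truth) {
  list(
    ELE = function(x) exp(-((x - truth$eleOpt)^2) / (2 * truth$eleBreadth^2)),
    Bio18 = function(x)
      exp(-((x - truth$bio18Opt)^2) / (2 * truth$bio18Breadth^2)),
    Bio11 = function(x)
      exp(-((x - truth$bio11Opt)^2) / (2 * truth$bio11Breadth^2)),
    HV = function(x) plogis((x - truth$hvThreshold) / truth$hvScale)
  )
}

#' Compute the truth suitability surface
#'
#' Per cell: `suitability = plogis(intercept + sum_w weights * response)`,
#' in `[0, 1]`; NODATA propagates. With `noiseSd > 0` a seeded smooth
#' logit-scale perturbation is added before the logistic transform.
#'
#' @param stack an [EnvStack-class] containing `ELE`, `Bio18`, `Bio11`, `HV`
#' @param truth a [truthParams()] object
#' @param seed seed for the optional noise field (ignored if `noiseSd == 0`)
#' @return a [Grid-class] of probabilities
#' @export
computeTrueSuitability <- function(stack, truth = truthParams(), seed = 1) {
  resp <- truthResponses(truth)
  need <- names(truth$weights)
  miss <- setdiff(need, layerNames(stack))
  if (length(miss))
    stop("stack is missing variable(s) required by the truth: ",
         paste(miss, collapse = ", "))
  g1 <- stack@layers[[1]]
  eta <- matrix(truth$intercept, nRows(g1), nCols(g1))
  for (v in need)
    eta <- eta + truth$weights[[v]] * resp[[v]](getLayer(stack, v)@values)
  if (truth$noiseSd > 0) {
    set.seed(seed)
    eta <- eta + truth$noiseSd * autocorrField(nRows(g1), nCols(g1))
  }
  s <- plogis(eta)
  s[!validMask(stack)] <- NA
  grid(s, xll = g1@xll, yll = g1@yll, cellSize = g1@cellSize,
       name = "truth_suitability")
}

#' Sample presence occurrences from a suitability surface
#'
#' Cells are drawn without replacement with probability proportional to
#' suitability; each point is then jittered uniformly within its cell so no
#' two records coincide exactly. Deterministic given `seed`.
#'
#' @param suitability a probability [Grid-class]
#' @param n number of presences (the real-data workflow retains 968 cleaned
#'   records; synthetic studies here default to 500)
#' @param seed integer seed
#' @return a data frame with columns `lon`, `lat`, `label` (= 1), `source`
#' @export
sampleOccurrences <- function(suitability, n = 500, seed = 1) {
  stopifnot(n >= 1)
  v <- suitability@values
  pos <- which(!is.na(v) & v > 0)
  if (length(pos) < n)
    stop("n = ", n, " exceeds the ", length(pos),
         " cells with positive suitability")
  set.seed(seed)
  cells <- sample(pos, n, prob = v[pos])
  nr <- nRows(suitability); cs <- suitability@cellSize
  row <- ((cells - 1) %% nr) + 1
  col <- ((cells - 1) %/% nr) + 1
  lon <- suitability@xll + (col - 1) * cs + runif(n) * cs
  lat <- suitability@yll + (nr - row) * cs + runif(n) * cs
  data.frame(lon = lon, lat = lat, label = 1L, source = "synthetic")
}

#' Future-scenario specification with pseudo-GCMs
#'
#' Describes one scenario x period as a temperature offset applied to Bio11
#' and a multiplier applied to Bio18, realized by `nGcms` pseudo-GCMs that
#' jitter around those central deltas. Defaults emulate a low-forcing
#' (SSP1-2.6-like) mid-century pathway; the canonical scenario set used in
#' the pipeline covers low and high forcing at two horizons.
#'
#' @param scenario scenario id, e.g. `"SSP1-2.6"`
#' @param period period id, e.g. `"2050s"`
#' @param bio11Offset central warming of the coldest quarter (deg C)
#' @param bio18Multiplier central precipitation multiplier (unitless, > 0)
#' @param nGcms number of pseudo-GCMs (the projection design uses 7)
#' @param jitterSdT per-GCM sd around the temperature offset (deg C)
#' @param jitterSdP per-GCM lognormal-ish sd around the multiplier
#' @param seed seed for the per-GCM jitters
#' @return a `scenarioSpec` list
#' @export
scenarioSpec <- function(scenario = "SSP1-2.6", period = "2050s",
                         bio11Offset = 1.5, bio18Multiplier = 1.05,
                         nGcms = 7, jitterSdT = 0.3, jitterSdP = 0.03,
                         seed = 1) {
  if (nGcms < 1) stop("nGcms must be >= 1")
  stopifnot(bio18Multiplier > 0)
  structure(list(scenario = scenario, period = period,
                 bio11Offset = bio11Offset,
                 bio18Multiplier = bio18Multiplier, nGcms = nGcms,
                 jitterSdT = jitterSdT, jitterSdP = jitterSdP, seed = seed),
            class = "scenarioSpec")
}

#' The four canonical future scenarios
#'
#' Low- and high-forcing pathways at two horizons, with warming and
#' precipitation deltas growing with forcing and time.
#' @param nGcms pseudo-GCMs per scenario
#' @param seed base seed (each scenario derives its own)
#' @return named list of [scenarioSpec()] objects
#' @export
defaultScenarios <- function(nGcms = 7, seed = 1) {
  list(
    `SSP1-2.6_2050s` = scenarioSpec("SSP1-2.6", "2050s", 1.5, 1.05,
                                    nGcms, seed = seed + 11),
    `SSP1-2.6_2100s` = scenarioSpec("SSP1-2.6", "2100s", 2.0, 1.07,
                                    nGcms, seed = seed + 12),
    `SSP5-8.5_2050s` = scenarioSpec("SSP5-8.5", "2050s", 2.5, 1.08,
                                    nGcms, seed = seed + 13),
    `SSP5-8.5_2100s` = scenarioSpec("SSP5-8.5", "2100s", 4.5, 1.12,
                                    nGcms, seed = seed + 14)
  )
}

#' Generate per-GCM future environmental stacks
#'
#' Only the climate layers change: `Bio11 += offset + jitter_g`,
#' `Bio18 *= multiplier * jitter_g`; terrain, soil and land cover stay fixed
#' (a no-dispersal world with a static substrate).
#'
#' @param stack the current [EnvStack-class] (must contain Bio11 and Bio18)
#' @param scenario a [scenarioSpec()]
#' @return a named list of [EnvStack-class], one per pseudo-GCM
#' @export
generateFutureScenario <- function(stack, scenario) {
  stopifnot(inherits(scenario, "scenarioSpec"))
  if (!all(c("Bio11", "Bio18") %in% layerNames(stack)))
    stop("stack must contain Bio11 and Bio18")
  set.seed(scenario$seed)
  dT <- scenario$bio11Offset + rnorm(scenario$nGcms, 0, scenario$jitterSdT)
  mP <- scenario$bio18Multiplier *
    exp(rnorm(scenario$nGcms, 0, scenario$jitterSdP))
  out <- vector("list", scenario$nGcms)
  for (g in seq_len(scenario$nGcms)) {
    s <- stack
    b11 <- getLayer(s, "Bio11"); b18 <- getLayer(s, "Bio18")
    b11@values <- b11@values + dT[g]
    b18@values <- b18@values * mP[g]
    s <- setLayer(s, "Bio11", b11)
    s <- setLayer(s, "Bio18", b18)
    out[[g]] <- s
  }
  names(out) <- paste0("GCM", seq_len(scenario$nGcms))
  out
}

#' Emit a synthetic world to disk
#'
#' Writes every layer as an `.asc` file, the occurrences as a CSV and a
#' `key=value` scenario manifest, so external tools can consume the world.
#'
#' @param dir output directory (created if needed)
#' @param geometry world geometry; see [worldGeometry()]
#' @param truth truth parameters; see [truthParams()]
#' @param nOccurrences presences to sample
#' @param seed master seed
#' @return invisibly, a character vector of the files written
#' @export
simulateWorld <- function(dir, geometry = worldGeometry(),
                          truth = truthParams(), nOccurrences = 500,
                          seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stk <- generateEnvironment(geometry, seed = seed)
  suit <- computeTrueSuitability(stk, truth, seed = seed)
  occ <- sampleOccurrences(suit, nOccurrences, seed = seed + 1)
  files <- character()
  for (nm in layerNames(stk)) {
    f <- file.path(dir, paste0(nm, ".asc"))
    writeAsciiGrid(getLayer(stk, nm), f)
    files <- c(files, f)
  }
  f <- file.path(dir, "truth_suitability.asc")
  writeAsciiGrid(suit, f); files <- c(files, f)
  f <- file.path(dir, "occurrences.csv")
  write.csv(occ, f, row.names = FALSE); files <- c(files, f)
  f <- file.path(dir, "manifest.txt")
  scen <- defaultScenarios(seed = seed)
  lines <- c(sprintf("seed=%d", seed),
             sprintf("n_occurrences=%d", nOccurrences),
             sprintf("layers=%s", paste(layerNames(stk), collapse = ",")),
             vapply(scen, function(s)
               sprintf("scenario.%s_%s=offset:%.3g,multiplier:%.3g,n_gcms:%d",
                       s$scenario, s$period, s$bio11Offset,
                       s$bio18Multiplier, s$nGcms), ""))
  writeLines(lines, f); files <- c(files, f)
  invisible(files)
}
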