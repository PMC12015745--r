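# End-to-end orchestration of the ensemble-SDM workflow on a synthetic (or
# user-supplied) world: clean -> screen -> run design -> gate -> combine ->
# rank -> binarize -> project per GCM -> consensus -> change/bands/regions
# -> hotspots -> centroid track -> economics.

#' Pipeline configuration
#'
#' Collects every knob of the workflow with the canonical defaults:
#' 2 pseudo-absence sets of 1000 points, 10 algorithms, 5 replicates
#' (100 runs), 80/20 split, TSS gate 0.7, importance gate 0.1, correlation
#' threshold 0.6, contribution threshold 15 % over 10 screening repetitions,
#' Gi* radius 3.
#'
#' @param algorithms algorithm ids to run
#' @param nPaSets,paSize,nReps pseudo-absence design
#' @param trainFraction training fraction
#' @param tssGate,importanceGate ensemble gates
#' @param rMax,contributionMin,nScreenReps variable-screen thresholds
#' @param hotspotRadius Gi* Chebyshev radius (cells)
#' @param nOccurrences synthetic presences to sample
#' @param geometry synthetic world geometry
#' @param truth synthetic truth parameters
#' @param scenarios list of [scenarioSpec()] (default the four canonical)
#' @param screen run the contribution screen (slower) or keep all variables
#' @param seed master seed
#' @return a `pipelineConfig` list
#' @export
pipelineConfig <- function(algorithms = listAlgorithms(),
                           nPaSets = 2, paSize = 1000, nReps = 5,
                           trainFraction = 0.8, tssGate = 0.7,
                           importanceGate = 0.1, rMax = 0.6,
                           contributionMin = 15, nScreenReps = 10,
                           hotspotRadius = 3, nOccurrences = 500,
                           geometry = worldGeometry(),
                           truth = truthParams(),
                           scenarios = NULL, screen = FALSE, seed = 1) {
  stopifnot(tssGate >= -1, tssGate <= 1, trainFraction > 0,
            trainFraction < 1, rMax > 0, rMax <= 1)
  if (is.null(scenarios)) scenarios <- defaultScenarios(seed = seed)
  structure(list(
    algorithms = algorithms, nPaSets = nPaSets, paSize = paSize,
    nReps = nReps, trainFraction = trainFraction, tssGate = tssGate,
    importanceGate = importanceGate, rMax = rMax,
    contributionMin = contributionMin, nScreenReps = nScreenReps,
    hotspotRadius = hotspotRadius, nOccurrences = nOccurrences,
    geometry = geometry, truth = truth, scenarios = scenarios,
    screen = screen, seed = seed), class = "pipelineConfig")
}

#' Run the full workflow
#'
#' Executes the whole pipeline on the synthetic world defined by the
#' configuration and writes every artifact (grids as `.asc`, tables as CSV)
#' under `outDir`, returning a manifest with one row per artifact (path and
#' md5 hash) plus the in-memory results. A failing stage is marked in the
#' manifest and its dependent stages are skipped. Identical configuration
#' and seed reproduce an identical manifest.
#'
#' @param config a [pipelineConfig()]
#' @param outDir output directory (created); `NULL` for a tempdir
#' @return list with `manifest` (data frame: stage, artifact, path, md5,
#'   status), `results` (named list of stage outputs) and `config`
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL) {
  stopifnot(inherits(config, "pipelineConfig"))
  if (is.null(outDir)) outDir <- file.path(tempdir(), "yartsa_run")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(stage = character(), artifact = character(),
                         path = character(), md5 = character(),
                         status = character())
  results <- list()
  note <- function(stage, artifact, path, status = "ok") {
    md5 <- if (!is.na(path) && file.exists(path))
      unname(tools::md5sum(path)) else NA_character_
    manifest <<- rbind(manifest, data.frame(
      stage = stage, artifact = artifact, path = path, md5 = md5,
      status = status))
  }
  runStage <- function(stage, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      note(stage, "error", NA_character_, paste("failed:",
                                                conditionMessage(res)))
      NULL
    } else res
  }
  saveGrid <- function(stage, g, nm) {
    p <- file.path(outDir, paste0(nm, ".asc"))
    writeAsciiGrid(g, p); note(stage, nm, p); p
  }
  saveTable <- function(stage, df, nm) {
    p <- file.path(outDir, paste0(nm, ".csv"))
    write.csv(df, p, row.names = FALSE); note(stage, nm, p); p
  }

  # --- world ---------------------------------------------------------------
  world <- runStage("world", {
    stk <- generateEnvironment(config$geometry, seed = config$seed)
    suit <- computeTrueSuitability(stk, config$truth, seed = config$seed)
    occRaw <- sampleOccurrences(suit, config$nOccurrences,
                                seed = config$seed + 1)
    list(stack = stk, truth = suit, occRaw = occRaw)
  })
  if (is.null(world)) return(list(manifest = manifest, results = results,
                                  config = config))
  results$world <- world
  saveGrid("world", world$truth, "truth_suitability")

  # --- clean ---------------------------------------------------------------
  occ <- runStage("clean", cleanOccurrences(world$occRaw))
  results$occurrences <- occ
  if (!is.null(occ)) {
    saveTable("clean", occurrencePoints(occ), "occurrences_clean")
    saveTable("clean", as.data.frame(t(cleaningReport(occ))),
              "cleaning_report")
  }

  # --- screen --------------------------------------------------------------
  stack <- world$stack
  if (config$screen && !is.null(occ)) {
    scr <- runStage("screen", contributionScreen(
      stack, occurrencePoints(occ), nReps = config$nScreenReps,
      contributionMin = config$contributionMin, rMax = config$rMax,
      paSize = config$paSize, seed = config$seed + 2))
    if (!is.null(scr)) {
      results$screen <- scr
      saveTable("screen", data.frame(variable = names(scr$contribution),
                                     contribution = scr$contribution),
                "screen_contributions")
      stack <- envStack(stack@layers[scr$retained],
                        stack@roles[scr$retained])
    }
  }

  # --- run design + ensemble ----------------------------------------------
  design <- if (!is.null(occ)) runStage("fit", runDesign(
    stack, occ, algorithms = config$algorithms, nPaSets = config$nPaSets,
    paSize = config$paSize, nReps = config$nReps,
    trainFraction = config$trainFraction, seed = config$seed + 3)) else NULL
  ens <- NULL
  if (!is.null(design)) {
    results$design <- design
    metrics <- do.call(rbind, lapply(design$runs, function(r) data.frame(
      algorithm = r@algorithm, paSet = r@paSet, replicate = r@replicate,
      tss = runTss(r), auc = runAuc(r),
      threshold = r@evaluation$threshold)))
    saveTable("fit", metrics, "run_metrics")
    ens <- runStage("ensemble", {
      sel <- selectRuns(design$runs, tssMin = config$tssGate,
                        importanceMin = config$importanceGate)
      rk <- rankEnsembles(sel$runs)
      list(selection = sel, ranking = rk, best = rk$models[[rk$best]])
    })
  }
  currentBin <- NULL
  if (!is.null(ens)) {
    results$ensemble <- ens
    saveTable("ensemble", ens$ranking$table, "ensemble_metrics")
    saveTable("ensemble", ensembleImportance(ens$best),
              "ensemble_importance")
    saveGrid("ensemble", ens$best@suitability, "ensemble_suitability")
    currentBin <- binarizeMap(ens$best@suitability, ens$best@threshold)
    saveGrid("ensemble", currentBin, "current_habitat")
  }

  # --- futures -------------------------------------------------------------
  futures <- NULL
  if (!is.null(ens) && length(config$scenarios)) {
    futures <- runStage("project", {
      out <- list()
      for (nm in names(config$scenarios)) {
        spec <- config$scenarios[[nm]]
        stks <- generateFutureScenario(stack, spec)
        proj <- projectEnsemble(ens$best, stks, currentBin)
        # gain/loss accounting uses the unconstrained consensus: under the
        # strict no-dispersal intersection no cell can ever be gained
        chg <- classifyChange(currentBin, proj$unconstrained)
        bands <- bandGainLoss(chg, getLayer(stack, "ELE"))
        out[[nm]] <- list(spec = spec, projection = proj, change = chg,
                          bands = bands,
                          futureStacks = stks)
      }
      out
    })
  }
  if (!is.null(futures)) {
    results$futures <- futures
    for (nm in names(futures)) {
      saveGrid("project", futures[[nm]]$projection$future,
               paste0("future_", gsub("[^A-Za-z0-9._-]", "_", nm)))
      saveGrid("project", futures[[nm]]$change$map,
               paste0("change_", gsub("[^A-Za-z0-9._-]", "_", nm)))
      saveTable("project", futures[[nm]]$bands,
                paste0("bands_", gsub("[^A-Za-z0-9._-]", "_", nm)))
    }
  }

  # --- hotspots ------------------------------------------------------------
  hs <- if (!is.null(ens)) runStage("hotspot", giStar(
    ens$best@suitability, radius = config$hotspotRadius)) else NULL
  if (!is.null(hs)) {
    results$hotspot <- hs
    saveGrid("hotspot", hs$bin, "gi_bin")
  }

  # --- centroid track ------------------------------------------------------
  trk <- NULL
  if (!is.null(ens) && !is.null(futures)) {
    trk <- runStage("centroid", {
      states <- data.frame(scenario = "current", period = "current",
                           lon = habitatCentroid(currentBin)[["lon"]],
                           lat = habitatCentroid(currentBin)[["lat"]])
      b11 <- list(getLayer(stack, "Bio11"))
      b18 <- list(getLayer(stack, "Bio18"))
      for (nm in names(futures)) {
        f <- futures[[nm]]
        cen <- habitatCentroid(f$projection$future)
        states <- rbind(states, data.frame(
          scenario = f$spec$scenario, period = f$spec$period,
          lon = cen[["lon"]], lat = cen[["lat"]]))
        # period-appropriate climate: mean over that scenario's GCM stacks
        avg <- function(layer) {
          g <- getLayer(f$futureStacks[[1]], layer)
          g@values <- Reduce(`+`, lapply(f$futureStacks, function(s)
            getLayer(s, layer)@values)) / length(f$futureStacks)
          g
        }
        b11[[length(b11) + 1]] <- avg("Bio11")
        b18[[length(b18) + 1]] <- avg("Bio18")
      }
      tr <- centroidClimate(centroidTrack(states), b11, b18)
      list(track = tr, shifts = centroidShift(tr))
    })
  }
  if (!is.null(trk)) {
    results$centroid <- trk
    saveTable("centroid", as.data.frame(trk$track), "centroid_track")
    saveTable("centroid", trk$shifts, "centroid_shifts")
  }

  # --- economics -----------------------------------------------------------
  if (!is.null(futures) && !is.null(currentBin)) {
    eco <- runStage("economics", {
      curArea <- habitatAreaKm2(currentBin)
      prodTab <- data.frame(region = "synthetic_region",
                            productionTons = 150, areaKm2 = curArea)
      chg <- do.call(rbind, lapply(names(futures), function(nm) {
        f <- futures[[nm]]
        data.frame(region = "synthetic_region", scenario = f$spec$scenario,
                   period = f$spec$period,
                   deltaAreaKm2 = f$change$areas[["gain"]] -
                     f$change$areas[["loss"]])
      }))
      scaleProduction(prodTab, chg)
    })
    if (!is.null(eco)) {
      results$economics <- eco
      saveTable("economics", eco, "production_projection")
    }
  }

  mpath <- file.path(outDir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  list(manifest = manifest, results = results, config = config,
       outDir = outDir)
}
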