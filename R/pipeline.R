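#' @include cohort-stats.R synthetic.R selection.R
NULL

defaultRunConfig <- function() {
  list(
    seed = 1L,
    outputDir = "fluxgsea-run",
    cohort = list(nPatients = 30L, model = "2C3K", noiseScale = 1.5,
                  aifNoiseSd = 0.5),
    aifFit = list(enabled = TRUE),
    models = c("patlak", "2C3K", "2C4K", "3C5K", "spline"),
    tStar = 10,
    knots = list(nInterior = 6L),
    expression = list(nGenes = 2000L, noiseSd = 1, baseMean = 5,
                      planted = list(list(name = "PLANTED_FLUX",
                                          size = 50L, rho = 0.8,
                                          measure = "kflux_true"))),
    collection = list(nNullSets = 99L, nullSetSize = 40L),
    gsea = list(methods = "pearson", nPerm = 10000L, alphaNumerator = 0.035,
                minSize = 15L, maxSize = 500L),
    microParameterGsea = TRUE,
    cohortStats = list(enabled = FALSE, nDatasets = 20L, nBoot = 10L,
                       fpMeasure = "SUVmean",
                       comparePair = c("patlak_K", "SUVmean"))
  )
}

mergeConfig <- function(base, user, path = "") {
  for (nm in names(user)) {
    full <- if (nzchar(path)) paste0(path, "$", nm) else nm
    if (!nm %in% names(base))
      stop("unknown configuration key: ", full)
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]])) &&
        is.list(user[[nm]]) && nm != "planted")
      base[[nm]] <- mergeConfig(base[[nm]], user[[nm]], full)
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Read and validate a pipeline configuration
#'
#' YAML key-value configuration overriding the documented defaults;
#' unknown keys are errors.
#'
#' @param path YAML file path, or a named list of overrides.
#' @return the validated full configuration list.
#' @export
readRunConfig <- function(path) {
  user <- if (is.character(path)) yaml::read_yaml(path) else path
  cfg <- mergeConfig(defaultRunConfig(), user)
  if (!all(cfg$models %in% ALL_MODELS))
    stop("models must be drawn from: ", paste(ALL_MODELS, collapse = ", "))
  if (cfg$seed < 0) stop("seed must be non-negative")
  cfg
}

## Fit every configured model to one patient's curves; returns a named
## list of KineticFit objects.
fitPatientModels <- function(models, tac, aifP, schedule, tStar, knotConfig,
                             seed) {
  fits <- list()
  for (m in models) {
    fits[[m]] <- if (m == "patlak") patlakFit(tac, aifP, schedule, tStar)
    else if (m == "spline") fitSplineResidue(tac, aifP, schedule, knotConfig)
    else fitCompartment(m, tac, aifP, schedule, seed = seed)
  }
  fits
}

## Assemble the imaging-measure table from static measures and fits.
measureTable <- function(static, fitsByPatient, models,
                         includeMicro = TRUE) {
  out <- static[, c("SUVmax", "SUVmean", "TBRmax", "TBRmean")]
  for (m in models) {
    col <- if (m == "patlak") "patlak_K" else paste0("kflux_", m)
    out[[col]] <- vapply(fitsByPatient, function(f) f[[m]]@kflux, 1)
    if (includeMicro && m != "patlak") {
      for (pn in names(fitsByPatient[[1]][[m]]@params)) {
        out[[paste0(pn, "_", m)]] <-
          vapply(fitsByPatient, function(f) unname(f[[m]]@params[pn]), 1)
      }
    }
  }
  out
}

#' Pathway x measure association grid
#'
#' Combines per-measure GSEA outputs into the union-of-significant-pathways
#' grid: rows are pathways significant for at least one measure, cells
#' hold the NES where significant (NA otherwise), plus a per-measure
#' significant-pathway count.
#'
#' @param gseaOutputs named list (measure name -> [gseaRun()] table).
#' @return a list: `grid` (data.frame, pathway column + one NES column per
#'   measure), `counts` (named integer vector of per-measure significant
#'   counts).
#' @export
associationGrid <- function(gseaOutputs) {
  stopifnot(length(gseaOutputs) >= 1L, !is.null(names(gseaOutputs)))
  sig <- lapply(gseaOutputs, function(d) d$pathway[d$significant])
  pathways <- sort(unique(unlist(sig)))
  grid <- data.frame(pathway = pathways, stringsAsFactors = FALSE)
  for (m in names(gseaOutputs)) {
    d <- gseaOutputs[[m]]
    nes <- rep(NA_real_, length(pathways))
    hit <- match(pathways, d$pathway)
    ok <- !is.na(hit) & d$significant[hit]
    nes[ok] <- d$NES[hit[ok]]
    grid[[m]] <- nes
  }
  counts <- vapply(gseaOutputs, function(d) sum(d$significant), 1L)
  list(grid = grid, counts = counts)
}

#' Run the end-to-end radiogenomic pipeline
#'
#' Simulates (or loads) a cohort, fits the three-exponential AIF model,
#' fits the configured kinetic models, derives flux-constants and static
#' uptake measures, runs GSEA per imaging measure, and (optionally) the
#' cohort-level false-positive and bootstrap studies. All stage seeds are
#' derived from the single master seed, every table carries the
#' configuration hash, and a JSON manifest records inputs, seeds and
#' per-stage wall time. Rerunning with an identical configuration
#' reproduces every numeric table byte for byte.
#'
#' @param config a configuration list or YAML path (see
#'   [readRunConfig()]).
#' @return invisibly, a list with the in-memory results (`cohort`,
#'   `fits`, `measures`, `gsea`, `grid`, `manifest`, `outputDir`).
#' @export
runAll <- function(config = list()) {
  cfg <- readRunConfig(config)
  dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
  cfgHash <- hashObject(cfg[setdiff(names(cfg), "outputDir")])
  manifest <- list(config = cfg, configHash = cfgHash,
                   packageVersion = as.character(utils::packageVersion("fluxgsea")),
                   stages = list())
  t0 <- proc.time()[["elapsed"]]
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    manifest$stages[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  ## --- cohort ------------------------------------------------------------
  schedule <- makePaperSchedule()
  cohort <- simulateCohort(cfg$cohort$nPatients,
                           cohortTruthDistributions(cfg$cohort$model),
                           seed = deriveSeed(cfg$seed, "cohort"),
                           schedule = schedule,
                           noiseScale = cfg$cohort$noiseScale,
                           aifNoiseSd = cfg$cohort$aifNoiseSd)
  writeTsv(cohort$truth, file.path(cfg$outputDir, "cohort_truth.tsv"), cfgHash)
  writeTsv(cohort$static, file.path(cfg$outputDir, "static_measures.tsv"),
           cfgHash)
  tick("simulate")

  ## --- AIF fits ----------------------------------------------------------
  aifPs <- if (isTRUE(cfg$aifFit$enabled)) {
    lapply(cohort$curves, function(cv) fitAif(cv$aif)$params)
  } else cohort$aifParams
  tick("fitAif")

  ## --- kinetic fits ------------------------------------------------------
  knotCfg <- splineKnots(cfg$knots$nInterior, tMax = tScan(schedule))
  fits <- lapply(seq_along(cohort$curves), function(i)
    fitPatientModels(cfg$models, cohort$curves[[i]]$tac, aifPs[[i]],
                     schedule, cfg$tStar, knotCfg,
                     seed = deriveSeed(cfg$seed, paste0("fit", i))))
  fitRows <- do.call(rbind, lapply(seq_along(fits), function(i) {
    do.call(rbind, lapply(cfg$models, function(m) {
      f <- fits[[i]][[m]]
      data.frame(patient = i, model = m,
                 parameter = names(f@params), value = unname(f@params),
                 wrss = f@wrss, kflux = f@kflux)
    }))
  }))
  writeTsv(fitRows, file.path(cfg$outputDir, "kinetic_fits.tsv"), cfgHash)
  tick("fitKinetics")

  ## --- measures ----------------------------------------------------------
  measures <- measureTable(cohort$static, fits, cfg$models,
                           includeMicro = isTRUE(cfg$microParameterGsea))
  measures <- cbind(patient = cohort$static$patient, measures,
                    kflux_true = cohort$truth$kflux)
  writeTsv(measures, file.path(cfg$outputDir, "imaging_measures.tsv"),
           cfgHash)
  tick("measures")

  ## --- expression + gene sets -------------------------------------------
  planted <- lapply(cfg$expression$planted, function(p) {
    ids <- geneIds(cfg$expression$nGenes)
    list(name = p$name, genes = tail(ids, p$size), rho = p$rho,
         measure = p$measure)
  })
  spec <- expressionSpec(cfg$expression$nGenes, cfg$cohort$nPatients,
                         planted, cfg$expression$noiseSd,
                         cfg$expression$baseMean,
                         seed = deriveSeed(cfg$seed, "expr"))
  exprSim <- simulateExpression(spec, as.list(measures[-1]))
  collection <- syntheticCollection(spec, cfg$collection$nNullSets,
                                    cfg$collection$nullSetSize,
                                    seed = deriveSeed(cfg$seed, "sets"))
  writeGmt(collection, file.path(cfg$outputDir, "gene_sets.gmt"))
  tick("expression")

  ## --- GSEA per measure --------------------------------------------------
  gseaOut <- list()
  measureCols <- setdiff(names(measures), c("patient", "kflux_true"))
  for (method in cfg$gsea$methods) {
    for (mc in measureCols) {
      res <- gseaRun(exprSim$matrix, measures[[mc]], collection,
                     method = method, nPerm = cfg$gsea$nPerm,
                     seed = deriveSeed(cfg$seed, paste0("gsea_", method, "_", mc)),
                     minSize = cfg$gsea$minSize, maxSize = cfg$gsea$maxSize,
                     alphaNumerator = cfg$gsea$alphaNumerator)
      key <- if (length(cfg$gsea$methods) > 1L) paste(method, mc, sep = ":")
             else mc
      gseaOut[[key]] <- res
      writeTsv(res, file.path(cfg$outputDir,
                              paste0("gsea_", method, "_", mc, ".tsv")),
               cfgHash)
    }
  }
  tick("gsea")

  ## --- association grid --------------------------------------------------
  grid <- associationGrid(gseaOut)
  writeTsv(grid$grid, file.path(cfg$outputDir, "association_grid.tsv"),
           cfgHash)
  writeTsv(data.frame(measure = names(grid$counts),
                      nSignificant = unname(grid$counts)),
           file.path(cfg$outputDir, "association_counts.tsv"), cfgHash)
  tick("grid")

  ## --- optional cohort statistics ----------------------------------------
  cohortStats <- NULL
  if (isTRUE(cfg$cohortStats$enabled)) {
    fp <- permutedPhenotypeStudy(exprSim$matrix,
                                 measures[[cfg$cohortStats$fpMeasure]],
                                 collection,
                                 nDatasets = cfg$cohortStats$nDatasets,
                                 alphaNumerator = cfg$gsea$alphaNumerator,
                                 nPerm = cfg$gsea$nPerm,
                                 seed = deriveSeed(cfg$seed, "fpstudy"))
    writeTsv(data.frame(dataset = seq_along(fp$counts), count = fp$counts),
             file.path(cfg$outputDir, "false_positive_study.tsv"), cfgHash)
    pair <- cfg$cohortStats$comparePair
    bd <- bootstrapCountDifference(exprSim$matrix, measures, collection,
                                   pair[1], pair[2],
                                   nBoot = cfg$cohortStats$nBoot,
                                   nPerm = cfg$gsea$nPerm,
                                   seed = deriveSeed(cfg$seed, "bootdiff"))
    writeTsv(data.frame(resample = seq_along(bd$differences),
                        countA = bd$countsA, countB = bd$countsB,
                        difference = bd$differences),
             file.path(cfg$outputDir, "bootstrap_differences.tsv"), cfgHash)
    cohortStats <- list(fp = fp, bootdiff = bd)
    tick("cohortStats")
  }

  manifest$measures <- measureCols
  jsonlite::write_json(manifest, file.path(cfg$outputDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, fits = fits, measures = measures,
                 gsea = gseaOut, grid = grid, cohortStats = cohortStats,
                 manifest = manifest, outputDir = cfg$outputDir))
}
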