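#' @include kinetics.R static.R
NULL

#' Default cohort truth distributions
#'
#' Sampling distributions of per-patient AIF and kinetic ground truth for
#' [simulateCohort()]. Rates and amplitudes are log-normal around typical
#' breast-tumour FDG values (K1 ~ 0.1 /min, k2 ~ 0.35 /min, k3 ~ 0.08
#' /min, Vb a few percent), AIF components around a bolus peaking near 40
#' kBq/mL; body weight is normal around 70 kg with a 3 MBq/kg injected
#' dose.
#'
#' @param model compartment model generating the cohort's TACs.
#' @return a named list of sampling functions, each `function(n)`.
#' @export
cohortTruthDistributions <- function(model = "2C3K") {
  list(
    model = model,
    K1 = function(n) rlnorm_(n, 0.10, 0.35),
    k2 = function(n) rlnorm_(n, 0.35, 0.30),
    k3 = function(n) rlnorm_(n, 0.08, 0.45),
    k4 = function(n) rlnorm_(n, 0.01, 0.30),
    k5 = function(n) rlnorm_(n, 0.03, 0.30),
    Vb = function(n) runif(n, 0.03, 0.12),
    aifDelay = function(n) runif(n, 0.2, 0.8),
    aifA1 = function(n) rlnorm_(n, 400, 0.15),
    aifA2 = function(n) rlnorm_(n, 6, 0.15),
    aifA3 = function(n) rlnorm_(n, 3, 0.15),
    aifMu1 = function(n) rlnorm_(n, 4, 0.10),
    aifMu2 = function(n) rlnorm_(n, 0.12, 0.10),
    aifMu3 = function(n) rlnorm_(n, 0.01, 0.10),
    bodyWeightKg = function(n) pmin(pmax(rnorm(n, 70, 12), 45), 110),
    suvMaxFactor = function(n) runif(n, 1.4, 2.2)
  )
}

## log-normal with a given median and log-sd
rlnorm_ <- function(n, med, sdlog) stats::rlnorm(n, log(med), sdlog)

#' Simulate a dynamic-PET cohort with known kinetic truth
#'
#' Per patient: a Feng-type AIF, a tumour TAC generated from known
#' compartment-model parameters with frame-duration-matched noise, and
#' static uptake inputs (tumour and blood concentrations at 60 min,
#' injected dose 3 MBq/kg, body weight) derived from the same kinetics so
#' that SUV/TBR correlate with the flux-constant by construction.
#'
#' @param nPatients cohort size (the emulated study analysed 30).
#' @param truth a [cohortTruthDistributions()] list.
#' @param seed master seed.
#' @param schedule a [FrameSchedule]; default the 45-min study schedule.
#' @param noiseScale TAC noise scale (see [simulateTac()]); default 1.5.
#' @param aifNoiseSd AIF frame noise sd, kBq/mL; default 0.5.
#' @return a list: `curves` (per patient, `list(aif=Curve, tac=Curve)`),
#'   `truth` (data.frame of AIF/kinetic ground truth incl. `kflux`),
#'   `static` (data.frame of static inputs and SUV/TBR measures),
#'   `aifParams` (list of [AifParams]).
#' @export
simulateCohort <- function(nPatients = 30L,
                           truth = cohortTruthDistributions(),
                           seed = 1L, schedule = makePaperSchedule(),
                           noiseScale = 1.5, aifNoiseSd = 0.5) {
  stopifnot(nPatients >= 2)
  model <- truth$model
  nm <- modelParamNames(model)
  draws <- withLocalSeed(seed, {
    d <- lapply(truth[setdiff(names(truth), "model")],
                function(f) f(nPatients))
    d
  })
  kin <- do.call(cbind, draws[intersect(c("K1", "k2", "k3", "k4", "k5", "Vb"),
                                        nm)])
  if (any(vapply(draws, function(v) sd(v) == 0, TRUE)))
    warning("degenerate truth distribution: zero variance across the cohort")

  aifs <- lapply(seq_len(nPatients), function(i)
    aifParams(draws$aifDelay[i], draws$aifA1[i], draws$aifA2[i],
              draws$aifA3[i], draws$aifMu1[i], draws$aifMu2[i],
              draws$aifMu3[i]))
  curves <- vector("list", nPatients)
  kflux <- numeric(nPatients)
  tum60 <- blood60 <- numeric(nPatients)
  for (i in seq_len(nPatients)) {
    p <- setNames(as.numeric(kin[i, nm]), nm)
    kflux[i] <- fluxConstant(model, p, tScan(schedule))
    aif <- simulateAif(aifs[[i]], schedule,
                       seed = deriveSeed(seed, paste0("aif", i)),
                       noiseSd = aifNoiseSd)
    tac <- simulateTac(model, p, aifs[[i]], schedule,
                       seed = deriveSeed(seed, paste0("tac", i)),
                       noiseScale = noiseScale)
    curves[[i]] <- list(aif = aif, tac = tac)
    tum60[i] <- pointwiseTac(model, p, aifs[[i]], 60)
    blood60[i] <- evalAif(aifs[[i]], 60)
  }
  weight <- draws$bodyWeightKg * 1000            # g
  dose <- pmin(3 * draws$bodyWeightKg, 400) * 1000  # kBq (3 MBq/kg, cap 400)
  tumMax <- tum60 * draws$suvMaxFactor
  static <- do.call(rbind, lapply(seq_len(nPatients), function(i) {
    sm <- staticMeasures(tumMax[i], tum60[i], blood60[i], dose[i], weight[i])
    data.frame(patient = i, tumourMaxConc = tumMax[i],
               tumourMeanConc = tum60[i], bloodMeanConc = blood60[i],
               injectedDose_kBq = dose[i], bodyWeight_g = weight[i],
               SUVmax = sm[["SUVmax"]], SUVmean = sm[["SUVmean"]],
               TBRmax = sm[["TBRmax"]], TBRmean = sm[["TBRmean"]])
  }))
  truthTab <- data.frame(patient = seq_len(nPatients), model = model,
                         kin, kflux = kflux,
                         aifDelay = draws$aifDelay, aifA1 = draws$aifA1,
                         aifA2 = draws$aifA2, aifA3 = draws$aifA3,
                         aifMu1 = draws$aifMu1, aifMu2 = draws$aifMu2,
                         aifMu3 = draws$aifMu3)
  list(curves = curves, truth = truthTab, static = static, aifParams = aifs)
}

#' Build a synthetic expression specification
#'
#' @param nGenes number of genes (default 2000, standing in for the ~17k
#'   of a filtered RNA-seq panel at desk scale).
#' @param nPatients cohort size.
#' @param planted list of planted pathways, each
#'   `list(name=, genes=, rho=, measure=)`; gene ids must refer to rows
#'   that will exist (use `"G%04d"` style ids within `nGenes`).
#' @param noiseSd iid Gaussian sd on the log2 scale.
#' @param baseMean log2 centre of the matrix.
#' @param seed generator seed.
#' @return a [SyntheticExpressionSpec].
#' @export
expressionSpec <- function(nGenes = 2000L, nPatients = 30L, planted = list(),
                           noiseSd = 1, baseMean = 5, seed = 1L) {
  new("SyntheticExpressionSpec", nGenes = as.integer(nGenes),
      nPatients = as.integer(nPatients), planted = planted,
      noiseSd = noiseSd, baseMean = baseMean, seed = as.integer(seed))
}

## Canonical synthetic gene identifiers.
geneIds <- function(n) sprintf("G%05d", seq_len(n))

#' Simulate a log2 expression matrix with planted imaging correlations
#'
#' Filler genes are iid Gaussian on the log2 scale. Each planted gene is
#' built as \eqn{x = \rho z + \sqrt{1-\rho^2}\,\varepsilon} on
#' standardised scales, where z is the standardised imaging measure, so
#' its population correlation with the measure equals the requested
#' effect size exactly.
#'
#' @param spec a [SyntheticExpressionSpec].
#' @param measureValues named list (or single numeric vector) of imaging
#'   measure values, one value per patient; planted pathways reference
#'   measures by name.
#' @return a list: `matrix` (genes x patients, log2), `annotation`
#'   (data.frame gene/pathway for planted genes), `spec`.
#' @export
simulateExpression <- function(spec, measureValues) {
  stopifnot(is(spec, "SyntheticExpressionSpec"))
  if (is.numeric(measureValues)) measureValues <- list(measure = measureValues)
  if (any(vapply(measureValues, length, 1L) != spec@nPatients))
    stop("each measure must have one value per patient")
  ids <- geneIds(spec@nGenes)
  for (p in spec@planted) {
    if (!p$measure %in% names(measureValues))
      stop("planted pathway '", p$name, "' references unknown measure '",
           p$measure, "'")
    if (!all(p$genes %in% ids))
      stop("planted pathway '", p$name, "' uses gene ids outside the matrix")
  }
  m <- withLocalSeed(spec@seed, {
    mat <- matrix(rnorm(spec@nGenes * spec@nPatients, 0, 1),
                  spec@nGenes, spec@nPatients,
                  dimnames = list(ids, sprintf("P%02d", seq_len(spec@nPatients))))
    for (p in spec@planted) {
      z <- as.numeric(scale(measureValues[[p$measure]]))
      rows <- match(p$genes, ids)
      eps <- matrix(rnorm(length(rows) * spec@nPatients), length(rows))
      mat[rows, ] <- p$rho * matrix(z, length(rows), spec@nPatients,
                                    byrow = TRUE) +
        sqrt(1 - p$rho^2) * eps
    }
    mat
  })
  annotation <- if (length(spec@planted)) {
    do.call(rbind, lapply(spec@planted, function(p)
      data.frame(gene = p$genes, pathway = p$name, rho = p$rho,
                 measure = p$measure)))
  } else data.frame(gene = character(), pathway = character(),
                    rho = numeric(), measure = character())
  list(matrix = spec@baseMean + spec@noiseSd * m, annotation = annotation,
       spec = spec)
}

#' Build a mixed planted/null gene-set collection
#'
#' Planted pathways keep their member genes; null sets are drawn uniformly
#' from the remaining (filler) genes.
#'
#' @param spec a [SyntheticExpressionSpec].
#' @param nNullSets number of null sets.
#' @param nullSetSize genes per null set (recycled).
#' @param seed RNG seed.
#' @return named list of character vectors (a GMT-ready collection).
#' @export
syntheticCollection <- function(spec, nNullSets = 99L, nullSetSize = 40L,
                                seed = 1L) {
  ids <- geneIds(spec@nGenes)
  plantedGenes <- unique(unlist(lapply(spec@planted, `[[`, "genes")))
  pool <- setdiff(ids, plantedGenes)
  sizes <- rep_len(nullSetSize, nNullSets)
  nulls <- withLocalSeed(seed, lapply(seq_len(nNullSets), function(i)
    sample(pool, sizes[i])))
  names(nulls) <- sprintf("NULL_SET_%03d", seq_len(nNullSets))
  planted <- lapply(spec@planted, `[[`, "genes")
  names(planted) <- vapply(spec@planted, `[[`, "", "name")
  c(planted, nulls)
}

#' Read and write GMT gene-set files
#'
#' The GMT dialect: one set per line, tab-separated, `name`,
#' `description`, then member gene ids (at least three fields).
#'
#' @param collection named list of character vectors; an optional
#'   `descriptions` attribute (named character) fills the second field.
#' @param path file path.
#' @return `readGmt()` a named list with a `descriptions` attribute;
#'   `writeGmt()` the path, invisibly.
#' @name gmt-io
NULL

#' @rdname gmt-io
#' @export
writeGmt <- function(collection, path) {
  if (is.null(names(collection)) || anyDuplicated(names(collection)))
    stop("gene-set names must be present and unique")
  if (any(vapply(collection, length, 1L) == 0L))
    stop("empty gene sets cannot be written")
  desc <- attr(collection, "descriptions")
  lines <- vapply(names(collection), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, collection[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname gmt-io
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1], ": fewer than 3 tab-separated fields")
  nms <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nms)) stop("duplicate gene-set names in GMT file")
  out <- lapply(parts, function(p) p[-(1:2)])
  names(out) <- nms
  attr(out, "descriptions") <- setNames(vapply(parts, `[[`, "", 2L), nms)
  out
}
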