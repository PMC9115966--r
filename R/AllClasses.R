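#' @import methods
NULL

#' Dynamic-scan frame schedule
#'
#' Holds the time-frame structure of a dynamic PET acquisition: per-frame
#' durations (seconds), frame mid-times in minutes post-injection, and the
#' post-injection scan span \eqn{T_{scan}}. The injection may occur after
#' acquisition starts, so early frames can have negative mid-times.
#'
#' @slot durations numeric, seconds per frame.
#' @slot injectionOffset numeric, seconds between acquisition start and
#'   tracer injection.
#' @slot midTimes numeric, frame mid-times in minutes post-injection.
#' @slot tScan numeric, minutes from injection to end of acquisition.
#' @exportClass FrameSchedule
setClass("FrameSchedule",
  representation(durations = "numeric", injectionOffset = "numeric",
                 midTimes = "numeric", tScan = "numeric"))

setValidity("FrameSchedule", function(object) {
  d <- object@durations
  if (length(d) == 0L || any(!is.finite(d)) || any(d <= 0))
    return("frame durations must be finite and positive")
  starts <- (cumsum(c(0, d))[-(length(d) + 1L)] - object@injectionOffset) / 60
  ends <- starts + d / 60
  m <- object@midTimes
  if (length(m) != length(d)) return("one mid-time per frame required")
  if (any(diff(m) <= 0)) return("mid-times must be strictly increasing")
  if (any(m < starts - 1e-9 | m > ends + 1e-9))
    return("each mid-time must lie inside its frame")
  if (abs(object@tScan - (sum(d) - object@injectionOffset) / 60) > 1e-9)
    return("tScan must equal total acquisition minus injection offset")
  TRUE
})

#' Sampled activity curve (AIF or TAC)
#'
#' Decay-corrected activity concentrations (kBq/mL) frame-averaged on a
#' [FrameSchedule].
#'
#' @slot schedule a [FrameSchedule].
#' @slot activity numeric, kBq/mL per frame.
#' @slot label character, free-text curve label ("aif", "tac", ...).
#' @exportClass Curve
setClass("Curve",
  representation(schedule = "FrameSchedule", activity = "numeric",
                 label = "character"))

setValidity("Curve", function(object) {
  if (length(object@activity) != length(object@schedule@durations))
    return("one activity value per frame required")
  if (any(is.na(object@activity))) return("activity values must not be NA")
  TRUE
})

#' Three-exponential arterial input function parameters
#'
#' Feng-type input function with appearance delay \eqn{\tau}:
#' \deqn{AIF(t) = (A_1 u - A_2 - A_3) e^{-\mu_1 u} + A_2 e^{-\mu_2 u}
#'   + A_3 e^{-\mu_3 u}, \quad u = t - \tau,}
#' zero for \eqn{t \le \tau}. Continuity at the delay (AIF(\eqn{\tau}) = 0)
#' is built into the form.
#'
#' @slot delay minutes; appearance delay \eqn{\tau \ge 0}.
#' @slot A1 kBq mL^-1 min^-1; ramp amplitude of the bolus peak.
#' @slot A2,A3 kBq/mL; amplitudes of the slower washout components.
#' @slot mu1,mu2,mu3 min^-1; decay rates, \eqn{\mu_1 > \mu_2 > \mu_3 > 0}.
#' @exportClass AifParams
setClass("AifParams",
  representation(delay = "numeric", A1 = "numeric", A2 = "numeric",
                 A3 = "numeric", mu1 = "numeric", mu2 = "numeric",
                 mu3 = "numeric"))

setValidity("AifParams", function(object) {
  v <- c(object@delay, object@A1, object@A2, object@A3,
         object@mu1, object@mu2, object@mu3)
  if (length(v) != 7L || any(!is.finite(v))) return("all parameters required")
  if (object@delay < 0) return("delay must be non-negative")
  if (!(object@mu1 > object@mu2 && object@mu2 > object@mu3 && object@mu3 > 0))
    return("rate ordering mu1 > mu2 > mu3 > 0 violated")
  TRUE
})

#' Fitted kinetic model
#'
#' Result of fitting a kinetic model to a tumour TAC: the model identity,
#' fitted parameters, the achieved weighted residual sum-of-squares, the
#' derived flux-constant and everything needed to evaluate the residue
#' function and the fitted curve.
#'
#' @slot modelId one of "patlak", "2C3K", "2C4K", "3C5K", "spline".
#' @slot params named numeric; micro-parameters (min^-1, Vb fraction) or
#'   Patlak slope/intercept.
#' @slot wrss weighted residual sum-of-squares of the fit.
#' @slot kflux derived flux-constant, min^-1.
#' @slot aif the [AifParams] used as input term (may be empty for Patlak
#'   fits driven by a sampled curve).
#' @slot schedule the [FrameSchedule] fitted on.
#' @slot details list; model-specific extras (spline knots/coefficients,
#'   multi-start diagnostics, frames used).
#' @exportClass KineticFit
setClass("KineticFit",
  representation(modelId = "character", params = "numeric", wrss = "numeric",
                 kflux = "numeric", aif = "AifParams",
                 schedule = "FrameSchedule", details = "list"))

setValidity("KineticFit", function(object) {
  if (!object@modelId %in% c("patlak", "2C3K", "2C4K", "3C5K", "spline"))
    return("unknown modelId")
  if (length(object@wrss) != 1L || object@wrss < 0)
    return("wrss must be a single non-negative number")
  if (length(object@kflux) != 1L || !is.finite(object@kflux))
    return("kflux must be a single finite number")
  TRUE
})

#' Correlation-ranked gene list
#'
#' Genes ordered by the correlation of their expression with an imaging
#' measure, ties broken uniformly at random under a dedicated seed.
#'
#' @slot gene character, gene identifiers in rank order.
#' @slot stat numeric, the ranking correlation coefficient per gene.
#' @slot method "pearson" or "spearman".
#' @slot tieSeed integer seed consumed by the random tie-break.
#' @exportClass RankedGeneList
setClass("RankedGeneList",
  representation(gene = "character", stat = "numeric", method = "character",
                 tieSeed = "integer"))

setValidity("RankedGeneList", function(object) {
  if (length(object@gene) != length(object@stat))
    return("gene and stat lengths differ")
  if (anyDuplicated(object@gene)) return("duplicate gene identifiers")
  if (any(diff(object@stat) > 1e-12))
    return("ranking statistic must be non-increasing")
  if (!object@method %in% c("pearson", "spearman")) return("unknown method")
  TRUE
})

#' Synthetic expression-matrix specification
#'
#' Describes a synthetic log2 expression matrix: size, iid Gaussian noise
#' on the log2 scale, and pathways whose member genes are constructed to
#' correlate with a named imaging measure at a target population
#' correlation (the effect size).
#'
#' @slot nGenes,nPatients matrix dimensions.
#' @slot planted list; each element a list with `name`, `genes`
#'   (character ids), `rho` (target correlation in (-1, 1)) and `measure`
#'   (imaging-measure name the genes track).
#' @slot noiseSd numeric, sd of the iid Gaussian log2 noise.
#' @slot baseMean numeric, centre of the log2 expression scale.
#' @slot seed integer generator seed.
#' @exportClass SyntheticExpressionSpec
setClass("SyntheticExpressionSpec",
  representation(nGenes = "integer", nPatients = "integer", planted = "list",
                 noiseSd = "numeric", baseMean = "numeric", seed = "integer"))

setValidity("SyntheticExpressionSpec", function(object) {
  if (object@nGenes < 1L || object@nPatients < 2L)
    return("need nGenes >= 1 and nPatients >= 2")
  if (object@noiseSd < 0) return("noiseSd must be non-negative")
  for (p in object@planted) {
    if (!all(c("name", "genes", "rho", "measure") %in% names(p)))
      return("each planted pathway needs name, genes, rho, measure")
    if (abs(p$rho) >= 1) return("effect sizes must lie in (-1, 1)")
    if (anyDuplicated(p$genes)) return("duplicate gene ids within a pathway")
  }
  pl <- unique(unlist(lapply(object@planted, `[[`, "genes")))
  if (length(pl) > object@nGenes)
    return("planted genes exceed nGenes")
  TRUE
})
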