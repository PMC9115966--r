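#' @include utils.R
NULL

#' Static uptake measures: SUV and TBR
#'
#' Standardised uptake values normalise tumour activity concentration by
#' injected dose per unit body weight (the g/mL convention: SUV =
#' concentration / (dose/weight)); tumour-to-blood ratios normalise by the
#' mean blood-pool concentration, so TBR = tumour concentration / blood
#' concentration independent of dose.
#'
#' @param tumourMaxConc,tumourMeanConc maximum and mean tumour activity
#'   concentration, kBq/mL.
#' @param bloodMeanConc mean blood-pool concentration, kBq/mL.
#' @param injectedDose kBq.
#' @param bodyWeight grams.
#' @return a named numeric vector: `SUVmax`, `SUVmean`, `TBRmax`,
#'   `TBRmean`.
#' @examples
#' staticMeasures(10, 5, 2, injectedDose = 1, bodyWeight = 1)
#' @export
staticMeasures <- function(tumourMaxConc, tumourMeanConc, bloodMeanConc,
                           injectedDose, bodyWeight) {
  if (any(c(tumourMaxConc, tumourMeanConc, bloodMeanConc, injectedDose,
            bodyWeight) <= 0))
    stop("all inputs must be positive")
  dpw <- injectedDose / bodyWeight
  c(SUVmax = tumourMaxConc / dpw, SUVmean = tumourMeanConc / dpw,
    TBRmax = tumourMaxConc / bloodMeanConc,
    TBRmean = tumourMeanConc / bloodMeanConc)
}
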