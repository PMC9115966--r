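#' @include AllClasses.R AllGenerics.R aif.R
NULL

COMPARTMENT_MODELS <- c("2C3K", "2C4K", "3C5K")
ALL_MODELS <- c("patlak", COMPARTMENT_MODELS, "spline")

modelParamNames <- function(modelId) {
  switch(modelId,
         "2C3K" = c("K1", "k2", "k3", "Vb"),
         "2C4K" = c("K1", "k2", "k3", "k4", "Vb"),
         "3C5K" = c("K1", "k2", "k3", "k4", "k5", "Vb"),
         "patlak" = c("K", "V"),
         stop("unknown compartment model: ", modelId))
}

checkCompartmentParams <- function(modelId, params) {
  nm <- modelParamNames(modelId)
  if (!all(nm %in% names(params)))
    stop(modelId, " requires parameters: ", paste(nm, collapse = ", "))
  p <- params[nm]
  if (any(p[setdiff(nm, "Vb")] < 0)) stop("rate constants must be non-negative")
  if (p["Vb"] < 0 || p["Vb"] >= 1) stop("Vb must lie in [0, 1)")
  p
}

## Tissue rate matrix (trap state included) for each compartment topology.
## States are ordered exchange compartments first, trap last.
rateMatrix <- function(modelId, p) {
  switch(modelId,
    "2C3K" = matrix(c(-(p["k2"] + p["k3"]), 0,
                      p["k3"], 0), 2, 2, byrow = TRUE),
    "2C4K" = matrix(c(-(p["k2"] + p["k3"]), p["k4"],
                      p["k3"], -p["k4"]), 2, 2, byrow = TRUE),
    ## free -k3-> bound1 -k5-> trapped, k4 back-transfer, k2 efflux from free
    "3C5K" = matrix(c(-(p["k2"] + p["k3"]), p["k4"], 0,
                      p["k3"], -(p["k4"] + p["k5"]), 0,
                      0, p["k5"], 0), 3, 3, byrow = TRUE),
    stop("no rate matrix for model ", modelId))
}

#' Exponential-sum representation of a compartment residue function
#'
#' Eigen-decomposition of the tissue rate matrix gives
#' \eqn{R(t) = \sum_j c_j e^{-\beta_j t}} with \eqn{\sum_j c_j = 1}
#' (R(0) = 1). Nearly defective matrices (coincident eigenvalues, a
#' measure-zero parameter set) are nudged by a relative 1e-9 jitter.
#' @noRd
residueExpSum <- function(modelId, params) {
  p <- checkCompartmentParams(modelId, params)
  if (modelId == "2C3K") {
    a <- p[["k2"]] + p[["k3"]]
    if (a == 0) return(list(beta = 0, coef = 1))
    return(list(beta = c(0, a), coef = c(p[["k3"]] / a, p[["k2"]] / a)))
  }
  M <- rateMatrix(modelId, p)
  for (jit in c(0, 1e-9, 1e-7)) {
    Mj <- M + diag(jit * (seq_len(nrow(M)) - 1), nrow(M))
    e <- eigen(Mj)
    V <- Re(e$vectors)
    if (rcond(V) > 1e-10) {
      a <- solve(V, c(1, rep(0, nrow(M) - 1L)))
      co <- colSums(V) * a
      beta <- -Re(e$values)
      beta[abs(beta) < 1e-12] <- 0
      keep <- abs(co) > 1e-14
      if (!any(keep)) keep <- TRUE
      return(list(beta = beta[keep], coef = co[keep]))
    }
  }
  stop("defective rate matrix; could not decompose residue function")
}

#' Residue function of a kinetic model
#'
#' The fraction R(t) of tracer delivered to tissue at time 0 that remains
#' at time t. Closed multi-exponential form for compartment models;
#' B-spline expansion for fitted spline models (see [fitSplineResidue()]).
#'
#' @param modelId one of "2C3K", "2C4K", "3C5K".
#' @param params named parameter vector (rate constants min^-1; `Vb` is
#'   accepted and ignored here).
#' @param times minutes.
#' @return R values; R(0) = 1.
#' @examples
#' residueFunction("2C3K", c(K1 = .1, k2 = .3, k3 = .1, Vb = 0), c(0, 1e6))
#' @export
residueFunction <- function(modelId, params, times) {
  es <- residueExpSum(modelId, params)
  out <- numeric(length(times))
  for (j in seq_along(es$beta))
    out <- out + es$coef[j] * exp(-es$beta[j] * pmax(times, 0))
  out
}

#' Flux-constant of a kinetic model
#'
#' The rate of irreversible tracer trapping per unit steady blood
#' concentration. Closed forms: 2C3K \eqn{K_1 k_3 / (k_2 + k_3)}; 3C5K
#' \eqn{K_1 k_3 k_5 / (k_2 (k_4 + k_5) + k_3 k_5)}; Patlak returns the
#' slope K. For reversible (2C4K) and spline models, whose asymptotic flux
#' is zero, the operational value \eqn{K_1 R(T_{scan})} is used.
#'
#' @param modelId model identity, or a [KineticFit] (method dispatch on
#'   fits is provided by [fluxConstantOfFit()]).
#' @param params named parameter vector.
#' @param tScanMin scan span in minutes; needed for 2C4K only.
#' @return k_flux in min^-1.
#' @examples
#' fluxConstant("2C3K", c(K1 = .1, k2 = .3, k3 = .1, Vb = 0))  # 0.025
#' @export
fluxConstant <- function(modelId, params, tScanMin = 45) {
  if (modelId == "patlak") return(unname(params[["K"]]))
  p <- checkCompartmentParams(modelId, params)
  K1 <- p[["K1"]]
  if (modelId == "2C3K") {
    den <- p[["k2"]] + p[["k3"]]
    return(if (den == 0) K1 else K1 * p[["k3"]] / den)
  }
  if (modelId == "3C5K") {
    den <- p[["k2"]] * (p[["k4"]] + p[["k5"]]) + p[["k3"]] * p[["k5"]]
    if (den == 0) {
      ## fully trapping degenerate corner: take the asymptote numerically
      return(K1 * residueFunction(modelId, p, 1e8))
    }
    return(K1 * p[["k3"]] * p[["k5"]] / den)
  }
  ## 2C4K: operationally K1 * R(Tscan)
  K1 * residueFunction(modelId, p, tScanMin)
}

#' Noiseless model TAC
#'
#' Frame-averaged tumour time-activity curve of a compartment model:
#' \deqn{TAC(t) = K_1 \int_0^t AIF(s) R(t-s) ds + V_b\, AIF(t),}
#' with the convolution evaluated analytically (exponential AIF basis
#' times exponential residue terms) and averaged over each acquisition
#' frame by composite Simpson quadrature.
#'
#' @param modelId "2C3K", "2C4K" or "3C5K".
#' @param params named parameters including `Vb`.
#' @param aifParams an [AifParams].
#' @param schedule a [FrameSchedule].
#' @return a [Curve] labelled "tac".
#' @export
modelTac <- function(modelId, params, aifParams, schedule) {
  p <- checkCompartmentParams(modelId, params)
  g <- frameGrid(schedule)
  v <- pointwiseTac(modelId, p, aifParams, as.numeric(g$times))
  Curve(schedule, frameAverageValues(matrix(v, nrow = g$nsub), g), "tac")
}

## Pointwise analytic TAC (no frame averaging).
pointwiseTac <- function(modelId, p, aifParams, times) {
  es <- residueExpSum(modelId, p)
  tissue <- numeric(length(times))
  for (j in seq_along(es$beta))
    tissue <- tissue + es$coef[j] * convAifExp(aifParams, es$beta[j], times)
  p[["K1"]] * tissue + p[["Vb"]] * evalAif(aifParams, times)
}

#' Simulate a noisy TAC
#'
#' The noiseless frame-averaged model TAC plus zero-mean Gaussian frame
#' noise with variance \eqn{\sigma_i^2 = s^2 / w_i}, the exact inverse of
#' the frame weights \eqn{w_i = (\Delta T_i/A_i) e^{-\lambda t_i}} used in
#' fitting, so that weighted least squares is the matched inverse-variance
#' scheme. Frames with non-positive noiseless activity get no noise.
#'
#' @param modelId compartment model identity.
#' @param params named parameters including `Vb`.
#' @param aifParams an [AifParams].
#' @param schedule a [FrameSchedule].
#' @param seed RNG seed.
#' @param noiseScale s in the variance model (kBq/mL scaled); 0 gives the
#'   noiseless curve.
#' @param decayConstant min^-1, decay factor of the weight formula.
#' @return a [Curve] labelled "tac".
#' @export
simulateTac <- function(modelId, params, aifParams, schedule, seed = NULL,
                        noiseScale = 0, decayConstant = F18_DECAY_CONSTANT) {
  if (noiseScale < 0) stop("noiseScale must be non-negative")
  tac <- modelTac(modelId, params, aifParams, schedule)
  if (noiseScale == 0) return(tac)
  a <- activity(tac)
  sd_ <- numeric(length(a))
  pos <- a > 0
  sd_[pos] <- noiseScale * sqrt(a[pos] *
    exp(decayConstant * midTimes(schedule)[pos]) / durations(schedule)[pos])
  Curve(schedule, a + withLocalSeed(seed, rnorm(length(a), 0, sd_)), "tac")
}
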