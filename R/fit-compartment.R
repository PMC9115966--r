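#' @include kinetics.R
NULL

RATE_BOUND <- 5      # min^-1 box bound on every rate constant
VB_BOUND <- 0.5      # fractional blood volume box bound

## Closure evaluating the frame-averaged model TAC as a function of the
## parameter vector, with the quadrature grid built once per (AIF,
## schedule) pair.
makeTacEvaluator <- function(modelId, aifParams, schedule, nsub = 11L) {
  g <- frameGrid(schedule, nsub)
  tt <- as.numeric(g$times)
  vbTerm <- frameAverageValues(matrix(evalAif(aifParams, tt), nrow = g$nsub), g)
  nm <- modelParamNames(modelId)
  function(theta) {
    p <- setNames(theta, nm)
    es <- residueExpSum(modelId, p)
    tissue <- numeric(length(tt))
    for (j in seq_along(es$beta))
      tissue <- tissue + es$coef[j] * convAifExp(aifParams, es$beta[j], tt)
    p[["K1"]] * frameAverageValues(matrix(tissue, nrow = g$nsub), g) +
      p[["Vb"]] * vbTerm
  }
}

## Seeded multi-start values: log-uniform rates, uniform Vb.
compartmentStarts <- function(modelId, nStarts, seed) {
  nm <- modelParamNames(modelId)
  withLocalSeed(seed, {
    lapply(seq_len(nStarts), function(i) {
      th <- vapply(nm, function(p) {
        if (p == "Vb") runif(1, 0.01, 0.3)
        else exp(runif(1, log(0.01), log(1)))
      }, 1)
      setNames(th, nm)
    })
  })
}

#' Fit a compartment model to a tumour TAC
#'
#' Box-bounded weighted least squares (Levenberg-Marquardt) of the
#' frame-averaged model TAC against the measured curve, weighting frames
#' by \eqn{w_i = (\Delta T_i/A_i) e^{-\lambda t_i}}. Only post-injection
#' frames with positive activity enter the fit. Multi-start (default 8
#' seeded starts plus a deterministic mid-box start) guards against local
#' minima; the lowest weighted RSS wins, ties to the earliest start.
#'
#' @param modelId "2C3K", "2C4K" or "3C5K".
#' @param tac a [Curve] of tumour samples.
#' @param aifParams an [AifParams] input term.
#' @param schedule optional [FrameSchedule]; defaults to the curve's.
#' @param weights optional precomputed [computeWeights()] result; by
#'   default recomputed from the measured activities.
#' @param nStarts number of random multi-starts.
#' @param seed seed of the start draw.
#' @param start optional named start vector; if given it is used as the
#'   first start (warm starting).
#' @param decayConstant min^-1 for the weight formula.
#' @return a [KineticFit].
#' @export
fitCompartment <- function(modelId, tac, aifParams, schedule = NULL,
                           weights = NULL, nStarts = 8L, seed = 1L,
                           start = NULL,
                           decayConstant = F18_DECAY_CONSTANT) {
  modelId <- match.arg(modelId, COMPARTMENT_MODELS)
  stopifnot(is(tac, "Curve"))
  if (is.null(schedule)) schedule <- schedule(tac)
  act <- activity(tac)
  if (is.null(weights)) weights <- computeWeights(schedule, act, decayConstant)
  use <- !weights$excluded & midTimes(schedule) > 0
  nm <- modelParamNames(modelId)
  if (sum(use) <= length(nm))
    stop("need more usable frames than parameters")
  y <- act[use]
  sw <- sqrt(weights$weights[use])
  evalTac <- makeTacEvaluator(modelId, aifParams, schedule)
  resid_ <- function(theta) sw * (evalTac(theta)[use] - y)

  lower <- setNames(rep(0, length(nm)), nm)
  upper <- setNames(rep(RATE_BOUND, length(nm)), nm)
  upper["Vb"] <- VB_BOUND
  starts <- compartmentStarts(modelId, nStarts, seed)
  if (!is.null(start)) starts <- c(list(pmin(pmax(start[nm], lower), upper)),
                                   starts)

  best <- NULL
  bestStart <- NA_integer_
  for (i in seq_along(starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(starts[[i]], lower = lower, upper = upper,
                         fn = resid_,
                         control = minpack.lm::nls.lm.control(maxiter = 150)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = fit, rss = rss)
      bestStart <- i
    }
  }
  if (is.null(best)) stop("compartment fit failed from every start")
  p <- setNames(as.numeric(best$fit$par), nm)
  new("KineticFit", modelId = modelId, params = p, wrss = best$rss,
      kflux = fluxConstant(modelId, p, tScan(schedule)), aif = aifParams,
      schedule = schedule,
      details = list(framesUsed = which(use), bestStart = bestStart,
                     nStarts = length(starts), weights = weights,
                     fitted = evalTac(p)))
}

#' Patlak graphical analysis
#'
#' Ordinary least squares of the Patlak coordinates
#' \eqn{y = TAC(t)/AIF(t)} against \eqn{x = \int_0^t AIF / AIF(t)} over
#' frames with mid-time at or after `tStar`. The slope is the Patlak
#' flux-constant K; the intercept estimates an effective distribution
#' volume.
#'
#' @param tac a [Curve].
#' @param aif an [AifParams] (analytic input) or a [Curve] of AIF samples
#'   (the running integral is then computed by trapezoid).
#' @param schedule optional [FrameSchedule].
#' @param tStar minutes; earliest mid-time included (default 10).
#' @return a [KineticFit] with `params["K"]`, `params["V"]` and OLS
#'   diagnostics in `details`.
#' @export
patlakFit <- function(tac, aif, schedule = NULL, tStar = 10) {
  stopifnot(is(tac, "Curve"))
  if (is.null(schedule)) schedule <- schedule(tac)
  tmid <- midTimes(schedule)
  if (is(aif, "AifParams")) {
    aifVal <- evalAif(aif, tmid)
    aifInt <- cumAif(aif, tmid)
    aifObj <- aif
  } else if (is(aif, "Curve")) {
    aifVal <- activity(aif)
    dt <- durations(schedule(aif)) / 60
    aifInt <- cumsum(pmax(aifVal, 0) * dt) - pmax(aifVal, 0) * dt / 2
    aifObj <- aifParams(0, 1, .5, .25, 3, 2, 1)   # placeholder, not used
  } else stop("aif must be AifParams or Curve")
  sel <- which(tmid >= tStar)
  if (length(sel) < 3L) stop("need at least 3 frames with mid-time >= tStar")
  if (any(aifVal[sel] <= 0)) stop("AIF must be positive on included frames")
  x <- aifInt[sel] / aifVal[sel]
  y <- activity(tac)[sel] / aifVal[sel]
  fit <- lm.fit(cbind(1, x), y)
  K <- unname(coef(fit)[2])
  V <- unname(coef(fit)[1])
  p <- c(K = K, V = V)
  new("KineticFit", modelId = "patlak", params = p, wrss = sum(fit$residuals^2),
      kflux = K, aif = aifObj, schedule = schedule,
      details = list(framesUsed = sel, tStar = tStar, x = x, y = y,
                     residuals = fit$residuals,
                     r.squared = if (var(y) > 0) 1 - var(fit$residuals) / var(y) else NA_real_))
}

#' Flux-constant of a fitted model
#'
#' Recomputes k_flux from a [KineticFit]: the closed micro-parameter form
#' for irreversible compartment models, the Patlak slope, or the
#' operational \eqn{K_1 R(T_{scan})} for 2C4K and spline fits.
#'
#' @param fit a [KineticFit].
#' @param schedule optional [FrameSchedule] setting \eqn{T_{scan}};
#'   defaults to the fit's.
#' @return k_flux in min^-1.
#' @export
fluxConstantOfFit <- function(fit, schedule = NULL) {
  stopifnot(is(fit, "KineticFit"))
  ts <- tScan(if (is.null(schedule)) fit@schedule else schedule)
  if (fit@modelId == "spline") {
    K1 <- fit@details$K1
    return(K1 * evalSplineResidue(fit, ts))
  }
  fluxConstant(fit@modelId, fit@params, ts)
}

## Fitted frame-averaged curve of any KineticFit, for residual diagnostics.
fittedCurve <- function(fit) {
  if (fit@modelId == "patlak")
    stop("Patlak fits are linear in transformed coordinates; use details$residuals")
  if (fit@modelId == "spline") return(fit@details$fitted)
  fit@details$fitted
}
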