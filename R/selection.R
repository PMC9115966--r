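#' @include fit-spline.R
NULL

## Refit a model with one frame excluded, warm-started from the full fit.
refitWithoutFrame <- function(fit, tac, frame) {
  w <- fit@details$weights
  w$excluded[frame] <- TRUE
  w$weights[frame] <- NA_real_
  if (fit@modelId %in% COMPARTMENT_MODELS) {
    fitCompartment(fit@modelId, tac, fit@aif, fit@schedule, weights = w,
                   nStarts = 0L, start = fit@params)
  } else if (fit@modelId == "spline") {
    rows <- setdiff(fit@details$framesUsed, frame)
    sol <- solveSplineNnls(fit@details$design, activity(tac)[rows],
                           sqrt(w$weights[rows]), rows)
    f <- fit
    f@details$fitted <- sol$fittedAll
    f
  } else stop("leave-one-out refits are defined for fitted curve models")
}

#' Leave-one-frame-out cross-validation score
#'
#' For each post-injection frame in turn, the model is refitted without
#' that frame (warm-started from the full-data optimum) and the held-out
#' frame predicted; the score accumulates the frame-weighted squared
#' prediction errors \eqn{\sum_i w_i (pred_i - obs_i)^2}, with the weights
#' of the full data. A frame whose refit fails is skipped and reported, and
#' the score flagged partial.
#'
#' @param modelId "2C3K", "2C4K", "3C5K" or "spline".
#' @param tac a [Curve].
#' @param aifParams an [AifParams].
#' @param schedule optional [FrameSchedule].
#' @param knotConfig spline models only; see [splineKnots()].
#' @param ... passed to the underlying fit (e.g. `seed`, `nStarts`).
#' @return a list: `score`, `perFrame` (named vector of weighted squared
#'   errors), `partial`, `failedFrames`, `fit` (the full-data fit).
#' @export
loocvScore <- function(modelId, tac, aifParams, schedule = NULL,
                       knotConfig = NULL, ...) {
  stopifnot(is(tac, "Curve"))
  if (is.null(schedule)) schedule <- schedule(tac)
  fit <- if (modelId == "spline")
    fitSplineResidue(tac, aifParams, schedule, knotConfig = knotConfig)
  else fitCompartment(modelId, tac, aifParams, schedule, ...)
  frames <- fit@details$framesUsed
  if (length(frames) <= length(fit@params) + 1L)
    stop("need more frames than parameters plus one")
  act <- activity(tac)
  w <- fit@details$weights$weights
  perFrame <- setNames(rep(NA_real_, length(frames)), frames)
  failed <- integer()
  for (i in frames) {
    rf <- tryCatch(refitWithoutFrame(fit, tac, i), error = function(e) NULL)
    if (is.null(rf)) { failed <- c(failed, i); next }
    pred <- rf@details$fitted[i]
    perFrame[as.character(i)] <- w[i] * (pred - act[i])^2
  }
  list(score = sum(perFrame, na.rm = TRUE), perFrame = perFrame,
       partial = length(failed) > 0L, failedFrames = failed, fit = fit)
}

## Exact conditional distribution of the number of runs given the class
## sizes (classic combinatorial form).
runsDistribution <- function(n1, n2) {
  n <- n1 + n2
  rmax <- 2L * min(n1, n2) + as.integer(n1 != n2)
  rs <- 2:rmax
  pr <- vapply(rs, function(r) {
    if (r %% 2 == 0) {
      k <- r / 2
      2 * choose(n1 - 1, k - 1) * choose(n2 - 1, k - 1) / choose(n, n1)
    } else {
      k <- (r - 1) / 2
      (choose(n1 - 1, k) * choose(n2 - 1, k - 1) +
         choose(n1 - 1, k - 1) * choose(n2 - 1, k)) / choose(n, n1)
    }
  }, 1)
  setNames(pr, rs)
}

#' Wald-Wolfowitz runs test on residual signs
#'
#' Tests for serial structure in fit residuals: signs are taken against
#' zero (exact zeros dropped), the number of sign runs counted, and a
#' two-sided p-value computed from the exact conditional runs
#' distribution for small samples (total n <= `exactLimit`) or the
#' continuity-corrected normal approximation beyond. The z-score of the
#' normal approximation is always reported.
#'
#' @param residuals numeric residual vector, in time order.
#' @param exactLimit largest sample size for which the exact conditional
#'   distribution is used (default 50).
#' @return a list: `nRuns`, `z`, `p`, `n1`, `n2` (positive/negative
#'   counts), `method` ("exact" or "normal"). `p` is `NA` when either
#'   sign class is empty.
#' @examples
#' runsTest(c(1, -1, 1, -1, 1, -1))$nRuns  # 6, maximal alternation
#' @export
runsTest <- function(residuals, exactLimit = 50L) {
  s <- sign(residuals)
  s <- s[s != 0]
  if (length(s) < 2L) stop("need at least 2 nonzero residuals")
  n1 <- sum(s > 0)
  n2 <- sum(s < 0)
  r <- 1L + sum(diff(s) != 0)
  n <- n1 + n2
  if (n1 == 0L || n2 == 0L)
    return(list(nRuns = r, z = NA_real_, p = NA_real_, n1 = n1, n2 = n2,
                method = "degenerate"))
  mu <- 2 * n1 * n2 / n + 1
  s2 <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  z <- if (s2 > 0) {
    d <- r - mu
    sign(d) * max(0, abs(d) - 0.5) / sqrt(s2)
  } else 0
  if (n <= exactLimit) {
    pr <- runsDistribution(n1, n2)
    rs <- as.integer(names(pr))
    p <- min(1, 2 * min(sum(pr[rs <= r]), sum(pr[rs >= r])))
    method <- "exact"
  } else {
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  list(nRuns = r, z = z, p = p, n1 = n1, n2 = n2, method = method)
}

#' Profile bounds of a weighted least-squares objective
#'
#' Generic profile-likelihood machinery: for each requested parameter the
#' scaled objective \eqn{s \cdot WSS(\theta)} is profiled (all other
#' parameters re-optimised at each step, warm-started) and the 1-SD bounds
#' reported where the profile rises `threshold` (default 1.0, the
#' chi-square 1-dof convention) above its minimum. Profiles that reach a
#' box bound before crossing are censored there and flagged.
#'
#' @param residFun function(theta) returning the weighted residual vector
#'   (so WSS = sum of its squares).
#' @param par named optimum parameter vector.
#' @param lower,upper box bounds aligned with `par`.
#' @param scale the sum-of-squares scale factor s (degrees of freedom of
#'   the best model's fit divided by that fit's WSS).
#' @param whichPar names of parameters to profile (default all).
#' @param threshold rise of the scaled objective defining the bound.
#' @param maxSteps marching steps per side.
#' @return a data.frame: parameter, estimate, lower, upper, halfWidth,
#'   lowerCensored, upperCensored.
#' @export
profileBounds <- function(residFun, par, lower, upper, scale,
                          whichPar = names(par), threshold = 1,
                          maxSteps = 14L) {
  stopifnot(length(par) == length(lower), length(par) == length(upper),
            !is.null(names(par)))
  wss <- function(th) sum(residFun(th)^2)
  F0 <- scale * wss(par)
  target <- F0 + threshold

  profiledWss <- function(k, val, warm) {
    free <- setdiff(seq_along(par), k)
    if (!length(free)) return(list(F = scale * wss(replace(par, k, val)),
                                   par = replace(par, k, val)))
    fn <- function(thFree) {
      th <- par
      th[free] <- thFree
      th[k] <- val
      residFun(th)
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(warm[free], lower = lower[free], upper = upper[free],
                         fn = fn,
                         control = minpack.lm::nls.lm.control(maxiter = 80)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    th <- par
    th[free] <- fit$par
    th[k] <- val
    list(F = scale * sum(fit$fvec^2), par = th)
  }

  oneSide <- function(k, dir) {
    est <- unname(par[k])
    span <- upper[k] - lower[k]
    step <- max(abs(est) * 0.08, ifelse(is.finite(span), span, 1) * 0.005)
    prevVal <- est
    prevF <- F0
    warm <- par
    for (s_ in seq_len(maxSteps)) {
      val <- est + dir * step * 2^(s_ - 1)
      censored <- FALSE
      if (val <= lower[k]) { val <- lower[k]; censored <- TRUE }
      if (val >= upper[k]) { val <- upper[k]; censored <- TRUE }
      pr <- profiledWss(k, val, warm)
      if (is.null(pr)) return(c(bound = NA_real_, censored = 1))
      if (pr$F >= target) {
        ## bracketed: refine the crossing. The profile is locally
        ## quadratic in the parameter, so interpolate on the sqrt scale
        ## and polish with a few re-optimised evaluations.
        lo <- prevVal; Flo <- prevF
        hi <- val; Fhi <- pr$F
        for (it in seq_len(8L)) {
          frac <- sqrt(max(target - Flo, 0) / max(Fhi - Flo, 1e-12))
          mid <- lo + max(min(frac, 0.95), 0.05) * (hi - lo)
          pm <- profiledWss(k, mid, warm)
          if (is.null(pm)) break
          if (abs(pm$F - target) < 0.01) return(c(bound = unname(mid),
                                                  censored = 0))
          if (pm$F < target) { lo <- mid; Flo <- pm$F; warm <- pm$par }
          else { hi <- mid; Fhi <- pm$F }
        }
        frac <- sqrt(max(target - Flo, 0) / max(Fhi - Flo, 1e-12))
        return(c(bound = unname(lo + frac * (hi - lo)), censored = 0))
      }
      if (censored) return(c(bound = val, censored = 1))
      warm <- pr$par
      prevVal <- val
      prevF <- pr$F
    }
    c(bound = prevVal, censored = 1)
  }

  rows <- lapply(whichPar, function(nm) {
    k <- match(nm, names(par))
    lo <- oneSide(k, -1)
    hi <- oneSide(k, +1)
    data.frame(parameter = nm, estimate = unname(par[k]),
               lower = unname(lo["bound"]), upper = unname(hi["bound"]),
               halfWidth = unname((hi["bound"] - lo["bound"]) / 2),
               lowerCensored = lo["censored"] > 0,
               upperCensored = hi["censored"] > 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Profile-likelihood uncertainties of a compartment fit
#'
#' Applies [profileBounds()] to a fitted compartment model, scaling the
#' weighted sum-of-squares by `scale` = dof/WSS of the best model's fit
#' (by default this fit's own: dof = usable post-injection frames minus
#' number of parameters). For the 2C3K model the derived flux-constant can
#' be profiled directly via the reparameterisation
#' \eqn{(k_{flux}, k_2, k_3, V_b)}, \eqn{K_1 = k_{flux}(k_2+k_3)/k_3}.
#'
#' @param fit a compartment [KineticFit].
#' @param tac the fitted [Curve].
#' @param parameters which parameters to profile; default all
#'   micro-parameters, plus `"kflux"` for 2C3K fits.
#' @param scale optional externally supplied scale factor s (from the
#'   cohort's best model); default dof/WSS of this fit.
#' @param threshold profile rise defining a 1-SD bound.
#' @return the [profileBounds()] table.
#' @export
profileUncertainty <- function(fit, tac, parameters = NULL, scale = NULL,
                               threshold = 1) {
  stopifnot(is(fit, "KineticFit"))
  if (!fit@modelId %in% COMPARTMENT_MODELS)
    stop("profile uncertainties are provided for compartment-model fits")
  use <- fit@details$framesUsed
  w <- fit@details$weights$weights
  act <- activity(tac)
  sw <- sqrt(w[use])
  if (is.null(scale)) {
    dof <- length(use) - length(fit@params)
    scale <- dof / fit@wrss
  }
  evalTac <- makeTacEvaluator(fit@modelId, fit@aif, fit@schedule)
  nm <- modelParamNames(fit@modelId)
  if (is.null(parameters))
    parameters <- if (fit@modelId == "2C3K") c(nm, "kflux") else nm

  out <- list()
  plain <- intersect(parameters, nm)
  if (length(plain)) {
    residFun <- function(th) sw * (evalTac(th)[use] - act[use])
    lower <- setNames(rep(0, length(nm)), nm)
    upper <- setNames(rep(RATE_BOUND, length(nm)), nm)
    upper["Vb"] <- VB_BOUND
    out$plain <- profileBounds(residFun, fit@params, lower, upper, scale,
                               whichPar = plain, threshold = threshold)
  }
  if ("kflux" %in% parameters) {
    if (fit@modelId != "2C3K")
      stop("direct kflux profiling is implemented for the 2C3K model")
    ## theta = (kflux, k2, k3, Vb); K1 = kflux (k2 + k3) / k3
    toNatural <- function(th) c(K1 = unname(th["kflux"] *
                                  (th["k2"] + th["k3"]) / max(th["k3"], 1e-8)),
                                th[c("k2", "k3", "Vb")])
    residFun <- function(th) sw * (evalTac(toNatural(th))[use] - act[use])
    p0 <- c(kflux = unname(fit@kflux), fit@params[c("k2", "k3", "Vb")])
    lower <- c(kflux = 0, k2 = 0, k3 = 1e-6, Vb = 0)
    upper <- c(kflux = RATE_BOUND, k2 = RATE_BOUND, k3 = RATE_BOUND,
               Vb = VB_BOUND)
    out$kflux <- profileBounds(residFun, p0, lower, upper, scale,
                               whichPar = "kflux", threshold = threshold)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[match(parameters, res$parameter), , drop = FALSE]
}

#' Cohort summary of profile uncertainties
#'
#' Root-mean-square 1-SD half-width per parameter expressed as a
#' percentage of the cohort mean parameter estimate.
#'
#' @param tables list of [profileUncertainty()] tables (one per patient).
#' @return data.frame: parameter, rmsHalfWidth, meanEstimate, pctOfMean.
#' @export
uncertaintySummary <- function(tables) {
  all_ <- do.call(rbind, tables)
  out <- do.call(rbind, lapply(split(all_, all_$parameter), function(d) {
    data.frame(parameter = d$parameter[1],
               rmsHalfWidth = sqrt(mean(d$halfWidth^2, na.rm = TRUE)),
               meanEstimate = mean(d$estimate))
  }))
  out$pctOfMean <- 100 * out$rmsHalfWidth / abs(out$meanEstimate)
  rownames(out) <- NULL
  out
}
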