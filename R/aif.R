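#' @include AllClasses.R AllGenerics.R schedule.R utils.R
NULL

#' Construct three-exponential AIF parameters
#'
#' @param delay appearance delay, minutes.
#' @param A1 ramp amplitude, kBq mL^-1 min^-1.
#' @param A2,A3 washout amplitudes, kBq/mL.
#' @param mu1,mu2,mu3 decay rates, min^-1, with `mu1 > mu2 > mu3 > 0`.
#' @return an [AifParams].
#' @examples
#' aifParams(0.4, 400, 6, 3, 4, 0.12, 0.01)
#' @export
aifParams <- function(delay, A1, A2, A3, mu1, mu2, mu3) {
  new("AifParams", delay = unname(as.numeric(delay)),
      A1 = unname(as.numeric(A1)), A2 = unname(as.numeric(A2)),
      A3 = unname(as.numeric(A3)), mu1 = unname(as.numeric(mu1)),
      mu2 = unname(as.numeric(mu2)), mu3 = unname(as.numeric(mu3)))
}

#' Construct a sampled curve
#'
#' @param schedule a [FrameSchedule].
#' @param activity numeric activity concentrations (kBq/mL), one per frame.
#' @param label optional curve label.
#' @return a [Curve].
#' @export
Curve <- function(schedule, activity, label = "curve") {
  new("Curve", schedule = schedule, activity = as.numeric(activity),
      label = label)
}

## Amplitude/rate decomposition of the Feng-type AIF into four
## exponential-family terms: A1*u*exp(-mu1 u) + B1*exp(-mu1 u)
## + A2*exp(-mu2 u) + A3*exp(-mu3 u) with B1 = -(A2+A3).
aifBasis <- function(p) {
  list(ramp = c(amp = p@A1, mu = p@mu1),
       exps = cbind(amp = c(-(p@A2 + p@A3), p@A2, p@A3),
                    mu = c(p@mu1, p@mu2, p@mu3)))
}

#' Evaluate an AIF analytically
#'
#' Vectorised pointwise evaluation; zero at and before the delay.
#'
#' @param params an [AifParams].
#' @param times numeric, minutes post-injection.
#' @return concentrations, kBq/mL.
#' @export
evalAif <- function(params, times) {
  stopifnot(is(params, "AifParams"))
  u <- times - params@delay
  pos <- u > 0
  out <- numeric(length(u))
  if (any(pos)) {
    up <- u[pos]
    out[pos] <- (params@A1 * up - params@A2 - params@A3) * exp(-params@mu1 * up) +
      params@A2 * exp(-params@mu2 * up) + params@A3 * exp(-params@mu3 * up)
  }
  out
}

## Stable kernels: h1 = (1 - exp(-d u))/d -> u, h2 = (exp(-d u) - 1 + d u)/d^2
## -> u^2/2 as d -> 0. Used to build exponential convolutions without
## cancellation when rates nearly coincide.
.h1 <- function(d, u) {
  x <- d * u
  small <- abs(x) < 1e-6
  out <- numeric(length(u))
  out[small] <- u[small] * (1 - x[small] / 2 + x[small]^2 / 6)
  if (any(!small)) out[!small] <- -expm1(-x[!small]) / d
  out
}
.h2 <- function(d, u) {
  x <- d * u
  small <- abs(x) < 1e-4
  out <- numeric(length(u))
  out[small] <- u[small]^2 / 2 * (1 - x[small] / 3 + x[small]^2 / 12)
  if (any(!small)) out[!small] <- (expm1(-x[!small]) + x[!small]) / d^2
  out
}
## g2 = (1 - (1 + d u) exp(-d u))/d^2 -> u^2/2; companion of .h2 for the
## opposite factoring of the ramp convolution (d >= 0 only).
.g2 <- function(d, u) {
  x <- d * u
  small <- abs(x) < 1e-4
  out <- numeric(length(u))
  out[small] <- u[small]^2 * (0.5 - x[small] / 3 + x[small]^2 / 8)
  if (any(!small)) out[!small] <- (1 - (1 + x[!small]) * exp(-x[!small])) / d^2
  out
}

#' Analytic convolution of an AIF with a decaying exponential
#'
#' Computes \eqn{\int_0^t AIF(s) e^{-\beta (t - s)} ds} in closed form
#' (\eqn{\beta = 0} yields the running integral of the AIF). Internal
#' workhorse for compartment-model TACs and the Patlak abscissa.
#' @noRd
convAifExp <- function(params, beta, times) {
  u <- times - params@delay
  pos <- u > 0
  out <- numeric(length(u))
  if (!any(pos)) return(out)
  up <- u[pos]
  b <- aifBasis(params)
  ## factorings chosen so every exponential argument is non-positive,
  ## keeping the closed forms finite at arbitrarily late times
  muR <- unname(b$ramp["mu"])
  acc <- b$ramp["amp"] * (if (beta >= muR)
    exp(-muR * up) * .h2(beta - muR, up)
  else exp(-beta * up) * .g2(muR - beta, up))
  for (k in seq_len(nrow(b$exps))) {
    mu <- b$exps[k, "mu"]
    acc <- acc + b$exps[k, "amp"] *
      exp(-pmin(mu, beta) * up) * .h1(abs(beta - mu), up)
  }
  out[pos] <- acc
  out
}

#' Running integral of an AIF
#'
#' \eqn{\int_0^t AIF(s) ds} in closed form; the Patlak normalised-time
#' numerator.
#' @param params an [AifParams].
#' @param times minutes post-injection.
#' @export
cumAif <- function(params, times) convAifExp(params, 0, times)

#' Simulate a frame-averaged AIF curve
#'
#' Frame averages of the analytic AIF over a schedule, plus optional iid
#' Gaussian noise.
#'
#' @param params an [AifParams].
#' @param schedule a [FrameSchedule].
#' @param seed RNG seed (NULL leaves the RNG stream untouched).
#' @param noiseSd Gaussian noise sd, kBq/mL; must be non-negative.
#' @return a [Curve] labelled "aif".
#' @export
simulateAif <- function(params, schedule, seed = NULL, noiseSd = 0) {
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  a <- frameAverage(function(t) evalAif(params, t), schedule)
  if (noiseSd > 0)
    a <- a + withLocalSeed(seed, rnorm(length(a), 0, noiseSd))
  Curve(schedule, a, "aif")
}

## Multi-start initial grid for the AIF fit: rate decades crossed with
## data-driven amplitude guesses.
aifStartGrid <- function(times, activities) {
  peakA <- max(activities)
  tail_ <- activities[which.max(times)]
  grid <- expand.grid(mu1 = c(1, 4, 12), mu2 = c(0.05, 0.12, 0.4),
                      mu3 = c(0.003, 0.01, 0.03))
  riseIdx <- which(activities > 0.05 * peakA)
  delay0 <- if (length(riseIdx)) max(0, min(times[riseIdx]) - 0.1) else 0.3
  lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    c(delay = min(delay0, 1.9), A1 = peakA * g$mu1 * exp(1),
      A2 = max(peakA * 0.1, 1e-3), A3 = max(tail_, 1e-3),
      mu3 = g$mu3, d2 = g$mu2 - g$mu3, d1 = g$mu1 - g$mu2)
  })
}

#' Fit the three-exponential model to an AIF
#'
#' Weighted least squares with the frame-duration/decay weighting scheme,
#' over post-injection frames with positive activity. Rate ordering
#' \eqn{\mu_1 > \mu_2 > \mu_3 > 0} is enforced by fitting positive rate
#' gaps; a 3 x 3 x 3 multi-start grid over rate decades guards against
#' local minima, the lowest weighted RSS winning (ties to the earliest
#' start).
#'
#' @param aifCurve a [Curve] of AIF samples.
#' @param schedule optional [FrameSchedule]; defaults to the curve's.
#' @param decayConstant min^-1; weight decay factor.
#' @param delayBounds delay search interval, minutes.
#' @return a list: `params` ([AifParams]), `wrss`, `weights`, `nStarts`,
#'   `converged`.
#' @export
fitAif <- function(aifCurve, schedule = NULL,
                   decayConstant = F18_DECAY_CONSTANT,
                   delayBounds = c(0, 2)) {
  stopifnot(is(aifCurve, "Curve"))
  if (is.null(schedule)) schedule <- schedule(aifCurve)
  act <- activity(aifCurve)
  wts <- computeWeights(schedule, act, decayConstant)
  use <- !wts$excluded & midTimes(schedule) > 0
  if (sum(use) < 7L)
    stop("need at least 7 post-injection frames with positive activity")
  tmid <- midTimes(schedule)[use]
  y <- act[use]
  sw <- sqrt(wts$weights[use])
  g <- frameGrid(schedule)

  resid_ <- function(th) {
    p <- aifParams(th[1], th[2], th[3], th[4],
                   th[5] + th[6] + th[7], th[5] + th[6], th[5])
    m <- frameAverageValues(matrix(evalAif(p, as.numeric(g$times)),
                                   nrow = g$nsub), g)[use]
    sw * (m - y)
  }
  lower <- c(delayBounds[1], 0, 0, 0, 1e-5, 1e-4, 1e-4)
  upper <- c(delayBounds[2], Inf, Inf, Inf, 1, 5, 50)

  best <- NULL
  for (st in aifStartGrid(tmid, y)) {
    st <- pmin(pmax(st, lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(st, lower = lower, upper = upper, fn = resid_,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("AIF fit failed to converge from every start")
  th <- best$fit$par
  list(params = aifParams(th[1], th[2], th[3], th[4],
                          th[5] + th[6] + th[7], th[5] + th[6], th[5]),
       wrss = best$rss, weights = wts, nStarts = 27L,
       converged = best$fit$info %in% 1:4)
}

#' Read and write curve tables
#'
#' TSV dialect: columns `frame_index`, `duration_s`, `mid_time_min`,
#' `concentration_kBq_per_mL`.
#'
#' @param curve a [Curve].
#' @param path file path.
#' @param injectionOffset seconds; needed to rebuild the schedule on read.
#' @return `writeCurve()` the path, invisibly; `readCurve()` a [Curve].
#' @name curve-io
NULL

#' @rdname curve-io
#' @export
writeCurve <- function(curve, path) {
  writeTsv(data.frame(frame_index = seq_along(activity(curve)),
                      duration_s = durations(curve),
                      mid_time_min = midTimes(curve),
                      concentration_kBq_per_mL = activity(curve)), path)
  invisible(path)
}

#' @rdname curve-io
#' @export
readCurve <- function(path, injectionOffset = NULL) {
  d <- readTsv(path)
  need <- c("frame_index", "duration_s", "mid_time_min",
            "concentration_kBq_per_mL")
  if (!all(need %in% names(d)))
    stop("curve table must have columns: ", paste(need, collapse = ", "))
  d <- d[order(d$frame_index), , drop = FALSE]
  if (is.null(injectionOffset)) {
    ## recover the offset from the first frame's timing
    injectionOffset <- -(d$mid_time_min[1] * 60 - d$duration_s[1] / 2)
  }
  s <- frameSchedule(d$duration_s, injectionOffset)
  Curve(s, d$concentration_kBq_per_mL, "curve")
}
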