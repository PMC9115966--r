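#' @include fit-compartment.R
NULL

#' Spline-residue knot configuration
#'
#' Cubic B-spline residue basis on `[0, tMax]` with `nInterior` interior
#' knots geometrically spaced on `(0, tMax]` (default 6, spanning
#' `[tLo, tMax)`), clamped at both ends.
#'
#' @param nInterior number of interior knots.
#' @param tMax right boundary, minutes (normally \eqn{T_{scan}}).
#' @param tLo left end of the geometric interior-knot span, minutes.
#' @param interior optional explicit interior knots overriding the
#'   geometric rule.
#' @return a list with the full clamped knot vector and basis size.
#' @export
splineKnots <- function(nInterior = 6L, tMax = 45, tLo = 0.5,
                        interior = NULL) {
  if (is.null(interior)) {
    interior <- exp(seq(log(tLo), log(tMax), length.out = nInterior + 1L))
    interior <- interior[seq_len(nInterior)]
  }
  interior <- sort(as.numeric(interior))
  if (any(interior <= 0) || any(interior >= tMax))
    stop("interior knots must lie strictly inside (0, tMax)")
  list(knots = c(rep(0, 4), interior, rep(tMax, 4)),
       nBasis = length(interior) + 4L, tMax = tMax)
}

## Frame-averaged convolution columns conv(AIF, B_b)(t) for every basis
## function, computed by FFT convolution on a half-second grid plus a
## trapezoid endpoint correction, then Simpson-averaged over frames.
splineDesignColumns <- function(aifParams, schedule, knotConfig,
                                dtSec = 0.5) {
  tMax <- knotConfig$tMax
  dt <- dtSec / 60
  grid <- seq(0, tMax, by = dt)
  n <- length(grid)
  a <- evalAif(aifParams, grid)
  B <- splines::splineDesign(knotConfig$knots, grid, ord = 4L)
  conv <- matrix(0, n, ncol(B))
  for (b in seq_len(ncol(B))) {
    r <- stats::convolve(a, rev(B[, b]), type = "open")[seq_len(n)]
    conv[, b] <- (r - a * B[1, b] / 2) * dt
  }
  g <- frameGrid(schedule)
  tt <- pmin(pmax(as.numeric(g$times), 0), tMax)
  frameCols <- vapply(seq_len(ncol(B)), function(b) {
    v <- approx(grid, conv[, b], xout = tt, rule = 2)$y
    frameAverageValues(matrix(v, nrow = g$nsub), g)
  }, numeric(g$nframes))
  aifCol <- frameAverageValues(matrix(evalAif(aifParams, as.numeric(g$times)),
                                      nrow = g$nsub), g)
  ## cumulative columns implement the non-increasing-coefficient
  ## reparameterisation gamma_b = sum_{m >= b} d_m
  cumCols <- t(apply(frameCols, 1L, cumsum))
  list(cumCols = cumCols, aifCol = aifCol)
}

## Core solver shared by the fit and leave-one-out refits: non-negative
## least squares in (d_1..d_nb, Vb) on the selected frames.
solveSplineNnls <- function(design, y, sw, rows) {
  A <- cbind(design$cumCols[rows, , drop = FALSE], design$aifCol[rows])
  Aw <- A * sw
  yw <- y * sw
  sol <- pracma::lsqnonneg(Aw, yw)
  x <- sol$x
  nb <- ncol(A) - 1L
  if (x[nb + 1L] > VB_BOUND) {
    ## Vb hit its physiological cap: fix it and re-solve the rest
    yw2 <- yw - VB_BOUND * design$aifCol[rows] * sw
    sol2 <- pracma::lsqnonneg(Aw[, seq_len(nb), drop = FALSE], yw2)
    x <- c(sol2$x, VB_BOUND)
  }
  d <- x[seq_len(nb)]
  vb <- x[nb + 1L]
  fittedAll <- as.numeric(cbind(design$cumCols, design$aifCol) %*% x)
  list(d = d, vb = vb, fittedAll = fittedAll,
       wrss = sum(((fittedAll[rows] - y) * sw)^2))
}

#' Fit the nonparametric spline-residue model
#'
#' Fits \eqn{TAC(t) = K_1 \int AIF(s) R(t-s) ds + V_b AIF(t)} with
#' \eqn{R(t)} a clamped cubic B-spline expansion constrained to
#' \eqn{R(0)=1}, \eqn{R' \le 0}, \eqn{R \ge 0}. The constraints are
#' imposed through non-increasing, non-negative B-spline coefficients (a
#' sufficient shape condition), which turns the weighted fit into an
#' exact non-negative least-squares problem in the coefficient increments
#' and \eqn{V_b}; \eqn{K_1} is recovered as the leading coefficient.
#'
#' @param tac a [Curve] of tumour samples.
#' @param aifParams an [AifParams].
#' @param schedule optional [FrameSchedule].
#' @param knotConfig a [splineKnots()] configuration; defaults to 6
#'   geometric interior knots on the scan span.
#' @param weights optional precomputed [computeWeights()] result.
#' @param decayConstant min^-1 for the weight formula.
#' @return a [KineticFit] with `modelId "spline"`, `params["K1"]`,
#'   `params["Vb"]`, spline coefficients in `details` and
#'   k_flux = \eqn{K_1 R(T_{scan})}.
#' @export
fitSplineResidue <- function(tac, aifParams, schedule = NULL,
                             knotConfig = NULL, weights = NULL,
                             decayConstant = F18_DECAY_CONSTANT) {
  stopifnot(is(tac, "Curve"))
  if (is.null(schedule)) schedule <- schedule(tac)
  if (is.null(knotConfig)) knotConfig <- splineKnots(tMax = tScan(schedule))
  act <- activity(tac)
  if (is.null(weights)) weights <- computeWeights(schedule, act, decayConstant)
  use <- which(!weights$excluded & midTimes(schedule) > 0)
  if (length(use) <= knotConfig$nBasis + 1L)
    stop("need more usable frames than free parameters")
  design <- splineDesignColumns(aifParams, schedule, knotConfig)
  sol <- solveSplineNnls(design, act[use], sqrt(weights$weights[use]), use)
  gamma <- rev(cumsum(rev(sol$d)))
  K1 <- sum(sol$d)
  ts <- tScan(schedule)
  Bts <- splines::splineDesign(knotConfig$knots, min(ts, knotConfig$tMax),
                               ord = 4L)
  kflux <- as.numeric(Bts %*% gamma)
  p <- c(K1 = K1, Vb = sol$vb)
  new("KineticFit", modelId = "spline", params = p, wrss = sol$wrss,
      kflux = kflux, aif = aifParams, schedule = schedule,
      details = list(knotConfig = knotConfig, gamma = gamma, K1 = K1,
                     design = design, framesUsed = use, weights = weights,
                     fitted = sol$fittedAll))
}

#' Evaluate the residue function of a spline fit
#'
#' @param fit a spline [KineticFit].
#' @param times minutes; values beyond the basis support are clamped.
#' @return R(t) values (1 at t = 0 when K1 > 0).
#' @export
evalSplineResidue <- function(fit, times) {
  stopifnot(is(fit, "KineticFit"), fit@modelId == "spline")
  kc <- fit@details$knotConfig
  tt <- pmin(pmax(times, 0), kc$tMax)
  B <- splines::splineDesign(kc$knots, tt, ord = 4L)
  K1 <- fit@details$K1
  if (K1 <= 0) return(rep(1, length(times)))
  as.numeric(B %*% fit@details$gamma) / K1
}
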