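test_that("compartment residue functions have the closed special forms", {
  t <- c(0, 0.5, 2, 10, 1e6)
  # no efflux, no transfer: everything entering stays
  expect_equal(residueFunction("2C3K", c(K1 = .1, k2 = 0, k3 = 0, Vb = 0), t),
               rep(1, 5))
  # single reversible compartment
  expect_equal(residueFunction("2C3K", c(K1 = .1, k2 = .3, k3 = 0, Vb = 0), t),
               exp(-0.3 * t))
  # asymptote k3/(k2+k3)
  expect_equal(residueFunction("2C3K", c(K1 = .1, k2 = .3, k3 = .1, Vb = 0),
                               1e6), 0.25)
  expect_error(residueFunction("2C3K", c(K1 = .1, k2 = -1, k3 = 0, Vb = 0), t),
               "non-negative")
})

test_that("closed-form flux-constants equal K1 R(inf) for random parameters", {
  set.seed(31)
  for (rep in 1:200) {
    p3 <- c(K1 = runif(1, .01, 1), k2 = runif(1, 0, 2), k3 = runif(1, 0, 2),
            Vb = runif(1, 0, .4))
    expect_equal(fluxConstant("2C3K", p3),
                 p3[["K1"]] * residueFunction("2C3K", p3, 1e4),
                 tolerance = 1e-6)
    p5 <- c(K1 = runif(1, .01, 1), k2 = runif(1, 0, 2), k3 = runif(1, 0, 2),
            k4 = runif(1, 0, 1), k5 = runif(1, 0, 1), Vb = runif(1, 0, .4))
    expect_equal(fluxConstant("3C5K", p5),
                 p5[["K1"]] * residueFunction("3C5K", p5, 1e4),
                 tolerance = 1e-6)
  }
  # formula limits
  expect_equal(fluxConstant("2C3K", c(K1 = .2, k2 = 0, k3 = .1, Vb = 0)), 0.2)
  expect_equal(fluxConstant("2C3K", c(K1 = .1, k2 = .3, k3 = .1, Vb = 0)),
               0.025)
})

test_that("model TACs reduce to Vb AIF at zero influx and wash out fully", {
  aif <- stdAif()
  s <- makePaperSchedule()
  tac <- modelTac("2C3K", c(K1 = 0, k2 = .3, k3 = .1, Vb = .2), aif, s)
  expect_equal(activity(tac), 0.2 * activity(simulateAif(aif, s)),
               tolerance = 1e-10)
  # fully reversible single compartment: late tissue signal decays
  late <- fluxgsea:::pointwiseTac("2C3K", c(K1 = .1, k2 = .5, k3 = 0, Vb = 0),
                                  aif, c(44, 500, 5000))
  expect_lt(late[3], late[1] * 1e-3)
})

test_that("analytic and quadrature convolution TACs agree to 1e-6", {
  aif <- stdAif()
  set.seed(17)
  for (rep in 1:5) {
    p <- c(K1 = runif(1, .05, .5), k2 = runif(1, .05, 1),
           k3 = runif(1, .01, .5), Vb = runif(1, 0, .3))
    ts <- c(1.2, 5, 20, 44.5)
    an <- fluxgsea:::pointwiseTac("2C3K", p, aif, ts)
    es <- fluxgsea:::residueExpSum("2C3K", p)
    nu <- vapply(ts, function(t) {
      tissue <- integrate(function(u) {
        R <- numeric(length(u))
        for (j in seq_along(es$beta))
          R <- R + es$coef[j] * exp(-es$beta[j] * (t - u))
        evalAif(aif, u) * R
      }, 0, t, rel.tol = 1e-10, subdivisions = 2000L)$value
      p[["K1"]] * tissue + p[["Vb"]] * evalAif(aif, t)
    }, 1)
    expect_equal(an, nu, tolerance = 1e-6)
  }
})

test_that("TAC noise is seeded and inverse-variance matched to the weights", {
  aif <- stdAif()
  s <- makePaperSchedule()
  pt <- stdParams2C3K()
  a <- simulateTac("2C3K", pt, aif, s, seed = 9, noiseScale = 1.5)
  b <- simulateTac("2C3K", pt, aif, s, seed = 9, noiseScale = 1.5)
  expect_identical(activity(a), activity(b))
  expect_error(simulateTac("2C3K", pt, aif, s, noiseScale = -1),
               "non-negative")
  # empirical frame variance proportional to 1/w_i
  noiseless <- activity(modelTac("2C3K", pt, aif, s))
  reps <- vapply(1:800, function(i)
    activity(simulateTac("2C3K", pt, aif, s, seed = i, noiseScale = 1.5)) -
      noiseless, numeric(40))
  v <- apply(reps, 1L, var)
  w <- computeWeights(s, noiseless)$weights
  ok <- !is.na(w)
  fit <- lm(v[ok] ~ I(1 / w[ok]))
  expect_gt(summary(fit)$r.squared, 0.9)
  expect_equal(unname(coef(fit)[2]), 1.5^2, tolerance = 0.15)
})

test_that("Patlak analysis recovers exact lines and closed-form flux", {
  aif <- stdAif()
  s <- makePaperSchedule()
  # synthetic exactly linear Patlak coordinates
  tm <- midTimes(s)
  av <- evalAif(aif, tm)
  K <- 0.031; V <- 0.4
  tacLin <- Curve(s, (K * cumAif(aif, tm) / pmax(av, 1e-12) + V) *
                    pmax(av, 0), "tac")
  pf <- patlakFit(tacLin, aif, s, tStar = 10)
  expect_equal(unname(kineticParams(pf)["K"]), K, tolerance = 1e-10)
  expect_lt(max(abs(pf@details$residuals)), 1e-10)
  # noiseless 2C3K: slope within 2% of K1 k3/(k2+k3)
  tac <- modelTac("2C3K", c(K1 = .1, k2 = .3, k3 = .1, Vb = 0), aif, s)
  pf2 <- patlakFit(tac, aif, s, tStar = 10)
  expect_equal(pf2@kflux, 0.025, tolerance = 0.02)
  # reversibility bends the plot: fitted K decreases with tStar
  tac4 <- modelTac("2C4K", c(K1 = .1, k2 = .3, k3 = .1, k4 = .05, Vb = 0),
                   aif, s)
  Ks <- vapply(c(8, 15, 25), function(ts)
    patlakFit(tac4, aif, s, tStar = ts)@kflux, 1)
  expect_true(all(diff(Ks) < 0))
  expect_error(patlakFit(tac, aif, s, tStar = 44), "at least 3")
})

test_that("compartment fitting recovers noiseless parameters within 1%", {
  aif <- stdAif()
  s <- makePaperSchedule()
  pt <- stdParams2C3K()
  tac <- modelTac("2C3K", pt, aif, s)
  fit <- fitCompartment("2C3K", tac, aif, s, seed = 1)
  expect_equal(kineticParams(fit), pt, tolerance = 0.01)
  expect_equal(fit@kflux, fluxConstant("2C3K", pt), tolerance = 0.01)
})

test_that("the reversible model nests the irreversible fit", {
  aif <- stdAif()
  s <- makePaperSchedule()
  tac <- simulateTac("2C3K", stdParams2C3K(), aif, s, seed = 4,
                     noiseScale = 1.5)
  f3 <- fitCompartment("2C3K", tac, aif, s, seed = 1)
  f4 <- fitCompartment("2C4K", tac, aif, s, seed = 1,
                       start = c(kineticParams(f3)[c("K1", "k2", "k3")],
                                 k4 = 0, Vb = kineticParams(f3)[["Vb"]]))
  expect_lte(wrss(f4), wrss(f3) + 1e-8)
})

test_that("rate constants are invariant to a common activity rescaling", {
  aif <- stdAif()
  s <- makePaperSchedule()
  tac <- simulateTac("2C3K", stdParams2C3K(), aif, s, seed = 6,
                     noiseScale = 1.5)
  f1 <- fitCompartment("2C3K", tac, aif, s, seed = 2)
  aif10 <- aifParams(aif@delay, aif@A1 * 10, aif@A2 * 10, aif@A3 * 10,
                     aif@mu1, aif@mu2, aif@mu3)
  tac10 <- Curve(s, activity(tac) * 10, "tac")
  f2 <- fitCompartment("2C3K", tac10, aif10, s, seed = 2)
  expect_equal(kineticParams(f1), kineticParams(f2), tolerance = 1e-4)
  p1 <- patlakFit(tac, aif, s)
  p2 <- patlakFit(tac10, aif10, s)
  expect_equal(p1@kflux, p2@kflux, tolerance = 1e-10)
})

test_that("the spline-residue fit is shape-constrained and near-exact", {
  aif <- stdAif()
  s <- makePaperSchedule()
  pt <- stdParams2C3K()
  tac <- modelTac("2C3K", pt, aif, s)
  fit <- fitSplineResidue(tac, aif, s)
  # flux from K1 R(Tscan) within 5% of the generating closed form
  expect_equal(fit@kflux, fluxConstant("2C3K", pt, tScan(s)),
               tolerance = 0.05)
  r <- evalSplineResidue(fit, seq(0, tScan(s), by = 0.25))
  expect_equal(r[1], 1)
  expect_true(all(diff(r) <= 1e-9))
  expect_true(all(r >= -1e-12))
})

test_that("richer spline knot grids never increase the weighted RSS", {
  aif <- stdAif()
  s <- makePaperSchedule()
  tac <- simulateTac("2C3K", stdParams2C3K(), aif, s, seed = 8,
                     noiseScale = 1.5)
  coarse <- splineKnots(tMax = tScan(s))
  finer <- splineKnots(tMax = tScan(s),
                       interior = sort(c(coarse$knots[5:10], 3, 16)))
  fC <- fitSplineResidue(tac, aif, s, coarse)
  fF <- fitSplineResidue(tac, aif, s, finer)
  expect_lte(wrss(fF), wrss(fC) + 1e-8)
})

test_that("static uptake measures follow the SUV and TBR definitions", {
  m <- staticMeasures(10, 5, 2, injectedDose = 1, bodyWeight = 1)
  expect_equal(unname(m["SUVmax"]), 10)
  expect_equal(unname(m["TBRmean"]), 2.5)
  # tumour concentration equal to dose/weight gives SUV 1
  expect_equal(unname(staticMeasures(3, 3, 1, 300, 100)["SUVmean"]), 1)
  # TBR is invariant to doubling all concentrations
  a <- staticMeasures(10, 5, 2, 100, 70)
  b <- staticMeasures(20, 10, 4, 100, 70)
  expect_equal(a[c("TBRmax", "TBRmean")], b[c("TBRmax", "TBRmean")])
  expect_error(staticMeasures(10, 5, 0, 100, 70), "positive")
})
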