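test_that("LOOCV of an identifiable model on noiseless data is ~ zero", {
  aif <- stdAif()
  s <- makePaperSchedule()
  tac <- modelTac("2C3K", stdParams2C3K(), aif, s)
  sc <- loocvScore("2C3K", tac, aif, s, seed = 1)
  w <- computeWeights(s, activity(tac))$weights
  energy <- sum(w * activity(tac)^2, na.rm = TRUE)
  expect_lt(sc$score / energy, 1e-8)
  expect_false(sc$partial)
})

test_that("LOOCV is invariant to the stored row order of the curve table", {
  aif <- stdAif()
  s <- makePaperSchedule()
  tac <- simulateTac("2C3K", stdParams2C3K(), aif, s, seed = 3,
                     noiseScale = 1.5)
  tf <- tempfile(fileext = ".tsv")
  writeCurve(tac, tf)
  d <- read.delim(tf)
  d <- d[rev(seq_len(nrow(d))), ]
  tf2 <- tempfile(fileext = ".tsv")
  write.table(d, tf2, sep = "\t", quote = FALSE, row.names = FALSE)
  s1 <- loocvScore("2C3K", readCurve(tf), aif, seed = 1)
  s2 <- loocvScore("2C3K", readCurve(tf2), aif, seed = 1)
  expect_equal(s1$score, s2$score)
})

test_that("the over-parameterised three-tissue model does not out-predict", {
  # on data generated by the simpler irreversible model, the box-bounded
  # 3C5K fit collapses onto the 2C3K solution, so its leave-one-frame-out
  # error is statistically indistinguishable (not substantially smaller)
  s <- makePaperSchedule()
  co <- simulateCohort(6, seed = 42)
  sc <- vapply(1:6, function(i) {
    tac <- co$curves[[i]]$tac
    c(loocvScore("2C3K", tac, co$aifParams[[i]], s, seed = 1)$score,
      loocvScore("3C5K", tac, co$aifParams[[i]], s, seed = 1)$score)
  }, numeric(2))
  expect_gte(median(sc[2, ]), 0.85 * median(sc[1, ]))
})

test_that("runs counting handles alternation, constancy and zeros", {
  expect_equal(runsTest(rep(c(1, -1), 5))$nRuns, 10L)
  allPos <- runsTest(rep(2, 6))
  expect_equal(allPos$nRuns, 1L)
  expect_true(is.na(allPos$p))
  # zero residuals are dropped before counting
  expect_equal(runsTest(c(1, 0, 1, -1, 0, -1, 1))$nRuns, 3L)
  expect_error(runsTest(c(0, 0, 1)), "at least 2")
})

test_that("runs-test p matches brute-force enumeration of sequences", {
  dist10 <- enumerateRunsDistribution(10L)
  runs <- dist10[["5_5"]]
  # two runs: all five positives then all five negatives
  res <- runsTest(c(rep(1, 5), rep(-1, 5)))
  expect_equal(res$nRuns, 2L)
  pOracle <- min(1, 2 * min(mean(runs <= 2), mean(runs >= 2)))
  expect_equal(res$p, pOracle, tolerance = 1e-12)
  # the reported z is the continuity-corrected normal score
  mu <- 2 * 25 / 10 + 1
  s2 <- 2 * 25 * (2 * 25 - 10) / (100 * 9)
  expect_equal(res$z, (2 - mu + 0.5) / sqrt(s2))
})

test_that("profile bounds reproduce closed-form linear-regression errors", {
  set.seed(7)
  x <- rnorm(25)
  X <- cbind(1, x)
  y <- X %*% c(2, 0.5) + rnorm(25, 0, 0.3)
  w <- runif(25, 0.5, 2)
  lmfit <- lm(y ~ x, weights = w)
  se <- summary(lmfit)$coefficients[, 2]
  residFun <- function(b) sqrt(w) * (X %*% b - y)
  bhat <- setNames(coef(lmfit), c("b0", "b1"))
  scale <- (25 - 2) / sum(residFun(bhat)^2)
  pb <- profileBounds(residFun, bhat, c(-10, -10), c(10, 10), scale)
  expect_equal(pb$halfWidth, unname(se), tolerance = 0.01)
  expect_false(any(pb$lowerCensored | pb$upperCensored))
})

test_that("rescaling all weights leaves profile bounds unchanged", {
  set.seed(8)
  x <- rnorm(15)
  y <- 1 + 0.3 * x + rnorm(15, 0, 0.2)
  residFun <- function(b) cbind(1, x) %*% b - y
  bhat <- setNames(coef(lm(y ~ x)), c("b0", "b1"))
  wss0 <- sum(residFun(bhat)^2)
  p1 <- profileBounds(residFun, bhat, c(-5, -5), c(5, 5), 13 / wss0)
  # doubling the weights doubles WSS; the dof/WSS scale factor halves and
  # the scaled objective (hence the bounds) is unchanged
  residFun2 <- function(b) sqrt(2) * residFun(b)
  p2 <- profileBounds(residFun2, bhat, c(-5, -5), c(5, 5), 13 / (2 * wss0))
  expect_equal(p1$lower, p2$lower, tolerance = 1e-6)
  expect_equal(p1$upper, p2$upper, tolerance = 1e-6)
})

test_that("flux-constant uncertainty is the tightest for the 2C3K model", {
  aif <- stdAif()
  s <- makePaperSchedule()
  pt <- stdParams2C3K()
  tabs <- lapply(1:4, function(i) {
    tac <- simulateTac("2C3K", pt, aif, s, seed = 40 + i, noiseScale = 1.5)
    fit <- fitCompartment("2C3K", tac, aif, s, seed = 1)
    profileUncertainty(fit, tac)
  })
  summ <- uncertaintySummary(tabs)
  pct <- setNames(summ$pctOfMean, summ$parameter)
  for (nm in c("K1", "k2", "k3", "Vb"))
    expect_lt(pct[["kflux"]], pct[[nm]])
})
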