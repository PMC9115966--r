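nullStudyFixture <- function(nPatients = 20, nGenes = 500, seed = 51) {
  set.seed(seed)
  meas <- rnorm(nPatients)
  spec <- expressionSpec(nGenes, nPatients, seed = seed + 1)
  ex <- simulateExpression(spec, list(m = meas))
  coll <- syntheticCollection(spec, nNullSets = 20, nullSetSize = 30,
                              seed = seed + 2)
  list(meas = meas, expr = ex$matrix, coll = coll, spec = spec)
}

test_that("the identity permutation reproduces the unpermuted analysis", {
  fx <- nullStudyFixture()
  direct <- gseaRun(fx$expr, fx$meas, fx$coll, nPerm = 300,
                    seed = fluxgsea:::deriveSeed(7, "fp1"))
  st <- permutedPhenotypeStudy(fx$expr, fx$meas, fx$coll, nDatasets = 1,
                               nPerm = 300, seed = 7,
                               identityPermutation = TRUE)
  expect_equal(st$counts[1], sum(direct$significant))
  expect_equal(unname(st$summary["median"]), st$counts[1])
})

test_that("the false-positive study is reproducible under its master seed", {
  fx <- nullStudyFixture()
  a <- permutedPhenotypeStudy(fx$expr, fx$meas, fx$coll, nDatasets = 4,
                              nPerm = 300, seed = 11)
  b <- permutedPhenotypeStudy(fx$expr, fx$meas, fx$coll, nDatasets = 4,
                              nPerm = 300, seed = 11)
  expect_identical(a$counts, b$counts)
  expect_true(all(a$counts >= 0 & a$counts <= length(fx$coll)))
})

test_that("bootstrap comparison degenerates cleanly and is seeded", {
  fx <- nullStudyFixture(nPatients = 15, nGenes = 300)
  mt <- data.frame(a = fx$meas, b = fx$meas)
  res <- bootstrapCountDifference(fx$expr, mt, fx$coll, "a", "b",
                                  nBoot = 3, nPerm = 200, seed = 5)
  expect_true(all(res$differences == 0))
  expect_true(res$degenerate)
  expect_true(is.na(res$p))
  res2 <- bootstrapCountDifference(fx$expr, mt, fx$coll, "a", "b",
                                   nBoot = 3, nPerm = 200, seed = 5)
  expect_identical(res$differences, res2$differences)
})

test_that("bootstrap comparison detects a one-sided planted design", {
  set.seed(61)
  n <- 24
  measA <- rnorm(n)
  measB <- rnorm(n)
  ids <- sprintf("G%05d", 1:500)
  spec <- expressionSpec(500, n,
                         planted = list(list(name = "ONLY_A",
                                             genes = ids[1:40], rho = 0.85,
                                             measure = "a")), seed = 62)
  ex <- simulateExpression(spec, list(a = measA, b = measB))
  coll <- syntheticCollection(spec, nNullSets = 12, nullSetSize = 40,
                              seed = 63)
  mt <- data.frame(a = measA, b = measB)
  res <- bootstrapCountDifference(ex$matrix, mt, coll, "a", "b",
                                  nBoot = 10, nPerm = 2000, seed = 64)
  expect_gt(mean(res$differences), 0)
  expect_lt(res$p, 0.05)
  # the point estimate can be perturbed by single false positives at this
  # deliberately liberal small-collection threshold
  expect_gte(res$observed, 0)
})

test_that("gene-by-measure correlation tables match direct recomputation", {
  set.seed(71)
  expr <- matrix(rnorm(5 * 8), 5, 8,
                 dimnames = list(paste0("g", 1:5), NULL))
  mt <- data.frame(m1 = rnorm(8), m2 = rnorm(8), m3 = rnorm(8))
  expr["g2", ] <- mt$m2                       # exact match to one measure
  tab <- correlationHeatmapTable(expr, mt, paste0("g", 1:5))
  expect_equal(dim(tab), c(5L, 3L))
  expect_equal(tab["g2", "m2"], 1)
  for (g in rownames(tab)) for (m in names(mt))
    expect_equal(tab[g, m], cor(expr[g, ], mt[[m]]), tolerance = 1e-12)
  # zero-variance genes excluded with a warning; unknown ids error
  expr["g4", ] <- 2
  expect_warning(t2 <- correlationHeatmapTable(expr, mt, paste0("g", 1:5)),
                 "zero-variance")
  expect_false("g4" %in% rownames(t2))
  expect_error(correlationHeatmapTable(expr, mt, "missing"), "missing")
  # low-expression filter
  e2 <- matrix(c(0.2, 5), 2, 4, byrow = FALSE,
               dimnames = list(c("lo", "hi"), NULL))
  expect_equal(rownames(filterLowExpression(e2, 1)), "hi")
})

test_that("the Wilcoxon comparison flags shifts and respects symmetry", {
  set.seed(81)
  a <- rnorm(20, 0, 0.1)
  ident <- wilcoxonCompare(a, a)
  expect_true(is.na(ident$p))
  b <- a + 0.2
  res <- wilcoxonCompare(b, a)
  expect_lt(res$p, 0.01)
  swapped <- wilcoxonCompare(a, b)
  expect_equal(res$p, swapped$p, tolerance = 1e-12)
  expect_error(wilcoxonCompare(a, a[-1]), "equal length")
})
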