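rankedFixture <- function(N = 200, seed = 13) {
  set.seed(seed)
  new("RankedGeneList", gene = sprintf("g%04d", seq_len(N)),
      stat = sort(rnorm(N), decreasing = TRUE), method = "pearson",
      tieSeed = 1L)
}

test_that("genes are ranked by correlation with random tie-breaking", {
  set.seed(3)
  meas <- rnorm(12)
  expr <- matrix(rnorm(20 * 12), 20, 12,
                 dimnames = list(sprintf("g%02d", 1:20), NULL))
  expr["g05", ] <- meas                     # perfectly correlated
  expr["g17", ] <- -meas                    # perfectly anti-correlated
  rl <- rankGenes(expr, meas, "pearson", seed = 1)
  expect_equal(rl@gene[1], "g05")
  expect_equal(rl@stat[1], 1)
  expect_equal(rl@gene[20], "g17")
  expect_equal(rl@stat[20], -1)
  expect_true(all(diff(rl@stat) <= 1e-12))
  # Spearman ranking is invariant under a monotone transform of the
  # measure; Pearson is not
  sp1 <- rankGenes(expr, meas, "spearman", seed = 1)
  sp2 <- rankGenes(expr, exp(meas), "spearman", seed = 1)
  expect_identical(sp1@gene, sp2@gene)
  pe2 <- rankGenes(expr, exp(meas), "pearson", seed = 1)
  expect_false(identical(rl@stat, pe2@stat))
  # zero-variance genes are dropped with a warning
  expr["g09", ] <- 3
  expect_warning(rz <- rankGenes(expr, meas, seed = 1), "zero-variance")
  expect_false("g09" %in% rz@gene)
})

test_that("tie-break permutations are seeded and uniform over ties", {
  meas <- c(1, 2, 3, 4, 5, 6)
  expr <- matrix(rep(c(1, 2, 1, 2, 1, 2), each = 8), 8, 6, byrow = FALSE,
                 dimnames = list(sprintf("t%d", 1:8), NULL))
  r1 <- rankGenes(expr, meas, seed = 5)
  r2 <- rankGenes(expr, meas, seed = 5)
  expect_identical(r1@gene, r2@gene)
  orders <- vapply(1:40, function(s) paste(rankGenes(expr, meas, seed = s)@gene,
                                           collapse = ","), "")
  expect_gt(length(unique(orders)), 10)
})

test_that("single extreme genes give unit-magnitude enrichment scores", {
  rl <- rankedFixture(50)
  top <- enrichmentScore(rl, rl@gene[1])
  expect_equal(top$ES, 1)
  expect_equal(top$leadingEdge, rl@gene[1])
  bottom <- enrichmentScore(rl, rl@gene[50])
  expect_equal(bottom$ES, -1)
  expect_equal(bottom$leadingEdge, rl@gene[50])
  expect_error(enrichmentScore(rl, rl@gene), "whole list")
  expect_error(enrichmentScore(rl, "absent"), "no overlap")
})

test_that("the enrichment walk equals a literal step-by-step oracle", {
  set.seed(19)
  for (rep in 1:120) {
    N <- sample(10:50, 1)
    stats <- sort(rnorm(N), decreasing = TRUE)
    genes <- sprintf("g%03d", seq_len(N))
    rl <- new("RankedGeneList", gene = genes, stat = stats,
              method = "pearson", tieSeed = 1L)
    set_ <- sample(genes, sample(1:(N - 1), 1))
    expect_equal(enrichmentScore(rl, set_)$ES,
                 bruteWalkES(stats, genes, set_), tolerance = 1e-12)
  }
})

test_that("reversing the ranking negates the enrichment score", {
  rl <- rankedFixture(80)
  rev_ <- new("RankedGeneList", gene = rev(rl@gene), stat = rev(-rl@stat),
              method = "pearson", tieSeed = 1L)
  set.seed(23)
  for (rep in 1:25) {
    set_ <- sample(rl@gene, sample(2:20, 1))
    expect_equal(enrichmentScore(rev_, set_)$ES,
                 -enrichmentScore(rl, set_)$ES, tolerance = 1e-12)
  }
})

test_that("a zero weight exponent reduces the walk to the classic KS form", {
  rl <- rankedFixture(60)
  set.seed(29)
  for (rep in 1:20) {
    set_ <- sample(rl@gene, 12)
    es <- enrichmentScore(rl, set_, weightExponent = 0)$ES
    hits <- rl@gene %in% set_
    ks <- cumsum(hits) / sum(hits) - cumsum(!hits) / sum(!hits)
    # magnitudes always agree; signs agree whenever the two-sided
    # extremum is unique beyond rounding
    expect_equal(abs(es), max(abs(ks)), tolerance = 1e-12)
    if (abs(max(ks) + min(ks)) > 1e-9)
      expect_equal(es, ks[which.max(abs(ks))], tolerance = 1e-12)
  }
})

test_that("our walk agrees with the reference GSEA statistic", {
  skip_if_not_installed("fgsea")
  rl <- rankedFixture(500, seed = 37)
  set.seed(41)
  for (sz in c(5, 20, 80)) {
    set_ <- sample(rl@gene, sz)
    ours <- enrichmentScore(rl, set_)$ES
    ref <- fgsea::calcGseaStat(rl@stat,
                               selectedStats = sort(match(set_, rl@gene)),
                               gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("permutation nulls are seeded, centred and match direct scoring", {
  rl <- rankedFixture(400, seed = 43)
  n1 <- permutationNull(rl, 30, 200, seed = 7)
  n2 <- permutationNull(rl, 30, 200, seed = 7)
  expect_identical(n1, n2)
  expect_lt(abs(mean(permutationNull(rl, 30, 5000, seed = 8))), 0.05)
  # the vectorised fast path equals scoring each drawn set directly
  n5 <- permutationNull(rl, 25, 5, seed = 77)
  drawn <- fluxgsea:::withLocalSeed(77, vapply(1:5, function(i)
    sort.int(sample.int(400, 25)), integer(25)))
  direct <- apply(drawn, 2L, function(ix)
    enrichmentScore(rl, rl@gene[ix])$ES)
  expect_equal(n5, direct, tolerance = 1e-12)
  expect_error(permutationNull(rl, 400, 10), "smaller")
})

test_that("the Bonferroni-style threshold is 0.035 over the set count", {
  expect_equal(bonferroniThreshold(1), 0.035)
  expect_equal(bonferroniThreshold(186), 0.035 / 186)
  expect_equal(bonferroniThreshold(70), 5e-4)
})

test_that("a planted pathway is flagged and p-values respect their floor", {
  set.seed(47)
  meas <- rnorm(30)
  ids <- sprintf("G%05d", 1:600)
  spec <- expressionSpec(600, 30,
                         planted = list(list(name = "PLANTED",
                                             genes = ids[1:40], rho = 0.8,
                                             measure = "m")), seed = 9)
  ex <- simulateExpression(spec, list(m = meas))
  coll <- syntheticCollection(spec, nNullSets = 15, nullSetSize = 40,
                              seed = 2)
  res <- gseaRun(ex$matrix, meas, coll, nPerm = 2000, seed = 3)
  expect_true(all(res$pval >= 1 / 2001))
  expect_true(all(res$pval > 0))
  planted <- res[res$pathway == "PLANTED", ]
  expect_true(planted$significant)
  expect_gt(planted$NES, 0)
  # a duplicate of a set under a new name scores identically
  coll2 <- c(coll, list(PLANTED_COPY = coll$PLANTED))
  res2 <- gseaRun(ex$matrix, meas, coll2, nPerm = 500, seed = 3)
  expect_equal(res2[res2$pathway == "PLANTED", c("ES", "leadingEdge")],
               setNames(res2[res2$pathway == "PLANTED_COPY",
                             c("ES", "leadingEdge")], c("ES", "leadingEdge")),
               ignore_attr = TRUE)
})

test_that("leading-edge overlap counts shared genes and conserves totals", {
  res <- data.frame(pathway = c("A", "B", "C"),
                    significant = c(TRUE, TRUE, TRUE),
                    leadingEdge = c("g1;g2;g3", "g3;g4", "g3;g5;g1"))
  ov <- leadingEdgeOverlap(res)
  expect_equal(unname(ov$sharedCounts["g3"]), 3)
  expect_equal(unname(ov$sharedCounts["g1"]), 2)
  expect_equal(sum(ov$matrix), 3 + 2 + 3)
  expect_equal(unname(colSums(ov$matrix)), c(3, 2, 3))
  # disjoint leading edges share nothing
  res2 <- data.frame(pathway = c("A", "B"), significant = TRUE,
                     leadingEdge = c("g1;g2", "g3;g4"))
  expect_true(all(leadingEdgeOverlap(res2)$sharedCounts == 1))
})
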