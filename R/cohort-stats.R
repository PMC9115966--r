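#' @include gsea.R
NULL

#' Permuted-phenotype false-positive study
#'
#' Re-runs the full GSEA on datasets in which the imaging-measure values
#' are randomly permuted across patients (breaking any true association
#' while preserving both marginals), counting how many gene sets are
#' flagged significant at the same 0.035/N threshold used on real data.
#'
#' @param expression genes x patients log2 matrix.
#' @param measureValues one value per patient.
#' @param collection named list of gene sets.
#' @param nDatasets number of permuted datasets (default 100).
#' @param alphaNumerator threshold numerator.
#' @param nPerm permutations per GSEA run.
#' @param method correlation method.
#' @param seed master seed; each dataset uses a derived sub-seed.
#' @param identityPermutation debug mode: use the identity permutation for
#'   every dataset (counts then equal the unpermuted analysis).
#' @return a list: `counts` (per dataset), `summary` (median, min, max,
#'   q95), `threshold`.
#' @export
permutedPhenotypeStudy <- function(expression, measureValues, collection,
                                   nDatasets = 100L, alphaNumerator = 0.035,
                                   nPerm = 1000L,
                                   method = c("pearson", "spearman"),
                                   seed = 1L, identityPermutation = FALSE) {
  stopifnot(nDatasets >= 1)
  method <- match.arg(method)
  n <- length(measureValues)
  counts <- vapply(seq_len(nDatasets), function(d) {
    sd_ <- deriveSeed(seed, paste0("fp", d))
    perm <- if (identityPermutation) seq_len(n)
            else withLocalSeed(sd_, sample.int(n))
    res <- gseaRun(expression, measureValues[perm], collection,
                   method = method, nPerm = nPerm, seed = sd_,
                   alphaNumerator = alphaNumerator)
    sum(res$significant)
  }, 1L)
  list(counts = counts,
       summary = c(median = median(counts), min = min(counts),
                   max = max(counts),
                   q95 = unname(quantile(counts, 0.95, type = 1))),
       threshold = alphaNumerator)
}

#' Bootstrap comparison of significant-pathway counts
#'
#' Draws bootstrap resamples of the cohort (patients with replacement;
#' expression columns and measure values jointly), reruns the GSEA for
#' two imaging measures on each resample, and compares the per-resample
#' counts of significant pathways with the paired t-test (pairing by
#' resample).
#'
#' @param expression genes x patients log2 matrix.
#' @param measuresTable data.frame of imaging measures, patients as rows.
#' @param collection named list of gene sets.
#' @param measureA,measureB column names of the two measures compared.
#' @param nBoot number of bootstrap resamples.
#' @param nPerm permutations per GSEA run.
#' @param method correlation method.
#' @param seed master seed.
#' @param alphaNumerator threshold numerator.
#' @return a list: `differences` (countA - countB per resample), `countsA`,
#'   `countsB`, `observed` (unresampled count difference), `p` (paired
#'   t-test, `NA` when degenerate), `degenerate`.
#' @export
bootstrapCountDifference <- function(expression, measuresTable, collection,
                                     measureA, measureB, nBoot = 25L,
                                     nPerm = 1000L,
                                     method = c("pearson", "spearman"),
                                     seed = 1L, alphaNumerator = 0.035) {
  stopifnot(nBoot >= 2, all(c(measureA, measureB) %in% names(measuresTable)))
  method <- match.arg(method)
  n <- nrow(measuresTable)
  if (ncol(expression) != n)
    stop("expression columns must align with measuresTable rows")
  countFor <- function(expr, vals, sd_) {
    res <- gseaRun(expr, vals, collection, method = method, nPerm = nPerm,
                   seed = sd_, alphaNumerator = alphaNumerator)
    sum(res$significant)
  }
  observed <- countFor(expression, measuresTable[[measureA]],
                       deriveSeed(seed, "obsA")) -
              countFor(expression, measuresTable[[measureB]],
                       deriveSeed(seed, "obsB"))
  countsA <- countsB <- numeric(nBoot)
  for (b in seq_len(nBoot)) {
    redraw <- 0L
    repeat {
      sd_ <- deriveSeed(seed, paste0("boot", b, "_", redraw))
      idx <- withLocalSeed(sd_, sample.int(n, n, replace = TRUE))
      va <- measuresTable[[measureA]][idx]
      vb <- measuresTable[[measureB]][idx]
      if (sd(va) > 0 && sd(vb) > 0) break
      redraw <- redraw + 1L
      message("bootstrap resample ", b, " redrawn (zero-variance measure)")
      if (redraw > 100L) stop("could not draw a non-degenerate resample")
    }
    ex <- expression[, idx, drop = FALSE]
    colnames(ex) <- make.unique(colnames(expression)[idx])
    countsA[b] <- countFor(ex, va, deriveSeed(seed, paste0("bootA", b)))
    countsB[b] <- countFor(ex, vb, deriveSeed(seed, paste0("bootB", b)))
  }
  differences <- countsA - countsB
  degenerate <- all(differences == differences[1])
  p <- if (degenerate) NA_real_ else t.test(countsA, countsB, paired = TRUE)$p.value
  list(differences = differences, countsA = countsA, countsB = countsB,
       observed = observed, p = p, degenerate = degenerate)
}

#' Gene x measure correlation table
#'
#' Pearson correlation of each listed gene's expression with each imaging
#' measure: the numbers behind correlation heatmaps. Zero-variance genes
#' are excluded with a warning.
#'
#' @param expression genes x patients log2 matrix (already filtered for
#'   low expression if desired; see [filterLowExpression()]).
#' @param measuresTable data.frame of imaging measures, patients as rows.
#' @param geneIds genes (rows) to correlate.
#' @return numeric matrix, genes x measures, of Pearson r.
#' @export
correlationHeatmapTable <- function(expression, measuresTable, geneIds) {
  if (!all(geneIds %in% rownames(expression)))
    stop("geneIds missing from the expression matrix: ",
         paste(setdiff(geneIds, rownames(expression)), collapse = ", "))
  sub <- expression[geneIds, , drop = FALSE]
  sds <- apply(sub, 1L, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s) excluded")
    sub <- sub[sds > 0, , drop = FALSE]
  }
  m <- vapply(measuresTable, function(v) as.numeric(cor(t(sub), v)),
              numeric(nrow(sub)))
  m <- matrix(m, nrow = nrow(sub),
              dimnames = list(rownames(sub), names(measuresTable)))
  m
}

#' Drop genes with low mean expression
#'
#' @param expression genes x patients log2 matrix.
#' @param floorLog2 minimum mean log2 expression retained (default 1.0).
#' @return the filtered matrix.
#' @export
filterLowExpression <- function(expression, floorLog2 = 1.0) {
  expression[rowMeans(expression) >= floorLog2, , drop = FALSE]
}

#' Wilcoxon signed-rank comparison of paired correlation vectors
#'
#' Two-sided signed-rank test on paired per-gene correlation coefficients
#' (zero differences dropped, the Wilcoxon convention).
#'
#' @param rVectorA,rVectorB equal-length paired coefficient vectors.
#' @return a list: `statistic` (V), `p` (`NA` with fewer than 5 nonzero
#'   differences), `nNonzero`.
#' @export
wilcoxonCompare <- function(rVectorA, rVectorB) {
  if (length(rVectorA) != length(rVectorB))
    stop("paired vectors must have equal length")
  d <- rVectorA - rVectorB
  nz <- sum(d != 0)
  if (nz < 5L)
    return(list(statistic = NA_real_, p = NA_real_, nNonzero = nz))
  wt <- suppressWarnings(wilcox.test(rVectorA, rVectorB, paired = TRUE,
                                     exact = FALSE, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value, nNonzero = nz)
}
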