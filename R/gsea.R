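#' @include utils.R AllClasses.R
NULL

#' Rank genes by correlation with an imaging measure
#'
#' Computes a Pearson or Spearman correlation coefficient per gene between
#' its (log2) expression across patients and the imaging measure, and
#' orders genes by decreasing coefficient. Genes with identical
#' coefficients are permuted uniformly at random under a dedicated
#' tie-break seed; zero-variance genes are dropped with a warning.
#'
#' @param expression numeric matrix, genes x patients, log2 scale.
#' @param measureValues numeric, one value per patient (column order).
#' @param method "pearson" or "spearman".
#' @param seed tie-break seed.
#' @return a [RankedGeneList].
#' @export
rankGenes <- function(expression, measureValues,
                      method = c("pearson", "spearman"), seed = 1L) {
  method <- match.arg(method)
  if (ncol(expression) != length(measureValues))
    stop("expression columns must align with measureValues")
  if (length(measureValues) < 3L) stop("need at least 3 patients")
  sds <- apply(expression, 1L, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s) dropped from the ranking")
    expression <- expression[sds > 0, , drop = FALSE]
  }
  r <- as.numeric(cor(t(expression), measureValues, method = method))
  names(r) <- rownames(expression)
  ord <- withLocalSeed(seed, order(-r, sample.int(length(r))))
  new("RankedGeneList", gene = names(r)[ord], stat = unname(r[ord]),
      method = method, tieSeed = as.integer(seed))
}

## Walk machinery shared by the single-set score and the permutation null:
## hits increment by |r|^p / sum_set |r|^p, misses decrement by 1/(N - NH).
walkEnrichment <- function(absw, positions, N) {
  NH <- length(positions)
  NR <- sum(absw[positions])
  hit <- numeric(N)
  hit[positions] <- if (NR > 0) absw[positions] / NR else 1 / NH
  miss <- rep(1 / (N - NH), N)
  miss[positions] <- 0
  cumsum(hit) - cumsum(miss)
}

#' Enrichment score of a gene set against a ranked list
#'
#' Weighted Kolmogorov-Smirnov-style running sum: walking down the ranked
#' list, set members increment the walk by \eqn{|r|^p / \sum_{set} |r|^p}
#' and non-members decrement it by \eqn{1/(N - N_H)}. The enrichment score
#' is the walk's extremum (ties broken towards the earlier list
#' position); the leading edge contains the set members at or before a
#' positive extremum, or at or after a negative one.
#'
#' @param ranked a [RankedGeneList].
#' @param geneSet character vector of gene ids.
#' @param weightExponent the weight p (default 1, the standard choice).
#' @return a list: `ES`, `leadingEdge` (character), `runningWalk`
#'   (numeric, length N), `positions` (hit positions).
#' @export
enrichmentScore <- function(ranked, geneSet, weightExponent = 1) {
  stopifnot(is(ranked, "RankedGeneList"))
  N <- length(ranked@gene)
  positions <- sort(match(unique(geneSet), ranked@gene))
  positions <- positions[!is.na(positions)]
  if (length(positions) == 0L) stop("gene set has no overlap with the ranked list")
  if (length(positions) >= N)
    stop("gene set covering the whole list leaves the miss step undefined")
  walk <- walkEnrichment(abs(ranked@stat)^weightExponent, positions, N)
  iMax <- which.max(walk)
  iMin <- which.min(walk)
  ES <- if (abs(walk[iMax]) > abs(walk[iMin])) walk[iMax]
        else if (abs(walk[iMin]) > abs(walk[iMax])) walk[iMin]
        else if (iMax <= iMin) walk[iMax] else walk[iMin]
  le <- if (ES >= 0) positions[positions <= iMax]
        else positions[positions >= iMin]
  list(ES = ES, leadingEdge = ranked@gene[le], runningWalk = walk,
       positions = positions)
}

#' Gene-wise permutation null for the enrichment score
#'
#' Scores `nPerm` uniformly drawn gene sets of the given size against the
#' fixed ranking (equivalent to permuting gene labels). Null samples are
#' reproducible under the seed and can be shared across sets of equal
#' size.
#'
#' @param ranked a [RankedGeneList].
#' @param setSize number of genes per draw.
#' @param nPerm number of permutations.
#' @param seed RNG seed.
#' @param weightExponent walk weight p.
#' @return numeric vector of `nPerm` null enrichment scores.
#' @export
permutationNull <- function(ranked, setSize, nPerm, seed = 1L,
                            weightExponent = 1) {
  stopifnot(is(ranked, "RankedGeneList"), nPerm >= 1)
  N <- length(ranked@gene)
  if (setSize >= N) stop("setSize must be smaller than the ranked list")
  absw <- abs(ranked@stat)^weightExponent
  idx <- withLocalSeed(seed, {
    vapply(seq_len(nPerm), function(i) sort.int(sample.int(N, setSize)),
           integer(setSize))
  })
  idx <- matrix(idx, nrow = setSize)
  ## vectorised extrema over the walk evaluated only at hit positions:
  ## just after hit j the walk is cumW_j/NR - (pos_j - j)/(N - s); just
  ## before hit j it is cumW_{j-1}/NR - (pos_j - 1 - (j - 1))/(N - s).
  s <- setSize
  W <- matrix(absw[idx], nrow = s)
  cumW <- apply(W, 2L, cumsum)
  NR <- rep(cumW[s, ], each = s)
  j <- rep(seq_len(s), times = nPerm)
  miss <- (idx - j) / (N - s)
  atHit <- cumW / NR - miss
  beforeHit <- rbind(0, cumW[-s, , drop = FALSE]) / NR - (idx - j) / (N - s)
  esPos <- apply(atHit, 2L, max)
  esNeg <- pmin(apply(beforeHit, 2L, min), 0)
  esPos <- pmax(esPos, 0)
  ifelse(esPos >= -esNeg, esPos, esNeg)
}

#' Bonferroni-style significance threshold
#'
#' The nominal adjusted p-value cut-off 0.035/N for a collection of N
#' gene sets.
#'
#' @param nSets number of gene sets after size filtering.
#' @param alphaNumerator numerator of the threshold (default 0.035).
#' @return the p-value cut-off.
#' @examples
#' bonferroniThreshold(70)  # 5e-4
#' @export
bonferroniThreshold <- function(nSets, alphaNumerator = 0.035) {
  stopifnot(nSets >= 1)
  alphaNumerator / nSets
}

#' Gene-set enrichment analysis of an imaging measure
#'
#' Ranks genes by correlation with the measure, scores every gene set in
#' the collection, and computes sign-stratified permutation p-values and
#' normalised enrichment scores against gene-wise permutation nulls
#' (shared across sets of equal size). NES = ES divided by the mean |null
#' ES| of the matching sign; p = (1 + #\{same-sign nulls at least as
#' extreme\}) / (1 + #\{same-sign nulls\}), never zero. Sets are flagged
#' significant below the 0.035/N Bonferroni-style threshold, N being the
#' post-filter collection size.
#'
#' @param expression genes x patients log2 matrix.
#' @param measureValues one value per patient.
#' @param collection named list of character gene-id vectors.
#' @param method correlation method for the ranking.
#' @param nPerm permutations per null.
#' @param seed master seed (fans out to tie-break and permutation
#'   streams).
#' @param weightExponent walk weight p.
#' @param minSize,maxSize set-size filter applied to the overlap with the
#'   ranked list (defaults 15 and 500).
#' @param alphaNumerator numerator of the significance threshold.
#' @param ranked optionally a precomputed [RankedGeneList] (then
#'   `expression`/`measureValues`/`method` are ignored).
#' @return data.frame: pathway, size, ES, NES, pval, significant,
#'   leadingEdge (semicolon-joined gene ids); attributes `threshold`,
#'   `nSets`, `ranked`.
#' @export
gseaRun <- function(expression, measureValues, collection,
                    method = c("pearson", "spearman"), nPerm = 1000L,
                    seed = 1L, weightExponent = 1, minSize = 15L,
                    maxSize = 500L, alphaNumerator = 0.035, ranked = NULL) {
  if (is.null(ranked))
    ranked <- rankGenes(expression, measureValues, match.arg(method),
                        seed = deriveSeed(seed, "ties"))
  if (length(collection) == 0L || is.null(names(collection)) ||
      anyDuplicated(names(collection)))
    stop("collection must be a non-empty uniquely named list of gene sets")
  sizes <- vapply(collection, function(g)
    length(intersect(unique(g), ranked@gene)), 1L)
  keep <- sizes >= minSize & sizes <= maxSize
  if (!any(keep)) stop("no gene set survives the size filter")
  collection <- collection[keep]
  sizes <- sizes[keep]
  nSets <- length(collection)
  pcut <- bonferroniThreshold(nSets, alphaNumerator)

  nulls <- new.env(parent = emptyenv())
  nullFor <- function(sz) {
    key <- as.character(sz)
    if (is.null(nulls[[key]]))
      nulls[[key]] <- permutationNull(ranked, sz, nPerm,
                                      seed = deriveSeed(seed, paste0("perm", sz)),
                                      weightExponent = weightExponent)
    nulls[[key]]
  }

  rows <- lapply(seq_along(collection), function(i) {
    es <- enrichmentScore(ranked, collection[[i]], weightExponent)
    nl <- nullFor(sizes[i])
    same <- if (es$ES >= 0) nl[nl >= 0] else nl[nl < 0]
    p <- (1 + sum(abs(same) >= abs(es$ES))) / (1 + length(same))
    nes <- if (length(same) && mean(abs(same)) > 0)
      es$ES / mean(abs(same)) else NA_real_
    data.frame(pathway = names(collection)[i], size = sizes[i], ES = es$ES,
               NES = nes, pval = p, significant = p < pcut,
               leadingEdge = paste(es$leadingEdge, collapse = ";"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "threshold") <- pcut
  attr(out, "nSets") <- nSets
  attr(out, "ranked") <- ranked
  out
}

#' Leading-edge overlap across pathways
#'
#' Builds the binary gene x pathway membership matrix over the union of
#' leading-edge genes and counts, per gene, how many pathways share it.
#'
#' @param results a [gseaRun()] table.
#' @param significantOnly restrict to pathways flagged significant.
#' @return a list: `matrix` (0/1, genes x pathways, rows ordered by
#'   decreasing shared-pathway count), `sharedCounts` (named vector).
#' @export
leadingEdgeOverlap <- function(results, significantOnly = TRUE) {
  d <- if (significantOnly) results[results$significant, , drop = FALSE]
       else results
  if (nrow(d) == 0L) stop("no pathway with a leading edge to overlap")
  les <- strsplit(d$leadingEdge, ";", fixed = TRUE)
  les <- lapply(les, function(g) g[nzchar(g)])
  genes <- sort(unique(unlist(les)))
  m <- vapply(les, function(g) as.integer(genes %in% g),
              integer(length(genes)))
  m <- matrix(m, nrow = length(genes),
              dimnames = list(genes, d$pathway))
  counts <- rowSums(m)
  ord <- order(-counts, rownames(m))
  list(matrix = m[ord, , drop = FALSE], sharedCounts = counts[ord])
}
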