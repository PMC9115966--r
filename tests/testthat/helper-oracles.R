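# Shared fixtures and independent oracles used across the suite.

stdAif <- function() aifParams(0.4, 400, 6, 3, 4, 0.12, 0.01)
stdParams2C3K <- function() c(K1 = 0.12, k2 = 0.35, k3 = 0.07, Vb = 0.06)

# Literal step-by-step recomputation of the weighted running-sum walk:
# maintains the hit and miss sums separately (the definition) and applies
# the documented extremum rule (larger |walk|, earlier position on exact
# ties).
bruteWalkES <- function(stats, genes, geneSet, p = 1) {
  N <- length(genes)
  hits <- genes %in% geneSet
  NR <- sum(abs(stats[hits])^p)
  nMiss <- N - sum(hits)
  hitSum <- 0
  missSum <- 0
  best <- 0
  bestAbs <- 0
  for (i in seq_len(N)) {
    if (hits[i]) hitSum <- hitSum + abs(stats[i])^p / NR
    else missSum <- missSum + 1 / nMiss
    w <- hitSum - missSum
    if (abs(w) > bestAbs) {
      bestAbs <- abs(w)
      best <- w
    }
  }
  best
}

# Exact runs-test distribution by brute enumeration of every sign
# sequence of length n (conditioned on the two class counts).
enumerateRunsDistribution <- function(n) {
  out <- list()
  for (code in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(n)]
    n1 <- sum(bits)
    if (n1 == 0L || n1 == n) next
    runs <- 1L + sum(diff(bits) != 0)
    key <- paste(n1, n - n1, sep = "_")
    if (is.null(out[[key]])) out[[key]] <- integer(0)
    out[[key]] <- c(out[[key]], runs)
  }
  out
}

# Construct a +/-1 sign sequence with the given class sizes and exactly
# r runs (first arranging whichever sign allows the split).
buildSignSequence <- function(n1, n2, r) {
  a <- ceiling(r / 2)
  b <- floor(r / 2)
  if (a <= n1 && b <= n2) {
    first <- 1; nf <- n1; kf <- a; second <- -1; ns <- n2; ks <- b
  } else {
    first <- -1; nf <- n2; kf <- a; second <- 1; ns <- n1; ks <- b
  }
  lf <- rep(1L, kf); lf[1] <- nf - kf + 1L
  ls <- if (ks > 0) { x <- rep(1L, ks); x[1] <- ns - ks + 1L; x } else integer()
  out <- integer(0)
  for (i in seq_len(max(kf, ks))) {
    if (i <= kf) out <- c(out, rep(first, lf[i]))
    if (i <= ks) out <- c(out, rep(second, ls[i]))
  }
  out
}

# Frame average of an arbitrary time function by fine-grid trapezoid
# quadrature, independent of the package's Simpson machinery.
quadFrameAverage <- function(f, schedule, nGrid = 801L) {
  starts <- frameStarts(schedule)
  dur <- durations(schedule) / 60
  vapply(seq_along(dur), function(i) {
    tt <- seq(starts[i], starts[i] + dur[i], length.out = nGrid)
    v <- f(tt)
    sum((v[-1] + v[-nGrid]) / 2) * (tt[2] - tt[1]) / dur[i]
  }, 1)
}
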