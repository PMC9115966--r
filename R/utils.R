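## Internal helpers: seeding, frame-averaged evaluation, table I/O.

#' @importFrom stats rnorm runif setNames approx coef cor lm.fit median
#'   pnorm quantile sd t.test wilcox.test var
#' @importFrom utils read.delim write.table head tail
#' @importFrom tools md5sum
NULL

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb
#' the caller's RNG stream. A `NULL` seed leaves the stream untouched.
#' @noRd
withLocalSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0)
    stop("'seed' must be a single non-negative number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage sub-seed from a master seed
#'
#' Deterministic fan-out of one master seed into independent per-stage
#' streams: a Lehmer-style step keeps results inside the 32-bit integer
#' range. Equal (seed, tag) pairs always map to the same sub-seed.
#' @noRd
deriveSeed <- function(seed, tag) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h * 7919 + 12345) %% 2147483629)
}

## Composite Simpson nodes/weights on [0, 1] with an odd node count.
simpsonRule <- function(n = 11L) {
  stopifnot(n >= 3L, n %% 2L == 1L)
  x <- seq(0, 1, length.out = n)
  w <- rep(c(2, 4), length.out = n)
  w[c(1L, n)] <- 1
  w <- w / sum(w)
  list(nodes = x, weights = w)
}

#' Per-frame quadrature grid for a schedule
#'
#' Returns subdivision times (minutes post-injection) and Simpson weights
#' used to average model curves over acquisition frames, mimicking how
#' scanner frames integrate activity.
#' @noRd
frameGrid <- function(schedule, nsub = 11L) {
  sr <- simpsonRule(nsub)
  st <- frameStarts(schedule)
  dur <- durations(schedule) / 60
  times <- outer(sr$nodes, dur) + rep(st, each = nsub)  # nsub x nframes
  list(times = times, weights = sr$weights, nframes = length(dur), nsub = nsub)
}

## Average pointwise values (matrix nsub x nframes) into frame means.
frameAverageValues <- function(values, grid) {
  as.numeric(crossprod(values, grid$weights))
}

## Frame-average an arbitrary vectorised function of time.
frameAverage <- function(f, schedule, nsub = 11L) {
  g <- frameGrid(schedule, nsub)
  v <- matrix(f(as.numeric(g$times)), nrow = g$nsub)
  frameAverageValues(v, g)
}

## Tables are written with a comment line naming the config hash (if any)
## so every artefact can be traced to the run that produced it.
writeTsv <- function(x, path, configHash = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(configHash))
    writeLines(paste0("# config_hash: ", configHash), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

## Content hash for configs without external digest dependencies: serialise
## to a tempfile and md5sum it.
hashObject <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2)
  unname(tools::md5sum(tf))
}
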