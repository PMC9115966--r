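#' @include AllClasses.R AllGenerics.R
NULL

#' 18F physical decay constant
#'
#' \eqn{\lambda = \ln 2 / 109.77} per minute (18F half-life 109.77 min).
#' @export
F18_DECAY_CONSTANT <- log(2) / 109.77

#' Construct a frame schedule
#'
#' @param durations numeric, seconds per frame, in acquisition order.
#' @param injectionOffset seconds between acquisition start and tracer
#'   injection (default 30 s: injection part-way through the first frame).
#' @return a [FrameSchedule]; mid-times are minutes post-injection.
#' @examples
#' frameSchedule(c(30, rep(5, 12)), injectionOffset = 30)
#' @export
frameSchedule <- function(durations, injectionOffset = 30) {
  durations <- as.numeric(durations)
  starts <- (cumsum(c(0, durations))[-(length(durations) + 1L)] -
               injectionOffset) / 60
  mid <- starts + durations / 120
  new("FrameSchedule", durations = durations,
      injectionOffset = as.numeric(injectionOffset), midTimes = mid,
      tScan = (sum(durations) - injectionOffset) / 60)
}

#' The 45-minute dynamic FDG acquisition schedule
#'
#' Forty frames, \{1 x 30 s, 12 x 5 s, 6 x 10 s, 5 x 30 s, 10 x 60 s,
#' 6 x 300 s\}, with injection 30 s after the start of acquisition: a
#' 45.5 min acquisition spanning 45 min post-injection. The first frame is
#' entirely pre-injection.
#'
#' @return a [FrameSchedule].
#' @examples
#' sched <- makePaperSchedule()
#' tScan(sched)  # 45
#' @export
makePaperSchedule <- function() {
  frameSchedule(c(rep(30, 1), rep(5, 12), rep(10, 6), rep(30, 5),
                  rep(60, 10), rep(300, 6)), injectionOffset = 30)
}

#' Frame weights for weighted least squares
#'
#' Computes the per-frame weights
#' \deqn{w_i = (\Delta T_i / A_i)\, e^{-\lambda t_i}}
#' where \eqn{\Delta T_i} is the frame duration (seconds), \eqn{A_i} the
#' measured activity concentration and \eqn{t_i} the frame mid-time
#' post-injection (minutes). Frames with non-positive activity (including
#' pre-injection frames) are excluded: their weight is `NA` and they are
#' flagged.
#'
#' @param schedule a [FrameSchedule].
#' @param activities numeric, activity concentration per frame, aligned
#'   with the schedule.
#' @param decayConstant \eqn{\lambda} in min^-1; defaults to the 18F value.
#' @return a list with `weights` (numeric, `NA` where excluded) and
#'   `excluded` (logical flags).
#' @examples
#' s <- frameSchedule(c(30, 60), injectionOffset = 0)
#' computeWeights(s, c(1, 2), decayConstant = 0)
#' @export
computeWeights <- function(schedule, activities,
                           decayConstant = F18_DECAY_CONSTANT) {
  stopifnot(is(schedule, "FrameSchedule"))
  if (length(activities) != length(durations(schedule)))
    stop("activities must align with the schedule (one value per frame)")
  if (decayConstant < 0) stop("decayConstant must be non-negative")
  excluded <- !is.finite(activities) | activities <= 0
  if (all(excluded)) stop("all frames have non-positive activity; cannot weight")
  w <- durations(schedule) / activities * exp(-decayConstant * midTimes(schedule))
  w[excluded] <- NA_real_
  list(weights = w, excluded = excluded)
}

## Post-injection frame indices (mid-time after injection).
postInjectionFrames <- function(schedule) which(midTimes(schedule) > 0)
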