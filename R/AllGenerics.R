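#' @include AllClasses.R
NULL

#' Accessors for frame schedules and curves
#'
#' @param x a [FrameSchedule] or [Curve].
#' @return `durations()` frame durations in seconds; `midTimes()` frame
#'   mid-times in minutes post-injection; `tScan()` the post-injection
#'   scan span in minutes; `frameStarts()` frame start times in minutes
#'   post-injection; `activity()` the sampled concentrations (kBq/mL);
#'   `schedule()` the underlying [FrameSchedule].
#' @name schedule-accessors
#' @aliases durations midTimes tScan frameStarts activity schedule
NULL

#' @rdname schedule-accessors
#' @export
setGeneric("durations", function(x) standardGeneric("durations"))
#' @rdname schedule-accessors
#' @export
setGeneric("midTimes", function(x) standardGeneric("midTimes"))
#' @rdname schedule-accessors
#' @export
setGeneric("tScan", function(x) standardGeneric("tScan"))
#' @rdname schedule-accessors
#' @export
setGeneric("frameStarts", function(x) standardGeneric("frameStarts"))
#' @rdname schedule-accessors
#' @export
setGeneric("activity", function(x) standardGeneric("activity"))
#' @rdname schedule-accessors
#' @export
setGeneric("schedule", function(x) standardGeneric("schedule"))

setMethod("durations", "FrameSchedule", function(x) x@durations)
setMethod("midTimes", "FrameSchedule", function(x) x@midTimes)
setMethod("tScan", "FrameSchedule", function(x) x@tScan)
setMethod("frameStarts", "FrameSchedule", function(x) {
  d <- x@durations
  (cumsum(c(0, d))[-(length(d) + 1L)] - x@injectionOffset) / 60
})
setMethod("durations", "Curve", function(x) durations(x@schedule))
setMethod("midTimes", "Curve", function(x) midTimes(x@schedule))
setMethod("tScan", "Curve", function(x) tScan(x@schedule))
setMethod("activity", "Curve", function(x) x@activity)
setMethod("schedule", "Curve", function(x) x@schedule)

#' Accessors for kinetic fits
#'
#' @param x a [KineticFit].
#' @return `modelId()` the model identity; `kineticParams()` the named
#'   fitted parameter vector; `wrss()` the achieved weighted residual
#'   sum-of-squares.
#' @name fit-accessors
#' @aliases modelId kineticParams wrss
NULL

#' @rdname fit-accessors
#' @export
setGeneric("modelId", function(x) standardGeneric("modelId"))
#' @rdname fit-accessors
#' @export
setGeneric("kineticParams", function(x) standardGeneric("kineticParams"))
#' @rdname fit-accessors
#' @export
setGeneric("wrss", function(x) standardGeneric("wrss"))

setMethod("modelId", "KineticFit", function(x) x@modelId)
setMethod("kineticParams", "KineticFit", function(x) x@params)
setMethod("wrss", "KineticFit", function(x) x@wrss)

setMethod("show", "FrameSchedule", function(object) {
  cat(sprintf("FrameSchedule: %d frames, %.1f min acquisition, Tscan %.1f min post-injection\n",
              length(object@durations), sum(object@durations) / 60, object@tScan))
  rle_ <- rle(object@durations)
  cat("  frames:", paste(sprintf("%dx%gs", rle_$lengths, rle_$values),
                         collapse = ", "), "\n")
})

setMethod("show", "Curve", function(object) {
  cat(sprintf("Curve (%s): %d frames, peak %.2f kBq/mL at %.2f min\n",
              if (length(object@label)) object@label else "unlabelled",
              length(object@activity), max(object@activity),
              midTimes(object)[which.max(object@activity)]))
})

setMethod("show", "AifParams", function(object) {
  cat(sprintf(
    "AifParams: delay %.3f min | A1 %.1f, A2 %.2f, A3 %.2f | mu %.3f > %.3f > %.4f /min\n",
    object@delay, object@A1, object@A2, object@A3,
    object@mu1, object@mu2, object@mu3))
})

setMethod("show", "KineticFit", function(object) {
  cat(sprintf("KineticFit [%s]: kflux %.4f /min, wRSS %.4g\n",
              object@modelId, object@kflux, object@wrss))
  p <- object@params
  if (length(p))
    cat("  ", paste(sprintf("%s=%.4g", names(p), p), collapse = ", "), "\n")
})

setMethod("show", "RankedGeneList", function(object) {
  n <- length(object@gene)
  cat(sprintf("RankedGeneList: %d genes, %s correlation, stat range [%.3f, %.3f]\n",
              n, object@method, object@stat[n], object@stat[1]))
})
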