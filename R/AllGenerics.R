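#' @include AllClasses.R
NULL

#' @export
setGeneric("lfpSamples", function(x) standardGeneric("lfpSamples"))
#' @export
setGeneric("rateHz", function(x) standardGeneric("rateHz"))
#' @export
setGeneric("channelIds", function(x) standardGeneric("channelIds"))
#' @export
setGeneric("startTime", function(x) standardGeneric("startTime"))
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))
#' @export
setGeneric("events", function(x) standardGeneric("events"))
#' @export
setGeneric("sessionDuration", function(x) standardGeneric("sessionDuration"))
#' @export
setGeneric("groomingEvents", function(x) standardGeneric("groomingEvents"))
#' @export
setGeneric("filterCenters", function(x) standardGeneric("filterCenters"))
#' @export
setGeneric("filterWeights", function(x) standardGeneric("filterWeights"))
#' @export
setGeneric("scheduleBlocks", function(x) standardGeneric("scheduleBlocks"))
#' @export
setGeneric("confusionVector", function(x) standardGeneric("confusionVector"))

#' Accessors
#'
#' Accessor functions for the core classes: \code{lfpSamples}, \code{rateHz},
#' \code{channelIds}, \code{startTime}, \code{nChannels} and \code{duration}
#' for \linkS4class{Recording}; \code{events}, \code{sessionDuration} and
#' \code{groomingEvents} for \linkS4class{BehaviorAnnotation};
#' \code{filterCenters} and \code{filterWeights} for
#' \linkS4class{FilterBank}; \code{scheduleBlocks} for
#' \linkS4class{TrialSchedule}; \code{confusionVector} for
#' \linkS4class{ConfusionCounts}.
#'
#' @param x the object.
#' @return the corresponding slot content (\code{duration} returns
#'   n_samples / rate in seconds; \code{groomingEvents} the grooming rows of
#'   the event table; \code{confusionVector} a named integer vector).
#' @name accessors
#' @aliases lfpSamples rateHz channelIds startTime nChannels duration events
#'   sessionDuration groomingEvents filterCenters filterWeights
#'   scheduleBlocks confusionVector
NULL

#' @rdname accessors
setMethod("lfpSamples", "Recording", function(x) x@samples)
#' @rdname accessors
setMethod("rateHz", "Recording", function(x) x@rateHz)
#' @rdname accessors
setMethod("channelIds", "Recording", function(x) x@channelIds)
#' @rdname accessors
setMethod("startTime", "Recording", function(x) x@t0)
#' @rdname accessors
setMethod("nChannels", "Recording", function(x) nrow(x@samples))
#' @rdname accessors
setMethod("duration", "Recording", function(x) ncol(x@samples) / x@rateHz)

#' @rdname accessors
setMethod("events", "BehaviorAnnotation", function(x) x@events)
#' @rdname accessors
setMethod("sessionDuration", "BehaviorAnnotation",
          function(x) x@sessionDurationS)
#' @rdname accessors
setMethod("groomingEvents", "BehaviorAnnotation", function(x) {
  ev <- x@events
  ev[ev$label == "grooming", , drop = FALSE]
})

#' @rdname accessors
setMethod("filterCenters", "FilterBank", function(x) x@centersHz)
#' @rdname accessors
setMethod("filterWeights", "FilterBank", function(x) x@weights)

#' @rdname accessors
setMethod("scheduleBlocks", "TrialSchedule", function(x) x@blocks)

#' @rdname accessors
setMethod("confusionVector", "ConfusionCounts", function(x) {
  c(TP = x@TP, FP = x@FP, TN = x@TN, FN = x@FN, excluded = x@excluded,
    missed_events = x@missedEvents, total_bins = x@totalBins)
})

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d channel(s), %.6g Hz, %.3f s (t0 = %.3f s)\n",
              nChannels(object), rateHz(object), duration(object),
              startTime(object)))
})

setMethod("show", "BehaviorAnnotation", function(object) {
  ev <- events(object)
  tab <- table(ev$label)
  cat(sprintf("BehaviorAnnotation: %d event(s) over %.1f s\n",
              nrow(ev), sessionDuration(object)))
  if (length(tab))
    cat("  ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
})

setMethod("show", "FilterBank", function(object) {
  cat(sprintf(
    "FilterBank: M = %d triangular filters on [%.3g, %.3g] Hz (F = %.3g Hz)\n",
    object@M, object@fAHz, object@fBHz, object@FHz))
  cat("  centers (Hz):", paste(signif(object@centersHz, 4), collapse = ", "),
      "\n")
})

setMethod("show", "ElectrodeClassifier", function(object) {
  cat(sprintf(
    "ElectrodeClassifier [%s]: %d-%d-%d-2 feedforward network (seed %d)\n",
    object@channelId, nrow(object@W1), ncol(object@W1), ncol(object@W2),
    object@seed))
})

setMethod("show", "ClassifierBank", function(object) {
  cat(sprintf("ClassifierBank: %d electrode classifier(s)\n",
              length(object@classifiers)))
})

setMethod("show", "TrialSchedule", function(object) {
  b <- object@blocks
  cat(sprintf("TrialSchedule: %d block(s), %.0f s total\n", nrow(b),
              sum(b$duration_s)))
  cat("  ", paste(b$condition, collapse = " > "), "\n")
})

setMethod("show", "ConfusionCounts", function(object) {
  v <- confusionVector(object)
  cat("ConfusionCounts:",
      paste(names(v), v, sep = " = ", collapse = ", "), "\n")
})

setMethod("show", "RampSummary", function(object) {
  cat(sprintf(
    "RampSummary: rising point %.3f s, peak frequency %.2f Hz (band %g-%g Hz)\n",
    object@risingPointS, object@freqAtMaxPowerHz, object@bandHz[1L],
    object@bandHz[2L]))
})
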