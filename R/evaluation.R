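#' Early-detection periods of a session
#'
#' One scoring interval per grooming event: from 2 s before onset to half
#' the bout's duration after onset, clipped to the session bounds.
#' Predictions falling inside an early-detection period (Ep) count as
#' correct grooming predictions.
#'
#' @param ann a cleaned \linkS4class{BehaviorAnnotation}.
#' @param preS seconds before onset; default 2.
#' @return data.frame with columns \code{start_s}, \code{end_s},
#'   \code{event_id} (zero rows when there is no grooming).
#' @examples
#' ann <- BehaviorAnnotation(
#'   data.frame(label = "grooming", onset_s = 10, offset_s = 16), 60)
#' computeEp(ann)  # [8, 13]
#' @export
computeEp <- function(ann, preS = 2) {
  stopifnot(is(ann, "BehaviorAnnotation"))
  g <- groomingEvents(ann)
  if (!nrow(g))
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      event_id = integer(0)))
  dur <- g$offset_s - g$onset_s
  data.frame(start_s = pmax(0, g$onset_s - preS),
             end_s = pmin(sessionDuration(ann), g$onset_s + dur / 2),
             event_id = seq_len(nrow(g)))
}

#' Score a decision stream against the early-detection periods
#'
#' Bin-level scoring of 200-ms decisions: a positive bin inside an Ep is a
#' true positive and a negative bin inside an Ep a false negative; outside
#' the Eps and outside grooming, a positive bin is a false positive and a
#' negative bin a true negative. Bins inside a grooming event but after its
#' Ep end (late-grooming bins) are excluded from all counts -- neither
#' correct detections nor errors are well defined there. Grooming events
#' whose Ep contains no positive bin are additionally counted as
#' \code{missedEvents} (the event-level miss count).
#'
#' @param decisions data.frame with columns \code{t_s} and \code{triggered}
#'   (logical positive/negative bin outcome), bins on a regular grid.
#' @param ann the session \linkS4class{BehaviorAnnotation}.
#' @param ep early-detection periods; default \code{computeEp(ann)}.
#' @return a \linkS4class{ConfusionCounts}.
#' @export
scoreDecisions <- function(decisions, ann, ep = computeEp(ann)) {
  stopifnot(is(ann, "BehaviorAnnotation"),
            all(c("t_s", "triggered") %in% names(decisions)))
  t <- decisions$t_s
  pos <- as.logical(decisions$triggered)
  inEp <- .inIntervals(t, ep$start_s, ep$end_s)
  g <- groomingEvents(ann)
  inGroom <- .inIntervals(t, g$onset_s, g$offset_s)
  excluded <- inGroom & !inEp
  tp <- sum(pos & inEp)
  fn <- sum(!pos & inEp)
  fp <- sum(pos & !inEp & !excluded)
  tn <- sum(!pos & !inEp & !excluded)
  missed <- 0L
  for (i in seq_len(nrow(ep)))
    if (!any(pos & t >= ep$start_s[i] & t < ep$end_s[i]))
      missed <- missed + 1L
  new("ConfusionCounts", TP = as.integer(tp), FP = as.integer(fp),
      TN = as.integer(tn), FN = as.integer(fn),
      excluded = as.integer(sum(excluded)), missedEvents = missed,
      totalBins = length(t))
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity, precision and specificity, in percent:
#' accuracy = 100 (TP + TN) / (TP + TN + FP + FN);
#' sensitivity = 100 TP / (TP + FN); precision = 100 TP / (TP + FP);
#' specificity = 100 TN / (TN + FP). A ratio with a zero denominator is
#' undefined and reported as \code{NA} with a warning, never as 0 or 100.
#'
#' @param counts a \linkS4class{ConfusionCounts}.
#' @return named numeric vector \code{accuracy}, \code{sensitivity},
#'   \code{precision}, \code{specificity} (percent).
#' @export
metricReport <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  tp <- counts@TP; fp <- counts@FP; tn <- counts@TN; fn <- counts@FN
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reported as NA")
      NA_real_
    } else 100 * num / den
  }
  c(accuracy = safe(tp + tn, tp + tn + fp + fn, "accuracy"),
    sensitivity = safe(tp, tp + fn, "sensitivity"),
    precision = safe(tp, tp + fp, "precision"),
    specificity = safe(tn, tn + fp, "specificity"))
}

#' Pseudorandom classification baseline
#'
#' The chance-level reference: a uniform pseudorandom binary generator
#' (1 for grooming, 0 for other behavior) emits a decision every
#' \code{intervalS} seconds over the session, is scored with
#' \code{\link{scoreDecisions}}, and the four metrics are averaged over
#' \code{nRuns} runs. Under bin-level scoring each of accuracy, sensitivity
#' and specificity converges to 50\%.
#'
#' @param ann a \linkS4class{BehaviorAnnotation} with at least one grooming
#'   event.
#' @param intervalS decision cadence (s); default 0.2.
#' @param nRuns runs to average; default 5.
#' @param seed integer RNG seed.
#' @return named numeric vector of averaged metrics (percent), with the
#'   per-run values in attribute \code{"runs"}.
#' @export
pseudorandomBaseline <- function(ann, intervalS = 0.2, nRuns = 5L,
                                 seed = 1L) {
  stopifnot(is(ann, "BehaviorAnnotation"))
  if (!nrow(groomingEvents(ann)))
    stop("annotation has no grooming events")
  set.seed(as.integer(seed))
  bins <- seq_len(floor(sessionDuration(ann) / intervalS + 1e-9)) * intervalS
  ep <- computeEp(ann)
  runs <- matrix(NA_real_, nrow = nRuns, ncol = 4L,
                 dimnames = list(NULL, c("accuracy", "sensitivity",
                                         "precision", "specificity")))
  for (r in seq_len(nRuns)) {
    dec <- data.frame(t_s = bins,
                      triggered = runif(length(bins)) < 0.5)
    runs[r, ] <- suppressWarnings(
      metricReport(scoreDecisions(dec, ann, ep)))
  }
  out <- colMeans(runs, na.rm = TRUE)
  attr(out, "runs") <- runs
  out
}

#' Behavioral endpoint: percent reduction of grooming
#'
#' Reduction of grooming bouts (\%) = 100 - Gbout_treated * 100 / Gbout_OFF,
#' and identically for grooming duration, with the no-stimulation (OFF)
#' condition as the reference baseline.
#'
#' @param offBouts,treatedBouts grooming bout counts in the OFF and treated
#'   conditions (OFF must be > 0).
#' @param offDurationS,treatedDurationS optional grooming durations (s).
#' @return list with \code{bouts} and (when durations are given)
#'   \code{duration}, both in percent.
#' @export
groomingReduction <- function(offBouts, treatedBouts,
                              offDurationS = NULL, treatedDurationS = NULL) {
  if (offBouts <= 0) stop("OFF bout count must be positive")
  out <- list(bouts = 100 - treatedBouts * 100 / offBouts)
  if (!is.null(offDurationS)) {
    if (offDurationS <= 0) stop("OFF duration must be positive")
    out$duration <- 100 - treatedDurationS * 100 / offDurationS
  }
  out
}

#' Inter-rater annotation error
#'
#' Error (\%) = (grooming_expert - grooming_naive) / grooming_expert * 100;
#' signed, positive when the naive rater under-scores.
#'
#' @param expertValue expert rater's value (nonzero).
#' @param naiveValue naive rater's value.
#' @return signed percent error.
#' @export
interraterError <- function(expertValue, naiveValue) {
  if (expertValue == 0) stop("expert value must be nonzero")
  (expertValue - naiveValue) / expertValue * 100
}

#' Full session evaluation report
#'
#' Assembles the scoring layer for one session: per-condition grooming
#' counts and durations (from the observed annotation, i.e. after any
#' stimulation effect), bin-level confusion counts and metrics of the
#' decision stream, stimulation-time accounting, and the behavioral
#' reduction endpoints when OFF and CL conditions are both present.
#'
#' @param run output of \code{\link{runClosedLoop}} (list with
#'   \code{decisions} and \code{stimEvents}).
#' @param schedule the \linkS4class{TrialSchedule} of the run.
#' @param ann the observed session annotation.
#' @param scoreAnn annotation used for decision scoring; defaults to
#'   \code{ann}. When stimulation suppressed bouts, score against the
#'   unstimulated annotation to assess the detector and against the
#'   observed one to assess behavior.
#' @return list with elements \code{per_condition} (data.frame),
#'   \code{confusion} (\linkS4class{ConfusionCounts}), \code{metrics},
#'   \code{stimulation}, and optionally \code{reduction}.
#' @export
evaluateSession <- function(run, schedule, ann, scoreAnn = ann) {
  blocks <- scheduleBlocks(schedule)
  g <- groomingEvents(ann)
  conds <- unique(blocks$condition)
  per <- data.frame(condition = conds, time_s = NA_real_,
                    grooming_bouts = NA_integer_,
                    grooming_duration_s = NA_real_)
  for (i in seq_along(conds)) {
    bsel <- blocks$condition == conds[i]
    per$time_s[i] <- sum(blocks$duration_s[bsel])
    inCond <- .inIntervals(g$onset_s, blocks$t_start_s[bsel],
                           blocks$t_start_s[bsel] + blocks$duration_s[bsel])
    per$grooming_bouts[i] <- sum(inCond)
    per$grooming_duration_s[i] <- sum((g$offset_s - g$onset_s)[inCond])
  }
  counts <- scoreDecisions(run$decisions, scoreAnn)
  metrics <- suppressWarnings(metricReport(counts))
  out <- list(per_condition = per, confusion = counts, metrics = metrics)
  if (nrow(run$stimEvents) || "ON_CONT" %in% conds)
    out$stimulation <- stimulationTime(schedule, run$stimEvents)
  if (all(c("OFF", "CL") %in% conds)) {
    off <- per[per$condition == "OFF", ]
    cl <- per[per$condition == "CL", ]
    if (off$grooming_bouts > 0 && off$grooming_duration_s > 0)
      out$reduction <- groomingReduction(off$grooming_bouts,
                                         cl$grooming_bouts,
                                         off$grooming_duration_s,
                                         cl$grooming_duration_s)
  }
  out
}

#' Write an evaluation report to JSON (plus per-condition CSV)
#'
#' @param report list from \code{\link{evaluateSession}}.
#' @param path output JSON path; the per-condition table is written next to
#'   it with suffix \code{_conditions.csv}.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(report, path) {
  ser <- report
  ser$confusion <- as.list(confusionVector(report$confusion))
  ser$metrics <- as.list(report$metrics)
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows", na = "null")
  write.csv(report$per_condition,
            sub("\\.json$", "_conditions.csv", path), row.names = FALSE)
  invisible(path)
}
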