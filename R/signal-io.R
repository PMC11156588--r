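#' Read and write session recordings
#'
#' A session is stored as a single Arrow IPC (Feather v2) container holding
#' one column per channel, with the sampling rate, channel order and session
#' start time carried in the file metadata. Double-precision samples
#' round-trip exactly.
#'
#' @param path file path.
#' @return \code{readRecording} returns a \linkS4class{Recording};
#'   \code{writeRecording} returns \code{path} invisibly.
#' @examples
#' rec <- Recording(matrix(rnorm(200), nrow = 2), rateHz = 100)
#' f <- tempfile(fileext = ".feather")
#' writeRecording(rec, f)
#' identical(lfpSamples(readRecording(f)), lfpSamples(rec))
#' @export
readRecording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- as.data.frame(arrow::read_feather(path))
  rate <- attr(df, "rate_hz")
  if (is.null(rate))
    stop("format error: container lacks a 'rate_hz' attribute")
  ids <- attr(df, "channel_ids") %||% names(df)
  t0 <- attr(df, "t0") %||% 0
  Recording(t(as.matrix(df)), rateHz = rate, channelIds = ids, t0 = t0)
}

#' @param rec a \linkS4class{Recording}.
#' @rdname readRecording
#' @export
writeRecording <- function(rec, path) {
  stopifnot(is(rec, "Recording"))
  df <- as.data.frame(t(lfpSamples(rec)))
  names(df) <- channelIds(rec)
  attr(df, "rate_hz") <- rateHz(rec)
  attr(df, "channel_ids") <- channelIds(rec)
  attr(df, "t0") <- startTime(rec)
  arrow::write_feather(df, path)
  invisible(path)
}

#' Read and write behavioral annotations
#'
#' Annotations live in a sidecar CSV table with header
#' \code{label,onset_s,offset_s} (UTF-8). Events are validated and sorted by
#' onset on read. An empty table yields a valid annotation with zero events.
#'
#' @param path CSV file path.
#' @param sessionDurationS session duration in seconds; when \code{NULL},
#'   taken from a \code{# session_duration_s:} comment line if present, else
#'   the last event offset (error on an empty table without a duration).
#' @return \code{readAnnotation} returns a \linkS4class{BehaviorAnnotation}.
#' @export
readAnnotation <- function(path, sessionDurationS = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sessionDurationS)) {
    first <- readLines(path, n = 1L)
    if (grepl("^#\\s*session_duration_s:", first))
      sessionDurationS <- as.numeric(sub("^#\\s*session_duration_s:", "",
                                         first))
  }
  ev <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("label", "onset_s", "offset_s")
  if (!all(need %in% names(ev)))
    stop("format error: annotation table needs columns ",
         paste(need, collapse = ", "))
  if (nrow(ev)) {
    bad <- which(ev$onset_s >= ev$offset_s)
    if (length(bad))
      stop("validation error: onset_s >= offset_s in row(s) ",
           paste(bad, collapse = ", "))
  }
  if (is.null(sessionDurationS)) {
    if (!nrow(ev))
      stop("sessionDurationS required for an empty annotation table")
    sessionDurationS <- max(ev$offset_s)
  }
  BehaviorAnnotation(ev, sessionDurationS)
}

#' @param ann a \linkS4class{BehaviorAnnotation}.
#' @rdname readAnnotation
#' @export
writeAnnotation <- function(ann, path) {
  stopifnot(is(ann, "BehaviorAnnotation"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# session_duration_s: %.10g", sessionDuration(ann)),
             con)
  write.csv(events(ann), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Session configuration
#'
#' Build or read the session configuration: decision cadence, analysis
#' window, channel count, nominal sampling rate and the feature / classifier
#' / protocol sub-configurations. \code{readSessionConfig} merges a YAML file
#' over these defaults.
#'
#' @param decision_interval_s decision cadence (s); default 0.2.
#' @param window_s analysis window length (s); default 1.
#' @param n_channels number of electrodes; default 32.
#' @param rate_hz nominal acquisition rate (Hz); default 20000.
#' @param features feature-stage settings (see \code{\link{buildFilterbank}}
#'   and \code{\link{featureMatrix}}).
#' @param classifier classifier settings (see
#'   \code{\link{trainElectrodeClassifier}}).
#' @param protocol protocol settings (stimulation duration, pulse train).
#' @param rng_seed integer seed.
#' @return a named list with the merged configuration.
#' @export
sessionConfig <- function(decision_interval_s = 0.2, window_s = 1.0,
                          n_channels = 32L, rate_hz = 20000,
                          features = list(), classifier = list(),
                          protocol = list(), rng_seed = 1L) {
  if (decision_interval_s > window_s)
    stop("decision_interval_s must not exceed window_s")
  if (decision_interval_s <= 0 || window_s <= 0)
    stop("durations must be positive")
  feat <- list(M = 7L, P = 5L, F_hz = 2.5, f_A_hz = 1, f_B_hz = 10,
               log_energies = TRUE, window_s = window_s,
               shift_s = decision_interval_s)
  feat[names(features)] <- features
  clf <- list(hidden = c(16L, 8L), epochs = 300L, lr = 0.01,
              val_fraction = 0.2, patience = 30L, n_starts = 3L)
  clf[names(classifier)] <- classifier
  proto <- list(stim_duration_s = 4, pulse_rate_hz = 20,
                pulse_width_s = 0.005, power_mw = 10, trial_s = 180)
  proto[names(protocol)] <- protocol
  list(decision_interval_s = decision_interval_s, window_s = window_s,
       n_channels = as.integer(n_channels), rate_hz = rate_hz,
       features = feat, classifier = clf, protocol = proto,
       rng_seed = as.integer(rng_seed))
}

#' @param path YAML file path.
#' @rdname sessionConfig
#' @export
readSessionConfig <- function(path) {
  user <- yaml::read_yaml(path)
  do.call(sessionConfig, user[intersect(names(user),
                                        names(formals(sessionConfig)))])
}

#' Apply the grooming bout scoring rules to an annotation
#'
#' Grooming bouts interrupted for less than 1 s belong to the same bout:
#' consecutive grooming events separated by a gap shorter than 1 s are merged
#' first; grooming events shorter than 1 s are then discarded. All other
#' labels pass through untouched. The operation is idempotent and never
#' increases the number of grooming events.
#'
#' @param ann a \linkS4class{BehaviorAnnotation}.
#' @param minGapS bout-ending interruption (s); default 1.
#' @param minDurationS minimum bout duration (s); default 1.
#' @return a \linkS4class{BehaviorAnnotation} with cleaned grooming events.
#' @export
cleanGroomingEvents <- function(ann, minGapS = 1, minDurationS = 1) {
  stopifnot(is(ann, "BehaviorAnnotation"))
  ev <- events(ann)
  g <- ev[ev$label == "grooming", , drop = FALSE]
  other <- ev[ev$label != "grooming", , drop = FALSE]
  if (nrow(g) > 1L) {
    g <- g[order(g$onset_s), , drop = FALSE]
    merged <- g[1L, , drop = FALSE]
    for (i in 2L:nrow(g)) {
      last <- nrow(merged)
      if (g$onset_s[i] - merged$offset_s[last] < minGapS) {
        merged$offset_s[last] <- max(merged$offset_s[last], g$offset_s[i])
      } else {
        merged <- rbind(merged, g[i, , drop = FALSE])
      }
    }
    g <- merged
  }
  if (nrow(g))
    g <- g[g$offset_s - g$onset_s >= minDurationS, , drop = FALSE]
  BehaviorAnnotation(rbind(other, g), sessionDuration(ann))
}
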