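#' @import methods
NULL

.BEHAVIOR_LABELS <- c("grooming", "walking", "rearing", "resting",
                      "scratching", "other")

#' Multi-channel LFP recording
#'
#' Container for a multi-channel extracellular local field potential (LFP)
#' recording: a channels-by-samples matrix, its sampling rate, ordered channel
#' labels and the session start time. Amplitude units are arbitrary.
#'
#' @slot samples numeric matrix, channels x samples.
#' @slot rateHz sampling frequency in Hz (> 0).
#' @slot channelIds character vector of ordered channel labels, one per row.
#' @slot t0 session start time in seconds; a negative value means the
#'   recording carries pre-roll signal acquired before the nominal session
#'   start (time 0), as a continuously acquired session would.
#'
#' @examples
#' rec <- Recording(matrix(rnorm(2000), nrow = 2), rateHz = 1000)
#' duration(rec)
#' @export
setClass("Recording",
  representation(samples = "matrix", rateHz = "numeric",
                 channelIds = "character", t0 = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@rateHz) != 1L || !is.finite(object@rateHz) ||
        object@rateHz <= 0)
      msg <- c(msg, "rateHz must be a single positive number")
    if (nrow(object@samples) != length(object@channelIds))
      msg <- c(msg, "one channelId per signal row is required")
    if (anyDuplicated(object@channelIds))
      msg <- c(msg, "channelIds must be unique")
    if (length(object@t0) != 1L || !is.finite(object@t0))
      msg <- c(msg, "t0 must be a single finite number")
    if (is.null(msg)) TRUE else msg
  })

#' @param samples numeric matrix (channels x samples) or a list of equal-length
#'   per-channel vectors.
#' @param rateHz sampling frequency (Hz).
#' @param channelIds optional channel labels; defaults to \code{ch1, ch2, ...}.
#' @param t0 session start time (s); default 0.
#' @rdname Recording-class
#' @export
Recording <- function(samples, rateHz, channelIds = NULL, t0 = 0) {
  if (is.list(samples)) {
    n <- vapply(samples, length, integer(1))
    if (length(unique(n)) > 1L)
      stop("ragged channels: all channels must have equal length")
    samples <- do.call(rbind, lapply(samples, as.numeric))
  }
  samples <- as.matrix(samples)
  if (is.null(channelIds))
    channelIds <- paste0("ch", seq_len(nrow(samples)))
  dimnames(samples) <- NULL
  new("Recording", samples = samples, rateHz = as.numeric(rateHz),
      channelIds = as.character(channelIds), t0 = as.numeric(t0))
}

#' Behavioral event annotation
#'
#' Labeled time intervals over a session. Intervals are half-open
#' \code{[onset, offset)} in seconds from session start. Labels are drawn from
#' the controlled vocabulary \code{grooming, walking, rearing, resting,
#' scratching, other}.
#'
#' @slot events data.frame with columns \code{label}, \code{onset_s},
#'   \code{offset_s}, sorted by onset.
#' @slot sessionDurationS session duration in seconds.
#' @export
setClass("BehaviorAnnotation",
  representation(events = "data.frame", sessionDurationS = "numeric"),
  validity = function(object) {
    ev <- object@events
    msg <- NULL
    need <- c("label", "onset_s", "offset_s")
    if (!all(need %in% names(ev)))
      return("events must have columns label, onset_s, offset_s")
    if (nrow(ev)) {
      bad <- which(ev$onset_s >= ev$offset_s)
      if (length(bad))
        msg <- c(msg, paste0("onset_s >= offset_s in row(s) ",
                             paste(bad, collapse = ", ")))
      if (is.unsorted(ev$onset_s))
        msg <- c(msg, "events must be sorted by onset")
      unknown <- setdiff(unique(ev$label), .BEHAVIOR_LABELS)
      if (length(unknown))
        msg <- c(msg, paste0("unknown label(s): ",
                             paste(unknown, collapse = ", ")))
    }
    if (length(object@sessionDurationS) != 1L || object@sessionDurationS <= 0)
      msg <- c(msg, "sessionDurationS must be a single positive number")
    if (is.null(msg)) TRUE else msg
  })

#' @param events data.frame with columns \code{label}, \code{onset_s},
#'   \code{offset_s}; sorted on construction.
#' @param sessionDurationS session duration (s).
#' @rdname BehaviorAnnotation-class
#' @export
BehaviorAnnotation <- function(events, sessionDurationS) {
  if (is.null(events) || nrow(events) == 0L) {
    events <- data.frame(label = character(0), onset_s = numeric(0),
                         offset_s = numeric(0))
  } else {
    events <- data.frame(label = as.character(events$label),
                         onset_s = as.numeric(events$onset_s),
                         offset_s = as.numeric(events$offset_s))
    events <- events[order(events$onset_s, events$offset_s), , drop = FALSE]
    rownames(events) <- NULL
  }
  new("BehaviorAnnotation", events = events,
      sessionDurationS = as.numeric(sessionDurationS))
}

#' Triangular filterbank
#'
#' A set of \code{M} triangular frequency-domain filters warped symmetrically
#' around a principal frequency of interest \code{F}, with center density
#' maximal near \code{F} and spacing growing with distance from it. Each
#' filter is peak-normalized to 1 and spans its two neighboring centers, so
#' adjacent filters cross at 50\% height.
#'
#' @slot M number of filters.
#' @slot FHz principal frequency of interest (Hz).
#' @slot fAHz,fBHz low and high band edges (Hz); first and last centers.
#' @slot centersHz ascending filter center frequencies (Hz).
#' @slot freqsHz PSD grid frequencies (Hz) on which the weights are sampled
#'   (band subset only).
#' @slot weights M x length(freqsHz) matrix of nonnegative triangular weights.
#' @slot gridHz PSD grid spacing (Hz).
#' @export
setClass("FilterBank",
  representation(M = "integer", FHz = "numeric", fAHz = "numeric",
                 fBHz = "numeric", centersHz = "numeric", freqsHz = "numeric",
                 weights = "matrix", gridHz = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@M < 1L) msg <- c(msg, "M must be >= 1")
    if (any(object@weights < 0)) msg <- c(msg, "weights must be nonnegative")
    if (is.unsorted(object@centersHz, strictly = TRUE))
      msg <- c(msg, "centers must be strictly ascending")
    if (nrow(object@weights) != object@M)
      msg <- c(msg, "one weight row per filter required")
    if (is.null(msg)) TRUE else msg
  })

#' Spectral density estimate of a single analysis window
#'
#' @slot freqsHz ascending frequency grid (Hz).
#' @slot power one-sided power spectral density (signal units^2 / Hz).
#' @slot meta list with window metadata (t_start, duration, channel, rate).
#' @export
setClass("SpectralEstimate",
  representation(freqsHz = "numeric", power = "numeric", meta = "list"),
  validity = function(object) {
    msg <- NULL
    if (length(object@freqsHz) != length(object@power))
      msg <- c(msg, "freqsHz and power lengths differ")
    if (is.unsorted(object@freqsHz))
      msg <- c(msg, "freqsHz must be ascending")
    if (any(object@power < 0)) msg <- c(msg, "power must be nonnegative")
    if (is.null(msg)) TRUE else msg
  })

#' Event-anchored wavelet spectrogram
#'
#' Average time-frequency power around behavioral event onsets, computed with
#' a generalized Morse wavelet (asymmetry gamma, time-bandwidth product P^2).
#'
#' @slot timesS times relative to event onset (s).
#' @slot freqsHz analysis frequencies (Hz).
#' @slot power frequency x time matrix of average wavelet power.
#' @slot params list with \code{gamma}, \code{timeBandwidth}, \code{nEvents}.
#' @export
setClass("Spectrogram",
  representation(timesS = "numeric", freqsHz = "numeric", power = "matrix",
                 params = "list"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@power) != length(object@freqsHz) ||
        ncol(object@power) != length(object@timesS))
      msg <- c(msg, "power must be length(freqsHz) x length(timesS)")
    if (is.null(msg)) TRUE else msg
  })

#' Per-electrode feedforward classifier
#'
#' Two-class feedforward network for one electrode: input layer of M*P
#' features, two sigmoid hidden layers, and a two-unit output layer normalized
#' to class probabilities ("pregrooming", "other"). Holds the per-feature
#' z-scoring statistics estimated on the training set.
#'
#' @slot W1,b1,W2,b2,W3,b3 weights and biases of the three affine layers.
#' @slot featMean,featSd per-feature normalization statistics.
#' @slot channelId electrode label.
#' @slot seed RNG seed used for initialization and data split.
#' @slot epochsRun number of training epochs actually run.
#' @export
setClass("ElectrodeClassifier",
  representation(W1 = "matrix", b1 = "numeric", W2 = "matrix", b2 = "numeric",
                 W3 = "matrix", b3 = "numeric", featMean = "numeric",
                 featSd = "numeric", channelId = "character",
                 seed = "integer", epochsRun = "integer"),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@W3) != 2L) msg <- c(msg, "output layer must have 2 units")
    if (length(object@featMean) != nrow(object@W1))
      msg <- c(msg, "normalization stats must match input size")
    if (is.null(msg)) TRUE else msg
  })

#' Bank of per-electrode classifiers
#'
#' One \linkS4class{ElectrodeClassifier} per recording channel, plus the
#' feature configuration they were trained with. Electrodes are always
#' processed individually; there is no pooled model.
#'
#' @slot classifiers named list of \linkS4class{ElectrodeClassifier}.
#' @slot featureConfig list of feature-stage settings (M, P, F_hz, band
#'   edges, window_s, shift_s, log_energies).
#' @export
setClass("ClassifierBank",
  representation(classifiers = "list", featureConfig = "list"),
  validity = function(object) {
    ok <- vapply(object@classifiers, is, logical(1), "ElectrodeClassifier")
    if (!all(ok)) "all elements must be ElectrodeClassifier objects" else TRUE
  })

#' Electrode voting policy
#'
#' Stimulation triggers only when the fraction of electrodes classifying the
#' current window as "pregrooming" strictly exceeds \code{thresholdFraction}
#' (default 0.5, i.e. a strict majority; exactly 50\% does not trigger).
#'
#' @slot thresholdFraction trigger threshold, strictly between 0 and 1.
#' @export
setClass("VotePolicy",
  representation(thresholdFraction = "numeric"),
  validity = function(object) {
    x <- object@thresholdFraction
    if (length(x) != 1L || x <= 0 || x >= 1)
      "thresholdFraction must lie strictly between 0 and 1" else TRUE
  })

#' @param thresholdFraction trigger threshold (default 0.5).
#' @rdname VotePolicy-class
#' @export
votePolicy <- function(thresholdFraction = 0.5) {
  new("VotePolicy", thresholdFraction = as.numeric(thresholdFraction))
}

#' Stimulation trial schedule
#'
#' Ordered, contiguous blocks of experimental conditions. The closed-loop
#' protocol alternates OFF, CL and RANDOM trials of 3 min in four cycles
#' (12 trials, 36 min); the continuous protocol alternates five OFF and five
#' ON_CONT trials of 3 min (30 min).
#'
#' @slot blocks data.frame with columns \code{condition}, \code{t_start_s},
#'   \code{duration_s}.
#' @slot habituationS habituation period preceding the schedule (metadata
#'   only; not simulated).
#' @export
setClass("TrialSchedule",
  representation(blocks = "data.frame", habituationS = "numeric"),
  validity = function(object) {
    b <- object@blocks
    msg <- NULL
    if (!all(c("condition", "t_start_s", "duration_s") %in% names(b)))
      return("blocks needs columns condition, t_start_s, duration_s")
    if (!all(b$condition %in% c("OFF", "ON_CONT", "CL", "RANDOM")))
      msg <- c(msg, "unknown condition")
    if (nrow(b) > 1L) {
      ends <- b$t_start_s + b$duration_s
      if (any(abs(b$t_start_s[-1L] - ends[-nrow(b)]) > 1e-9))
        msg <- c(msg, "blocks must be contiguous and non-overlapping")
    }
    if (any(b$duration_s <= 0)) msg <- c(msg, "durations must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' Bin-level confusion counts over a decision stream
#'
#' Decision bins are scored against the early-detection periods (Ep): a
#' positive bin inside an Ep is a true positive, a negative bin inside an Ep a
#' false negative; outside Ep and outside grooming, positives are false
#' positives and negatives true negatives. Bins inside a grooming event but
#' after its Ep end are excluded from all counts. \code{missedEvents} counts
#' grooming events whose Ep contains no positive bin (event-level misses).
#'
#' @slot TP,FP,TN,FN,excluded nonnegative bin counts.
#' @slot missedEvents number of grooming events with no positive bin in Ep.
#' @slot totalBins total number of scored decision bins.
#' @export
setClass("ConfusionCounts",
  representation(TP = "integer", FP = "integer", TN = "integer",
                 FN = "integer", excluded = "integer",
                 missedEvents = "integer", totalBins = "integer"),
  validity = function(object) {
    counts <- c(object@TP, object@FP, object@TN, object@FN, object@excluded)
    msg <- NULL
    if (any(counts < 0)) msg <- c(msg, "counts must be nonnegative")
    if (sum(counts) != object@totalBins)
      msg <- c(msg, "TP+FP+TN+FN+excluded must equal totalBins")
    if (is.null(msg)) TRUE else msg
  })

#' Band-power ramp summary
#'
#' Result of the rising-point analysis of an event-anchored band-power curve:
#' the time, relative to onset, at which the pre-onset power increase begins
#' its sustained rise, and the frequency at maximal spectrogram power.
#'
#' @slot risingPointS rising point (s, relative to onset; expected negative);
#'   \code{NA} when the curve is flat (no ramp).
#' @slot freqAtMaxPowerHz frequency at the spectrogram power maximum (Hz).
#' @slot bandHz two-element band (Hz) over which the curve was computed.
#' @export
setClass("RampSummary",
  representation(risingPointS = "numeric", freqAtMaxPowerHz = "numeric",
                 bandHz = "numeric"),
  validity = function(object) {
    if (length(object@bandHz) == 2L && object@bandHz[1L] >= object@bandHz[2L])
      "band low must be below band high" else TRUE
  })
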