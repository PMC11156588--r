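#' Behavior generation model
#'
#' Parameters of the synthetic behavior generator. Grooming onsets follow a
#' gamma-renewal process (shape 2) at the configured rate -- a renewal rather
#' than Poisson process so that unrealistically short inter-bout intervals
#' are avoided and bouts never overlap. Bout durations are log-normal
#' (defaults give a mean bout of about 4 s, matching roughly 50 s of
#' early-detection-period time per 10-min session at 12.9 bouts). The time
#' between bouts is tiled with other behaviors by a semi-Markov chain with
#' label-specific exponential dwell times.
#'
#' @param groomingRatePer10min mean grooming bouts per 10 minutes
#'   (default 12.9).
#' @param boutMeanlog,boutSdlog log-normal bout duration parameters
#'   (log-seconds); defaults \code{log(4) - 0.125} and \code{0.5} give a mean
#'   of 4 s.
#' @param sessionDurationS session length (s); default 600.
#' @param otherBehaviors data.frame with columns \code{label}, \code{weight},
#'   \code{meanDwellS} describing the non-grooming behavior menu.
#' @param seed integer RNG seed.
#' @return a list of class \code{BehaviorModel}.
#' @export
behaviorModel <- function(groomingRatePer10min = 12.9,
                          boutMeanlog = log(4) - 0.125, boutSdlog = 0.5,
                          sessionDurationS = 600,
                          otherBehaviors = NULL, seed = 1L) {
  if (groomingRatePer10min < 0) stop("rate must be >= 0")
  if (sessionDurationS <= 0) stop("sessionDurationS must be positive")
  if (is.null(otherBehaviors))
    otherBehaviors <- data.frame(
      label = c("resting", "walking", "rearing", "scratching", "other"),
      weight = c(0.35, 0.25, 0.15, 0.10, 0.15),
      meanDwellS = c(20, 8, 4, 3, 5))
  structure(list(groomingRatePer10min = groomingRatePer10min,
                 boutMeanlog = boutMeanlog, boutSdlog = boutSdlog,
                 sessionDurationS = sessionDurationS,
                 otherBehaviors = otherBehaviors, seed = as.integer(seed)),
            class = "BehaviorModel")
}

#' Simulate a session of behavioral annotations
#'
#' Draws grooming bouts from the gamma-renewal model and tiles the remaining
#' time with the other-behavior menu. Generated annotations pass
#' \code{\link{cleanGroomingEvents}} unchanged: inter-bout gaps are at least
#' 1 s and bout durations at least 1 s.
#'
#' @param model a \code{\link{behaviorModel}}.
#' @return a \linkS4class{BehaviorAnnotation}.
#' @examples
#' ann <- simulateBehavior(behaviorModel(seed = 7))
#' nrow(groomingEvents(ann))
#' @export
simulateBehavior <- function(model) {
  stopifnot(inherits(model, "BehaviorModel"))
  set.seed(model$seed)
  dur <- model$sessionDurationS
  meanBout <- exp(model$boutMeanlog + model$boutSdlog^2 / 2)
  if (dur < meanBout)
    warning("session shorter than one mean bout; annotation may be empty")
  onsets <- numeric(0)
  offsets <- numeric(0)
  if (model$groomingRatePer10min > 0) {
    meanIbi <- 600 / model$groomingRatePer10min
    t <- 0
    lastOff <- -Inf
    repeat {
      t <- t + rgamma(1L, shape = 2, scale = meanIbi / 2)
      # a new bout cannot begin during, or within 1 s of, the previous one
      t <- max(t, lastOff + 1.05)
      d <- rlnorm(1L, model$boutMeanlog, model$boutSdlog)
      while (d < 1) d <- rlnorm(1L, model$boutMeanlog, model$boutSdlog)
      if (t + d > dur) break
      onsets <- c(onsets, t)
      offsets <- c(offsets, t + d)
      lastOff <- t + d
    }
  }
  groom <- data.frame(label = rep("grooming", length(onsets)),
                      onset_s = onsets, offset_s = offsets)
  # tile the gaps with the other-behavior semi-Markov chain
  menu <- model$otherBehaviors
  gapStart <- c(0, offsets)
  gapEnd <- c(onsets, dur)
  other <- list()
  for (i in seq_along(gapStart)) {
    t <- gapStart[i]
    while (t < gapEnd[i] - 1e-9) {
      lab <- sample(menu$label, 1L, prob = menu$weight)
      dwell <- max(0.5, rexp(1L, 1 / menu$meanDwellS[menu$label == lab]))
      end <- min(t + dwell, gapEnd[i])
      if (end - t > 1e-6)
        other[[length(other) + 1L]] <- data.frame(label = lab, onset_s = t,
                                                  offset_s = end)
      t <- end
    }
  }
  ev <- rbind(groom, do.call(rbind, other))
  BehaviorAnnotation(ev, dur)
}

#' Biomarker (LFP) generation model
#'
#' Parameters of the synthetic LFP generator: a 1/f^alpha Gaussian background
#' per channel plus, around each grooming onset, a narrowband stochastic
#' oscillation centered at \code{rampPeakFreqHz} whose amplitude ramps
#' linearly from zero starting \code{rampStartSBeforeOnset} seconds before
#' onset, holds its peak through 0.5 s after onset, and is then tapered off.
#' Channels share event timing but carry independent noise and independent
#' oscillation realizations. \code{rampAmplitudeRel} is the peak oscillation
#' power relative to the background power inside the oscillation band; the
#' default of 8 puts the pre-onset 1.5-3 Hz band-power ratio versus rest
#' around 3.5-4, the clearly-detectable regime.
#'
#' @param rampStartSBeforeOnset ramp start before onset (s); default 0.9.
#' @param rampPeakFreqHz oscillation center frequency (Hz); default 2.
#' @param rampBandwidthHz spectral half-width of the oscillation band
#'   (Gaussian sd = bandwidth/2); default 1 (a 2 +/- 1 Hz oscillation).
#' @param rampAmplitudeRel peak oscillation power relative to background
#'   band power; default 8. Zero injects no signal.
#' @param backgroundExponent alpha in the 1/f^alpha background; default 1.
#' @param channelJitter relative per-channel amplitude variability
#'   (uniform +/- jitter); default 0.2.
#' @param rateHz simulation sampling rate (Hz); default 1000. The biomarker
#'   lives below 13 Hz, so a moderate rate suffices; the nominal 20 kHz
#'   acquisition rate only matters for reduction-ratio bookkeeping.
#' @param seed integer RNG seed.
#' @return a list of class \code{BiomarkerModel}.
#' @export
biomarkerModel <- function(rampStartSBeforeOnset = 0.9, rampPeakFreqHz = 2,
                           rampBandwidthHz = 1, rampAmplitudeRel = 8,
                           backgroundExponent = 1, channelJitter = 0.2,
                           rateHz = 1000, seed = 1L) {
  if (rampStartSBeforeOnset <= 0) stop("rampStartSBeforeOnset must be > 0")
  if (rampPeakFreqHz <= 0 || rampPeakFreqHz >= rateHz / 2)
    stop("rampPeakFreqHz must lie within (0, rate/2)")
  structure(list(rampStartSBeforeOnset = rampStartSBeforeOnset,
                 rampPeakFreqHz = rampPeakFreqHz,
                 rampBandwidthHz = rampBandwidthHz,
                 rampAmplitudeRel = rampAmplitudeRel,
                 backgroundExponent = backgroundExponent,
                 channelJitter = channelJitter, rateHz = rateHz,
                 seed = as.integer(seed)),
            class = "BiomarkerModel")
}

# colored Gaussian noise with power spectrum |S(f)|^2 on an n-sample grid,
# scaled to unit variance; shape(f) gives amplitude weights for f > 0
.shapedNoise <- function(n, rate, shape) {
  f <- seq(0, rate, length.out = n + 1L)[seq_len(n)]
  f[f > rate / 2] <- rate - f[f > rate / 2]  # two-sided frequency magnitudes
  w <- shape(f)
  w[1L] <- 0
  x <- Re(fft(fft(rnorm(n)) * w, inverse = TRUE)) / n
  s <- sd(x)
  if (s > 0) x / s else x
}

# flatten the slow amplitude envelope of a narrowband noise trace so that
# its local (~1 s) power is steady: the deterministic event ramp then sets
# the burst amplitude, not the oscillation's own chance envelope
.levelNoise <- function(x, rate) {
  n <- length(x)
  k <- round(rate)
  box <- c(rep(1 / k, ceiling(k / 2)), rep(0, n - k),
           rep(1 / k, floor(k / 2)))
  ms <- Re(fft(fft(x^2) * Conj(fft(box)), inverse = TRUE)) / n
  y <- x / sqrt(pmax(ms, 1e-3 * mean(x^2)))
  y / sd(y)
}

#' Simulate a multi-channel LFP recording for an annotated session
#'
#' @param ann a \linkS4class{BehaviorAnnotation} giving event timing.
#' @param model a \code{\link{biomarkerModel}}.
#' @param nChannels number of electrodes.
#' @param preRollS seconds of signal generated before time zero (stored as a
#'   negative recording start time); gives the streaming engine its feature
#'   history at the first scheduled decision. Default 0.
#' @return a \linkS4class{Recording} of duration
#'   \code{sessionDuration(ann) + preRollS} starting at \code{-preRollS}.
#' @export
simulateLfp <- function(ann, model, nChannels, preRollS = 0) {
  stopifnot(is(ann, "BehaviorAnnotation"), inherits(model, "BiomarkerModel"))
  set.seed(model$seed)
  rate <- model$rateHz
  f0 <- model$rampPeakFreqHz
  bw <- model$rampBandwidthHz
  if (f0 + bw >= rate / 2)
    stop("oscillation band violates the Nyquist limit")
  t0 <- -preRollS
  n <- round((sessionDuration(ann) + preRollS) * rate)
  alpha <- model$backgroundExponent

  # shared amplitude envelope: linear rise before onset, peak held through
  # onset + 0.5 s, 0.1-s cosine release
  tt <- seq_len(n) / rate + t0
  env <- numeric(n)
  g <- groomingEvents(ann)
  rs <- model$rampStartSBeforeOnset
  for (i in seq_len(nrow(g))) {
    on <- g$onset_s[i]
    rise <- tt >= on - rs & tt < on
    env[rise] <- pmax(env[rise], (tt[rise] - (on - rs)) / rs)
    hold <- tt >= on & tt < on + 0.5
    env[hold] <- 1
    rel <- tt >= on + 0.5 & tt < on + 0.6
    env[rel] <- pmax(env[rel], 0.5 + 0.5 * cos(pi * (tt[rel] - on - 0.5) / 0.1))
  }

  # oscillation amplitude from the requested power ratio: background band
  # power inside [f0 - bw, f0 + bw] for a unit-variance 1/f^alpha background
  fGrid <- seq(0.25, rate / 2, by = 0.25)
  bgShape <- pmax(fGrid, 0.5)^(-alpha)
  bandFrac <- sum(bgShape[fGrid >= f0 - bw & fGrid <= f0 + bw]) / sum(bgShape)
  A <- sqrt(model$rampAmplitudeRel * bandFrac)

  samples <- matrix(0, nrow = nChannels, ncol = n)
  for (ch in seq_len(nChannels)) {
    bg <- .shapedNoise(n, rate, function(f) pmax(f, 0.5)^(-alpha / 2))
    gain <- 1 + model$channelJitter * runif(1L, -1, 1)
    x <- gain * bg
    if (model$rampAmplitudeRel > 0 && any(env > 0)) {
      osc <- .levelNoise(.shapedNoise(
        n, rate, function(f) exp(-(f - f0)^2 / (2 * (bw / 2)^2))), rate)
      x <- x + gain * A * env * osc
    }
    samples[ch, ] <- x
  }
  Recording(samples, rateHz = rate, t0 = t0)
}

#' Stimulation response model
#'
#' A simple in-silico model of the behavioral effect of striatal
#' stimulation: a grooming bout whose pre-onset window
#' \code{[onset - suppressionWindowS, onset]} overlaps any stimulation
#' interval is cancelled with probability \code{pSuppress}. The model is a
#' package device for end-to-end simulation; it is not fit to data.
#'
#' @param suppressionWindowS pre-onset window length (s); default 2.
#' @param pSuppress cancellation probability in [0, 1]; default 0.7.
#' @param seed integer RNG seed.
#' @return a list of class \code{StimulationResponseModel}.
#' @export
stimulationResponseModel <- function(suppressionWindowS = 2,
                                     pSuppress = 0.7, seed = 1L) {
  if (pSuppress < 0 || pSuppress > 1) stop("pSuppress must lie in [0, 1]")
  structure(list(suppressionWindowS = suppressionWindowS,
                 pSuppress = pSuppress, seed = as.integer(seed)),
            class = "StimulationResponseModel")
}

#' Apply the stimulation response model to an annotation
#'
#' Removes each grooming bout whose pre-onset window overlaps a stimulation
#' interval with probability \code{pSuppress}; non-grooming events are
#' conserved exactly. For continuous-ON trials, pass the whole trial as one
#' stimulation interval.
#'
#' @param ann a \linkS4class{BehaviorAnnotation}.
#' @param stimEvents data.frame with columns \code{t_start_s},
#'   \code{duration_s} (an empty data.frame leaves \code{ann} unchanged).
#' @param model a \code{\link{stimulationResponseModel}}.
#' @return the modified \linkS4class{BehaviorAnnotation}.
#' @export
applyStimulationEffect <- function(ann, stimEvents, model) {
  stopifnot(is(ann, "BehaviorAnnotation"),
            inherits(model, "StimulationResponseModel"))
  ev <- events(ann)
  if (!nrow(ev) || is.null(stimEvents) || !nrow(stimEvents) ||
      model$pSuppress == 0)
    return(ann)
  set.seed(model$seed)
  s0 <- stimEvents$t_start_s
  s1 <- s0 + stimEvents$duration_s
  keep <- rep(TRUE, nrow(ev))
  gi <- which(ev$label == "grooming")
  for (i in gi) {
    w0 <- ev$onset_s[i] - model$suppressionWindowS
    w1 <- ev$onset_s[i]
    covered <- any(s0 < w1 & s1 > w0)
    if (covered && runif(1L) < model$pSuppress) keep[i] <- FALSE
  }
  BehaviorAnnotation(ev[keep, , drop = FALSE], sessionDuration(ann))
}

#' Build a labeled window dataset and split it 70/30
#'
#' Extracts labeled 1-s analysis windows from one or more annotated
#' sessions: class \code{"pregrooming"} windows lie inside
#' \code{[onset - 2 s, onset]} of each grooming event (two window
#' placements per event, ending at onset and 0.2 s before it -- the part of
#' the labeling interval the detector must recognize at decision time);
#' class
#' \code{"other"} windows are sampled, in equal number, from annotated
#' non-grooming behaviors at least 2.5 s away from any grooming bout. The
#' pooled windows are shuffled and split randomly into disjoint training
#' (70\%) and test (30\%) sets.
#'
#' @param recordings list of \linkS4class{Recording} (one per session);
#'   only used to bound window placement, may be \code{NULL} to skip that
#'   check.
#' @param annotations list of \linkS4class{BehaviorAnnotation}.
#' @param split two fractions summing to 1; default \code{c(0.7, 0.3)}.
#' @param seed integer RNG seed (same seed, same split).
#' @param windowS analysis window length (s); default 1.
#' @param minWindows minimum pooled windows required; default 100.
#' @param warmupS earliest usable window end (s), so that the feature stage
#'   has its history; default 2.
#' @return list with data.frames \code{train} and \code{test}, each with
#'   columns \code{session}, \code{label}, \code{t_end_s}, \code{event_id}.
#' @export
buildLabeledDataset <- function(recordings, annotations, split = c(0.7, 0.3),
                                seed = 1L, windowS = 1, minWindows = 100L,
                                warmupS = 2) {
  stopifnot(abs(sum(split) - 1) < 1e-9, length(split) == 2L)
  if (is(annotations, "BehaviorAnnotation")) annotations <- list(annotations)
  set.seed(as.integer(seed))
  rows <- list()
  for (s in seq_along(annotations)) {
    ann <- annotations[[s]]
    maxEnd <- sessionDuration(ann)
    if (!is.null(recordings))
      maxEnd <- min(maxEnd, startTime(recordings[[s]]) +
                              duration(recordings[[s]]))
    g <- groomingEvents(ann)
    for (i in seq_len(nrow(g))) {
      ends <- g$onset_s[i] - c(0, 0.2)
      ends <- ends[ends - windowS >= g$onset_s[i] - 2 & ends >= warmupS &
                     ends <= maxEnd]
      if (length(ends))
        rows[[length(rows) + 1L]] <- data.frame(
          session = s, label = "pregrooming", t_end_s = ends, event_id = i)
    }
    nPos <- sum(vapply(rows, function(r)
      sum(r$session == s & r$label == "pregrooming"), numeric(1)))
    # candidate negative ends: inside non-grooming intervals, clear of every
    # grooming bout (2.5 s before onset through 0.5 s after offset)
    ev <- events(ann)
    og <- ev[ev$label != "grooming", , drop = FALSE]
    cand <- numeric(0)
    for (i in seq_len(nrow(og))) {
      lo <- max(og$onset_s[i] + windowS, warmupS)
      hi <- min(og$offset_s[i], maxEnd)
      if (hi > lo)
        cand <- c(cand, runif(max(1L, ceiling((hi - lo) / 4)), lo, hi))
    }
    if (nrow(g)) {
      bad <- .inIntervals(cand, g$onset_s - 2.5, g$offset_s + 0.5) |
        .inIntervals(cand - windowS, g$onset_s - 2.5, g$offset_s + 0.5)
      cand <- cand[!bad]
    }
    if (length(cand) && nPos > 0) {
      take <- sample(cand, min(length(cand), nPos))
      rows[[length(rows) + 1L]] <- data.frame(
        session = s, label = "other", t_end_s = take, event_id = NA_integer_)
    }
  }
  windows <- do.call(rbind, rows)
  if (is.null(windows) || !any(windows$label == "pregrooming"))
    stop("no pregrooming windows available; simulate more grooming events")
  if (nrow(windows) < minWindows)
    stop("only ", nrow(windows), " labeled windows available (minimum ",
         minWindows, "); simulate longer or more sessions")
  windows <- windows[sample(nrow(windows)), , drop = FALSE]
  rownames(windows) <- NULL
  nTrain <- round(split[1L] * nrow(windows))
  list(train = windows[seq_len(nTrain), , drop = FALSE],
       test = windows[-seq_len(nTrain), , drop = FALSE])
}
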