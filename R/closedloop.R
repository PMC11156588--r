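#' Build a stimulation trial schedule
#'
#' \code{"closed_loop"}: four cycles of OFF, CL, RANDOM trials of 3 min each
#' (12 trials, 36 min). \code{"continuous"}: five interleaved OFF and ON
#' trials of 3 min (10 trials, 30 min). \code{"assessment"}: a single OFF
#' block (default 10 min) in which decisions are logged without any
#' stimulation, the configuration used to measure classifier performance
#' independent of neuromodulation.
#'
#' @param protocol one of \code{"closed_loop"}, \code{"continuous"},
#'   \code{"assessment"}.
#' @param trialS trial length (s); default 180.
#' @param assessmentS assessment-block length (s); default 600.
#' @param habituationS habituation metadata (s); default 600 (not simulated).
#' @return a \linkS4class{TrialSchedule}.
#' @examples
#' buildSchedule("closed_loop")
#' @export
buildSchedule <- function(protocol = c("closed_loop", "continuous",
                                       "assessment"),
                          trialS = 180, assessmentS = 600,
                          habituationS = 600) {
  protocol <- match.arg(protocol)
  cond <- switch(protocol,
    closed_loop = rep(c("OFF", "CL", "RANDOM"), times = 4L),
    continuous = rep(c("OFF", "ON_CONT"), times = 5L),
    assessment = "OFF")
  durs <- if (protocol == "assessment") assessmentS else
    rep(trialS, length(cond))
  starts <- cumsum(c(0, durs[-length(durs)]))
  new("TrialSchedule",
      blocks = data.frame(condition = cond, t_start_s = starts,
                          duration_s = durs),
      habituationS = habituationS)
}

#' Pre-assign randomized (yoked) stimulation events
#'
#' Places \code{n} non-overlapping stimulation events of \code{durationS}
#' seconds uniformly at random within a trial -- the yoked control that
#' delivers the same number of stimulations as the preceding closed-loop
#' trial but at random times. Placement uses the order-statistics
#' construction (sorted uniforms plus accumulated event lengths), which is
#' exactly uniform over non-overlapping configurations.
#'
#' @param n number of events (from the previous CL trial).
#' @param trialStartS trial start time (s).
#' @param trialDurationS trial length (s); default 180.
#' @param durationS event length (s); default 4.
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{t_start_s}, \code{duration_s}
#'   (empty for \code{n = 0}).
#' @export
assignRandomStims <- function(n, trialStartS, trialDurationS = 180,
                              durationS = 4, seed = 1L) {
  n <- as.integer(n)
  if (n < 0L) stop("n must be >= 0")
  if (n == 0L)
    return(data.frame(t_start_s = numeric(0), duration_s = numeric(0)))
  slack <- trialDurationS - n * durationS
  if (slack <= 0)
    stop("cannot fit ", n, " non-overlapping ", durationS,
         "-s events in a ", trialDurationS, "-s trial")
  set.seed(as.integer(seed))
  starts <- sort(runif(n, 0, slack)) + (seq_len(n) - 1L) * durationS
  data.frame(t_start_s = trialStartS + starts,
             duration_s = rep(durationS, n))
}

#' Duty cycle of a stimulation pulse train
#'
#' @param pulseWidthS pulse width (s); default 0.005.
#' @param pulseRateHz pulse rate (Hz); default 20.
#' @return percent of time the light is on within the train
#'   (\code{100 * width * rate}); 10\% at the defaults.
#' @export
dutyCycle <- function(pulseWidthS = 0.005, pulseRateHz = 20) {
  if (pulseWidthS * pulseRateHz > 1)
    stop("pulse width times rate exceeds 1: pulses overlap")
  100 * pulseWidthS * pulseRateHz
}

#' Run the streaming decision engine over a scheduled session
#'
#' Emits a decision every \code{decision_interval_s} (200 ms) on the session
#' grid: per electrode, the M x P feature matrix of the trailing windows is
#' classified, and the electrode votes are combined under the strict-majority
#' policy. In CL blocks a triggered decision emits a 4-s stimulation starting
#' at its timestamp, during which no further decisions are made (lockout).
#' In OFF and RANDOM blocks decisions are still computed and logged for
#' offline evaluation, but never stimulate; RANDOM blocks carry pre-assigned
#' yoked events equal in number to the stimulations of the immediately
#' preceding CL trial. Decisions begin once the recording provides the full
#' feature history (window plus P-1 shifts); recordings with pre-roll
#' (t0 < 0) cover the schedule from its first grid point.
#'
#' @param rec a \linkS4class{Recording} spanning the schedule.
#' @param bank a \linkS4class{ClassifierBank} covering all channels.
#' @param schedule a \linkS4class{TrialSchedule}.
#' @param policy a \linkS4class{VotePolicy}; default strict majority.
#' @param fb the \linkS4class{FilterBank} used for features; must match the
#'   bank's feature configuration.
#' @param cfg session configuration (\code{\link{sessionConfig}}).
#' @param seed integer RNG seed (yoked-event placement).
#' @return list with \code{decisions} (data.frame: \code{t_s},
#'   \code{condition}, \code{positive_fraction}, \code{triggered},
#'   \code{stimulated}) and \code{stimEvents} (data.frame: \code{t_start_s},
#'   \code{duration_s}, \code{condition}, plus pulse-train parameters).
#' @export
runClosedLoop <- function(rec, bank, schedule, policy = votePolicy(),
                          fb = buildFilterbank(), cfg = sessionConfig(),
                          seed = 1L) {
  stopifnot(is(rec, "Recording"), is(bank, "ClassifierBank"),
            is(schedule, "TrialSchedule"))
  ids <- channelIds(rec)
  if (!all(ids %in% names(bank@classifiers)))
    stop("model/channel mismatch: no classifier for channel(s) ",
         paste(setdiff(ids, names(bank@classifiers)), collapse = ", "))
  step <- cfg$decision_interval_s
  P <- cfg$features$P
  winS <- cfg$features$window_s
  histS <- winS + (P - 1L) * step
  blocks <- scheduleBlocks(schedule)
  totalS <- max(blocks$t_start_s + blocks$duration_s)
  t0 <- startTime(rec)
  tEndRec <- t0 + duration(rec)
  if (tEndRec + 1e-9 < totalS)
    stop("recording (", tEndRec, " s) does not span the schedule (",
         totalS, " s)")

  grid <- seq_len(.gridIndex(totalS, step)) * step
  ready <- grid - histS >= t0 - 1e-9
  grid <- grid[ready]
  if (!length(grid)) stop("recording too short for any decision")

  # batch per-electrode classification of every grid point
  x <- lfpSamples(rec)
  gridKey <- .gridIndex(grid, step)
  endKey <- seq(min(gridKey) - (P - 1L), max(gridKey))  # contiguous grid
  allEnds <- endKey * step
  votesPos <- matrix(FALSE, nrow = length(grid), ncol = length(ids))
  for (ch in seq_along(ids)) {
    co <- .windowCoefficients(x[ch, ], rateHz(rec), allEnds, t0, fb, winS,
                              logEnergies = cfg$features$log_energies)
    # P x nGrid window-end indices into endKey (oldest first), by arithmetic
    colIdx <- outer(-(P:1 - 1L), gridKey - endKey[1L] + 1L, "+")
    A <- array(co[, as.vector(colIdx)], dim = c(fb@M, P, length(grid)))
    feat <- t(matrix(aperm(A, c(2L, 1L, 3L)), nrow = P * fb@M))
    pr <- predictElectrode(bank@classifiers[[ids[ch]]], feat)
    votesPos[, ch] <- pr$class == "pregrooming"
  }
  frac <- rowMeans(votesPos)
  positive <- frac > policy@thresholdFraction

  # sequential schedule pass with CL lockout and yoked RANDOM events
  blockOf <- findInterval(grid - 1e-9, blocks$t_start_s)
  stimDur <- cfg$protocol$stim_duration_s
  keep <- logical(length(grid))
  stimmed <- logical(length(grid))
  stimT <- numeric(0)
  stimCond <- character(0)
  lockoutUntil <- -Inf
  lastClCount <- 0L
  curBlock <- 0L
  clCountThisBlock <- 0L
  for (j in seq_along(grid)) {
    t <- grid[j]
    b <- blockOf[j]
    if (b != curBlock) {
      if (curBlock > 0L && blocks$condition[curBlock] == "CL")
        lastClCount <- clCountThisBlock
      curBlock <- b
      clCountThisBlock <- 0L
      if (blocks$condition[b] == "RANDOM" && lastClCount > 0L) {
        rq <- assignRandomStims(
          lastClCount, blocks$t_start_s[b], blocks$duration_s[b], stimDur,
          seed = .childSeed(seed, b))
        stimT <- c(stimT, rq$t_start_s)
        stimCond <- c(stimCond, rep("RANDOM", nrow(rq)))
      }
    }
    if (t <= lockoutUntil + 1e-9) next  # no decision during stimulation
    keep[j] <- TRUE
    if (blocks$condition[b] == "CL" && positive[j]) {
      stimmed[j] <- TRUE
      lockoutUntil <- t + stimDur
      clCountThisBlock <- clCountThisBlock + 1L
      stimT <- c(stimT, t)
      stimCond <- c(stimCond, "CL")
    }
  }
  decisions <- data.frame(t_s = grid[keep],
                          condition = blocks$condition[blockOf[keep]],
                          positive_fraction = frac[keep],
                          triggered = positive[keep],
                          stimulated = stimmed[keep])
  stimEvents <- data.frame(t_start_s = stimT,
                           duration_s = rep(stimDur, length(stimT)),
                           condition = stimCond)
  if (nrow(stimEvents)) {
    stimEvents$pulse_rate_hz <- cfg$protocol$pulse_rate_hz
    stimEvents$pulse_width_s <- cfg$protocol$pulse_width_s
    stimEvents$power_mw <- cfg$protocol$power_mw
    stimEvents <- stimEvents[order(stimEvents$t_start_s), , drop = FALSE]
    rownames(stimEvents) <- NULL
  }
  rownames(decisions) <- NULL
  list(decisions = decisions, stimEvents = stimEvents)
}

#' Stimulation time accounting
#'
#' Total stimulation seconds per condition and as percent of the session.
#' Continuous-ON blocks count their full block time as stimulation time;
#' CL and RANDOM conditions count the summed durations of their events. When
#' both a CL total and a continuous reference exist, the percent reduction
#' of CL stimulation time relative to continuous is included.
#'
#' @param schedule a \linkS4class{TrialSchedule}.
#' @param stimEvents data.frame with \code{t_start_s}, \code{duration_s},
#'   \code{condition}.
#' @param continuousRefS reference continuous-protocol stimulation time (s);
#'   default 900 (five 3-min ON trials).
#' @return list with \code{seconds} (named per condition),
#'   \code{percent_of_session}, and \code{percent_reduction_vs_continuous}.
#' @export
stimulationTime <- function(schedule, stimEvents,
                            continuousRefS = 900) {
  blocks <- scheduleBlocks(schedule)
  totalS <- sum(blocks$duration_s)
  secs <- c(ON_CONT = sum(blocks$duration_s[blocks$condition == "ON_CONT"]),
            CL = sum(stimEvents$duration_s[stimEvents$condition == "CL"]),
            RANDOM = sum(
              stimEvents$duration_s[stimEvents$condition == "RANDOM"]))
  relevant <- names(secs) %in% c(blocks$condition, stimEvents$condition)
  secs <- secs[relevant]
  out <- list(seconds = secs, percent_of_session = 100 * secs / totalS)
  if ("CL" %in% names(secs) && continuousRefS > 0)
    out$percent_reduction_vs_continuous <-
      100 * (1 - unname(secs["CL"]) / continuousRefS)
  out
}
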