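# small in-code fixtures shared across test files

# annotation with explicit events over a resting background
makeAnnotation <- function(events, durationS = 60) {
  BehaviorAnnotation(events, durationS)
}

# single grooming bout plus resting fill
oneBoutAnnotation <- function(onset = 10, offset = 16, durationS = 60) {
  makeAnnotation(data.frame(
    label = c("resting", "grooming", "resting"),
    onset_s = c(0, onset, offset),
    offset_s = c(onset, offset, durationS)), durationS)
}

# pure-tone recording
toneRecording <- function(freqHz, rate = 250, durS = 10, amp = 1,
                          nCh = 1, t0 = 0) {
  t <- seq_len(round(durS * rate)) / rate
  x <- amp * sin(2 * pi * freqHz * t)
  Recording(matrix(rep(x, each = nCh), nrow = nCh), rateHz = rate, t0 = t0)
}

# classifier with constant output: always "pregrooming" or always "other"
constantClassifier <- function(positive = TRUE, d = 35L, id = "ch1") {
  b3 <- if (positive) c(10, -10) else c(-10, 10)
  new("ElectrodeClassifier",
      W1 = matrix(0, d, 2L), b1 = c(0, 0),
      W2 = matrix(0, 2L, 2L), b2 = c(0, 0),
      W3 = matrix(0, 2L, 2L), b3 = b3,
      featMean = rep(0, d), featSd = rep(1, d),
      channelId = id, seed = 0L, epochsRun = 0L)
}

# classifier that fires on high broadband level of the newest window:
# feature 5 (first cosine coefficient of the most recent 1-s window) is
# sqrt(7) * mean log filter energy, ~ -4 on unit background and >> 0 during
# a strong-amplitude burst
levelClassifier <- function(id = "ch1", d = 35L) {
  W1 <- matrix(0, d, 2L); W1[5L, 1L] <- 2
  W2 <- matrix(0, 2L, 2L); W2[1L, 1L] <- 10
  W3 <- matrix(0, 2L, 2L); W3[1L, 1L] <- 20
  new("ElectrodeClassifier", W1 = W1, b1 = c(4, 0), W2 = W2, b2 = c(-5, 0),
      W3 = W3, b3 = c(-10, 0), featMean = rep(0, d), featSd = rep(1, d),
      channelId = id, seed = 0L, epochsRun = 0L)
}

levelBank <- function(ids) {
  clfs <- lapply(ids, levelClassifier)
  names(clfs) <- ids
  new("ClassifierBank", classifiers = clfs,
      featureConfig = sessionConfig()$features)
}

# unit background with strong bursts (x30) of the given duration
burstRecording <- function(burstsAtS, totalS, rate = 250, burstDurS = 1.5,
                           t0 = -2, seed = 1) {
  set.seed(seed)
  n <- round((totalS - t0) * rate)
  x <- rnorm(n)
  tt <- seq_len(n) / rate + t0
  for (b in burstsAtS) x[tt >= b & tt < b + burstDurS] <- 30 * rnorm(
    sum(tt >= b & tt < b + burstDurS))
  Recording(matrix(x, 1), rateHz = rate, t0 = t0)
}

constantBank <- function(ids, positive = TRUE) {
  clfs <- lapply(ids, function(id) constantClassifier(positive, id = id))
  names(clfs) <- ids
  new("ClassifierBank", classifiers = clfs,
      featureConfig = sessionConfig()$features)
}

# independent brute-force bin tally used as the scoring oracle
bruteForceScore <- function(decisions, ann) {
  ep <- computeEp(ann)
  g <- events(ann)
  g <- g[g$label == "grooming", , drop = FALSE]
  tp <- fp <- tn <- fn <- ex <- 0L
  for (i in seq_len(nrow(decisions))) {
    t <- decisions$t_s[i]
    pos <- decisions$triggered[i]
    inEp <- FALSE
    for (j in seq_len(nrow(ep)))
      if (t >= ep$start_s[j] && t < ep$end_s[j]) inEp <- TRUE
    inG <- FALSE
    for (j in seq_len(nrow(g)))
      if (t >= g$onset_s[j] && t < g$offset_s[j]) inG <- TRUE
    if (inEp) {
      if (pos) tp <- tp + 1L else fn <- fn + 1L
    } else if (inG) {
      ex <- ex + 1L
    } else {
      if (pos) fp <- fp + 1L else tn <- tn + 1L
    }
  }
  c(TP = tp, FP = fp, TN = tn, FN = fn, excluded = ex)
}
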