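test_that("zero grooming rate yields zero grooming events", {
  ann <- simulateBehavior(behaviorModel(groomingRatePer10min = 0, seed = 1))
  expect_equal(nrow(groomingEvents(ann)), 0L)
  expect_gt(nrow(events(ann)), 0L)  # time still tiled with other behaviors
})

test_that("bout count calibrates to the configured rate", {
  counts <- vapply(1:400, function(s)
    nrow(groomingEvents(simulateBehavior(behaviorModel(seed = s)))),
    numeric(1))
  expect_lt(abs(mean(counts) / 12.9 - 1), 0.05)
})

test_that("generated annotations satisfy the bout scoring rules", {
  for (s in 1:5) {
    ann <- simulateBehavior(behaviorModel(seed = 100 + s))
    g <- groomingEvents(ann)
    expect_true(all(g$offset_s - g$onset_s >= 1))
    if (nrow(g) > 1)
      expect_true(all(g$onset_s[-1] - head(g$offset_s, -1) >= 1))
    expect_equal(events(cleanGroomingEvents(ann)), events(ann))
  }
})

test_that("identical seeds give bit-identical simulations", {
  a1 <- simulateBehavior(behaviorModel(seed = 9))
  a2 <- simulateBehavior(behaviorModel(seed = 9))
  expect_identical(events(a1), events(a2))
  r1 <- simulateLfp(a1, biomarkerModel(rateHz = 250, seed = 9), 2)
  r2 <- simulateLfp(a2, biomarkerModel(rateHz = 250, seed = 9), 2)
  expect_identical(lfpSamples(r1), lfpSamples(r2))
})

test_that("recording duration matches annotation plus pre-roll", {
  ann <- simulateBehavior(behaviorModel(sessionDurationS = 120, seed = 3))
  rec <- simulateLfp(ann, biomarkerModel(rateHz = 250, seed = 3), 2,
                     preRollS = 3)
  expect_equal(duration(rec), 123)
  expect_equal(startTime(rec), -3)
  expect_error(simulateLfp(ann, biomarkerModel(rampPeakFreqHz = 2,
                                               rampBandwidthHz = 130,
                                               rateHz = 250, seed = 1), 1),
               "[Nn]yquist")
})

test_that("the pre-onset ramp raises band power above rest per event", {
  # strong-amplitude generator: pregrooming band power should beat a
  # resting-epoch window for nearly every event
  rate <- 250
  nPre <- 0; nTot <- 0
  for (s in 1:10) {
    ann <- simulateBehavior(behaviorModel(seed = 700 + s))
    rec <- simulateLfp(ann, biomarkerModel(rampAmplitudeRel = 60,
                                           rateHz = rate, seed = 800 + s), 1,
                       preRollS = 2)
    x <- lfpSamples(rec)[1, ]
    g <- groomingEvents(ann)
    bp <- function(endS) {
      i2 <- round((endS + 2) * rate)
      .psd <- computePsd(x[(i2 - rate + 1):i2], rate)
      sel <- .psd@freqsHz >= 1.5 & .psd@freqsHz <= 3
      sum(.psd@power[sel])
    }
    for (i in seq_len(nrow(g))) {
      restT <- g$onset_s[i] - 8  # far from any ramp?
      if (restT < 1) next
      if (any(g$onset_s - 2 < restT & g$offset_s + 1 > restT - 1)) next
      nTot <- nTot + 1
      nPre <- nPre + (bp(g$onset_s[i]) > bp(restT))
    }
  }
  expect_gte(nTot, 100)
  expect_gt(nPre / nTot, 0.95)
})

test_that("zero ramp amplitude injects no band-power contrast", {
  rate <- 250
  diffs <- vapply(1:6, function(s) {
    ann <- simulateBehavior(behaviorModel(seed = 900 + s))
    rec <- simulateLfp(ann, biomarkerModel(rampAmplitudeRel = 0,
                                           rateHz = rate, seed = 950 + s),
                       1, preRollS = 2)
    x <- lfpSamples(rec)[1, ]
    g <- groomingEvents(ann)
    bp <- function(endS) {
      i2 <- round((endS + 2) * rate)
      p <- computePsd(x[(i2 - rate + 1):i2], rate)
      sum(p@power[p@freqsHz >= 1.5 & p@freqsHz <= 3])
    }
    pre <- vapply(g$onset_s, bp, numeric(1))
    rst <- vapply(pmax(g$onset_s - 8, 1), bp, numeric(1))
    median(pre / rst)
  }, numeric(1))
  # paired band-power ratio centered on 1 over seeds
  expect_lt(abs(median(diffs) - 1), 0.35)
})

test_that("stimulation suppression follows its probability model", {
  on <- seq(10, 5000, by = 10)
  ev <- data.frame(label = "grooming", onset_s = on, offset_s = on + 3)
  ann <- makeAnnotation(ev, 5010)
  stims <- data.frame(t_start_s = on - 1, duration_s = 4)

  unchanged <- applyStimulationEffect(
    ann, stims, stimulationResponseModel(pSuppress = 0, seed = 1))
  expect_identical(events(unchanged), events(ann))

  none <- applyStimulationEffect(
    ann, stims, stimulationResponseModel(pSuppress = 1, seed = 1))
  expect_equal(nrow(groomingEvents(none)), 0L)

  part <- applyStimulationEffect(
    ann, stims, stimulationResponseModel(pSuppress = 0.6, seed = 1))
  surv <- nrow(groomingEvents(part))
  # binomial expectation: 500 * 0.4 survivors, +/- 4 sd
  expect_lt(abs(surv - 200), 4 * sqrt(500 * 0.6 * 0.4))
})

test_that("stimulation effect conserves non-grooming events exactly", {
  ann <- simulateBehavior(behaviorModel(seed = 77))
  g <- groomingEvents(ann)
  stims <- data.frame(t_start_s = g$onset_s - 1, duration_s = 4)
  out <- applyStimulationEffect(ann, stims,
                                stimulationResponseModel(seed = 5))
  other <- function(a) {
    ev <- events(a)
    ev <- ev[ev$label != "grooming", ]
    rownames(ev) <- NULL
    ev
  }
  expect_equal(other(out), other(ann))
})

test_that("labeled datasets split 70/30, disjoint and reproducible", {
  anns <- lapply(1:4, function(s)
    simulateBehavior(behaviorModel(seed = 40 + s)))
  ds <- buildLabeledDataset(NULL, anns, seed = 5)
  n <- nrow(ds$train) + nrow(ds$test)
  expect_gte(n, 100)
  expect_equal(nrow(ds$train), round(0.7 * n))
  keyOf <- function(d) paste(d$session, d$label, d$t_end_s)
  expect_length(intersect(keyOf(ds$train), keyOf(ds$test)), 0L)
  ds2 <- buildLabeledDataset(NULL, anns, seed = 5)
  expect_identical(ds, ds2)
  # window classes and placement within the labeling interval
  pos <- ds$train[ds$train$label == "pregrooming", ]
  for (j in seq_len(min(20, nrow(pos)))) {
    g <- groomingEvents(anns[[pos$session[j]]])
    on <- g$onset_s[pos$event_id[j]]
    expect_gte(pos$t_end_s[j], on - 2 + 1)  # window inside [onset-2, onset]
    expect_lte(pos$t_end_s[j], on)
  }
})

test_that("dataset construction fails without enough material", {
  annNo <- simulateBehavior(behaviorModel(groomingRatePer10min = 0,
                                          seed = 1))
  expect_error(buildLabeledDataset(NULL, list(annNo), seed = 1),
               "pregrooming")
  annFew <- simulateBehavior(behaviorModel(sessionDurationS = 120,
                                           seed = 2))
  expect_error(buildLabeledDataset(NULL, list(annFew), seed = 1),
               "minimum")
})
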