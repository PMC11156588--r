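test_that("early-detection periods follow the -2 s to half-duration rule", {
  ann <- oneBoutAnnotation(onset = 10, offset = 16)
  ep <- computeEp(ann)
  expect_equal(c(ep$start_s, ep$end_s), c(8, 13))

  annEdge <- oneBoutAnnotation(onset = 1, offset = 5)
  expect_equal(computeEp(annEdge)$start_s, 0)  # clipped to session start

  annNone <- makeAnnotation(data.frame(label = "resting", onset_s = 0,
                                       offset_s = 60), 60)
  expect_equal(nrow(computeEp(annNone)), 0L)
})

test_that("degenerate decision streams score as expected", {
  ann <- oneBoutAnnotation(onset = 10, offset = 16, durationS = 20)
  bins <- seq(0.2, 20, by = 0.2)
  epBins <- sum(bins >= 8 & bins < 13)

  allPos <- data.frame(t_s = bins, triggered = TRUE)
  cp <- scoreDecisions(allPos, ann)
  expect_equal(cp@TP, epBins)
  expect_equal(cp@FN, 0L)
  expect_equal(cp@TN, 0L)

  allNeg <- data.frame(t_s = bins, triggered = FALSE)
  cn <- scoreDecisions(allNeg, ann)
  expect_equal(cn@FN, epBins)
  expect_equal(cn@TP, 0L)
  expect_equal(cn@FP, 0L)
  expect_equal(cn@missedEvents, 1L)
  # late-grooming bins (after Ep end, before offset) are excluded
  expect_equal(cn@excluded, sum(bins >= 13 & bins < 16))
})

test_that("a hand-built 20-bin toy session matches manual enumeration", {
  # grooming [2, 4): Ep = [0, 3); bins at 0.2..4.0
  ann <- makeAnnotation(data.frame(label = "grooming", onset_s = 2,
                                   offset_s = 4), 4)
  dec <- data.frame(
    t_s = seq(0.2, 4, by = 0.2),
    triggered = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE,
                  TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE,
                  TRUE, FALSE, TRUE, FALSE))
  cc <- scoreDecisions(dec, ann)
  # Ep bins: t in [0, 3) -> 0.2..2.8 (14 bins, 7 positive); late-grooming
  # bins 3.0..3.8 excluded; bin 4.0 (grooming ended, half-open) negative
  expect_equal(confusionVector(cc)[c("TP", "FP", "TN", "FN", "excluded")],
               c(TP = 7L, FP = 0L, TN = 1L, FN = 7L, excluded = 5L))
})

test_that("bin scoring matches the brute-force oracle on random sessions", {
  set.seed(33)
  for (k in 1:200) {
    dur <- 20
    n <- sample(0:3, 1)
    ev <- NULL
    t <- 1
    for (i in seq_len(n)) {
      on <- t + runif(1, 0, 4)
      off <- on + runif(1, 1, 3)
      ev <- rbind(ev, data.frame(label = "grooming", onset_s = on,
                                 offset_s = off))
      t <- off + 1.2
    }
    ann <- if (is.null(ev))
      makeAnnotation(data.frame(label = "resting", onset_s = 0,
                                offset_s = dur), dur)
    else makeAnnotation(ev, dur)
    dec <- data.frame(t_s = seq(0.2, dur, by = 0.2),
                      triggered = runif(100) < 0.5)
    cc <- confusionVector(scoreDecisions(dec, ann))
    oracle <- bruteForceScore(dec, ann)
    expect_identical(cc[names(oracle)], oracle)
    # bins conserved
    expect_equal(sum(cc[c("TP", "FP", "TN", "FN", "excluded")]),
                 nrow(dec))
  }
})

test_that("metrics follow their defining ratios", {
  mk <- function(tp, fp, tn, fn)
    new("ConfusionCounts", TP = tp, FP = fp, TN = tn, FN = fn,
        excluded = 0L, missedEvents = 0L,
        totalBins = tp + fp + tn + fn)
  m <- metricReport(mk(5L, 5L, 45L, 45L))
  expect_equal(unname(m), c(50, 10, 50, 90))
  m2 <- metricReport(mk(25L, 25L, 25L, 25L))
  expect_equal(unname(m2), rep(50, 4))
  m3 <- metricReport(mk(10L, 0L, 5L, 0L))
  expect_equal(unname(m3[c("precision", "sensitivity")]), c(100, 100))
  expect_warning(m4 <- metricReport(mk(0L, 0L, 10L, 0L)), "undefined")
  expect_true(is.na(m4["precision"]))
})

test_that("sensitivity depends only on Ep bins, specificity only on rest", {
  ann <- oneBoutAnnotation(onset = 10, offset = 16, durationS = 30)
  bins <- seq(0.2, 30, by = 0.2)
  set.seed(7)
  base <- runif(length(bins)) < 0.5
  inEp <- bins >= 8 & bins < 13
  flipOut <- base
  flipOut[!inEp] <- !flipOut[!inEp]
  m1 <- suppressWarnings(metricReport(scoreDecisions(
    data.frame(t_s = bins, triggered = base), ann)))
  m2 <- suppressWarnings(metricReport(scoreDecisions(
    data.frame(t_s = bins, triggered = flipOut), ann)))
  expect_equal(m1["sensitivity"], m2["sensitivity"])
  flipIn <- base
  flipIn[inEp] <- !flipIn[inEp]
  m3 <- suppressWarnings(metricReport(scoreDecisions(
    data.frame(t_s = bins, triggered = flipIn), ann)))
  expect_equal(m1["specificity"], m3["specificity"])
})

test_that("the pseudorandom baseline converges to 50% at large n", {
  ann <- simulateBehavior(behaviorModel(sessionDurationS = 2000, seed = 2))
  pb <- pseudorandomBaseline(ann, nRuns = 10, seed = 4)
  expect_lt(abs(pb["sensitivity"] - 50), 2)
  expect_lt(abs(pb["specificity"] - 50), 2)
  expect_lt(abs(pb["accuracy"] - 50), 2)
  annNone <- makeAnnotation(data.frame(label = "resting", onset_s = 0,
                                       offset_s = 60), 60)
  expect_error(pseudorandomBaseline(annNone), "grooming")
})

test_that("behavioral endpoint formulas are exact", {
  expect_equal(groomingReduction(20, 8)$bouts, 60)
  expect_equal(groomingReduction(10, 10)$bouts, 0)
  expect_equal(groomingReduction(10, 0)$bouts, 100)
  r <- groomingReduction(20, 8, 100, 30)
  expect_equal(r$duration, 70)
  expect_error(groomingReduction(0, 5), "positive")

  expect_equal(interraterError(10, 9), 10)
  expect_equal(interraterError(10, 10), 0)
  expect_equal(interraterError(10, 11), -10)
  expect_error(interraterError(0, 1), "nonzero")
})

test_that("session reports are internally consistent", {
  rate <- 250
  sch <- buildSchedule("closed_loop", trialS = 30)
  totalS <- sum(scheduleBlocks(sch)$duration_s)
  ann <- simulateBehavior(behaviorModel(sessionDurationS = totalS,
                                        seed = 12))
  set.seed(3)
  rec <- Recording(matrix(rnorm((totalS + 2) * rate), 1), rateHz = rate,
                   t0 = -2)
  run <- runClosedLoop(rec, constantBank("ch1", FALSE), sch,
                       cfg = sessionConfig(n_channels = 1))
  rep <- evaluateSession(run, sch, ann)
  expect_equal(sum(rep$per_condition$grooming_bouts),
               nrow(groomingEvents(ann)))
  expect_equal(sum(rep$per_condition$time_s), totalS)
  v <- confusionVector(rep$confusion)
  expect_equal(unname(sum(v[1:5])), nrow(run$decisions))
  # OFF-only assessment: no stimulation accounting
  schA <- buildSchedule("assessment", assessmentS = totalS)
  runA <- runClosedLoop(rec, constantBank("ch1", FALSE), schA,
                        cfg = sessionConfig(n_channels = 1))
  repA <- evaluateSession(runA, schA, ann)
  expect_null(repA$stimulation)
  f <- withr::local_tempfile(fileext = ".json")
  writeReport(repA, f)
  expect_true(file.exists(f))
  expect_true(file.exists(sub("\\.json$", "_conditions.csv", f)))
})
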