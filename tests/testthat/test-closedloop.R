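test_that("protocol schedules match their block structure", {
  cl <- buildSchedule("closed_loop")
  b <- scheduleBlocks(cl)
  expect_equal(nrow(b), 12L)
  expect_equal(b$condition, rep(c("OFF", "CL", "RANDOM"), 4))
  expect_true(all(b$duration_s == 180))
  expect_equal(sum(b$duration_s), 2160)

  co <- buildSchedule("continuous")
  bc <- scheduleBlocks(co)
  expect_equal(nrow(bc), 10L)
  expect_equal(bc$condition, rep(c("OFF", "ON_CONT"), 5))
  expect_equal(sum(bc$duration_s), 1800)

  # contiguity: each block starts where the previous ends
  expect_equal(b$t_start_s[-1], head(b$t_start_s + b$duration_s, -1))
  expect_equal(max(bc$t_start_s + bc$duration_s), 1800)
})

test_that("yoked random stimulations fit, avoid overlap, and reproduce", {
  expect_equal(nrow(assignRandomStims(0, 0)), 0L)
  expect_error(assignRandomStims(45, 0), "cannot fit")
  for (s in 1:20) {
    ev <- assignRandomStims(10, 100, seed = s)
    expect_equal(nrow(ev), 10L)
    expect_true(all(ev$t_start_s >= 100))
    expect_true(all(ev$t_start_s + ev$duration_s <= 280 + 1e-9))
    expect_true(all(diff(ev$t_start_s) >= 4 - 1e-9))
  }
  expect_identical(assignRandomStims(5, 0, seed = 3),
                   assignRandomStims(5, 0, seed = 3))
})

test_that("single random stimulation start times are uniform", {
  starts <- vapply(1:2000, function(s)
    assignRandomStims(1, 0, seed = s)$t_start_s, numeric(1))
  ks <- suppressWarnings(ks.test(starts, "punif", 0, 176))
  expect_gt(ks$p.value, 0.01)
})

test_that("pulse-train duty cycle follows width times rate", {
  expect_equal(dutyCycle(0.005, 20), 10)
  expect_equal(dutyCycle(0.025, 20), 50)
  expect_equal(dutyCycle(0, 20), 0)
  expect_error(dutyCycle(0.06, 20), "overlap")
})

test_that("a trigger-free schedule emits the full decision grid", {
  rate <- 250
  sch <- buildSchedule("closed_loop", trialS = 60)  # 12 x 1 min
  totalS <- sum(scheduleBlocks(sch)$duration_s)
  rec <- Recording(matrix(rnorm(2 * (totalS + 2) * rate), 2),
                   rateHz = rate, t0 = -2)
  bank <- constantBank(c("ch1", "ch2"), positive = FALSE)
  run <- runClosedLoop(rec, bank, sch, cfg = sessionConfig(n_channels = 2))
  expect_equal(nrow(run$decisions), totalS / 0.2)
  expect_equal(nrow(run$stimEvents), 0L)
  expect_false(any(run$decisions$triggered))
  # timestamps form the exact 200-ms grid
  expect_equal(run$decisions$t_s, seq(0.2, totalS, by = 0.2))
})

test_that("stimulation lockout removes 4 s of decisions per trigger", {
  rate <- 250
  sch <- buildSchedule("assessment", assessmentS = 60)
  # assessment blocks never stimulate even for an always-positive bank
  rec <- Recording(matrix(rnorm(60 * rate + 500), 1), rateHz = rate, t0 = -2)
  bank <- constantBank("ch1", positive = TRUE)
  cfg1 <- sessionConfig(n_channels = 1)
  runA <- runClosedLoop(rec, bank, sch, cfg = cfg1)
  expect_equal(nrow(runA$stimEvents), 0L)
  expect_equal(nrow(runA$decisions), 300L)

  # one CL trial with three well-separated trigger bursts: each 4-s
  # stimulation removes exactly 20 decision bins
  schCL <- new("TrialSchedule",
               blocks = data.frame(condition = "CL", t_start_s = 0,
                                   duration_s = 60),
               habituationS = 0)
  recB <- burstRecording(c(15, 30, 45), 60)
  runB <- runClosedLoop(recB, levelBank("ch1"), schCL, cfg = cfg1)
  n <- nrow(runB$stimEvents)
  expect_equal(n, 3L)
  expect_equal(nrow(runB$decisions), 60 / 0.2 - 20 * n)
  # every stimulation coincides with a triggered decision timestamp
  expect_true(all(runB$stimEvents$t_start_s %in%
                    runB$decisions$t_s[runB$decisions$stimulated]))
  # no decisions inside any stimulation window
  for (k in seq_len(n)) {
    t0k <- runB$stimEvents$t_start_s[k]
    expect_false(any(runB$decisions$t_s > t0k &
                       runB$decisions$t_s <= t0k + 4))
  }
  # decision grid minus lockout gaps only
  expect_true(all(abs(runB$decisions$t_s / 0.2 -
                        round(runB$decisions$t_s / 0.2)) < 1e-9))
})

test_that("RANDOM trials inherit the preceding CL trial's event count", {
  sch <- buildSchedule("closed_loop", trialS = 60)
  totalS <- sum(scheduleBlocks(sch)$duration_s)
  b <- scheduleBlocks(sch)
  # bursts only inside CL blocks: 2, 1, 3, 2 triggers across the cycles
  bursts <- c(b$t_start_s[2] + c(10, 30), b$t_start_s[5] + 20,
              b$t_start_s[8] + c(10, 25, 40), b$t_start_s[11] + c(15, 35))
  rec <- burstRecording(bursts, totalS)
  run <- runClosedLoop(rec, levelBank("ch1"), sch,
                       cfg = sessionConfig(n_channels = 1))
  se <- run$stimEvents
  inBlock <- function(i, cond = NULL) {
    sel <- se$t_start_s >= b$t_start_s[i] &
      se$t_start_s < b$t_start_s[i] + b$duration_s[i]
    if (!is.null(cond)) sel <- sel & se$condition == cond
    sum(sel)
  }
  expect_equal(vapply(c(2, 5, 8, 11), inBlock, numeric(1), cond = "CL"),
               c(2, 1, 3, 2))
  for (cyc in 0:3) {
    expect_equal(inBlock(3 * cyc + 3, "RANDOM"), inBlock(3 * cyc + 2, "CL"))
    expect_equal(inBlock(3 * cyc + 1), 0)  # OFF blocks never stimulate
  }
  # no two stimulation events overlap in any condition
  seo <- se[order(se$t_start_s), ]
  expect_true(all(diff(seo$t_start_s) >= 4 - 1e-9))
})

test_that("the engine validates channel coverage and span", {
  rec <- Recording(matrix(rnorm(250 * 30), 1), rateHz = 250, t0 = -2)
  bank <- constantBank("chX", positive = FALSE)
  sch <- buildSchedule("assessment", assessmentS = 20)
  expect_error(runClosedLoop(rec, bank, sch,
                             cfg = sessionConfig(n_channels = 1)),
               "mismatch")
  bank2 <- constantBank("ch1", positive = FALSE)
  schLong <- buildSchedule("assessment", assessmentS = 600)
  expect_error(runClosedLoop(rec, bank2, schLong,
                             cfg = sessionConfig(n_channels = 1)),
               "span")
})

test_that("stimulation-time accounting separates protocols", {
  co <- buildSchedule("continuous")
  stNone <- data.frame(t_start_s = numeric(0), duration_s = numeric(0),
                       condition = character(0))
  st <- stimulationTime(co, stNone)
  expect_equal(unname(st$seconds["ON_CONT"]), 900)
  expect_equal(unname(st$percent_of_session["ON_CONT"]), 50)

  cl <- buildSchedule("closed_loop")
  ev <- data.frame(t_start_s = seq(200, 312, by = 4)[1:29],
                   duration_s = 4, condition = "CL")
  st2 <- stimulationTime(cl, ev)
  expect_equal(unname(st2$seconds["CL"]), 116)
  st3 <- stimulationTime(cl, stNone)
  expect_equal(st3$percent_reduction_vs_continuous, 100)
})
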