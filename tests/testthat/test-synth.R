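# Synthetic-session generator: determinism, null behavior, ground-truth
# parameter recovery.

test_that("whisking generator: exact periodic case and amplitude", {
  set.seed(1)
  cfg <- synthConfig(durationS = 10, cycleJitterCv = 0, whiskRateHz = 8,
                     whiskAmplitudeDeg = 20)
  w <- generateWhisking(cfg)
  starts <- attr(w, "cycleStarts")
  expect_equal(length(starts), 80)
  expect_equal(diff(starts), rep(0.125, 79), tolerance = 1e-12)
  expect_lt(abs(mean(angles(w))), 0.5)
  # post-filter peak-to-trough cycle amplitudes within [18, 22] degrees
  cyc <- detectCycles(preprocessTrace(w))
  inner <- cyc[cyc$start_s > 0.5 & cyc$end_s < 9.5, ]
  expect_true(all(inner$amplitude_deg >= 18 & inner$amplitude_deg <= 22))
})

test_that("whisk rate is recovered by the PSD within 0.5 Hz", {
  for (rate in c(7, 8.1)) {
    set.seed(2)
    w <- generateWhisking(synthConfig(durationS = 40, whiskRateHz = rate,
                                      cycleJitterCv = 0.1))
    p <- welchPsdPeak(preprocessTrace(w))
    expect_lt(abs(p$peakHz - rate), 0.5 + p$resolution / 2)
  }
})

test_that("uncoupled call process is homogeneous Poisson", {
  cfg <- synthConfig(durationS = 200, aloneDurationS = 0, phaseKappa = 0,
                     callRateOut = 0.8, callRateIn = 0.8)
  counts <- vapply(1:200, function(seed) {
    set.seed(seed)
    nrow(generateCalls(cfg, phase = NULL))
  }, numeric(1))
  expK <- 0.8 * 200
  expect_lt(abs(mean(counts) - expK), 3 * sqrt(expK / 200))
  # dispersion consistent with Poisson
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.35)
})

test_that("coupling with no phase trace is a config error", {
  cfg <- synthConfig(phaseKappa = 2)
  expect_error(generateCalls(cfg, phase = NULL), "no phase trace")
})

test_that("in/out-of-touch call-rate ratio is recovered within 10%", {
  # pooled over 10 independent 2000 s sessions (the per-session Poisson CV of
  # the ratio is ~8%, so pooling is needed for a 10% tolerance to be a
  # reliable check of the estimator rather than of one draw)
  tIn <- tOut <- nIn <- nOut <- 0
  for (seed in 1:10) {
    cfg <- synthConfig(durationS = 2000, aloneDurationS = 0, phaseKappa = 0,
                       seed = seed)
    set.seed(seed)
    touches <- generateTouchEpisodes(cfg, matrix(c(0, 2000), ncol = 2))
    calls <- generateCalls(cfg, phase = NULL, touches = touches)
    sr <- scenarioRates(calls,
                        list(social_setting = matrix(c(0, 2000), ncol = 2)),
                        touches, 2000)
    tIn <- tIn + sr$inTouchTime; tOut <- tOut + sr$outTouchTime
    nIn <- nIn + sr$inTouch * sr$inTouchTime
    nOut <- nOut + sr$outTouch * sr$outTouchTime
  }
  ratio <- (nIn / tIn) / (nOut / tOut)
  expect_lt(abs(ratio - 1.5 / 0.8) / (1.5 / 0.8), 0.10)
})

test_that("touch episodes: durations, disjointness, feasibility error", {
  cfg <- synthConfig(durationS = 30000, aloneDurationS = 0,
                     touchRatePerS = 1000 / 30000)
  set.seed(6)
  t1 <- generateTouchEpisodes(cfg, matrix(c(0, 30000), ncol = 2))
  d <- t1$whisker_off_s - t1$whisker_on_s
  expect_gt(nrow(t1), 800)
  expect_lt(abs(mean(d) - 2.86) / 2.86, 0.10)
  expect_true(all(d >= 0.2 - 1e-9))
  o <- order(t1$whisker_on_s)
  expect_true(all(t1$whisker_on_s[o][-1] >= t1$whisker_off_s[o][-nrow(t1)]))
  # snout intervals nest in whisker intervals
  has <- !is.na(t1$snout_on_s)
  expect_true(all(t1$snout_on_s[has] >= t1$whisker_on_s[has] &
                    t1$snout_off_s[has] <= t1$whisker_off_s[has]))
  # zero-rate request gives an empty table
  cfg0 <- synthConfig(durationS = 100, aloneDurationS = 0, touchRatePerS = 0)
  set.seed(1)
  expect_equal(nrow(generateTouchEpisodes(cfg0, matrix(c(0, 100), ncol = 2))),
               0)
  # infeasible schedule errors
  cfgBad <- synthConfig(durationS = 60, aloneDurationS = 0,
                        touchRatePerS = 2, touchMeanS = 5, touchSdS = 1)
  set.seed(2)
  expect_error(generateTouchEpisodes(cfgBad, matrix(c(0, 60), ncol = 2)),
               "infeasible")
})

test_that("unit generator: null rate, gain windows, RI sign recovery", {
  set.seed(7)
  u <- generateUnit(unitSpec("RS", baseRate = 5), usvwhisk:::emptyCallTable(),
                    usvwhisk:::emptyTouchTable(), 500)
  n <- length(spikeTimes(u))
  expect_lt(abs(n - 2500), 3 * sqrt(2500))
  expect_false(is.unsorted(spikeTimes(u)))
})

test_that("sessions are reproducible under a fixed seed and differ across seeds", {
  cfg <- synthConfig(durationS = 60, aloneDurationS = 20, seed = 20)
  s1 <- generateSession(cfg)
  s2 <- generateSession(cfg)
  expect_session_equal(s1, s2)
  s3 <- generateSession(synthConfig(durationS = 60, aloneDurationS = 20,
                                    seed = 21))
  expect_false(isTRUE(all.equal(callTable(s1)$onset_s,
                                callTable(s3)$onset_s)))
})

test_that("ground truth covers every configured generator parameter", {
  s <- generateSession(synthConfig(durationS = 60, aloneDurationS = 20,
                                   seed = 22))
  tr <- groundTruth(s)
  expect_true(all(c("whiskRateHz", "callRateAlone", "callRateOut",
                    "callRateIn", "phaseKappa", "preferredPhaseDeg",
                    "micDirectionality", "intensityNoiseCv", "emitter",
                    "unitClass", "baseRate", "callGain", "touchGain",
                    "offGain", "seed") %in% names(tr)))
  expect_equal(length(tr$emitter), nrow(callTable(s)))
  expect_equal(length(tr$unitClass), length(unitList(s)))
})

test_that("symmetric intensities stay unassigned at any margin above 1", {
  cfg <- synthConfig(micDirectionality = 1 + 1e-9, intensityNoiseCv = 0)
  set.seed(8)
  calls <- randomCallTable(50, 100)
  calls$emitter <- "subject"
  calls <- generateMicIntensities(calls, cfg)
  res <- assignSources(calls, 1.5)
  expect_true(all(res$decision == "unassigned"))
})

test_that("null coupling keeps the Hodges-Ajne rejection near nominal", {
  sp <- standardPhase(duration = 300, seed = 30)
  cfg <- synthConfig(durationS = 300, aloneDurationS = 0, phaseKappa = 0,
                     subjectCallFraction = 1, callRateOut = 2, callRateIn = 2)
  rej <- vapply(1:100, function(seed) {
    set.seed(seed)
    calls <- generateCalls(cfg, phase = NULL)
    pac <- phaseAtCalls(sp$phase, calls$onset_s)
    hodgesAjne(pac$phase_deg[pac$valid])$p < 0.05
  }, logical(1))
  # binomial 99% CI around 5% at n = 100 is about [0, 11]
  expect_lte(mean(rej), 0.11)
})

test_that("end-to-end: a strongly coupled session flags coupling", {
  cfg <- synthConfig(durationS = 240, aloneDurationS = 40, phaseKappa = 2,
                     subjectCallFraction = 0.8, seed = 33)
  s <- generateSession(cfg)
  rep <- suppressMessages(runPipeline(
    s, analysisConfig(nShuffles = 100, nPermStability = 20, seed = 33)))
  co <- rep$report$stages$coordination
  expect_equal(co$status, "ok")
  expect_lt(co$summary$emitterTest$p, 0.05)
})
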