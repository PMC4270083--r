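# Matched baselines, event rates, response indices, touch responses,
# in/out-of-touch modulation, bootstrap, group comparisons.

test_that("matched baselines: clean shift, exclusion jump, short history", {
  # no exclusions: baseline is the event window shifted by exactly -10 s
  ev <- cbind(50, 50.4)
  mb <- matchedBaselineWindows(ev, NULL, 100, shift = 10)
  expect_equal(unname(mb$windows[1, ]), c(40, 40.4))
  # a 2 s exclusion inside the lookback shifts 2 s further back
  mb2 <- matchedBaselineWindows(ev, cbind(45, 47), 100, shift = 10)
  expect_equal(unname(mb2$windows[1, ]), c(38, 38.4))
  # insufficient history: dropped and counted
  mb3 <- matchedBaselineWindows(cbind(5, 5.4), NULL, 100, shift = 10)
  expect_equal(mb3$nDropped, 1)
  expect_equal(nrow(mb3$windows), 0)
})

test_that("baseline windows never intersect exclusions (property)", {
  set.seed(21)
  for (rep in 1:25) {
    span <- 600
    ex <- randomTouchTable(sample(3:8, 1), span)
    exW <- cbind(ex$whisker_on_s, ex$whisker_off_s)
    ev <- cbind(runif(10, 100, span - 1), 0)
    ev[, 2] <- ev[, 1] + runif(10, 0.05, 2)
    mb <- matchedBaselineWindows(ev, exW, span, shift = 10)
    if (nrow(mb$windows))
      for (i in seq_len(nrow(mb$windows)))
        expect_false(any(mb$windows[i, 1] < exW[, 2] &
                           exW[, 1] < mb$windows[i, 2]))
    # matched lengths
    expect_equal(mb$windows[, 2] - mb$windows[, 1],
                 (ev[, 2] - ev[, 1])[mb$keptEvents], tolerance = 1e-9)
  }
})

test_that("event rate: arithmetic, empty train, split-window invariance", {
  expect_equal(eventRate(seq(0.1, 1.9, by = 0.2), cbind(0, 2)), 5)
  expect_equal(eventRate(numeric(0), cbind(0, 2)), 0)
  spk <- sort(runif(100, 0, 10))
  expect_equal(eventRate(spk, cbind(2, 6)),
               eventRate(spk, rbind(c(2, 4), c(4, 6))))
  expect_error(eventRate(spk, cbind(2, 2)), "zero total")
})

test_that("response index: bounds, antisymmetry, worked value", {
  expect_equal(responseIndex(8, 8), 0)
  expect_equal(responseIndex(0, 5), -1)
  expect_equal(responseIndex(5, 0), 1)
  expect_equal(responseIndex(9.3, 8.8), 0.0276, tolerance = 1e-3)
  expect_true(is.na(responseIndex(0, 0)))
  set.seed(2)
  a <- runif(50, 0, 20); b <- runif(50, 0, 20)
  ri <- responseIndex(a, b)
  expect_true(all(ri >= -1 & ri <= 1))
  expect_equal(ri, -responseIndex(b, a))
})

test_that("spike PSTH localizes a fixed-latency response", {
  trig <- seq(10, 200, by = 2)
  spk <- sort(trig + 0.03)
  p <- spikePsth(spk, trig, window = c(-0.1, 0.2), bin = 0.01)
  hot <- abs(p$lag_s - 0.035) < 1e-9  # bin [0.03, 0.04)
  expect_equal(p$rate_hz[hot], 100)
  expect_true(all(p$rate_hz[!hot] == 0))

  set.seed(4)
  pois <- sort(runif(5 * 400, 0, 400))
  pp <- spikePsth(pois, seq(50, 350, by = 1.5), window = c(-0.2, 0.2),
                  bin = 0.02)
  sdExp <- sqrt(5 / (length(seq(50, 350, by = 1.5)) * 0.02))
  expect_true(all(abs(pp$rate_hz - 5) < 3.5 * sdExp))
})

test_that("call-gain recovery: window rate matches base x gain", {
  cfg <- synthConfig(durationS = 1000, aloneDurationS = 0, phaseKappa = 0,
                     callRateOut = 0.5, callRateIn = 0.5, seed = 6)
  set.seed(6)
  calls <- generateCalls(cfg, phase = NULL)
  spec <- unitSpec("RS", baseRate = 5, callGain = 3, callLatencyS = 0)
  set.seed(7)
  u <- generateUnit(spec, calls, usvwhisk:::emptyTouchTable(), 1000)
  w <- callResponseWindows(calls, "call_duration_plus_25ms")
  inRate <- eventRate(spikeTimes(u), w)
  expect_lt(abs(inRate - 15) / 15, 0.10)
})

test_that("touch and off response indices recover the configured signs", {
  signOk <- 0
  nSeeds <- 30
  for (seed in seq_len(nSeeds)) {
    cfg <- synthConfig(durationS = 1000, aloneDurationS = 0, seed = seed)
    set.seed(seed)
    touches <- generateTouchEpisodes(cfg, matrix(c(0, 1000), ncol = 2))
    spec <- unitSpec("RS", baseRate = 8.2, touchGain = 0.8, offGain = 1.5)
    u <- generateUnit(spec, usvwhisk:::emptyCallTable(), touches, 1000)
    tw <- cbind(touches$whisker_on_s, touches$whisker_off_s)
    tr <- touchResponse(spikeTimes(u), touches, tw, 1000)
    if (tr$riTouch < 0 && tr$riOff > 0) signOk <- signOk + 1
  }
  expect_gte(signOk / nSeeds, 0.9)
})

test_that("null units show no touch modulation", {
  cfg <- synthConfig(durationS = 1000, aloneDurationS = 0, seed = 3)
  set.seed(3)
  touches <- generateTouchEpisodes(cfg, matrix(c(0, 1000), ncol = 2))
  tw <- cbind(touches$whisker_on_s, touches$whisker_off_s)
  ris <- vapply(1:12, function(seed) {
    set.seed(seed + 50)
    u <- generateUnit(unitSpec("RS", baseRate = 8), usvwhisk:::emptyCallTable(),
                      touches, 1000)
    tr <- touchResponse(spikeTimes(u), touches, tw, 1000)
    c(tr$riTouch, tr$riOff)
  }, numeric(2))
  expect_lt(abs(mean(ris[1, ])), 0.05)
  expect_lt(mean(abs(ris[1, ]) > 0.2), 0.1)
})

test_that("half-open rule: a call exactly at touch offset is out of touch", {
  touches <- data.frame(whisker_on_s = 10, snout_on_s = NA_real_,
                        snout_off_s = NA_real_, whisker_off_s = 20,
                        stimulus_kind = "conspecific")
  calls <- randomCallTable(8, 100)
  calls$onset_s[1] <- 20  # exactly at offset
  calls$offset_s[1] <- 20.05
  tw <- usvwhisk:::touchWindows(touches)
  expect_false(usvwhisk:::inAnyWindow(20, tw))
  expect_true(usvwhisk:::inAnyWindow(10, tw))  # onset is inside
})

test_that("in-touch call modulation exceeds out-of-touch on gain-switching units", {
  # units whose call gain applies only to calls during touch
  cfg <- synthConfig(durationS = 1500, aloneDurationS = 0, phaseKappa = 0,
                     seed = 8)
  set.seed(8)
  touches <- generateTouchEpisodes(cfg, matrix(c(0, 1500), ncol = 2))
  calls <- generateCalls(cfg, phase = NULL, touches = touches)
  tw <- cbind(touches$whisker_on_s, touches$whisker_off_s)
  inTouch <- usvwhisk:::inAnyWindow(calls$onset_s, tw)
  riIn <- c(); riOut <- c()
  for (seed in 1:40) {
    set.seed(seed + 100)
    gain <- sample(c(2.5, 0.4), 1)  # excitation or inhibition, touch only
    # the call gain is applied only to the in-touch calls: units respond to
    # calls during touch but not outside it
    spec <- unitSpec("RS", baseRate = 6, callGain = gain, callLatencyS = 0)
    u <- generateUnit(spec, calls[inTouch, ], usvwhisk:::emptyTouchTable(),
                      1500)
    io <- callsInOutTouch(spikeTimes(u), calls, touches,
                          cbind(calls$onset_s, calls$offset_s), 1500)
    if (!io$flagged) { riIn <- c(riIn, io$riIn); riOut <- c(riOut, io$riOut) }
  }
  expect_gt(stats::sd(riIn), stats::sd(riOut))
  ks <- stats::ks.test(abs(riIn), abs(riOut))
  expect_lt(ks$p.value, 0.05)
})

test_that("bootstrap RI: degenerate resample, unbiasedness, determinism", {
  cfg <- synthConfig(durationS = 800, aloneDurationS = 0, phaseKappa = 0,
                     seed = 10)
  set.seed(10)
  calls <- generateCalls(cfg, phase = NULL)
  u <- generateUnit(unitSpec("RS", baseRate = 6, callGain = 2,
                             callLatencyS = 0), calls,
                    usvwhisk:::emptyTouchTable(), 800)
  ex <- cbind(calls$onset_s, calls$offset_s)
  nAll <- nrow(calls)
  # n_in = all calls: every resample identical -> degenerate distribution
  b1 <- bootstrapEqualizedRi(spikeTimes(u), calls, nAll, ex, 800, B = 20,
                             seed = 1)
  expect_equal(stats::sd(b1$ri), 0)
  w <- callResponseWindows(calls)
  mb <- matchedBaselineWindows(w, ex, 800)
  full <- responseIndex(eventRate(spikeTimes(u), w[mb$keptEvents, ]),
                        eventRate(spikeTimes(u), mb$windows))
  expect_equal(b1$ri[1], full, tolerance = 1e-12)
  # unbiasedness at subsample
  b2 <- bootstrapEqualizedRi(spikeTimes(u), calls, round(nAll / 3), ex, 800,
                             B = 300, seed = 2)
  expect_lt(abs(b2$mean - full), 0.02)
  # determinism and argument validation
  b3 <- bootstrapEqualizedRi(spikeTimes(u), calls, round(nAll / 3), ex, 800,
                             B = 50, seed = 7)
  b4 <- bootstrapEqualizedRi(spikeTimes(u), calls, round(nAll / 3), ex, 800,
                             B = 50, seed = 7)
  expect_identical(b3$ri, b4$ri)
  expect_error(bootstrapEqualizedRi(spikeTimes(u), calls, nAll + 1, ex, 800),
               "exceeds")
})

test_that("population comparisons behave on ties, shifts and identity", {
  a <- c(1, 2, 3, 4, 5, 6)
  expect_warning(res <- populationCompare(a, a, paired = TRUE), "zero")
  expect_equal(res$p, 1)
  expect_true(res$tieWarning)
  # shifted Gaussians are detected by Mann-Whitney
  hits <- vapply(1:30, function(seed) {
    set.seed(seed)
    x <- rnorm(100); y <- rnorm(100, 1)
    populationCompare(x, y)$p < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # KS of a sample against itself has statistic 0
  set.seed(1)
  z <- rnorm(40)
  expect_equal(unname(suppressWarnings(stats::ks.test(z, z)$statistic)), 0)
})

test_that("D'Agostino-Pearson matches an independent reference", {
  # reference values computed with scipy.stats.normaltest
  x <- sin(1:60) * 3 + (1:60 %% 7)
  r <- dagostinoPearson(x)
  expect_equal(r$k2, 1.8692495828662863, tolerance = 1e-10)
  expect_equal(r$p, 0.39273319474935664, tolerance = 1e-10)
  y <- exp(sin(1:80) * 2)
  r2 <- dagostinoPearson(y)
  expect_equal(r2$k2, 12.823730328558343, tolerance = 1e-10)
  expect_equal(r2$p, 0.0016419591207394945, tolerance = 1e-10)
})
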