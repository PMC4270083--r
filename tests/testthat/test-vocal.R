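# Spectrogram arithmetic, call statistics, source assignment, rates, PSTHs,
# periodicity and trigger-locked power.

test_that("spectrogram resolution arithmetic matches the standard setups", {
  s1 <- spectrogramSpec(fftLength = 1024, overlapFraction = 0.9375,
                        sampleRate = 250000)
  expect_equal(freqResolution(s1), 244.140625)
  expect_equal(timeResolution(s1), 0.000256)
  s2 <- spectrogramSpec(fftLength = 500, overlapFraction = 0.8,
                        sampleRate = 250000)
  expect_equal(timeResolution(s2), 0.0004)
  # identity: freq resolution times fft length = sample rate, exactly
  for (n in c(256, 500, 1024, 4096))
    expect_identical(freqResolution(spectrogramSpec(fftLength = n,
                                                    sampleRate = 250000)) * n,
                     250000)
})

test_that("spectrogram localizes a tone at the right frequency", {
  fs <- 250000
  tt <- seq(0, 0.02, by = 1 / fs)
  a <- new("AudioTrack", samples = sin(2 * pi * 50000 * tt), sampleRate = fs)
  sp <- spectrogramSpec(fftLength = 1024, overlapFraction = 0.5,
                        window = "hanning", sampleRate = fs)
  sg <- computeSpectrogram(a, sp)
  peakF <- sg$freq[apply(sg$power, 2, which.max)]
  expect_true(all(abs(peakF - 50000) < 2 * sg$freqResolution))
  expect_error(computeSpectrogram(
    new("AudioTrack", samples = rnorm(100), sampleRate = fs), sp),
    "exceeds")
})

test_that("category statistics reproduce hand-computed values", {
  calls <- data.frame(onset_s = c(0, 1, 2), offset_s = c(0.010, 1.020, 2.030),
                      category = "trill", mean_freq_khz = c(60, 62, 64),
                      bandwidth_khz = c(10, 10, 10))
  cs <- categoryStats(calls)
  expect_equal(cs$duration_ms_mean, 20)
  expect_equal(cs$duration_ms_sem, 10 / sqrt(3), tolerance = 1e-6)
  expect_equal(cs$duration_ms_sem, 5.774, tolerance = 1e-3)
  # single call: SEM 0 with flag
  one <- categoryStats(calls[1, ])
  expect_equal(one$duration_ms_sem, 0)
  expect_true(one$n1_flag)
  # empty category omitted
  expect_false("flat" %in% cs$category)
})

test_that("category sampling recovers the configured trill duration", {
  cfg <- synthConfig(durationS = 4000, aloneDurationS = 0, phaseKappa = 0,
                     seed = 2,
                     categoryProportions = c(trill = 1))
  set.seed(2)
  calls <- generateCalls(cfg, phase = NULL)
  trills <- calls[calls$category == "trill", ]
  expect_gt(nrow(trills), 1000)
  expect_lt(abs(mean((trills$offset_s - trills$onset_s) * 1000) - 50.9), 2)
})

test_that("source assignment follows the margin rule", {
  df <- data.frame(i_ch1 = c(10, 5, 0), i_ch2 = c(8, 5, 0),
                   i_ch3 = c(2, 5, 0), i_ch4 = c(1, 5, 0))
  expect_warning(res <- assignSources(df, 1.5), "all-zero")
  expect_equal(res$decision, c("subject", "unassigned", "unassigned"))
  # ties stay unassigned for any threshold > 1
  expect_equal(assignSources(df[2, ], 1.0001)$decision, "unassigned")
})

test_that("raising the margin threshold never decreases unassigned calls", {
  set.seed(4)
  calls <- randomCallTable(400, 100)
  nUn <- vapply(c(1.2, 1.5, 2, 3, 5), function(th)
    sum(assignSources(calls, th)$decision == "unassigned"), numeric(1))
  expect_true(all(diff(nUn) >= 0))
  # counts conserve for every threshold
  for (th in c(1.2, 2, 4)) {
    acc <- assignmentAccuracy(assignSources(calls, th)$decision,
                              calls$emitter)
    expect_equal(acc$nCorrect + acc$nWrong + acc$nUnassigned, acc$nTotal)
  }
})

test_that("assignment accuracy reproduces the two control conditions", {
  d1 <- rep(c("subject", "stimulus", "unassigned"), c(1286, 284, 263))
  a1 <- assignmentAccuracy(d1, rep("subject", 1833))
  expect_equal(round(a1$pctCorrect), 70)
  expect_equal(round(a1$pctWrong), 15)
  expect_equal(round(a1$pctUnassigned), 14)
  d2 <- rep(c("subject", "stimulus", "unassigned"), c(3406, 196, 697))
  a2 <- assignmentAccuracy(d2, rep("subject", 4299))
  expect_equal(round(a2$pctCorrect), 79)
  expect_equal(round(a2$pctWrong), 5)
  a3 <- assignmentAccuracy(rep("subject", 10), rep("subject", 10))
  expect_equal(a3$pctCorrect, 100)
  expect_error(assignmentAccuracy("subject", c("subject", "subject")),
               "length")
})

test_that("noiseless directional intensities are assigned perfectly", {
  cfg <- synthConfig(micDirectionality = 4, intensityNoiseCv = 0)
  set.seed(6)
  calls <- randomCallTable(200, 500)
  calls$emitter <- sample(c("subject", "stimulus"), 200, TRUE)
  calls <- generateMicIntensities(calls, cfg)
  acc <- assignmentAccuracy(assignSources(calls, 1.5)$decision, calls$emitter)
  expect_equal(acc$pctCorrect, 100)
  expect_equal(acc$pctUnassigned, 0)
})

test_that("noisy directionality 2 lands in the realistic accuracy band", {
  cfg <- synthConfig(micDirectionality = 2, intensityNoiseCv = 0.5)
  set.seed(7)
  calls <- randomCallTable(2000, 4000)
  calls$emitter <- sample(c("subject", "stimulus"), 2000, TRUE)
  calls <- generateMicIntensities(calls, cfg)
  acc <- assignmentAccuracy(assignSources(calls, 1.5)$decision, calls$emitter)
  expect_gt(acc$pctCorrect, 60)
  expect_lt(acc$pctCorrect, 95)
})

test_that("scenario rates: worked example and no-touch degradation", {
  calls <- data.frame(onset_s = seq(0.5, 19.5, length.out = 10),
                      offset_s = seq(0.5, 19.5, length.out = 10) + 0.05,
                      category = "trill", mean_freq_khz = 60,
                      bandwidth_khz = 10, i_ch1 = 1, i_ch2 = 1, i_ch3 = 0,
                      i_ch4 = 0, emitter = "subject")
  sr <- scenarioRates(calls, list(social_setting = matrix(c(0, 20), ncol = 2)),
                      usvwhisk:::emptyTouchTable(), 20)
  expect_equal(sr$scenario$rate_hz, 0.5)
  expect_true(is.na(sr$inTouch))
  expect_equal(sr$outTouch, 0.5)
})

test_that("event PSTH: exact-lag events, flat null, touch modulation", {
  trig <- seq(10, 190, by = 2)
  ev <- trig  # one event exactly at each trigger
  p <- eventPsth(ev, trig, window = c(-1, 1), bin = 0.5)
  expect_equal(p$rate_hz[p$lag_s == 0.25], 1 / 0.5)
  expect_equal(sum(p$rate_hz > 0), 1)

  set.seed(3)
  pois <- sort(runif(400, 0, 400))
  trg <- sort(runif(100, 50, 350))
  pf <- eventPsth(pois, trg, window = c(-2, 2), bin = 0.5)
  expect_lt(max(pf$rate_hz) / mean(pf$rate_hz), 1.8)
})

test_that("call periodicity: periodic train, Poisson null, too few calls", {
  on <- seq(0, 60, by = 0.1316)
  cp <- callPeriodicity(on)
  expect_true(cp$sufficient)
  expect_lt(abs(cp$peakHz - 7.6), 0.5 + 0.5)
  expect_true(cp$dominant)

  set.seed(5)
  nullDominant <- vapply(1:20, function(i)
    callPeriodicity(sort(runif(400, 0, 300)))$dominant, logical(1))
  expect_lte(mean(nullDominant), 0.2)

  expect_false(callPeriodicity(1:5)$sufficient)
})

test_that("trigger-locked power: stationary noise, tone burst, exclusions", {
  fs <- 50000
  dur <- 30
  set.seed(9)
  noise <- rnorm(fs * dur) * 0.05
  trig <- seq(2, 28, by = 2)
  # tone burst 50 ms after each trigger
  burst <- sin(2 * pi * 8000 * seq(0, 0.05, by = 1 / fs))
  x <- noise
  for (tr in trig) {
    i <- round((tr + 0.05) * fs)
    x[i:(i + length(burst) - 1)] <- x[i:(i + length(burst) - 1)] + burst
  }
  spec <- spectrogramSpec(fftLength = 512, overlapFraction = 0.5,
                          window = "hanning", sampleRate = fs)
  audio <- new("AudioTrack", samples = x, sampleRate = fs)
  res <- triggerLockedPower(audio, trig, window = c(-0.5, 0.5), spec = spec)
  post <- res$relPower[res$lag_s > 0.04 & res$lag_s < 0.11]
  expect_gt(max(post), 2)
  expect_lt(abs(mean(res$relPower[res$lag_s < 0]) - 1), 1e-9)

  # stationary noise alone stays near 1 everywhere
  audioN <- new("AudioTrack", samples = noise, sampleRate = fs)
  resN <- triggerLockedPower(audioN, trig, window = c(-0.5, 0.5), spec = spec)
  expect_true(all(resN$relPower > 0.8 & resN$relPower < 1.2))

  # all triggers excluded -> informative error
  ex <- cbind(trig - 0.6, trig + 0.6)
  expect_error(triggerLockedPower(audio, trig, window = c(-0.5, 0.5),
                                  exclusions = ex, spec = spec), "excluded")
})
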