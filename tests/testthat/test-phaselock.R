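# Occupancy-normalized phase histograms, Rayleigh vector, shuffle test,
# locking criterion.

test_that("Rayleigh vector: coherence bound, cancellation, closed form", {
  expect_equal(rayleighVector(rep(90, 10))$length, 1)
  expect_equal(rayleighVector(rep(90, 10))$angleDeg, 90)
  expect_lt(rayleighVector(c(0, 180))$length, 1e-12)
  set.seed(1)
  ph <- usvwhisk:::rVonMisesDeg(1000, 45, 1)
  r <- rayleighVector(ph)
  expect_equal(r$length, besselI(1, 1) / besselI(1, 0), tolerance = 0.07)
  expect_lt(usvwhisk:::angularDiffDeg(r$angleDeg, 45), 10)
})

test_that("Rayleigh vector is rotation-invariant in length, equivariant in angle", {
  set.seed(2)
  ph <- usvwhisk:::rVonMisesDeg(400, 120, 2)
  r0 <- rayleighVector(ph)
  r1 <- rayleighVector(usvwhisk:::wrapDeg(ph + 77))
  expect_equal(r1$length, r0$length, tolerance = 1e-12)
  expect_lt(usvwhisk:::angularDiffDeg(r1$angleDeg, r0$angleDeg + 77), 1e-6)
})

test_that("spike-phase histogram is occupancy-normalized", {
  sp <- standardPhase(duration = 40, seed = 9, jitter = 0)
  ph <- sp$phase
  # spikes planted inside one phase bin (bin 5 spans (90, 112.5])
  tv <- sampleTimes(ph)[validMask(ph) & phases(ph) > 95 & phases(ph) < 108]
  h <- spikePhaseHistogram(sort(sample(tv, 50)), ph, nBins = 16)
  expect_equal(sum(h$n_spikes > 0), 1)
  expect_equal(which(h$n_spikes > 0), 5)

  # Poisson spikes independent of phase -> flat rate across bins
  set.seed(10)
  spk <- sort(runif(2000, 0, 40))
  hf <- spikePhaseHistogram(spk, ph, nBins = 16)
  expect_true(all(abs(hf$rate_hz - mean(hf$rate_hz)) <
                    4 * sqrt(mean(hf$n_spikes)) / mean(hf$occupancy_s)))
  # occupancy identity: the rate estimate is insensitive to occupancy skew
  expect_equal(sum(hf$occupancy_s), sum(validMask(ph)) / 1000)
})

test_that("shuffle test: extremes and criterion ordering", {
  sp <- standardPhase(duration = 60, seed = 11, jitter = 0)
  ph <- sp$phase
  tv <- sampleTimes(ph)[validMask(ph) & abs(phases(ph) - 90) < 1.5]
  locked <- sort(sample(tv, 120))
  st <- shuffleTest(locked, ph, nShuffles = 300, seed = 1)
  expect_gte(st$quantile, 0.99)
  expect_gt(st$observed, 0.95)

  res <- classifyPhaseLocked(
    list(new("UnitRecording", unitId = "locked", spikeTimes = locked,
             waveform = rnorm(32)),
         new("UnitRecording", unitId = "few", spikeTimes = locked[1:9],
             waveform = rnorm(32))),
    ph, analysisConfig(nShuffles = 200))
  expect_true(res$locked[res$unit_id == "locked"])
  # count floor: 9 spikes fail regardless of length/quantile
  expect_false(res$locked[res$unit_id == "few"])
  expect_gt(res$rayleigh_length[2], 0.9)
})

test_that("weak concentration fails the Rayleigh-length floor", {
  sp <- standardPhase(duration = 120, seed = 12)
  ph <- sp$phase
  set.seed(3)
  # slight concentration: kappa 0.25 -> R ~ 0.12 < 0.2
  target <- usvwhisk:::rVonMisesDeg(500, 90, 0.25)
  tv <- sampleTimes(ph)[validMask(ph)]
  pv <- phases(ph)[validMask(ph)]
  spk <- sort(vapply(target, function(d)
    tv[which.min(usvwhisk:::angularDiffDeg(pv, d) +
                   runif(length(pv), 0, 30))], numeric(1)))
  spk <- unique(spk)
  res <- classifyPhaseLocked(
    list(new("UnitRecording", unitId = "weak", spikeTimes = spk,
             waveform = rnorm(32))), ph, analysisConfig(nShuffles = 300))
  expect_false(res$locked[1] && res$rayleigh_length[1] <= 0.2)
})

test_that("strongly coupled units are detected across seeds", {
  sp <- standardPhase(duration = 100, seed = 13)
  ph <- sp$phase
  tv <- sampleTimes(ph)[validMask(ph)]
  pv <- phases(ph)[validMask(ph)]
  hits <- vapply(1:12, function(seed) {
    set.seed(seed)
    target <- usvwhisk:::rVonMisesDeg(200, 90, 2)
    idx <- vapply(target, function(d) {
      cand <- which(usvwhisk:::angularDiffDeg(pv, d) < 8)
      cand[sample.int(length(cand), 1)]
    }, numeric(1))
    spk <- sort(unique(tv[idx]))
    res <- classifyPhaseLocked(
      list(new("UnitRecording", unitId = "c", spikeTimes = spk,
               waveform = rnorm(32))), ph,
      analysisConfig(nShuffles = 300, seed = seed))
    res$locked[1]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("shuffle quantiles are uniform under the null", {
  sp <- standardPhase(duration = 100, seed = 14)
  ph <- sp$phase
  qs <- vapply(1:120, function(seed) {
    set.seed(seed)
    spk <- sort(runif(rpois(1, 400), 0, 100))
    shuffleTest(spk, ph, nShuffles = 300, seed = seed)$quantile
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(qs, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("shuffle quantile is insensitive to spike count at matched coupling", {
  sp <- standardPhase(duration = 100, seed = 15)
  ph <- sp$phase
  tv <- sampleTimes(ph)[validMask(ph)]
  pv <- phases(ph)[validMask(ph)]
  qAt <- function(nSpikes, seed) {
    set.seed(seed)
    target <- usvwhisk:::rVonMisesDeg(nSpikes, 90, 0.8)
    idx <- vapply(target, function(d) {
      cand <- which(usvwhisk:::angularDiffDeg(pv, d) < 10)
      cand[sample.int(length(cand), 1)]
    }, numeric(1))
    shuffleTest(sort(unique(tv[idx])), ph, nShuffles = 300,
                seed = seed)$quantile
  }
  qSmall <- vapply(1:10, function(s) qAt(30, s), numeric(1))
  qLarge <- vapply(1:10, function(s) qAt(600, s + 100), numeric(1))
  # both regimes detect the same moderate coupling at similar rates
  expect_gt(mean(qSmall >= 0.95), 0.5)
  expect_gt(mean(qLarge >= 0.95), 0.5)
})

test_that("units driven by phase-coupled calls inherit spurious locking", {
  # short calls (inverted-u-like durations) tightly coupled to the whisking
  # phase: a unit that only responds to calls nevertheless passes the
  # locking criterion far above the 5% chance level
  cfg <- synthConfig(durationS = 600, aloneDurationS = 0, phaseKappa = 4,
                     subjectCallFraction = 1, callRateOut = 1, callRateIn = 1,
                     seed = 16, categoryProportions = c(inverted_u = 1))
  set.seed(16)
  w <- generateWhisking(cfg)
  ft <- preprocessTrace(w); ph <- computePhase(ft, detectCycles(ft))
  calls <- generateCalls(cfg, phase = ph)
  flagged <- vapply(1:8, function(seed) {
    set.seed(seed + 30)
    u <- generateUnit(unitSpec("RS", baseRate = 1, callGain = 20,
                               callLatencyS = 0), calls,
                      usvwhisk:::emptyTouchTable(), 600)
    res <- classifyPhaseLocked(list(u), ph,
                               analysisConfig(nShuffles = 200, seed = seed))
    isTRUE(res$locked[1])
  }, logical(1))
  expect_gte(mean(flagged), 0.5)
})
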