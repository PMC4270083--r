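# Fixtures built in code: traces, phase traces and small random sessions.

# brute-force oracle for the Hodges-Ajne statistic: minimum half-circle
# count over all boundaries at the data points
# count over an exhaustive fine grid of boundary angles (independent of the
# data-point construction used by the implementation)
haOracle <- function(phasesDeg) {
  th <- usvwhisk:::wrapDeg(phasesDeg)
  cand <- seq(0, 360, by = 0.05)
  cnt <- vapply(cand, function(b)
    sum(usvwhisk:::wrapDeg(th - b) < 180), numeric(1))
  as.integer(min(cnt))
}

sineTrace <- function(freq = 8, amp = 20, duration = 10, fs = 250,
                      offset = 0, phase0 = 0) {
  tt <- seq(0, duration - 1 / fs, by = 1 / fs)
  new("WhiskerTrace", animalId = "a", times = tt,
      angle = amp * cos(2 * pi * freq * tt + phase0) + offset,
      sampleRate = fs)
}

# filtered trace + phase for a standard 8 Hz synthetic whisk
standardPhase <- function(duration = 60, seed = 42, jitter = 0.1) {
  set.seed(seed)
  w <- generateWhisking(synthConfig(durationS = duration,
                                    cycleJitterCv = jitter, seed = seed))
  ft <- preprocessTrace(w)
  cyc <- detectCycles(ft)
  list(raw = w, filtered = ft, cycles = cyc, phase = computePhase(ft, cyc))
}

randomCallTable <- function(n, duration) {
  if (n == 0) return(usvwhisk:::emptyCallTable())
  on <- sort(runif(n, 0, duration - 0.3))
  data.frame(onset_s = on, offset_s = on + runif(n, 0.01, 0.2),
             category = sample(c("trill", "complex", "flat"), n, TRUE),
             mean_freq_khz = runif(n, 30, 80),
             bandwidth_khz = runif(n, 2, 15),
             i_ch1 = runif(n), i_ch2 = runif(n), i_ch3 = runif(n),
             i_ch4 = runif(n),
             emitter = sample(c("subject", "stimulus", "unassigned"), n, TRUE),
             stringsAsFactors = FALSE)
}

randomTouchTable <- function(n, duration) {
  if (n == 0) return(usvwhisk:::emptyTouchTable())
  gap <- duration / (2 * n)
  on <- seq(1, by = 2 * gap, length.out = n) + runif(n, 0, gap / 4)
  off <- on + runif(n, 0.3, gap)
  snout <- runif(n) < 0.5
  data.frame(whisker_on_s = on,
             snout_on_s = ifelse(snout, on + 0.05, NA_real_),
             snout_off_s = ifelse(snout, off - 0.05, NA_real_),
             whisker_off_s = off,
             stimulus_kind = sample(c("conspecific", "object"), n, TRUE),
             stringsAsFactors = FALSE)
}

# small random session assembled directly (no generator run): fast fixture
# for I/O round-trip properties
randomSession <- function(seed, duration = 30) {
  set.seed(seed)
  tr <- lapply(c("subject", "stimulus"), function(a) {
    tt <- seq(0, 2, by = 1 / 250)
    new("WhiskerTrace", animalId = a, times = tt,
        angle = rnorm(length(tt)), sampleRate = 250)
  })
  units <- lapply(seq_len(sample(1:3, 1)), function(i)
    new("UnitRecording", unitId = sprintf("u%d", i),
        spikeTimes = sort(runif(rpois(1, 40), 0, duration)),
        waveform = rnorm(32), waveformRate = 32000,
        subregion = sample(c("Au1", "AuD", "AuV"), 1)))
  new("SessionRecording", sessionId = sprintf("rand%d", seed),
      duration = duration, whiskerTraces = tr,
      calls = randomCallTable(rpois(1, 10), duration),
      touches = randomTouchTable(sample(0:3, 1), duration),
      units = units,
      scenarioWindows = list(
        subject_alone = matrix(c(0, duration / 3), ncol = 2),
        social_setting = matrix(c(duration / 3, duration), ncol = 2)),
      audio = NULL, truth = list())
}

expect_session_equal <- function(a, b) {
  expect_equal(sessionId(a), sessionId(b))
  expect_equal(sessionDuration(a), sessionDuration(b))
  expect_equal(length(whiskerTraces(a)), length(whiskerTraces(b)))
  for (i in seq_along(whiskerTraces(a))) {
    ta <- whiskerTraces(a)[[i]]; tb <- whiskerTraces(b)[[i]]
    expect_equal(angles(ta), angles(tb))
    expect_equal(sampleTimes(ta), sampleTimes(tb))
  }
  expect_equal(callTable(a), callTable(b), tolerance = 1e-15)
  expect_equal(touchTable(a), touchTable(b), tolerance = 1e-15)
  expect_equal(length(unitList(a)), length(unitList(b)))
  for (i in seq_along(unitList(a))) {
    expect_equal(spikeTimes(unitList(a)[[i]]), spikeTimes(unitList(b)[[i]]))
    expect_equal(waveform(unitList(a)[[i]]), waveform(unitList(b)[[i]]))
  }
}
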