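# Synthetic-session generator: whisking, touch episodes, phase-coupled call
# point processes, directional microphone intensities and modulated spike
# trains, with ground truth retained for parameter-recovery tests.

# USV category parameter table. Durations: lognormal matched to the reported
# mean and SD (SEM * sqrt(n)); mean frequency and bandwidth: normal with SD
# inferred from the 20th-80th quantile spread (the duration SEM-derived SD is
# consistent with the reported trill SD, the frequency one is not, the
# distributions being skewed).
usvCategoryTable <- function() {
  d <- data.frame(
    category = c("trill", "complex", "flat", "upward_ramp", "downward_ramp",
                 "inverted_u", "short", "split", "fear"),
    n = c(16549, 13662, 13656, 1280, 258, 501, 26, 1072, 299),
    freq_mean = c(63.1, 54.8, 49.0, 51.6, 48.0, 55.5, 49.6, 45.2, 28.0),
    freq_q20 = c(51.7, 48.1, 38.6, 45.7, 31.7, 45.0, 36.1, 34.0, 22.9),
    freq_q80 = c(76.9, 62.9, 56.0, 59.8, 59.7, 67.4, 65.1, 57.2, 31.0),
    bw_mean = c(10.3, 7.8, 5.2, 6.5, 5.5, 5.7, 4.1, 7.4, 2.4),
    bw_q20 = c(5.1, 3.9, 2.7, 3.5, 3.2, 3.2, 3.1, 3.1, 1.1),
    bw_q80 = c(12.6, 8.7, 5.3, 8.4, 6.8, 7.2, 5.4, 7.3, 2.3),
    dur_mean_ms = c(50.9, 39.0, 44.1, 26.8, 19.9, 16.4, 13.7, 68.1, 206.5),
    dur_sem_ms = c(0.2, 0.2, 0.3, 0.3, 0.8, 0.5, 0.9, 1.4, 16.6))
  d$dur_sd_ms <- d$dur_sem_ms * sqrt(d$n)
  qspan <- stats::qnorm(0.8) - stats::qnorm(0.2)
  d$freq_sd <- (d$freq_q80 - d$freq_q20) / qspan
  d$bw_sd <- (d$bw_q80 - d$bw_q20) / qspan
  d
}

defaultCategoryProportions <- function() {
  tab <- usvCategoryTable()
  pUnspec <- 0.058
  p <- tab$n / sum(tab$n) * (1 - pUnspec)
  stats::setNames(c(p, pUnspec), c(tab$category, "unspecified"))
}

defaultUnitSpecs <- function() {
  # paper-like population: mostly RS units around the reported median rates,
  # weak call excitation, touch suppression and a post-touch off-response
  specs <- list()
  for (i in 1:6)
    specs[[i]] <- unitSpec("RS", callGain = 1.06, touchGain = 0.956,
                           offGain = 1.04)
  for (i in 7:8)
    specs[[i]] <- unitSpec("FS", callGain = 1.1, touchGain = 0.956,
                           offGain = 1.04)
  specs
}

#' Generate a synthetic whisking trace
#'
#' A frequency-jittered oscillator rather than filtered noise: cycle periods
#' are drawn from a lognormal with mean `1/whiskRateHz` and coefficient of
#' variation `cycleJitterCv`, and the angle follows a cosine over each cycle
#' (maximum protraction at every cycle start, so ground-truth cycle markers
#' are known exactly). Sampled at the camera rate (250 Hz) to exercise the
#' up-sampling in [preprocessTrace()].
#'
#' @param cfg a [SynthConfig-class].
#' @param animalId trace label.
#' @return a [WhiskerTrace-class]; true cycle start times in
#'   `attr(, "cycleStarts")`.
#' @export
generateWhisking <- function(cfg, animalId = "subject") {
  stopifnot(cfg@durationS > 0)
  mu <- 1 / cfg@whiskRateHz
  cv <- cfg@cycleJitterCv
  nGuess <- ceiling(cfg@durationS / mu * 1.5) + 10
  periods <- if (cv <= 0) rep(mu, nGuess) else {
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(nGuess, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
  }
  starts <- cumsum(c(0, periods))
  while (starts[length(starts)] < cfg@durationS) {
    more <- if (cv <= 0) mu else
      stats::rlnorm(1, meanlog = log(mu) - log(1 + cv^2) / 2,
                    sdlog = sqrt(log(1 + cv^2)))
    starts <- c(starts, starts[length(starts)] + more)
  }
  # half-open sampling grid [0, duration)
  tt <- seq(0, cfg@durationS - 1 / cfg@traceSampleRateHz,
            by = 1 / cfg@traceSampleRateHz)
  ci <- findInterval(tt, starts)
  frac <- (tt - starts[ci]) / (starts[ci + 1] - starts[ci])
  # whiskAmplitudeDeg is the peak-to-trough cycle amplitude
  ang <- cfg@whiskAmplitudeDeg / 2 * cos(2 * pi * frac)
  tr <- new("WhiskerTrace", animalId = animalId, times = tt, angle = ang,
            sampleRate = cfg@traceSampleRateHz)
  attr(tr, "cycleStarts") <- starts[starts < cfg@durationS]
  tr
}

#' Generate touch episodes
#'
#' Non-overlapping episodes with lognormal durations matched to the
#' configured mean and SD (default 2.86 +/- 2.68 s), truncated at a 0.2 s
#' minimum, placed at the configured event rate within the given windows.
#'
#' @param cfg a [SynthConfig-class].
#' @param within 2-column matrix of windows in which touches may occur
#'   (default: the social period).
#' @return a touch table (see [SessionRecording-class]).
#' @export
generateTouchEpisodes <- function(cfg, within = NULL) {
  if (is.null(within))
    within <- matrix(c(cfg@aloneDurationS, cfg@durationS), ncol = 2)
  within <- mergeWindows(within)
  avail <- totalWindowTime(within)
  if (nrow(cfg@touchSchedule)) {
    sched <- cfg@touchSchedule
    return(data.frame(whisker_on_s = sched[, 1], snout_on_s = NA_real_,
                      snout_off_s = NA_real_, whisker_off_s = sched[, 2],
                      stimulus_kind = cfg@stimulusKind))
  }
  nEp <- stats::rpois(1, cfg@touchRatePerS * avail)
  if (nEp == 0)
    return(emptyTouchTable())
  cv <- cfg@touchSdS / cfg@touchMeanS
  sdlog <- sqrt(log(1 + cv^2))
  durs <- pmax(cfg@touchMinS,
               stats::rlnorm(nEp, log(cfg@touchMeanS) - sdlog^2 / 2, sdlog))
  if (sum(durs) > avail)
    stop("infeasible touch schedule: requested touch time exceeds the session")
  placed <- placeMatchedPeriods(durs, within)
  if (is.null(placed))
    stop("infeasible touch schedule: could not place non-overlapping episodes")
  placed <- placed[order(placed[, 1]), , drop = FALSE]
  # snout contact nested inside roughly half of the episodes
  hasSnout <- stats::runif(nrow(placed)) < 0.5 & (placed[, 2] - placed[, 1]) > 0.4
  sOn <- ifelse(hasSnout, placed[, 1] + 0.25 * (placed[, 2] - placed[, 1]),
                NA_real_)
  sOff <- ifelse(hasSnout, placed[, 1] + 0.75 * (placed[, 2] - placed[, 1]),
                 NA_real_)
  data.frame(whisker_on_s = placed[, 1], snout_on_s = sOn, snout_off_s = sOff,
             whisker_off_s = placed[, 2], stimulus_kind = cfg@stimulusKind)
}

# thinning sampler for one call process: piecewise base rate (alone /
# social-out / social-in-touch), optionally modulated by a von Mises density
# of the whisking phase (unit mean over uniform phase)
sampleCallProcess <- function(cfg, baseWindows, touches, phase = NULL) {
  # baseWindows: list(alone=, social=) of window matrices; rates from cfg
  tw <- touchWindows(touches)
  pieces <- list()
  addPiece <- function(w, rate) {
    if (!is.null(w) && nrow(w) && rate > 0)
      pieces[[length(pieces) + 1]] <<- cbind(w, rate)
  }
  soc <- baseWindows$social
  addPiece(baseWindows$alone, cfg@callRateAlone)
  if (!is.null(soc) && nrow(soc)) {
    addPiece(intersectWindows(soc, tw), cfg@callRateIn)
    addPiece(intersectWindows(
      soc, complementWindows(tw, 0, cfg@durationS)), cfg@callRateOut)
  }
  if (!length(pieces)) return(numeric(0))
  seg <- do.call(rbind, pieces)
  kappa <- if (is.null(phase)) 0 else cfg@phaseKappa
  boost <- if (kappa > 0) exp(kappa) / besselI(kappa, 0) else 1
  onsets <- numeric(0)
  for (i in seq_len(nrow(seg))) {
    lam <- seg[i, 3] * boost
    k <- stats::rpois(1, lam * (seg[i, 2] - seg[i, 1]))
    if (k > 0) onsets <- c(onsets, stats::runif(k, seg[i, 1], seg[i, 2]))
  }
  onsets <- sort(onsets)
  if (kappa > 0 && length(onsets)) {
    if (!any(phase@valid)) stop("phase coupling requested with no valid phase")
    ph <- phaseAtCalls(phase, onsets)$phase_deg
    ph[is.na(ph)] <- stats::runif(sum(is.na(ph)), 0, 360)
    acc <- stats::runif(length(onsets)) <
      vonMisesAcceptRatio(ph, cfg@preferredPhaseDeg, kappa)
    onsets <- onsets[acc]
  }
  onsets
}

#' Generate phase-coupled call events
#'
#' Inhomogeneous point process by thinning (exact for an inhomogeneous
#' Poisson process): a piecewise base intensity (`callRateAlone` /
#' `callRateOut` / elevated to `callRateIn` inside touch episodes) is
#' multiplied by a von Mises density of the whisking phase (concentration
#' `phaseKappa`, center `preferredPhaseDeg`), normalized so the mean rate
#' matches the configured rates under uniform phase occupancy. The subject's
#' process is phase-coupled to the subject's whisking; the stimulus animal's
#' process is not. Categories follow the configured proportions; durations,
#' mean frequencies and bandwidths are drawn per category.
#'
#' @param cfg a [SynthConfig-class].
#' @param phase the subject's [PhaseTrace-class] (required when
#'   `phaseKappa > 0`).
#' @param touches touch table (episodes elevate the call rate).
#' @param scenarios named list of scenario windows; defaults derived from
#'   `aloneDurationS`.
#' @return a call table with true emitters in the `emitter` column and
#'   intensities left at 0 (see [generateMicIntensities()]).
#' @export
generateCalls <- function(cfg, phase = NULL, touches = emptyTouchTable(),
                          scenarios = NULL) {
  if (cfg@phaseKappa > 0 && is.null(phase))
    stop("phase coupling requested (phaseKappa > 0) but no phase trace given")
  if (is.null(scenarios))
    scenarios <- list(
      subject_alone = matrix(c(0, cfg@aloneDurationS), ncol = 2),
      social_setting = matrix(c(cfg@aloneDurationS, cfg@durationS), ncol = 2))
  alone <- scenarios$subject_alone
  soc <- scenarios$social_setting
  fr <- cfg@subjectCallFraction
  cfgS <- cfg; cfgS@callRateOut <- cfg@callRateOut * fr
  cfgS@callRateIn <- cfg@callRateIn * fr
  subjOn <- sampleCallProcess(cfgS, list(alone = alone, social = soc),
                              touches, phase = phase)
  cfgT <- cfg; cfgT@callRateAlone <- 0
  cfgT@callRateOut <- cfg@callRateOut * (1 - fr)
  cfgT@callRateIn <- cfg@callRateIn * (1 - fr)
  stimOn <- sampleCallProcess(cfgT, list(alone = NULL, social = soc),
                              touches, phase = NULL)
  onsets <- c(subjOn, stimOn)
  emitter <- rep(c("subject", "stimulus"), c(length(subjOn), length(stimOn)))
  o <- order(onsets); onsets <- onsets[o]; emitter <- emitter[o]
  n <- length(onsets)
  if (!n) return(emptyCallTable())
  props <- cfg@categoryProportions
  cats <- sample(names(props), n, replace = TRUE, prob = props)
  tab <- usvCategoryTable()
  dur <- freq <- bw <- numeric(n)
  for (cc in unique(cats)) {
    i <- cats == cc
    row <- tab[tab$category == cc, ]
    if (!nrow(row)) row <- tab[tab$category == "complex", ]  # unspecified
    cvd <- row$dur_sd_ms / row$dur_mean_ms
    sdlog <- sqrt(log(1 + cvd^2))
    dur[i] <- pmax(5, stats::rlnorm(sum(i), log(row$dur_mean_ms) -
                                      sdlog^2 / 2, sdlog)) / 1000
    freq[i] <- stats::rnorm(sum(i), row$freq_mean, row$freq_sd)
    bw[i] <- pmax(0.5, stats::rnorm(sum(i), row$bw_mean, row$bw_sd))
  }
  off <- pmin(onsets + dur, cfg@durationS)
  keep <- off > onsets
  data.frame(onset_s = onsets[keep], offset_s = off[keep],
             category = cats[keep], mean_freq_khz = freq[keep],
             bandwidth_khz = bw[keep], i_ch1 = 0, i_ch2 = 0, i_ch3 = 0,
             i_ch4 = 0, emitter = emitter[keep], stringsAsFactors = FALSE)
}

#' Add directional microphone intensities to calls
#'
#' The two microphones on the true emitter's side receive intensity I, the
#' two on the far side I / `micDirectionality`, each multiplied by lognormal
#' noise with coefficient of variation `intensityNoiseCv`. Channels 1-2 are
#' the subject side, 3-4 the stimulus side; the true emitter stays in the
#' `emitter` column as ground truth.
#'
#' @param calls call table with true `emitter` labels.
#' @param cfg a [SynthConfig-class].
#' @return the call table with `i_ch1..i_ch4` filled in.
#' @export
generateMicIntensities <- function(calls, cfg) {
  n <- nrow(calls)
  if (!n) return(calls)
  base <- stats::rlnorm(n, 0, 0.3)  # per-call loudness
  cv <- cfg@intensityNoiseCv
  sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  noise <- function() if (sdlog > 0)
    stats::rlnorm(n, -sdlog^2 / 2, sdlog) else rep(1, n)
  nearSubject <- calls$emitter == "subject"
  near <- base; far <- base / cfg@micDirectionality
  calls$i_ch1 <- ifelse(nearSubject, near, far) * noise()
  calls$i_ch2 <- ifelse(nearSubject, near, far) * noise()
  calls$i_ch3 <- ifelse(nearSubject, far, near) * noise()
  calls$i_ch4 <- ifelse(nearSubject, far, near) * noise()
  calls
}

#' Generate one synthetic unit
#'
#' Inhomogeneous Poisson spike train with rate
#' `baseRate x callGain` (inside call windows of call duration + 25 ms,
#' delayed by the call latency) `x touchGain` (inside touch episodes)
#' `x offGain` (within 200 ms after each touch offset), sampled exactly via
#' piecewise-constant segments. The mean waveform is a peak-normalized bump
#' whose 25 %-width is drawn from the class-specific Gaussian.
#'
#' @param spec a [UnitSpec-class].
#' @param calls call table.
#' @param touches touch table.
#' @param duration session length, seconds.
#' @param unitId label.
#' @return a [UnitRecording-class].
#' @export
generateUnit <- function(spec, calls, touches, duration, unitId = "u1") {
  callW <- if (nrow(calls))
    mergeWindows(cbind(calls$onset_s + spec@callLatencyS,
                       calls$offset_s + spec@callLatencyS + 0.025))
  else matrix(numeric(0), ncol = 2)
  tw <- touchWindows(touches)
  offW <- if (nrow(tw))
    mergeWindows(intersectWindows(
      cbind(tw[, 2], tw[, 2] + 0.2),
      complementWindows(tw, 0, duration + 1)))
  else matrix(numeric(0), ncol = 2)
  bounds <- sort(unique(pmin(pmax(
    c(0, duration, as.vector(callW), as.vector(tw), as.vector(offW)),
    0), duration)))
  mids <- (bounds[-1] + bounds[-length(bounds)]) / 2
  rate <- rep(spec@baseRate, length(mids))
  rate[inAnyWindow(mids, callW)] <- rate[inAnyWindow(mids, callW)] *
    spec@callGain
  rate[inAnyWindow(mids, tw)] <- rate[inAnyWindow(mids, tw)] * spec@touchGain
  rate[inAnyWindow(mids, offW)] <- rate[inAnyWindow(mids, offW)] *
    spec@offGain
  spk <- samplePiecewisePoisson(bounds, rate)
  # mean waveform: 1 ms at 32 kHz, peak at sample 9 (250 us pre / 750 us post).
  # Asymmetric bump: fast fixed rise, class-dependent decay, so that the
  # full width at 25% of peak equals the drawn `width`.
  fs <- 32000
  width <- max(1.5e-4, stats::rnorm(1, spec@widthMeanS, spec@widthSdS))
  cross <- sqrt(2 * log(4))             # crossing distance in sigmas
  sigmaRise <- 5e-5
  sigmaFall <- max(3e-5, width / cross - sigmaRise)
  tts <- (seq_len(32) - 9) / fs
  wf <- -exp(-tts^2 / (2 * ifelse(tts < 0, sigmaRise, sigmaFall)^2))
  new("UnitRecording", unitId = unitId, spikeTimes = spk, waveform = wf,
      waveformRate = fs, subregion = spec@subregion,
      cellClass = NA_character_, stabilityR = NA_real_)
}

#' Generate a full synthetic session
#'
#' Composes whisking (subject and stimulus), touch episodes, phase-coupled
#' calls, microphone intensities and unit spike trains under one seed.
#' Ground truth (true emitters, coupling and rate parameters, true cell
#' classes) is stored in the session's `truth` list.
#'
#' @param cfg a [SynthConfig-class]; see [synthConfig()].
#' @return a [SessionRecording-class].
#' @examples
#' s <- generateSession(synthConfig(durationS = 60, aloneDurationS = 20,
#'                                  seed = 1))
#' s
#' @export
generateSession <- function(cfg = synthConfig()) {
  validObject(cfg)
  set.seed(cfg@seed)
  subj <- generateWhisking(cfg, "subject")
  stim <- if (cfg@nAnimals >= 2) generateWhisking(cfg, "stimulus") else NULL
  filt <- preprocessTrace(subj)
  cyc <- detectCycles(filt)
  phase <- tryCatch(computePhase(filt, cyc), error = function(e) NULL)
  if (is.null(phase) && cfg@phaseKappa > 0) {
    warning("no valid whisking cycles; generating phase-uncoupled calls")
    cfg@phaseKappa <- 0
  }
  scenarios <- list(
    subject_alone = matrix(c(0, cfg@aloneDurationS), ncol = 2),
    social_setting = matrix(c(cfg@aloneDurationS, cfg@durationS), ncol = 2))
  touches <- if (cfg@aloneDurationS < cfg@durationS)
    generateTouchEpisodes(cfg) else emptyTouchTable()
  calls <- generateCalls(cfg, phase = phase, touches = touches,
                         scenarios = scenarios)
  calls <- generateMicIntensities(calls, cfg)
  units <- lapply(seq_along(cfg@unitSpecs), function(i)
    generateUnit(cfg@unitSpecs[[i]], calls, touches, cfg@durationS,
                 unitId = sprintf("u%02d", i)))
  truth <- list(
    whiskRateHz = cfg@whiskRateHz, cycleJitterCv = cfg@cycleJitterCv,
    whiskAmplitudeDeg = cfg@whiskAmplitudeDeg,
    callRateAlone = cfg@callRateAlone, callRateOut = cfg@callRateOut,
    callRateIn = cfg@callRateIn, phaseKappa = cfg@phaseKappa,
    preferredPhaseDeg = cfg@preferredPhaseDeg,
    micDirectionality = cfg@micDirectionality,
    intensityNoiseCv = cfg@intensityNoiseCv,
    subjectCallFraction = cfg@subjectCallFraction,
    emitter = calls$emitter,
    unitClass = vapply(cfg@unitSpecs, function(s) s@cellClass, character(1)),
    baseRate = vapply(cfg@unitSpecs, function(s) s@baseRate, numeric(1)),
    callGain = vapply(cfg@unitSpecs, function(s) s@callGain, numeric(1)),
    touchGain = vapply(cfg@unitSpecs, function(s) s@touchGain, numeric(1)),
    offGain = vapply(cfg@unitSpecs, function(s) s@offGain, numeric(1)),
    seed = cfg@seed)
  traces <- if (is.null(stim)) list(subj) else list(subj, stim)
  new("SessionRecording",
      sessionId = sprintf("synthetic-seed%d", cfg@seed),
      duration = cfg@durationS, whiskerTraces = traces, calls = calls,
      touches = touches, units = units, scenarioWindows = scenarios,
      audio = NULL, truth = truth)
}
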