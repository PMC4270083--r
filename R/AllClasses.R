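#' @import methods
NULL

CALL_CATEGORIES <- c("trill", "complex", "flat", "upward_ramp",
                     "downward_ramp", "inverted_u", "split", "short",
                     "fear", "unspecified")
EMITTER_LEVELS <- c("subject", "stimulus", "unassigned")
STIMULUS_KINDS <- c("conspecific", "object", "plastinate", "anaesthetized")
SUBREGIONS <- c("AuD", "Au1", "AuV")

#' WhiskerTrace: a whisker-angle time series
#'
#' Angle of one tracked whisker versus time, on a uniform grid. Protraction
#' (forward sweep) takes positive values, 0 degrees is orthogonal to the head
#' axis. Raw traces are typically sampled at the high-speed camera rate
#' (250 Hz); see [preprocessTrace()] for up-sampling and band-pass filtering.
#'
#' @slot animalId character scalar identifying the tracked animal.
#' @slot times numeric, seconds; strictly increasing uniform grid.
#' @slot angle numeric, degrees; finite or NA (masked).
#' @slot sampleRate numeric, Hz.
#' @export
setClass("WhiskerTrace",
  representation(animalId = "character", times = "numeric",
                 angle = "numeric", sampleRate = "numeric"),
  prototype(animalId = NA_character_, times = numeric(0),
            angle = numeric(0), sampleRate = NA_real_))

setValidity("WhiskerTrace", function(object) {
  msg <- character(0)
  if (length(object@times) != length(object@angle))
    msg <- c(msg, "times and angle must have equal length")
  n <- length(object@times)
  if (n >= 2) {
    dt <- diff(object@times)
    if (any(dt <= 0))
      msg <- c(msg, "times must be strictly increasing")
    else if (max(dt) - min(dt) > 1e-9)
      msg <- c(msg, "times must lie on a uniform grid (tolerance 1e-9 s)")
  }
  if (any(is.infinite(object@angle)))
    msg <- c(msg, "angle must be finite or NA")
  if (length(msg)) msg else TRUE
})

#' FilteredTrace: band-passed whisker trace at 1 kHz
#'
#' Result of [preprocessTrace()]: linear-interpolation up-sampling to 1000 Hz
#' followed by zero-phase fourth-order Butterworth band-pass filtering in the
#' whisking band (1-25 Hz). Mean is approximately zero (the DC posture
#' component is removed).
#'
#' @export
setClass("FilteredTrace", contains = "WhiskerTrace")

#' PhaseTrace: instantaneous whisking phase
#'
#' Phase within the whisk cycle in degrees, 0 at maximum protraction,
#' 180 at maximum retraction, wrapping below 360. Samples outside
#' quality-controlled cycles carry `valid = FALSE` and are excluded from all
#' phase statistics. Retraction is the half (0, 180], protraction (180, 360).
#'
#' @slot animalId character scalar.
#' @slot times numeric, seconds.
#' @slot phase numeric, degrees in [0, 360).
#' @slot valid logical mask, one flag per sample.
#' @slot sampleRate numeric, Hz.
#' @export
setClass("PhaseTrace",
  representation(animalId = "character", times = "numeric",
                 phase = "numeric", valid = "logical", sampleRate = "numeric"))

setValidity("PhaseTrace", function(object) {
  msg <- character(0)
  if (length(object@times) != length(object@phase) ||
      length(object@times) != length(object@valid))
    msg <- c(msg, "times, phase and valid must have equal length")
  ph <- object@phase[object@valid]
  if (length(ph) && (any(ph < 0) || any(ph >= 360)))
    msg <- c(msg, "valid phase samples must lie in [0, 360)")
  if (length(msg)) msg else TRUE
})

#' AudioTrack: single-channel PCM audio
#'
#' @slot samples numeric vector, linear amplitude.
#' @slot sampleRate numeric, Hz (ultrasound recordings: 250 kHz).
#' @export
setClass("AudioTrack",
  representation(samples = "numeric", sampleRate = "numeric"))

#' UnitRecording: one sorted single unit
#'
#' Spike times, mean spike waveform, anatomical subregion, and (once computed)
#' the putative cell class and recording-stability score.
#'
#' @slot unitId character scalar.
#' @slot spikeTimes numeric, seconds, sorted ascending.
#' @slot waveform numeric, mean spike waveform samples.
#' @slot waveformRate numeric, Hz of the waveform sampling (typically 32 kHz).
#' @slot subregion one of "AuD", "Au1", "AuV" (or NA).
#' @slot cellClass "RS", "FS" or NA before classification.
#' @slot stabilityR mean absolute Pearson R of the drift permutation test,
#'   NA before computation.
#' @export
setClass("UnitRecording",
  representation(unitId = "character", spikeTimes = "numeric",
                 waveform = "numeric", waveformRate = "numeric",
                 subregion = "character", cellClass = "character",
                 stabilityR = "numeric"),
  prototype(unitId = NA_character_, spikeTimes = numeric(0),
            waveform = numeric(0), waveformRate = 32000,
            subregion = NA_character_, cellClass = NA_character_,
            stabilityR = NA_real_))

setValidity("UnitRecording", function(object) {
  msg <- character(0)
  st <- object@spikeTimes
  if (is.unsorted(st))
    msg <- c(msg, sprintf("spike times of unit %s not sorted ascending",
                          object@unitId))
  if (length(st) >= 2 && any(diff(st) < 1e-9))
    msg <- c(msg, sprintf("duplicate spike times in unit %s", object@unitId))
  if (!is.na(object@subregion) && !object@subregion %in% SUBREGIONS)
    msg <- c(msg, "subregion must be one of AuD, Au1, AuV")
  if (!is.na(object@cellClass) && !object@cellClass %in% c("RS", "FS"))
    msg <- c(msg, "cellClass must be RS or FS")
  if (length(msg)) msg else TRUE
})

CALL_COLUMNS <- c("onset_s", "offset_s", "category", "mean_freq_khz",
                  "bandwidth_khz", "i_ch1", "i_ch2", "i_ch3", "i_ch4",
                  "emitter")
TOUCH_COLUMNS <- c("whisker_on_s", "snout_on_s", "snout_off_s",
                   "whisker_off_s", "stimulus_kind")

emptyCallTable <- function() {
  data.frame(onset_s = numeric(0), offset_s = numeric(0),
             category = character(0), mean_freq_khz = numeric(0),
             bandwidth_khz = numeric(0), i_ch1 = numeric(0),
             i_ch2 = numeric(0), i_ch3 = numeric(0), i_ch4 = numeric(0),
             emitter = character(0), stringsAsFactors = FALSE)
}

emptyTouchTable <- function() {
  data.frame(whisker_on_s = numeric(0), snout_on_s = numeric(0),
             snout_off_s = numeric(0), whisker_off_s = numeric(0),
             stimulus_kind = character(0), stringsAsFactors = FALSE)
}

#' SessionRecording: one recording session on a common clock
#'
#' Binds whisker traces, USV call events, facial-touch episodes, sorted units
#' and (optionally) audio, all in seconds on a single session clock starting
#' at 0. Calls and touches are stored as data frames with fixed schemas (see
#' [loadSession()]); touch intervals are half-open `[start, end)`, so an event
#' at exactly a touch offset falls outside the touch.
#'
#' @slot sessionId character scalar.
#' @slot duration session length, seconds.
#' @slot whiskerTraces list of [WhiskerTrace-class], one per tracked animal.
#' @slot calls data.frame: onset_s, offset_s, category, mean_freq_khz,
#'   bandwidth_khz, i_ch1..i_ch4, emitter.
#' @slot touches data.frame: whisker_on_s, snout_on_s, snout_off_s,
#'   whisker_off_s, stimulus_kind.
#' @slot units list of [UnitRecording-class].
#' @slot scenarioWindows named list; each element a 2-column matrix of
#'   (start, end) windows in seconds ("subject_alone", "social_setting", ...).
#' @slot audio an [AudioTrack-class] or NULL.
#' @slot truth list of ground-truth generator parameters (synthetic sessions
#'   only; empty for real data).
#' @export
setClass("SessionRecording",
  representation(sessionId = "character", duration = "numeric",
                 whiskerTraces = "list", calls = "data.frame",
                 touches = "data.frame", units = "list",
                 scenarioWindows = "list", audio = "ANY", truth = "list"),
  prototype(sessionId = "session", duration = 0, whiskerTraces = list(),
            calls = emptyCallTable(), touches = emptyTouchTable(),
            units = list(), scenarioWindows = list(), audio = NULL,
            truth = list()))

setValidity("SessionRecording", function(object) {
  msg <- character(0)
  msg <- c(msg, validateCallTable(object@calls, object@duration))
  msg <- c(msg, validateTouchTable(object@touches, object@duration))
  for (tr in object@whiskerTraces)
    if (!is(tr, "WhiskerTrace")) msg <- c(msg, "whiskerTraces must contain WhiskerTrace objects")
  for (u in object@units) {
    if (!is(u, "UnitRecording")) { msg <- c(msg, "units must contain UnitRecording objects"); next }
    if (length(u@spikeTimes) && (min(u@spikeTimes) < 0 ||
                                 max(u@spikeTimes) > object@duration))
      msg <- c(msg, sprintf("spike times of unit %s outside [0, duration]", u@unitId))
  }
  sw <- object@scenarioWindows
  if (all(c("subject_alone", "social_setting") %in% names(sw))) {
    if (windowsOverlap(sw[["subject_alone"]], sw[["social_setting"]]))
      msg <- c(msg, "subject_alone and social_setting windows must be disjoint")
  }
  if (length(msg)) msg else TRUE
})

# ---- event-table validation ---------------------------------------------

validateCallTable <- function(calls, duration = Inf) {
  msg <- character(0)
  missing <- setdiff(CALL_COLUMNS, names(calls))
  if (length(missing))
    return(sprintf("calls table missing column(s): %s",
                   paste(missing, collapse = ", ")))
  if (!nrow(calls)) return(msg)
  bad <- which(calls$offset_s <= calls$onset_s)
  if (length(bad))
    msg <- c(msg, sprintf("call(s) with offset <= onset at row(s) %s",
                          paste(utils::head(bad, 5), collapse = ", ")))
  if (any(calls$onset_s < 0) || any(calls$offset_s > duration + 1e-9))
    msg <- c(msg, "call events outside [0, session duration]")
  ich <- as.matrix(calls[, c("i_ch1", "i_ch2", "i_ch3", "i_ch4")])
  if (any(ich < 0, na.rm = TRUE))
    msg <- c(msg, "channel intensities must be >= 0")
  if (!all(calls$category %in% CALL_CATEGORIES))
    msg <- c(msg, "unknown call category label")
  if (!all(calls$emitter %in% EMITTER_LEVELS))
    msg <- c(msg, "emitter must be subject, stimulus or unassigned")
  msg
}

validateTouchTable <- function(touches, duration = Inf) {
  msg <- character(0)
  missing <- setdiff(TOUCH_COLUMNS, names(touches))
  if (length(missing))
    return(sprintf("touches table missing column(s): %s",
                   paste(missing, collapse = ", ")))
  if (!nrow(touches)) return(msg)
  if (any(touches$whisker_on_s >= touches$whisker_off_s))
    msg <- c(msg, "touch episode(s) with whisker_on >= whisker_off")
  if (any(touches$whisker_on_s < 0) ||
      any(touches$whisker_off_s > duration + 1e-9))
    msg <- c(msg, "touch episodes outside [0, session duration]")
  has_snout <- !is.na(touches$snout_on_s)
  if (any(has_snout & (touches$snout_on_s < touches$whisker_on_s |
                       touches$snout_off_s > touches$whisker_off_s |
                       touches$snout_on_s >= touches$snout_off_s), na.rm = TRUE))
    msg <- c(msg, "snout interval must nest within its whisker interval")
  if (nrow(touches) >= 2) {
    o <- order(touches$whisker_on_s)
    on <- touches$whisker_on_s[o]; off <- touches$whisker_off_s[o]
    ov <- which(on[-1] < off[-length(off)])
    if (length(ov))
      msg <- c(msg, sprintf("overlapping touch episodes (sorted rows %s)",
                            paste(utils::head(ov, 5), collapse = ", ")))
  }
  if (!all(touches$stimulus_kind %in% STIMULUS_KINDS))
    msg <- c(msg, "unknown stimulus_kind")
  msg
}

windowsOverlap <- function(a, b) {
  if (is.null(a) || is.null(b)) return(FALSE)
  if (!is.matrix(a)) a <- matrix(a, ncol = 2, byrow = TRUE)
  if (!is.matrix(b)) b <- matrix(b, ncol = 2, byrow = TRUE)
  if (!nrow(a) || !nrow(b)) return(FALSE)
  for (i in seq_len(nrow(a)))
    if (any(a[i, 1] < b[, 2] & b[, 1] < a[i, 2])) return(TRUE)
  FALSE
}

# ---- configuration objects ----------------------------------------------

#' AnalysisConfig: tunable parameters of the analysis pipeline
#'
#' All downstream tunables with defaults matching the documented analysis:
#' 1-25 Hz fourth-order zero-phase Butterworth band, 1 kHz up-sampling,
#' 50-250 ms / 7.5 degree cycle quality control, call-duration + 25 ms
#' response window, -10 s clean-time baseline shift, assignment margin 1.5,
#' 16 phase bins, >=10 spikes / Rayleigh > 0.2 / 95 % shuffle-quantile
#' locking criterion. `nShuffles` defaults to 10000 as in the original
#' procedure; analyses at desk scale may lower it via the config.
#'
#' @export
setClass("AnalysisConfig",
  representation(
    filterLowHz = "numeric", filterHighHz = "numeric", filterOrder = "numeric",
    upsampleRateHz = "numeric",
    cycleMinS = "numeric", cycleMaxS = "numeric", cycleMinAmpDeg = "numeric",
    peakMinSepS = "numeric",
    psdBandHz = "numeric",
    responseWindowMode = "character", baselineShiftS = "numeric",
    offWindowS = "numeric", callPadS = "numeric",
    assignMargin = "numeric",
    psthBinCallS = "numeric", psthBinTouchS = "numeric",
    psthBinCallsTouchS = "numeric",
    phaseBins = "numeric", minSpikes = "numeric", rayleighMin = "numeric",
    shuffleAlpha = "numeric", nShuffles = "numeric",
    nBootstrap = "numeric", nPermStability = "numeric",
    stabilityMaxR = "numeric", minCallsPerCondition = "numeric",
    seed = "numeric"),
  prototype(
    filterLowHz = 1, filterHighHz = 25, filterOrder = 4,
    upsampleRateHz = 1000,
    cycleMinS = 0.050, cycleMaxS = 0.250, cycleMinAmpDeg = 7.5,
    peakMinSepS = 0.040,
    psdBandHz = c(4, 25),
    responseWindowMode = "call_duration_plus_25ms", baselineShiftS = 10,
    offWindowS = 0.200, callPadS = 0.025,
    assignMargin = 1.5,
    psthBinCallS = 0.010, psthBinTouchS = 0.077, psthBinCallsTouchS = 0.500,
    phaseBins = 16, minSpikes = 10, rayleighMin = 0.2,
    shuffleAlpha = 0.05, nShuffles = 10000,
    nBootstrap = 1000, nPermStability = 1000,
    stabilityMaxR = 0.4, minCallsPerCondition = 5,
    seed = 1))

RESPONSE_WINDOW_MODES <- c("call_duration", "call_duration_plus_25ms",
                           "onset_0_25", "onset_26_50", "onset_51_75",
                           "onset_76_100")

setValidity("AnalysisConfig", function(object) {
  msg <- character(0)
  if (object@filterLowHz <= 0 || object@filterHighHz <= object@filterLowHz)
    msg <- c(msg, "filter band must satisfy 0 < low < high")
  if (!object@responseWindowMode %in% RESPONSE_WINDOW_MODES)
    msg <- c(msg, sprintf("responseWindowMode must be one of: %s",
                          paste(RESPONSE_WINDOW_MODES, collapse = ", ")))
  if (object@cycleMinS >= object@cycleMaxS)
    msg <- c(msg, "cycleMinS must be below cycleMaxS")
  if (length(object@psdBandHz) != 2 || diff(object@psdBandHz) <= 0)
    msg <- c(msg, "psdBandHz must be an increasing pair")
  if (object@shuffleAlpha <= 0 || object@shuffleAlpha >= 1)
    msg <- c(msg, "shuffleAlpha must be in (0,1)")
  if (length(msg)) msg else TRUE
})

#' Create an analysis configuration
#'
#' @param ... named slot overrides of [AnalysisConfig-class] defaults.
#' @return an `AnalysisConfig` object.
#' @examples
#' cfg <- analysisConfig(nShuffles = 1000, seed = 7)
#' @export
analysisConfig <- function(...) new("AnalysisConfig", ...)

#' UnitSpec: generative parameters of one synthetic unit
#'
#' Rate model: inhomogeneous Poisson with rate = baseRate, multiplied by
#' `callGain` inside each call window (call duration + 25 ms, delayed by
#' `callLatencyS`), by `touchGain` inside touch episodes, and by `offGain` in
#' the 200 ms after each touch offset. Waveform width is drawn from a
#' class-specific Gaussian (RS wide, FS narrow).
#'
#' @export
setClass("UnitSpec",
  representation(cellClass = "character", baseRate = "numeric",
                 callGain = "numeric", callLatencyS = "numeric",
                 touchGain = "numeric", offGain = "numeric",
                 widthMeanS = "numeric", widthSdS = "numeric",
                 subregion = "character"),
  prototype(cellClass = "RS", baseRate = 5, callGain = 1, callLatencyS = 0.010,
            touchGain = 1, offGain = 1, widthMeanS = 6e-4, widthSdS = 5e-5,
            subregion = "Au1"))

setValidity("UnitSpec", function(object) {
  msg <- character(0)
  if (!object@cellClass %in% c("RS", "FS"))
    msg <- c(msg, "cellClass must be RS or FS")
  if (any(c(object@baseRate, object@callGain, object@touchGain,
            object@offGain) < 0))
    msg <- c(msg, "rates and gain factors must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create a synthetic unit specification
#'
#' Class defaults follow the population medians of the study system: regular
#' spiking (RS) units fire around 4.4 Hz with wide (~0.6 ms) waveforms,
#' fast spiking (FS) units around 11.1 Hz with narrow (~0.3 ms) waveforms.
#'
#' @param cellClass "RS" or "FS".
#' @param ... further slot overrides of [UnitSpec-class].
#' @export
unitSpec <- function(cellClass = "RS", ...) {
  defaults <- if (cellClass == "FS")
    list(baseRate = 11.1, widthMeanS = 3e-4, widthSdS = 5e-5)
  else
    list(baseRate = 4.4, widthMeanS = 6e-4, widthSdS = 5e-5)
  args <- utils::modifyList(defaults, list(...))
  do.call(new, c(list("UnitSpec", cellClass = cellClass), args))
}

#' SynthConfig: parameters of the synthetic-session generator
#'
#' Defaults encode the study conditions: ~8 Hz whisking with cycle-length
#' jitter, a 5 min subject-alone baseline followed by a social period,
#' calling at 0.13 Hz alone / 0.80 Hz social / 1.50 Hz during touch,
#' touch episodes of 2.86 +/- 2.68 s (lognormal) at 1.76 events/min, subject
#' calls phase-locked to the subject's whisker retraction (von Mises about
#' 90 degrees), directional four-microphone intensities, and units with
#' call-evoked excitation, touch-evoked suppression and a post-touch
#' off-response.
#'
#' @export
setClass("SynthConfig",
  representation(
    durationS = "numeric", aloneDurationS = "numeric",
    whiskRateHz = "numeric", whiskAmplitudeDeg = "numeric",
    cycleJitterCv = "numeric", traceSampleRateHz = "numeric",
    nAnimals = "numeric",
    touchSchedule = "matrix", touchRatePerS = "numeric",
    touchMeanS = "numeric", touchSdS = "numeric", touchMinS = "numeric",
    stimulusKind = "character",
    callRateAlone = "numeric", callRateOut = "numeric", callRateIn = "numeric",
    subjectCallFraction = "numeric",
    phaseKappa = "numeric", preferredPhaseDeg = "numeric",
    micDirectionality = "numeric", intensityNoiseCv = "numeric",
    categoryProportions = "numeric",
    unitSpecs = "list", seed = "numeric"),
  prototype(
    durationS = 600, aloneDurationS = 300,
    whiskRateHz = 8, whiskAmplitudeDeg = 20,
    cycleJitterCv = 0.1, traceSampleRateHz = 250,
    nAnimals = 2,
    touchSchedule = matrix(numeric(0), ncol = 2), touchRatePerS = 1.76 / 60,
    touchMeanS = 2.86, touchSdS = 2.68, touchMinS = 0.2,
    stimulusKind = "conspecific",
    callRateAlone = 0.13, callRateOut = 0.80, callRateIn = 1.50,
    subjectCallFraction = 0.6,
    phaseKappa = 1, preferredPhaseDeg = 90,
    micDirectionality = 2, intensityNoiseCv = 0.5,
    categoryProportions = numeric(0),
    unitSpecs = list(), seed = 1))

setValidity("SynthConfig", function(object) {
  msg <- character(0)
  if (any(c(object@callRateAlone, object@callRateOut, object@callRateIn) < 0))
    msg <- c(msg, "call rates must be >= 0")
  if (object@phaseKappa < 0) msg <- c(msg, "phaseKappa must be >= 0")
  if (object@micDirectionality <= 1)
    msg <- c(msg, "micDirectionality must exceed 1")
  if (object@durationS <= 0) msg <- c(msg, "durationS must be positive")
  if (object@aloneDurationS < 0 || object@aloneDurationS > object@durationS)
    msg <- c(msg, "aloneDurationS must lie in [0, durationS]")
  if (length(msg)) msg else TRUE
})

#' Create a synthetic-session configuration
#'
#' @param ... named slot overrides of [SynthConfig-class] defaults.
#' @return a `SynthConfig` object.
#' @examples
#' cfg <- synthConfig(durationS = 120, seed = 42)
#' @export
synthConfig <- function(...) {
  args <- list(...)
  if (!is.null(args$durationS) && is.null(args$aloneDurationS))
    args$aloneDurationS <- min(300, args$durationS / 2)
  cfg <- do.call(new, c(list("SynthConfig"), args))
  if (!length(cfg@categoryProportions))
    cfg@categoryProportions <- defaultCategoryProportions()
  if (!length(cfg@unitSpecs))
    cfg@unitSpecs <- defaultUnitSpecs()
  cfg
}
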