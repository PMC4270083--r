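# Session I/O: CSV dialects for traces and event tables, session metadata
# JSON, PCM WAV audio, and YAML analysis configuration.
#
# Numeric columns are written with %.17g so doubles round-trip exactly.

fmtNum <- function(x) {
  out <- vapply(x, function(v)
    if (is.na(v)) "" else sprintf("%.17g", v), character(1))
  out
}

writeTable <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- fmtNum(out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
}

readTable <- function(path, requiredCols, numericCols) {
  if (!file.exists(path)) stop(sprintf("missing input file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(requiredCols, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", basename(path),
                 paste(missing, collapse = ", ")))
  for (cc in intersect(numericCols, names(df)))
    df[[cc]] <- as.numeric(df[[cc]])
  df
}

#' Write a session to a directory of CSV files
#'
#' Emits `whisker_trace.csv`, `calls.csv`, `touches.csv`, `spikes.csv`,
#' `waveforms.csv`, `units.csv` and `session.json` (plus `truth.json` for
#' synthetic sessions); lossless for all fields ([loadSession()] of the
#' output reproduces the session exactly).
#'
#' @param session a [SessionRecording-class].
#' @param outDir output directory (created if absent).
#' @return invisibly, the vector of file paths written.
#' @export
writeSession <- function(session, outDir) {
  stopifnot(is(session, "SessionRecording"))
  validObject(session)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- function(f) file.path(outDir, f)

  wt <- do.call(rbind, lapply(session@whiskerTraces, function(tr)
    data.frame(animal_id = tr@animalId, time_s = tr@times,
               angle_deg = tr@angle)))
  if (is.null(wt))
    wt <- data.frame(animal_id = character(0), time_s = numeric(0),
                     angle_deg = numeric(0))
  writeTable(wt, p("whisker_trace.csv")); paths <- c(paths, p("whisker_trace.csv"))
  writeTable(session@calls[, CALL_COLUMNS, drop = FALSE], p("calls.csv"))
  writeTable(session@touches[, TOUCH_COLUMNS, drop = FALSE], p("touches.csv"))
  paths <- c(paths, p("calls.csv"), p("touches.csv"))

  spikes <- do.call(rbind, lapply(session@units, function(u)
    if (length(u@spikeTimes))
      data.frame(unit_id = u@unitId, spike_time_s = u@spikeTimes)
    else NULL))
  if (is.null(spikes))
    spikes <- data.frame(unit_id = character(0), spike_time_s = numeric(0))
  writeTable(spikes, p("spikes.csv"))
  wf <- do.call(rbind, lapply(session@units, function(u)
    if (length(u@waveform))
      data.frame(unit_id = u@unitId,
                 sample_idx = seq_along(u@waveform) - 1L,
                 amplitude = u@waveform)
    else NULL))
  if (is.null(wf))
    wf <- data.frame(unit_id = character(0), sample_idx = integer(0),
                     amplitude = numeric(0))
  writeTable(wf, p("waveforms.csv"))
  un <- do.call(rbind, lapply(session@units, function(u)
    data.frame(unit_id = u@unitId, subregion = u@subregion,
               cell_class = u@cellClass, stability_r = u@stabilityR,
               waveform_rate_hz = u@waveformRate)))
  if (is.null(un))
    un <- data.frame(unit_id = character(0), subregion = character(0),
                     cell_class = character(0), stability_r = numeric(0),
                     waveform_rate_hz = numeric(0))
  writeTable(un, p("units.csv"))
  paths <- c(paths, p("spikes.csv"), p("waveforms.csv"), p("units.csv"))

  meta <- list(
    session_id = session@sessionId, duration_s = session@duration,
    trace_sample_rates = lapply(session@whiskerTraces,
                                function(tr) tr@sampleRate),
    trace_animals = lapply(session@whiskerTraces, function(tr) tr@animalId),
    scenario_windows = lapply(session@scenarioWindows, function(w)
      lapply(seq_len(nrow(w)), function(i) c(w[i, 1], w[i, 2]))))
  jsonlite::write_json(meta, p("session.json"), auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p("session.json"))
  if (length(session@truth)) {
    jsonlite::write_json(session@truth, p("truth.json"), auto_unbox = TRUE,
                         digits = NA)
    paths <- c(paths, p("truth.json"))
  }
  if (!is.null(session@audio)) {
    writeWavPcm(session@audio, p("audio.wav"))
    paths <- c(paths, p("audio.wav"))
  }
  invisible(paths)
}

#' Load a session from a directory of CSV files
#'
#' Reads the CSV dialects written by [writeSession()] and returns a validated
#' [SessionRecording-class]. Missing required columns raise a schema error
#' naming the column; invariant violations (non-monotone spike times,
#' overlapping touch episodes, calls with non-positive duration) raise
#' validation errors listing the offenders.
#'
#' @param dir directory containing the session files.
#' @param config an [AnalysisConfig-class] (reserved for unit conversions).
#' @return a [SessionRecording-class].
#' @export
loadSession <- function(dir, config = analysisConfig()) {
  p <- function(f) file.path(dir, f)
  meta <- jsonlite::read_json(p("session.json"), simplifyVector = TRUE)
  wt <- readTable(p("whisker_trace.csv"),
                  c("animal_id", "time_s", "angle_deg"),
                  c("time_s", "angle_deg"))
  rates <- unlist(meta$trace_sample_rates)
  animals <- unlist(meta$trace_animals)
  traces <- lapply(seq_along(animals), function(i) {
    sel <- wt$animal_id == animals[i]
    new("WhiskerTrace", animalId = animals[i], times = wt$time_s[sel],
        angle = wt$angle_deg[sel], sampleRate = rates[i])
  })
  calls <- readTable(p("calls.csv"), CALL_COLUMNS,
                     setdiff(CALL_COLUMNS, c("category", "emitter")))
  if (!nrow(calls)) calls <- emptyCallTable()
  calls$category <- as.character(calls$category)
  calls$emitter <- as.character(calls$emitter)
  touches <- readTable(p("touches.csv"), TOUCH_COLUMNS,
                       setdiff(TOUCH_COLUMNS, "stimulus_kind"))
  if (!nrow(touches)) touches <- emptyTouchTable()
  touches$stimulus_kind <- as.character(touches$stimulus_kind)
  spikes <- readTable(p("spikes.csv"), c("unit_id", "spike_time_s"),
                      "spike_time_s")
  wf <- readTable(p("waveforms.csv"),
                  c("unit_id", "sample_idx", "amplitude"),
                  c("sample_idx", "amplitude"))
  un <- readTable(p("units.csv"), c("unit_id", "subregion"),
                  c("stability_r", "waveform_rate_hz"))
  units <- lapply(seq_len(nrow(un)), function(i) {
    uid <- un$unit_id[i]
    st <- spikes$spike_time_s[spikes$unit_id == uid]
    if (is.unsorted(st))
      stop(sprintf("validation error: spike times of unit %s are not monotone",
                   uid))
    w <- wf[wf$unit_id == uid, ]
    w <- w[order(w$sample_idx), ]
    new("UnitRecording", unitId = uid, spikeTimes = st,
        waveform = w$amplitude,
        waveformRate = if ("waveform_rate_hz" %in% names(un) &&
                           is.finite(un$waveform_rate_hz[i]))
          un$waveform_rate_hz[i] else 32000,
        subregion = as.character(un$subregion[i]),
        cellClass = if ("cell_class" %in% names(un))
          naIfEmpty(un$cell_class[i]) else NA_character_,
        stabilityR = if ("stability_r" %in% names(un))
          un$stability_r[i] else NA_real_)
  })
  sw <- lapply(meta$scenario_windows, function(w) {
    if (is.null(w) || !length(w)) return(matrix(numeric(0), ncol = 2))
    if (is.matrix(w)) return(w)
    if (is.list(w)) return(do.call(rbind, lapply(w, as.numeric)))
    matrix(as.numeric(w), ncol = 2, byrow = TRUE)
  })
  audio <- if (file.exists(p("audio.wav"))) readWavPcm(p("audio.wav")) else NULL
  truth <- if (file.exists(p("truth.json")))
    jsonlite::read_json(p("truth.json"), simplifyVector = TRUE) else list()
  new("SessionRecording", sessionId = meta$session_id,
      duration = meta$duration_s, whiskerTraces = traces, calls = calls,
      touches = touches, units = units, scenarioWindows = sw, audio = audio,
      truth = truth)
}

naIfEmpty <- function(x) {
  x <- as.character(x)
  if (!length(x) || is.na(x) || !nzchar(x)) NA_character_ else x
}

#' Read / write 16-bit PCM WAV audio
#'
#' Minimal single-channel PCM reader/writer (RIFF/WAVE, format 1, 16 bit).
#' Samples are scaled to \[-1, 1\].
#'
#' @param path file path.
#' @return `readWavPcm`: an [AudioTrack-class].
#' @export
readWavPcm <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (hdr != "RIFF") stop("not a RIFF file")
  invisible(readBin(con, integer(), 1, 4, endian = "little"))
  if (readChar(con, 4, useBytes = TRUE) != "WAVE") stop("not a WAVE file")
  fmt <- NULL; samples <- NULL; rate <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (!length(id) || !nzchar(id)) break
    size <- readBin(con, integer(), 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), 2, 2, endian = "little")
      if (fmt[1] != 1 || fmt[2] != 1)
        stop("only single-channel PCM WAV is supported")
      rate <- readBin(con, integer(), 1, 4, endian = "little")
      invisible(readBin(con, integer(), 1, 4, endian = "little"))
      invisible(readBin(con, integer(), 2, 2, endian = "little"))
      if (size > 16) invisible(readBin(con, raw(), size - 16))
    } else if (id == "data") {
      samples <- readBin(con, integer(), size / 2, 2, signed = TRUE,
                         endian = "little")
      break
    } else invisible(readBin(con, raw(), size))
  }
  if (is.null(samples) || is.null(rate)) stop("malformed WAV file")
  new("AudioTrack", samples = samples / 32767, sampleRate = rate)
}

#' @rdname readWavPcm
#' @param audio an [AudioTrack-class]; samples clipped to \[-1, 1\].
#' @export
writeWavPcm <- function(audio, path) {
  stopifnot(is(audio, "AudioTrack"))
  s <- as.integer(round(pmin(pmax(audio@samples, -1), 1) * 32767))
  con <- file(path, "wb"); on.exit(close(con))
  dataSize <- 2L * length(s)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + dataSize), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L, 1L), con, 2, endian = "little")
  writeBin(as.integer(audio@sampleRate), con, 4, endian = "little")
  writeBin(as.integer(audio@sampleRate * 2), con, 4, endian = "little")
  writeBin(c(2L, 16L), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(dataSize, con, 4, endian = "little")
  writeBin(s, con, 2, endian = "little")
  invisible(path)
}

#' Read / write an analysis configuration as YAML
#'
#' Flat key/value file mirroring [AnalysisConfig-class] slot names.
#'
#' @param path file path.
#' @return `readAnalysisConfig`: an [AnalysisConfig-class].
#' @export
readAnalysisConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- slotNames("AnalysisConfig")
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  do.call(new, c(list("AnalysisConfig"), vals))
}

#' @rdname readAnalysisConfig
#' @param config an [AnalysisConfig-class].
#' @export
writeAnalysisConfig <- function(config, path) {
  vals <- lapply(slotNames("AnalysisConfig"), function(s) slot(config, s))
  names(vals) <- slotNames("AnalysisConfig")
  yaml::write_yaml(vals, path)
  invisible(path)
}
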