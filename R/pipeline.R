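# End-to-end pipeline: whisking -> vocal -> coordination -> units ->
# responses -> phase locking, with per-stage skipping on missing data and a
# machine-readable report.

stageSafely <- function(name, expr) {
  res <- tryCatch(list(status = "ok", result = expr),
                  error = function(e)
                    list(status = "skipped", reason = conditionMessage(e),
                         result = NULL))
  message(sprintf("[usvwhisk] stage %-14s %s%s", name, res$status,
                  if (res$status == "skipped")
                    paste0(" (", res$reason, ")") else ""))
  res
}

#' Run the full analysis pipeline on a session
#'
#' Executes the stages in order (whisking kinematics, vocal analysis,
#' call-whisking coordination, unit classification, response metrics,
#' phase locking) and collects a report. A stage with no qualifying data
#' (e.g. zero tracked cycles, no audio) is marked `"skipped"` in the report
#' rather than crashing. Deterministic for a fixed `config@seed`.
#'
#' @param session a [SessionRecording-class].
#' @param config an [AnalysisConfig-class].
#' @return a list of class `usvwhiskReport`: per-stage results with status,
#'   plus `sessionId` and the configuration used.
#' @export
runPipeline <- function(session, config = analysisConfig()) {
  stopifnot(is(session, "SessionRecording"))
  validObject(session)
  set.seed(config@seed)
  duration <- session@duration
  calls <- session@calls
  touches <- session@touches
  tw <- touchWindows(touches)
  exclusions <- mergeWindows(rbind(
    if (nrow(calls)) cbind(calls$onset_s, calls$offset_s) else NULL, tw))

  report <- list(sessionId = session@sessionId,
                 config = configAsList(config), stages = list())

  # -- whisking ------------------------------------------------------------
  whisk <- stageSafely("whisking", {
    perTrace <- lapply(session@whiskerTraces, function(tr) {
      ft <- preprocessTrace(tr, config)
      cyc <- detectCycles(ft, config)
      if (!any(cyc$valid)) stop("zero tracked cycles")
      ph <- computePhase(ft, cyc)
      psd <- welchPsdPeak(ft, band = config@psdBandHz)
      list(animalId = tr@animalId, filtered = ft, cycles = cyc, phase = ph,
           peakHz = psd$peakHz, dominant = psd$dominant,
           nValidCycles = sum(cyc$valid))
    })
    names(perTrace) <- vapply(perTrace, `[[`, character(1), "animalId")
    perTrace
  })
  report$stages$whisking <- stripStage(whisk, function(r)
    lapply(r, function(x) x[c("animalId", "peakHz", "dominant",
                              "nValidCycles")]))

  # -- vocal ---------------------------------------------------------------
  vocal <- stageSafely("vocal", {
    if (!nrow(calls)) stop("no calls")
    cs <- categoryStats(calls)
    asg <- assignSources(calls, marginThreshold = config@assignMargin)
    acc <- if (length(session@truth$emitter))
      assignmentAccuracy(asg$decision, session@truth$emitter) else NULL
    rates <- scenarioRates(calls, session@scenarioWindows, touches, duration)
    periodicity <- callPeriodicity(calls$onset_s)
    psthOn <- if (nrow(touches))
      eventPsth(calls$onset_s, touches$whisker_on_s, window = c(-2, 4),
                bin = config@psthBinCallsTouchS) else NULL
    power <- if (!is.null(session@audio))
      triggerLockedPower(session@audio, touches$whisker_on_s,
                         exclusions = cbind(calls$onset_s, calls$offset_s))
    else NULL
    list(categoryStats = cs, decisions = asg$decision, accuracy = acc,
         rates = rates, periodicity = periodicity, psthTouchOnset = psthOn,
         triggerPower = power,
         powerSkipped = is.null(session@audio))
  })
  report$stages$vocal <- stripStage(vocal, function(r)
    r[c("categoryStats", "accuracy", "rates", "periodicity", "powerSkipped")])

  # -- coordination --------------------------------------------------------
  coord <- stageSafely("coordination", {
    if (whisk$status != "ok") stop("whisking stage unavailable")
    if (!nrow(calls)) stop("no calls")
    subj <- whisk$result[["subject"]]
    if (is.null(subj)) subj <- whisk$result[[1]]
    subjCalls <- calls$onset_s[calls$emitter == "subject"]
    if (length(subjCalls) < 4) stop("too few subject calls")
    emit <- phaseAtCalls(subj$phase, subjCalls, role = "emitter")
    emitTest <- hodgesAjne(emit$phase_deg[emit$valid])
    split <- retractionProtractionSplit(emit)
    cta <- callTriggeredAverage(subj$filtered, subjCalls)
    partner <- NULL
    if (length(whisk$result) >= 2) {
      ptr <- whisk$result[[setdiff(names(whisk$result),
                                   subj$animalId)[1]]]
      ps <- phaseAtCalls(ptr$phase, subjCalls, role = "partner")
      if (sum(ps$valid) >= 4)
        partner <- list(samples = ps,
                        test = hodgesAjne(ps$phase_deg[ps$valid]))
    }
    list(emitterSamples = emit, emitterTest = emitTest, split = split,
         callTriggeredAverage = cta, partner = partner)
  })
  report$stages$coordination <- stripStage(coord, function(r) list(
    emitterTest = r$emitterTest, split = r$split[c("nRetraction",
                                                   "nProtraction", "p")],
    partnerTest = if (!is.null(r$partner)) r$partner$test else NULL))

  # -- units ---------------------------------------------------------------
  unitsStage <- stageSafely("units", {
    if (length(session@units) < 4) stop("fewer than 4 units")
    feats <- waveformFeatures(session@units)
    feats <- classifyRsFs(feats, seed = config@seed)
    stab <- lapply(session@units, function(u)
      tryCatch(unitStability(u@spikeTimes, tw, duration,
                             nPerm = config@nPermStability,
                             seed = config@seed,
                             maxR = config@stabilityMaxR),
               error = function(e) list(meanAbsR = NA_real_,
                                        excluded = FALSE,
                                        silent = FALSE)))
    feats$mean_abs_r <- vapply(stab, function(s)
      s$meanAbsR[1], numeric(1))[match(
        feats$unit_id, vapply(session@units, unitId, character(1)))]
    feats$excluded <- !is.na(feats$mean_abs_r) &
      feats$mean_abs_r > config@stabilityMaxR
    feats
  })
  report$stages$units <- stripStage(unitsStage, identity)

  # -- responses -----------------------------------------------------------
  resp <- stageSafely("responses", {
    if (!length(session@units)) stop("no units")
    if (!nrow(calls)) stop("no calls")
    rows <- list()
    for (u in session@units) {
      w <- callResponseWindows(calls, config@responseWindowMode)
      mb <- matchedBaselineWindows(w, exclusions, duration,
                                   shift = config@baselineShiftS)
      riCall <- if (nrow(mb$windows))
        responseIndex(eventRate(u@spikeTimes,
                                w[mb$keptEvents, , drop = FALSE]),
                      eventRate(u@spikeTimes, mb$windows)) else NA_real_
      tr <- if (nrow(touches))
        tryCatch(touchResponse(u@spikeTimes, touches, exclusions, duration,
                               offWindow = config@offWindowS,
                               shift = config@baselineShiftS),
                 error = function(e) NULL) else NULL
      io <- tryCatch(
        callsInOutTouch(u@spikeTimes, calls, touches, exclusions, duration,
                        mode = config@responseWindowMode,
                        shift = config@baselineShiftS,
                        minCalls = config@minCallsPerCondition),
        error = function(e) NULL)
      rows[[length(rows) + 1]] <- data.frame(
        unit_id = u@unitId, ri_call = riCall,
        ri_touch = if (!is.null(tr)) tr$riTouch else NA_real_,
        ri_off = if (!is.null(tr)) tr$riOff else NA_real_,
        ri_call_in_touch = if (!is.null(io)) io$riIn else NA_real_,
        ri_call_out_touch = if (!is.null(io)) io$riOut else NA_real_)
    }
    do.call(rbind, rows)
  })
  report$stages$responses <- stripStage(resp, identity)

  # -- phase locking -------------------------------------------------------
  plock <- stageSafely("phase_locking", {
    if (whisk$status != "ok") stop("whisking stage unavailable")
    if (!length(session@units)) stop("no units")
    subj <- whisk$result[["subject"]]
    if (is.null(subj)) subj <- whisk$result[[1]]
    res <- classifyPhaseLocked(session@units, subj$phase, config)
    # cross-reference call responsiveness: locking in a unit that responds
    # to phase-coupled calls can be an artifact of that response
    if (resp$status == "ok")
      res$call_responsive <- abs(resp$result$ri_call[
        match(res$unit_id, resp$result$unit_id)]) > 0.2
    res
  })
  report$stages$phase_locking <- stripStage(plock, identity)

  structure(list(report = report,
                 details = list(whisking = whisk, vocal = vocal,
                                coordination = coord, units = unitsStage,
                                responses = resp, phase_locking = plock)),
            class = "usvwhiskReport")
}

stripStage <- function(stage, f) {
  if (stage$status != "ok")
    list(status = stage$status, reason = stage$reason)
  else c(list(status = "ok"), list(summary = f(stage$result)))
}

configAsList <- function(config) {
  vals <- lapply(slotNames(class(config)), function(s) slot(config, s))
  names(vals) <- slotNames(class(config))
  vals
}

#' @export
print.usvwhiskReport <- function(x, ...) {
  cat(sprintf("usvwhisk report for session '%s'\n", x$report$sessionId))
  for (nm in names(x$report$stages))
    cat(sprintf("  %-14s %s\n", nm, x$report$stages[[nm]]$status))
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Writes `report.json` (machine readable; stage summaries and statuses) and
#' per-stage CSV tables (`units_classified.csv`, `responses.csv`,
#' `phase_locking.csv`, `cycles.csv`, `coordination.csv`) where the
#' corresponding stage ran.
#'
#' @param bundle result of [runPipeline()].
#' @param outDir output directory.
#' @return invisibly, the paths written.
#' @export
writeReport <- function(bundle, outDir) {
  stopifnot(inherits(bundle, "usvwhiskReport"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(outDir, "report.json")
  jsonlite::write_json(bundle$report, paths[1], auto_unbox = TRUE,
                       digits = NA, force = TRUE, null = "null")
  d <- bundle$details
  emit <- function(df, name) {
    if (!is.null(df)) {
      fp <- file.path(outDir, name)
      writeTable(df, fp)
      paths <<- c(paths, fp)
    }
  }
  if (d$whisking$status == "ok") {
    cyc <- do.call(rbind, lapply(d$whisking$result, function(r) {
      out <- r$cycles
      out$animal_id <- r$animalId
      out
    }))
    emit(cyc, "cycles.csv")
  }
  if (d$coordination$status == "ok")
    emit(d$coordination$result$emitterSamples, "coordination.csv")
  if (d$units$status == "ok") emit(d$units$result, "units_classified.csv")
  if (d$responses$status == "ok") emit(d$responses$result, "responses.csv")
  if (d$phase_locking$status == "ok")
    emit(d$phase_locking$result, "phase_locking.csv")
  invisible(paths)
}
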