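# Accessors and show methods. Slots are never accessed with @ outside the
# package; these are the supported surface.

#' @rdname SessionRecording-class
#' @export
setMethod("sessionId", "SessionRecording", function(x) x@sessionId)
#' @rdname SessionRecording-class
#' @export
setMethod("sessionDuration", "SessionRecording", function(x) x@duration)
#' @rdname SessionRecording-class
#' @export
setMethod("whiskerTraces", "SessionRecording", function(x) x@whiskerTraces)
#' @rdname SessionRecording-class
#' @export
setMethod("callTable", "SessionRecording", function(x) x@calls)
#' @rdname SessionRecording-class
#' @export
setMethod("touchTable", "SessionRecording", function(x) x@touches)
#' @rdname SessionRecording-class
#' @export
setMethod("unitList", "SessionRecording", function(x) x@units)
#' @rdname SessionRecording-class
#' @export
setMethod("scenarioWindows", "SessionRecording", function(x) x@scenarioWindows)
#' @rdname SessionRecording-class
#' @export
setMethod("audioTrack", "SessionRecording", function(x) x@audio)
#' @rdname SessionRecording-class
#' @export
setMethod("groundTruth", "SessionRecording", function(x) x@truth)

#' @rdname UnitRecording-class
#' @export
setMethod("unitId", "UnitRecording", function(x) x@unitId)
#' @rdname UnitRecording-class
#' @export
setMethod("spikeTimes", "UnitRecording", function(x) x@spikeTimes)
#' @rdname UnitRecording-class
#' @export
setMethod("waveform", "UnitRecording", function(x) x@waveform)
#' @rdname UnitRecording-class
#' @export
setMethod("cellClass", "UnitRecording", function(x) x@cellClass)

#' @rdname WhiskerTrace-class
#' @export
setMethod("angles", "WhiskerTrace", function(x) x@angle)
#' @rdname WhiskerTrace-class
#' @export
setMethod("sampleTimes", "WhiskerTrace", function(x) x@times)
#' @rdname WhiskerTrace-class
#' @export
setMethod("sampleRate", "WhiskerTrace", function(x) x@sampleRate)
#' @rdname PhaseTrace-class
#' @export
setMethod("sampleTimes", "PhaseTrace", function(x) x@times)
#' @rdname PhaseTrace-class
#' @export
setMethod("sampleRate", "PhaseTrace", function(x) x@sampleRate)
#' @rdname PhaseTrace-class
#' @export
setMethod("phases", "PhaseTrace", function(x) x@phase)
#' @rdname PhaseTrace-class
#' @export
setMethod("validMask", "PhaseTrace", function(x) x@valid)

setMethod("show", "WhiskerTrace", function(object) {
  cat(sprintf("%s of animal %s: %d samples at %g Hz (%.2f s)\n",
              class(object), object@animalId, length(object@times),
              object@sampleRate,
              if (length(object@times)) diff(range(object@times)) else 0))
})

setMethod("show", "PhaseTrace", function(object) {
  cat(sprintf("PhaseTrace of animal %s: %d samples at %g Hz, %.1f%% valid\n",
              object@animalId, length(object@times), object@sampleRate,
              if (length(object@valid)) 100 * mean(object@valid) else 0))
})

setMethod("show", "UnitRecording", function(object) {
  cat(sprintf("UnitRecording %s [%s/%s]: %d spikes%s\n",
              object@unitId,
              ifelse(is.na(object@subregion), "?", object@subregion),
              ifelse(is.na(object@cellClass), "?", object@cellClass),
              length(object@spikeTimes),
              if (is.na(object@stabilityR)) ""
              else sprintf(", stability R = %.3f", object@stabilityR)))
})

setMethod("show", "SessionRecording", function(object) {
  cat(sprintf("SessionRecording '%s' (%.1f s)\n", object@sessionId,
              object@duration))
  cat(sprintf("  %d whisker trace(s), %d call(s), %d touch episode(s), %d unit(s)\n",
              length(object@whiskerTraces), nrow(object@calls),
              nrow(object@touches), length(object@units)))
  if (length(object@scenarioWindows))
    cat("  scenarios:", paste(names(object@scenarioWindows), collapse = ", "),
        "\n")
  if (!is.null(object@audio))
    cat(sprintf("  audio: %d samples at %g Hz\n",
                length(object@audio@samples), object@audio@sampleRate))
  if (length(object@truth)) cat("  ground truth attached (synthetic session)\n")
})
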