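#' @rdname SessionRecording-class
#' @param object,x an object.
#' @export
setGeneric("sessionId", function(x) standardGeneric("sessionId"))
#' @rdname SessionRecording-class
#' @export
setGeneric("sessionDuration", function(x) standardGeneric("sessionDuration"))
#' @rdname SessionRecording-class
#' @export
setGeneric("whiskerTraces", function(x) standardGeneric("whiskerTraces"))
#' @rdname SessionRecording-class
#' @export
setGeneric("callTable", function(x) standardGeneric("callTable"))
#' @rdname SessionRecording-class
#' @export
setGeneric("touchTable", function(x) standardGeneric("touchTable"))
#' @rdname SessionRecording-class
#' @export
setGeneric("unitList", function(x) standardGeneric("unitList"))
#' @rdname SessionRecording-class
#' @export
setGeneric("scenarioWindows", function(x) standardGeneric("scenarioWindows"))
#' @rdname SessionRecording-class
#' @export
setGeneric("audioTrack", function(x) standardGeneric("audioTrack"))
#' @rdname SessionRecording-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname UnitRecording-class
#' @param x an object.
#' @export
setGeneric("unitId", function(x) standardGeneric("unitId"))
#' @rdname UnitRecording-class
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))
#' @rdname UnitRecording-class
#' @export
setGeneric("waveform", function(x) standardGeneric("waveform"))
#' @rdname UnitRecording-class
#' @export
setGeneric("cellClass", function(x) standardGeneric("cellClass"))

#' @rdname WhiskerTrace-class
#' @param x an object.
#' @export
setGeneric("angles", function(x) standardGeneric("angles"))
#' @rdname WhiskerTrace-class
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))
#' @rdname WhiskerTrace-class
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname PhaseTrace-class
#' @param x an object.
#' @export
setGeneric("phases", function(x) standardGeneric("phases"))
#' @rdname PhaseTrace-class
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
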