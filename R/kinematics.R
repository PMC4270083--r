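# Whisking kinematics: filtering, cycle detection + QC, analytic-signal
# phase, and periodicity measures.

#' Band-pass filter and up-sample a whisker trace
#'
#' Up-samples the raw whisker-angle trace to 1000 Hz by linear interpolation,
#' then applies a zero-phase (forward-backward) fourth-order Butterworth
#' band-pass in the whisking band (default 1-25 Hz). Zero-phase filtering is
#' used so cycle timing is not lagged; the effective roll-off is that of an
#' eighth-order filter.
#'
#' @param raw a [WhiskerTrace-class].
#' @param config an [AnalysisConfig-class].
#' @return a [FilteredTrace-class] at `config@upsampleRateHz` with
#'   approximately zero mean (the DC posture offset is removed by the filter).
#' @examples
#' tr <- new("WhiskerTrace", animalId = "a", times = seq(0, 5, 1/250),
#'           angle = 20 * cos(2 * pi * 8 * seq(0, 5, 1/250)),
#'           sampleRate = 250)
#' ft <- preprocessTrace(tr)
#' @export
preprocessTrace <- function(raw, config = analysisConfig()) {
  stopifnot(is(raw, "WhiskerTrace"))
  times <- raw@times; ang <- raw@angle
  ok <- is.finite(ang)
  if (sum(ok) < 2) stop("trace too short")
  if (raw@sampleRate < 100) stop("raw sample rate must be >= 100 Hz")
  span <- times[length(times)] - times[1]
  minSpan <- max(1, 3 / (2 * pi * config@filterLowHz))
  if (span < minSpan) stop("trace too short")
  fs <- config@upsampleRateHz
  grid <- seq(times[1], times[length(times)], by = 1 / fs)
  up <- stats::approx(times[ok], ang[ok], xout = grid, rule = 2)$y
  up <- up - mean(up)  # remove the posture offset before filtering to keep
                       # the forward-backward filter's edge transients small
  bf <- signal::butter(config@filterOrder,
                       c(config@filterLowHz, config@filterHighHz) / (fs / 2),
                       type = "pass")
  filt <- as.numeric(signal::filtfilt(bf, up))
  new("FilteredTrace", animalId = raw@animalId, times = grid, angle = filt,
      sampleRate = fs)
}

#' Detect whisking cycles and apply quality control
#'
#' Cycle boundaries are successive local maxima of the filtered angle (points
#' of maximum protraction), detected with a minimum peak separation of 40 ms
#' (below the 50 ms QC floor, so legitimate cycles cannot be suppressed).
#' A cycle is `valid` iff its duration lies in \[50, 250\] ms and its
#' peak-to-trough amplitude is at least 7.5 degrees.
#'
#' @param trace a [FilteredTrace-class].
#' @param config an [AnalysisConfig-class].
#' @return data.frame with columns `start_s`, `end_s`, `duration_s`,
#'   `amplitude_deg`, `valid`; zero rows when no maxima are found.
#' @export
detectCycles <- function(trace, config = analysisConfig()) {
  stopifnot(is(trace, "FilteredTrace"))
  fs <- trace@sampleRate
  minSep <- max(1, round(config@peakMinSepS * fs))
  pk <- pracma::findpeaks(trace@angle, minpeakdistance = minSep)
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0), amplitude_deg = numeric(0),
                      valid = logical(0))
  if (is.null(pk) || nrow(pk) < 2) return(empty)
  idx <- sort(pk[, 2])
  out <- data.frame(start_s = trace@times[idx[-length(idx)]],
                    end_s = trace@times[idx[-1]])
  out$duration_s <- out$end_s - out$start_s
  out$amplitude_deg <- vapply(seq_len(nrow(out)), function(i) {
    seg <- trace@angle[idx[i]:idx[i + 1]]
    max(seg) - min(seg)
  }, numeric(1))
  out$valid <- out$duration_s >= config@cycleMinS &
    out$duration_s <= config@cycleMaxS &
    out$amplitude_deg >= config@cycleMinAmpDeg
  out
}

#' Instantaneous whisking phase from the analytic signal
#'
#' Phase is the unwrapped angle of the analytic signal (Hilbert transform) of
#' the filtered trace, re-anchored per cycle so that phase is exactly 0 at
#' each detected maximum protraction, passes 180 degrees at maximum
#' retraction, and stays below 360 until the next protraction peak. Samples
#' outside valid cycles carry `valid = FALSE`.
#'
#' @param trace a [FilteredTrace-class].
#' @param cycles cycle table from [detectCycles()].
#' @return a [PhaseTrace-class].
#' @export
computePhase <- function(trace, cycles) {
  stopifnot(is(trace, "FilteredTrace"))
  if (!nrow(cycles) || !any(cycles$valid))
    stop("no valid whisking cycle; cannot compute phase")
  a <- analyticSignal(trace@angle)
  phiu <- unwrapRad(Arg(a))
  n <- length(phiu)
  fs <- trace@sampleRate
  t0 <- trace@times[1]
  phase <- wrapDeg(radToDeg(phiu))
  valid <- rep(FALSE, n)
  toIdx <- function(tt) pmin(pmax(round((tt - t0) * fs) + 1, 1), n)
  for (i in seq_len(nrow(cycles))) {
    i0 <- toIdx(cycles$start_s[i]); i1 <- toIdx(cycles$end_s[i])
    if (i1 <= i0) next
    seg <- i0:(i1 - 1)  # half-open: the end sample starts the next cycle
    rel <- (phiu[seg] - phiu[i0]) / (phiu[i1] - phiu[i0])
    phase[seg] <- pmin(pmax(rel, 0), 1 - 1e-9) * 360
    if (cycles$valid[i]) valid[seg] <- TRUE
  }
  new("PhaseTrace", animalId = trace@animalId, times = trace@times,
      phase = phase, valid = valid, sampleRate = fs)
}

unwrapRad <- function(p) {
  dp <- diff(p)
  jumps <- round(dp / (2 * pi))
  p - c(0, cumsum(jumps)) * 2 * pi
}

#' Dominant whisking frequency by Welch's method
#'
#' Welch power spectral density of the filtered trace restricted to the
#' whisking band (default 4-25 Hz), with segment length chosen for a
#' resolution of at most 0.5 Hz. A peak is flagged as a dominant rhythm only
#' if it exceeds three times the median in-band power.
#'
#' @param trace a [FilteredTrace-class].
#' @param band numeric pair, Hz.
#' @return list with `freq`, `power` (in-band), `peakHz`, `resolution`, and
#'   logical `dominant`.
#' @export
welchPsdPeak <- function(trace, band = c(4, 25)) {
  stopifnot(is(trace, "FilteredTrace"))
  fs <- trace@sampleRate
  n <- length(trace@angle)
  if (n < 4 * fs) stop("need at least 4 s of data for the whisking PSD")
  nperseg <- min(n, 2^ceiling(log2(2 * fs)))  # >= 2 s segments -> <= 0.5 Hz
  ps <- welchPsd(trace@angle, fs, nperseg = nperseg)
  sel <- ps$freq >= band[1] & ps$freq <= band[2]
  fb <- ps$freq[sel]; pb <- ps$psd[sel]
  if (!length(pb)) stop("empty analysis band")
  peak <- fb[which.max(pb)]
  list(freq = fb, power = pb, peakHz = peak, resolution = ps$resolution,
       dominant = max(pb) > 3 * stats::median(pb))
}

#' Interval histogram between event markers
#'
#' `auto` mode: distribution of successive intervals of `markersA`.
#' `cross` mode: for each marker in `markersA`, the interval to the nearest
#' following marker in `markersB`. Counts are normalized to sum to 1 over the
#' occupied range.
#'
#' @param markersA,markersB sorted event times, seconds.
#' @param mode "auto" or "cross".
#' @param bin bin width, seconds.
#' @param maxLag maximum interval retained, seconds.
#' @return list with `breaks`, `mids`, `counts`, `norm` (normalized counts)
#'   and `intervals` (the raw intervals <= maxLag).
#' @export
intervalHistogram <- function(markersA, markersB = NULL,
                              mode = c("auto", "cross"),
                              bin = 0.005, maxLag = 1) {
  mode <- match.arg(mode)
  breaks <- seq(0, maxLag, by = bin)
  if (breaks[length(breaks)] < maxLag) breaks <- c(breaks, maxLag)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  empty <- list(breaks = breaks, mids = mids,
                counts = rep(0L, length(mids)), norm = rep(0, length(mids)),
                intervals = numeric(0))
  if (!length(markersA)) return(empty)
  iv <- if (mode == "auto") {
    diff(markersA)
  } else {
    if (is.null(markersB) || !length(markersB)) return(empty)
    pos <- findInterval(markersA, markersB)  # last b <= a
    nxt <- pos + 1
    ok <- nxt <= length(markersB)
    markersB[nxt[ok]] - markersA[ok]
  }
  iv <- iv[iv >= 0 & iv <= maxLag]
  if (!length(iv)) return(empty)
  counts <- graphics::hist(iv, breaks = breaks, plot = FALSE,
                           right = FALSE)$counts
  list(breaks = breaks, mids = mids, counts = counts,
       norm = counts / sum(counts), intervals = iv)
}
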