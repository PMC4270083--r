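# Vocalization analysis: spectrogram parameterization, per-category call
# statistics, microphone-based source assignment, calling-rate analyses and
# trigger-locked sound power.

#' SpectrogramSpec: short-time Fourier parameters
#'
#' Frequency and time resolution are always derived from the primary fields
#' (`freqResolution = sampleRate / fftLength`,
#' `timeResolution = fftLength * (1 - overlapFraction) / sampleRate`), never
#' stored.
#'
#' @slot fftLength FFT window length, samples.
#' @slot overlapFraction fractional overlap in \[0, 1).
#' @slot window window name: "hanning", "hamming", "blackman", "flattop" or
#'   "rectangular".
#' @slot sampleRate audio sample rate, Hz.
#' @export
setClass("SpectrogramSpec",
  representation(fftLength = "numeric", overlapFraction = "numeric",
                 window = "character", sampleRate = "numeric"),
  prototype(fftLength = 1024, overlapFraction = 0.9375, window = "flattop",
            sampleRate = 250000))

setValidity("SpectrogramSpec", function(object) {
  msg <- character(0)
  if (object@overlapFraction < 0 || object@overlapFraction >= 1)
    msg <- c(msg, "overlapFraction must be in [0, 1)")
  if (object@fftLength < 2) msg <- c(msg, "fftLength must be >= 2")
  if (length(msg)) msg else TRUE
})

#' @rdname SpectrogramSpec-class
#' @param ... slot overrides.
#' @export
spectrogramSpec <- function(...) new("SpectrogramSpec", ...)

#' @rdname SpectrogramSpec-class
#' @param spec a `SpectrogramSpec`.
#' @return `freqResolution`: Hz per frequency bin; `timeResolution`: seconds
#'   per spectrogram time step.
#' @examples
#' freqResolution(spectrogramSpec(fftLength = 1024, sampleRate = 250000))
#' @export
freqResolution <- function(spec) spec@sampleRate / spec@fftLength

#' @rdname SpectrogramSpec-class
#' @export
timeResolution <- function(spec)
  spec@fftLength * (1 - spec@overlapFraction) / spec@sampleRate

windowVector <- function(name, n) {
  switch(name,
    hanning = signal::hanning(n),
    hamming = signal::hamming(n),
    blackman = signal::blackman(n),
    rectangular = rep(1, n),
    flattop = {
      k <- seq(0, n - 1) / (n - 1)
      0.21557895 - 0.41663158 * cos(2 * pi * k) +
        0.277263158 * cos(4 * pi * k) - 0.083578947 * cos(6 * pi * k) +
        0.006947368 * cos(8 * pi * k)
    },
    stop(sprintf("unknown window '%s'", name)))
}

#' Short-time Fourier power spectrogram
#'
#' @param audio an [AudioTrack-class] (its sample rate must equal the spec's).
#' @param spec a [SpectrogramSpec-class].
#' @return list with `power` (frequency x time magnitude-squared matrix),
#'   `freq` (Hz), `time` (s, window centers), `freqResolution` and
#'   `timeResolution` from the spec formulas.
#' @export
computeSpectrogram <- function(audio, spec = spectrogramSpec()) {
  stopifnot(is(audio, "AudioTrack"))
  if (abs(audio@sampleRate - spec@sampleRate) > 1e-6)
    stop("audio sample rate does not match the spectrogram spec")
  n <- spec@fftLength
  if (n > length(audio@samples))
    stop("fftLength exceeds the audio length")
  ov <- round(n * spec@overlapFraction)
  sg <- signal::specgram(audio@samples, n = n, Fs = audio@sampleRate,
                         window = windowVector(spec@window, n), overlap = ov)
  list(power = abs(sg$S)^2, freq = as.numeric(sg$f), time = as.numeric(sg$t),
       freqResolution = freqResolution(spec),
       timeResolution = timeResolution(spec))
}

#' Per-category call statistics
#'
#' For each call category present: n, mean, SEM and 20th/80th quantiles
#' (linear interpolation between order statistics) of mean frequency (kHz),
#' bandwidth (kHz) and duration (ms). Categories with no calls are omitted;
#' for n = 1 the SEM is reported as 0 with `n1_flag = TRUE`.
#'
#' @param calls a call table (see [SessionRecording-class]).
#' @return data.frame, one row per category.
#' @export
categoryStats <- function(calls) {
  stopifnot(all(c("onset_s", "offset_s", "category") %in% names(calls)))
  dur_ms <- (calls$offset_s - calls$onset_s) * 1000
  stat1 <- function(x) {
    n <- length(x)
    q <- stats::quantile(x, c(0.2, 0.8), names = FALSE, type = 7)
    c(mean = mean(x), sem = if (n > 1) stats::sd(x) / sqrt(n) else 0,
      q20 = q[1], q80 = q[2])
  }
  cats <- intersect(CALL_CATEGORIES, unique(calls$category))
  rows <- lapply(cats, function(cc) {
    i <- calls$category == cc
    out <- data.frame(category = cc, n = sum(i), n1_flag = sum(i) == 1)
    for (v in c("mean_freq_khz", "bandwidth_khz")) {
      s <- stat1(calls[[v]][i])
      names(s) <- paste0(sub("_khz", "", v), "_", names(s))
      out <- cbind(out, as.data.frame(as.list(s)))
    }
    s <- stat1(dur_ms[i]); names(s) <- paste0("duration_ms_", names(s))
    cbind(out, as.data.frame(as.list(s)))
  })
  do.call(rbind, rows)
}

#' Assign each call to its putative emitter from microphone intensities
#'
#' Microphones 1-2 sit on the subject side, 3-4 on the stimulus side. Each
#' side's score is the maximum peak intensity over its two channels (robust
#' to a single occluded microphone); the call is assigned to the louder side
#' when the score ratio reaches `marginThreshold`, otherwise left unassigned.
#'
#' @param calls call table with `i_ch1..i_ch4`.
#' @param marginThreshold linear score ratio required for assignment
#'   (default 1.5).
#' @return the call table with a `decision` column in
#'   `c("subject", "stimulus", "unassigned")`.
#' @examples
#' df <- data.frame(i_ch1 = 10, i_ch2 = 8, i_ch3 = 2, i_ch4 = 1)
#' assignSources(df)$decision  # "subject"
#' @export
assignSources <- function(calls, marginThreshold = 1.5) {
  stopifnot(all(paste0("i_ch", 1:4) %in% names(calls)),
            marginThreshold >= 1)
  sSubj <- pmax(calls$i_ch1, calls$i_ch2)
  sStim <- pmax(calls$i_ch3, calls$i_ch4)
  hi <- pmax(sSubj, sStim); lo <- pmin(sSubj, sStim)
  decision <- rep("unassigned", nrow(calls))
  if (any(hi == 0))
    warning(sprintf("%d call(s) with all-zero intensities left unassigned",
                    sum(hi == 0)))
  ratio <- ifelse(lo > 0, hi / lo, ifelse(hi > 0, Inf, 1))
  assign <- ratio >= marginThreshold & hi > 0 & sSubj != sStim
  decision[assign] <- ifelse(sSubj[assign] > sStim[assign],
                             "subject", "stimulus")
  calls$decision <- decision
  calls
}

#' Assignment accuracy against ground-truth emitters
#'
#' @param decisions character vector of per-call decisions
#'   ("subject"/"stimulus"/"unassigned").
#' @param truth character vector of true emitters, same length.
#' @return list with counts `nTotal`, `nCorrect`, `nWrong`, `nUnassigned`
#'   and percentages (`pctCorrect`, `pctWrong`, `pctUnassigned`) on the full
#'   call count; percentages are exact, rounding is left to presentation.
#' @examples
#' # worked example: 1286 correct, 284 wrong, 263 unassigned of 1833
#' d <- rep(c("subject", "stimulus", "unassigned"), c(1286, 284, 263))
#' assignmentAccuracy(d, rep("subject", 1833))$pctCorrect  # 70.2
#' @export
assignmentAccuracy <- function(decisions, truth) {
  if (length(decisions) != length(truth))
    stop("decisions and truth differ in length")
  n <- length(decisions)
  unass <- decisions == "unassigned"
  correct <- !unass & decisions == truth
  wrong <- !unass & decisions != truth
  res <- list(nTotal = n, nCorrect = sum(correct), nWrong = sum(wrong),
              nUnassigned = sum(unass))
  res$pctCorrect <- 100 * res$nCorrect / n
  res$pctWrong <- 100 * res$nWrong / n
  res$pctUnassigned <- 100 * res$nUnassigned / n
  res
}

#' Calling rates per scenario and in/out of touch
#'
#' Rates are call onsets per second of scenario time. A call counts as
#' in-touch iff its onset falls inside a touch episode (half-open intervals,
#' so a call at exactly a touch offset is out of touch). In/out rates are
#' evaluated within the social-setting windows when defined, otherwise over
#' the whole session.
#'
#' @param calls call table.
#' @param scenarios named list of 2-column (start, end) window matrices.
#' @param touches touch table.
#' @param duration session duration, seconds.
#' @return list with `scenario` (data.frame name/time/n/rate), `inTouch`,
#'   `outTouch` (overall Hz, NA when undefined), and `perCategory`
#'   (data.frame of in/out rates per call category).
#' @export
scenarioRates <- function(calls, scenarios, touches, duration) {
  onsets <- calls$onset_s
  scen <- data.frame(scenario = character(0), time_s = numeric(0),
                     n = integer(0), rate_hz = numeric(0))
  for (nm in names(scenarios)) {
    w <- mergeWindows(scenarios[[nm]])
    tt <- totalWindowTime(w)
    n <- countInWindows(onsets, w)
    scen <- rbind(scen, data.frame(
      scenario = nm, time_s = tt, n = n,
      rate_hz = if (tt > 0) n / tt else NA_real_))
  }
  tw <- touchWindows(touches)
  base <- if ("social_setting" %in% names(scenarios))
    mergeWindows(scenarios[["social_setting"]])
  else matrix(c(0, duration), ncol = 2)
  inW <- intersectWindows(tw, base)
  outW <- intersectWindows(complementWindows(tw, 0, duration), base)
  tIn <- totalWindowTime(inW); tOut <- totalWindowTime(outW)
  sel <- inAnyWindow(onsets, base)
  inside <- inAnyWindow(onsets, tw) & sel
  rateIn <- if (tIn > 0) sum(inside) / tIn else NA_real_
  rateOut <- if (tOut > 0) sum(sel & !inside) / tOut else NA_real_
  perCat <- do.call(rbind, lapply(
    intersect(CALL_CATEGORIES, unique(calls$category)), function(cc) {
      i <- calls$category == cc
      data.frame(category = cc,
                 rate_in_hz = if (tIn > 0) sum(inside & i) / tIn else NA_real_,
                 rate_out_hz = if (tOut > 0) sum(sel & !inside & i) / tOut
                               else NA_real_)
    }))
  list(scenario = scen, inTouch = rateIn, outTouch = rateOut,
       inTouchTime = tIn, outTouchTime = tOut, perCategory = perCat)
}

touchWindows <- function(touches) {
  if (is.null(touches) || !nrow(touches)) return(matrix(numeric(0), ncol = 2))
  mergeWindows(cbind(touches$whisker_on_s, touches$whisker_off_s))
}

#' Trigger-aligned event rate (PSTH)
#'
#' Event counts in lag bins around each trigger, divided by
#' (number of triggers x bin width), in Hz. Used both for calls around touch
#' onsets/offsets and (via [spikePsth()]) for spike trains.
#'
#' @param eventTimes sorted event times, seconds.
#' @param triggers sorted trigger times, seconds.
#' @param window numeric pair `c(pre, post)` with pre < 0 < post, seconds.
#' @param bin bin width, seconds.
#' @return data.frame with `lag_s` (bin centers) and `rate_hz`.
#' @export
eventPsth <- function(eventTimes, triggers, window = c(-2, 4), bin = 0.5) {
  if (!length(triggers)) stop("no triggers supplied")
  stopifnot(window[1] < 0, window[2] > 0, bin > 0)
  breaks <- seq(window[1], window[2] + bin - 1e-12, by = bin)
  lags <- unlist(lapply(triggers, function(tr) {
    d <- eventTimes - tr
    d[d >= window[1] & d < breaks[length(breaks)]]
  }))
  counts <- if (length(lags))
    graphics::hist(lags, breaks = breaks, plot = FALSE, right = FALSE)$counts
  else rep(0L, length(breaks) - 1)
  data.frame(lag_s = (breaks[-1] + breaks[-length(breaks)]) / 2,
             rate_hz = counts / (length(triggers) * bin))
}

#' Calling periodicity: interval histogram and PSD peak
#'
#' The successive-interval histogram gives the modal inter-call interval.
#' The spectral estimate applies Welch's method to the smoothed (5-bin moving
#' average) outline of the all-order interval histogram (intervals from each
#' call to every later call within `maxLag`), whose periodic bumps at
#' multiples of the calling period carry the rhythm; a successive-interval
#' histogram alone would reduce to a single bin for a perfectly periodic
#' train.
#'
#' @param callOnsets sorted call onset times, seconds.
#' @param bin histogram bin, seconds.
#' @param maxLag histogram extent, seconds.
#' @param band frequency band searched for the peak, Hz.
#' @return list with `histogram` (successive intervals), `modalIntervalS`,
#'   `freq`, `power`, `peakHz`, `dominant` (peak > 3x in-band median) and
#'   `sufficient` (FALSE with all else NA when fewer than 10 calls).
#' @export
callPeriodicity <- function(callOnsets, bin = 0.005, maxLag = 6,
                            band = c(4, 25)) {
  if (length(callOnsets) < 10)
    return(list(sufficient = FALSE, histogram = NULL,
                modalIntervalS = NA_real_, freq = NULL, power = NULL,
                peakHz = NA_real_, dominant = NA))
  h <- intervalHistogram(callOnsets, mode = "auto", bin = bin, maxLag = 1)
  modal <- if (sum(h$counts)) h$mids[which.max(h$counts)] else NA_real_
  # all-order intervals within maxLag (correlogram outline)
  ao <- unlist(lapply(seq_along(callOnsets), function(i) {
    d <- callOnsets[-seq_len(i)] - callOnsets[i]
    d[d <= maxLag]
  }))
  breaks <- seq(0, maxLag, by = bin)
  counts <- graphics::hist(ao[ao > 0 & ao <= maxLag], breaks = breaks,
                           plot = FALSE, right = FALSE)$counts
  outline <- movingAverage(counts, 5)
  # Welch with 2 s segments (0.5 Hz resolution) at 75% overlap, plus light
  # spectral (Daniell) smoothing, so the noise floor is stable enough for
  # the 3x-median dominance criterion
  ps <- welchPsd(outline - mean(outline), fs = 1 / bin,
                 nperseg = min(length(outline), 400), overlap = 0.75)
  sel <- ps$freq >= band[1] & ps$freq <= band[2]
  fb <- ps$freq[sel]; pb <- movingAverage(ps$psd[sel], 5)
  list(sufficient = TRUE, histogram = h, modalIntervalS = modal,
       freq = fb, power = pb, peakHz = fb[which.max(pb)],
       dominant = max(pb) > 3 * stats::median(pb))
}

#' Trigger-locked relative sound power
#'
#' For each trigger, the short-time power spectrum of the surrounding audio
#' window is cumulated over frequencies, giving intensity versus lag. Because
#' intensities span orders of magnitude, traces are combined across triggers
#' by the geometric mean, then divided by the average over the pre-trigger
#' lags, so the pre-trigger portion is 1 by construction. Triggers whose
#' window overlaps any exclusion interval (e.g. vocalizations) are dropped;
#' `nMax` triggers can be subsampled at random to equalize trigger counts
#' across classes.
#'
#' @param audio an [AudioTrack-class].
#' @param triggers trigger times, seconds.
#' @param window numeric pair `c(pre, post)` with pre < 0 < post, seconds.
#' @param exclusions 2-column matrix of (start, end) intervals to avoid.
#' @param spec a [SpectrogramSpec-class] for the short-time power.
#' @param nMax optional trigger subsample size.
#' @param seed RNG seed for the subsample.
#' @return list with `lag_s`, `relPower`, `nUsed`, `nExcluded`.
#' @export
triggerLockedPower <- function(audio, triggers, window = c(-0.5, 0.5),
                               exclusions = NULL,
                               spec = spectrogramSpec(fftLength = 512,
                                                      overlapFraction = 0.5,
                                                      window = "hanning",
                                                      sampleRate = 250000),
                               nMax = NULL, seed = 1) {
  stopifnot(is(audio, "AudioTrack"), window[1] < 0, window[2] > 0)
  dur <- length(audio@samples) / audio@sampleRate
  usable <- triggers[triggers + window[1] >= 0 & triggers + window[2] <= dur]
  if (!is.null(exclusions) && nrow(exclusions)) {
    ex <- mergeWindows(exclusions)
    keep <- vapply(usable, function(tr) {
      !any(tr + window[1] < ex[, 2] & ex[, 1] < tr + window[2])
    }, logical(1))
    nExcluded <- sum(!keep)
    usable <- usable[keep]
  } else nExcluded <- length(triggers) - length(usable)
  if (!length(usable))
    stop(sprintf("all %d trigger(s) excluded from trigger-locked power",
                 length(triggers)))
  if (!is.null(nMax) && length(usable) > nMax) {
    set.seed(seed)
    usable <- sort(sample(usable, nMax))
  }
  fs <- audio@sampleRate
  traces <- vector("list", length(usable))
  lag <- NULL
  for (k in seq_along(usable)) {
    tr <- usable[k]
    i0 <- max(1, floor((tr + window[1]) * fs) + 1)
    i1 <- min(length(audio@samples), ceiling((tr + window[2]) * fs))
    seg <- new("AudioTrack", samples = audio@samples[i0:i1], sampleRate = fs)
    sg <- computeSpectrogram(seg, spec)
    traces[[k]] <- log(colSums(sg$power) + 1e-300)
    if (is.null(lag)) lag <- sg$time + window[1]
  }
  m <- min(vapply(traces, length, integer(1)))
  lag <- lag[seq_len(m)]
  logTraces <- do.call(rbind, lapply(traces, function(x) x[seq_len(m)]))
  gm <- exp(colMeans(logTraces))
  pre <- lag < 0
  rel <- gm / mean(gm[pre])
  list(lag_s = lag, relPower = rel, nUsed = length(usable),
       nExcluded = nExcluded)
}
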