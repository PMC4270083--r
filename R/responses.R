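# Response quantification: PSTHs, matched event-free baselines, response
# indices for calls and touch, in/out-of-touch call modulation and the
# sample-size-equalizing bootstrap.

#' Spike PSTH around triggers
#'
#' Trigger-aligned firing rate, in Hz; thin wrapper over [eventPsth()] with
#' spike-train defaults (10 ms bins for call-triggered histograms; touch uses
#' 77 ms and calls-around-touch 500 ms).
#'
#' @inheritParams eventPsth
#' @param spikeTimes sorted spike times, seconds.
#' @export
spikePsth <- function(spikeTimes, triggers, window = c(-0.1, 0.2),
                      bin = 0.010) {
  eventPsth(spikeTimes, triggers, window = window, bin = bin)
}

#' Response windows for a set of calls
#'
#' @param calls call table.
#' @param mode one of `"call_duration"`, `"call_duration_plus_25ms"`
#'   (default) or the fixed onset windows `"onset_0_25"`, `"onset_26_50"`,
#'   `"onset_51_75"`, `"onset_76_100"` (ms after call onset).
#' @return 2-column matrix of (start, end) windows, one row per call.
#' @export
callResponseWindows <- function(calls, mode = "call_duration_plus_25ms") {
  stopifnot(mode %in% RESPONSE_WINDOW_MODES)
  on <- calls$onset_s; off <- calls$offset_s
  w <- switch(mode,
    call_duration = cbind(on, off),
    call_duration_plus_25ms = cbind(on, off + 0.025),
    onset_0_25 = cbind(on, on + 0.025),
    onset_26_50 = cbind(on + 0.025, on + 0.050),
    onset_51_75 = cbind(on + 0.050, on + 0.075),
    onset_76_100 = cbind(on + 0.075, on + 0.100))
  colnames(w) <- c("start", "end")
  w
}

#' Matched event-free baseline windows
#'
#' For each event window of length L, a baseline window of the same length is
#' placed 10 s of *clean* time before the event onset: walking backwards from
#' the onset, only time outside every exclusion window (all calls and all
#' interactions) is accumulated; once `shift` seconds of clean time have
#' accrued, the baseline is the latest unbroken clean stretch of length L
#' ending at or before that point (split baselines are disallowed, so the
#' window slides earlier until it fits inside one clean stretch). Events with
#' insufficient clean history are dropped and counted.
#'
#' @param eventWindows 2-column matrix of (start, end) event windows.
#' @param exclusions 2-column matrix of intervals that baselines must avoid
#'   (and that do not count towards the shift).
#' @param sessionSpan session length, seconds.
#' @param shift clean-time lookback, seconds (default 10).
#' @return list with `windows` (2-column matrix, one row per kept event),
#'   `keptEvents` (row indices into `eventWindows`), `nDropped`.
#' @export
matchedBaselineWindows <- function(eventWindows, exclusions, sessionSpan,
                                   shift = 10) {
  eventWindows <- as.matrix(eventWindows)
  if (!nrow(eventWindows)) stop("no event windows")
  ex <- mergeWindows(exclusions)
  clean <- complementWindows(ex, 0, sessionSpan)
  K <- nrow(clean)
  lens <- clean[, 2] - clean[, 1]
  cumLen <- c(0, cumsum(lens))  # clean time before the start of segment k+1
  out <- matrix(NA_real_, nrow = nrow(eventWindows), ncol = 2)
  for (i in seq_len(nrow(eventWindows))) {
    t0 <- min(eventWindows[i, 1], sessionSpan)
    L <- eventWindows[i, 2] - eventWindows[i, 1]
    # clean time accumulated before the event onset
    j0 <- findInterval(t0, clean[, 1])
    if (j0 < 1) next
    cleanBefore <- cumLen[j0] + max(0, min(t0, clean[j0, 2]) - clean[j0, 1])
    target <- cleanBefore - shift
    if (target < 0) next  # insufficient clean history
    # the shift point in session time: `target` clean seconds from t = 0
    k <- findInterval(target, cumLen)
    k <- min(max(k, 1), K)
    if (target < cumLen[k]) k <- k - 1
    if (k < 1) next
    tShift <- clean[k, 1] + (target - cumLen[k])
    # baseline starts at the shift point (event window translated back by
    # `shift` seconds of clean time); if it does not fit in one clean
    # stretch, slide earlier until an unbroken stretch of length L is found
    for (kk in seq(k, 1)) {
      lo <- clean[kk, 1]; hi <- min(clean[kk, 2], t0)  # never past the event
      sCand <- if (kk == k) min(tShift, hi - L) else hi - L
      if (sCand >= lo && sCand + L <= hi + 1e-12) {
        out[i, ] <- c(sCand, sCand + L)
        break
      }
    }
  }
  kept <- which(is.finite(out[, 1]))
  list(windows = out[kept, , drop = FALSE], keptEvents = kept,
       nDropped = nrow(eventWindows) - length(kept))
}

#' Average firing rate over a set of windows
#'
#' Total spikes inside the (half-open) windows divided by total window
#' duration, in Hz; invariant to splitting a window into contiguous halves.
#'
#' @param spikeTimes sorted spike times, seconds.
#' @param windows 2-column matrix of (start, end).
#' @export
eventRate <- function(spikeTimes, windows) {
  windows <- as.matrix(windows)
  if (!nrow(windows)) stop("no windows")
  tot <- sum(windows[, 2] - windows[, 1])
  if (tot <= 0) stop("zero total window duration")
  n <- sum(vapply(seq_len(nrow(windows)), function(i)
    sum(spikeTimes >= windows[i, 1] & spikeTimes < windows[i, 2]),
    numeric(1)))
  n / tot
}

#' Response index
#'
#' `(in - out) / (in + out)`: bounded in \[-1, 1\], antisymmetric under
#' argument swap, 0 for equal rates, NA (flagged undefined) when both rates
#' are 0.
#'
#' @param inRate,outRate firing rates, Hz (response vs matched baseline).
#' @examples
#' responseIndex(9.3, 8.8)  # 0.0276
#' @export
responseIndex <- function(inRate, outRate) {
  stopifnot(all(inRate >= 0), all(outRate >= 0))
  ifelse(inRate + outRate > 0, (inRate - outRate) / (inRate + outRate),
         NA_real_)
}

#' Touch response and off-response of a unit
#'
#' In-touch rate over all touch episodes, off-response rate in the 200 ms
#' windows after each touch offset (truncated by the next touch onset or the
#' session end, duration-corrected), and a matched baseline via
#' [matchedBaselineWindows()]; response indices for both against baseline.
#'
#' @param spikeTimes sorted spike times, seconds.
#' @param touches touch table.
#' @param exclusions intervals excluded from baselines (all calls and all
#'   interactions).
#' @param sessionSpan session length, seconds.
#' @param offWindow off-response window length, seconds.
#' @param shift baseline clean-time shift, seconds.
#' @return list with `inTouchRate`, `offRate`, `baselineRate`, `riTouch`,
#'   `riOff`, `nBaselineDropped`.
#' @export
touchResponse <- function(spikeTimes, touches, exclusions, sessionSpan,
                          offWindow = 0.2, shift = 10) {
  if (is.null(touches) || !nrow(touches)) stop("no touch episodes")
  tw <- cbind(touches$whisker_on_s, touches$whisker_off_s)
  tw <- tw[order(tw[, 1]), , drop = FALSE]
  offW <- cbind(tw[, 2], pmin(tw[, 2] + offWindow,
                              c(tw[-1, 1], sessionSpan)))
  offW <- offW[offW[, 2] > offW[, 1], , drop = FALSE]
  mb <- matchedBaselineWindows(tw, exclusions, sessionSpan, shift = shift)
  if (!nrow(mb$windows)) stop("no touch episode with sufficient clean history")
  inRate <- eventRate(spikeTimes, tw)
  offRate <- eventRate(spikeTimes, offW)
  baseRate <- eventRate(spikeTimes, mb$windows)
  list(inTouchRate = inRate, offRate = offRate, baselineRate = baseRate,
       riTouch = responseIndex(inRate, baseRate),
       riOff = responseIndex(offRate, baseRate),
       nBaselineDropped = mb$nDropped)
}

#' Call response indices split by in-touch versus out-of-touch calls
#'
#' Calls are partitioned by whether their onset falls inside a touch episode
#' (half-open, so a call at exactly a touch offset is out of touch). Each
#' condition gets its own response windows and matched baselines; conditions
#' with fewer than `minCalls` calls are flagged and return NA.
#'
#' @param spikeTimes sorted spike times, seconds.
#' @param calls call table.
#' @param touches touch table.
#' @param exclusions baseline exclusion intervals.
#' @param sessionSpan session length, seconds.
#' @param mode response-window mode, see [callResponseWindows()].
#' @param shift baseline clean-time shift, seconds.
#' @param minCalls per-condition floor (default 5).
#' @return list with `riIn`, `riOut`, `nIn`, `nOut`, `flagged`.
#' @export
callsInOutTouch <- function(spikeTimes, calls, touches, exclusions,
                            sessionSpan, mode = "call_duration_plus_25ms",
                            shift = 10, minCalls = 5) {
  tw <- touchWindows(touches)
  inTouch <- inAnyWindow(calls$onset_s, tw)
  conditionRi <- function(sub) {
    if (nrow(sub) < minCalls) return(NA_real_)
    w <- callResponseWindows(sub, mode)
    mb <- matchedBaselineWindows(w, exclusions, sessionSpan, shift = shift)
    if (!nrow(mb$windows)) return(NA_real_)
    responseIndex(eventRate(spikeTimes, w[mb$keptEvents, , drop = FALSE]),
                  eventRate(spikeTimes, mb$windows))
  }
  riIn <- conditionRi(calls[inTouch, , drop = FALSE])
  riOut <- conditionRi(calls[!inTouch, , drop = FALSE])
  list(riIn = riIn, riOut = riOut, nIn = sum(inTouch), nOut = sum(!inTouch),
       flagged = !is.finite(riIn) || !is.finite(riOut))
}

#' Bootstrap response indices at an equalized sample size
#'
#' `B` times, `nIn` calls are sampled without replacement from the
#' out-of-touch calls and the response index recomputed, so that the
#' in-touch versus out-of-touch comparison is matched in sample size (only a
#' fraction of calls occurs during touch).
#'
#' @param spikeTimes sorted spike times, seconds.
#' @param callsOut out-of-touch call table.
#' @param nIn target sample size (number of in-touch calls).
#' @param exclusions baseline exclusion intervals.
#' @param sessionSpan session length, seconds.
#' @param B bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param mode response-window mode.
#' @param shift baseline clean-time shift, seconds.
#' @return list with `ri` (length-B vector), `mean`, `nIn`, `B`.
#' @export
bootstrapEqualizedRi <- function(spikeTimes, callsOut, nIn, exclusions,
                                 sessionSpan, B = 1000, seed = 1,
                                 mode = "call_duration_plus_25ms",
                                 shift = 10) {
  nOut <- nrow(callsOut)
  if (nIn > nOut) stop("nIn exceeds the number of out-of-touch calls")
  if (nIn < 1) stop("nIn must be >= 1")
  set.seed(seed)
  ri <- vapply(seq_len(B), function(b) {
    sub <- callsOut[sample.int(nOut, nIn), , drop = FALSE]
    w <- callResponseWindows(sub, mode)
    mb <- matchedBaselineWindows(w, exclusions, sessionSpan, shift = shift)
    if (!nrow(mb$windows)) return(NA_real_)
    responseIndex(eventRate(spikeTimes, w[mb$keptEvents, , drop = FALSE]),
                  eventRate(spikeTimes, mb$windows))
  }, numeric(1))
  list(ri = ri, mean = mean(ri, na.rm = TRUE), nIn = nIn, B = B)
}

#' Nonparametric group comparison
#'
#' Paired data: Wilcoxon signed-rank; unpaired: Mann-Whitney U. A
#' Kolmogorov-Smirnov test compares distribution shapes, and a
#' D'Agostino-Pearson omnibus normality screen is reported for each group
#' (informational; it does not gate the nonparametric tests). All-tied paired
#' data yield p = 1 with a tie warning.
#'
#' @param a,b numeric samples.
#' @param paired logical.
#' @return list with `test`, `p`, `statistic`, `ksP`, `normalityP` (length-2)
#'   and `tieWarning`.
#' @export
populationCompare <- function(a, b, paired = FALSE) {
  stopifnot(length(a) >= 5, length(b) >= 5)
  tie <- FALSE
  if (paired) {
    stopifnot(length(a) == length(b))
    if (all(a == b)) {
      tie <- TRUE
      wt <- list(statistic = c(V = 0), p.value = 1)
      warning("all paired differences are zero; p = 1")
    } else {
      wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
    }
    test <- "wilcoxon_signed_rank"
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b))
    test <- "mann_whitney_u"
  }
  ks <- suppressWarnings(stats::ks.test(a, b))
  list(test = test, p = wt$p.value, statistic = unname(wt$statistic),
       ksP = ks$p.value,
       normalityP = c(dagostinoPearson(a)$p, dagostinoPearson(b)$p),
       tieWarning = tie)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' K^2 statistic combining the z-transformed sample skewness and kurtosis,
#' referred to a chi-squared distribution with 2 degrees of freedom.
#'
#' @param x numeric sample, n >= 20 recommended (minimum 8).
#' @return list with `k2` and `p`.
#' @export
dagostinoPearson <- function(x) {
  n <- length(x)
  if (n < 8) return(list(k2 = NA_real_, p = NA_real_))
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  if (m2 <= 0) return(list(k2 = NA_real_, p = NA_real_))
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  # skewness z (D'Agostino 1970)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Z1 <- delta * asinh(Y / alpha)
  # kurtosis z (Anscombe & Glynn 1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(Vb2)
  sqB1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqB1 * (2 / sqB1 + sqrt(1 + 4 / sqB1^2))
  Z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) *
    sqrt(9 * A / 2)
  k2 <- Z1^2 + Z2^2
  list(k2 = k2, p = stats::pchisq(k2, df = 2, lower.tail = FALSE))
}
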