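# Spike-whisking phase locking: occupancy-normalized circular histograms,
# Rayleigh vector, and the count-insensitive circular time-shift shuffle
# test with the three-part locking criterion.

# internal: map spikes into the concatenated valid (tracked) time of a phase
# trace. Returns valid-sample phase array, per-bin occupancy, and the spike
# positions (indices into the concatenated array).
trackedContext <- function(spikeTimes, phase, nBins = 16) {
  stopifnot(is(phase, "PhaseTrace"))
  vIdx <- which(phase@valid)
  if (!length(vIdx)) stop("phase trace has no valid samples")
  P <- phase@phase[vIdx]
  fs <- phase@sampleRate
  t0 <- phase@times[1]
  sIdx <- round((spikeTimes - t0) * fs) + 1
  keep <- sIdx >= 1 & sIdx <= length(phase@valid)
  sIdx <- sIdx[keep]
  inValid <- phase@valid[sIdx]
  # spike position within the concatenated valid array
  rank <- cumsum(phase@valid)
  pos <- rank[sIdx[inValid]]
  bins <- pmin(floor(P / (360 / nBins)) + 1, nBins)
  occupancy <- tabulate(bins, nbins = nBins) / fs  # seconds per bin
  list(P = P, pos = pos, fs = fs, nBins = nBins, bins = bins,
       occupancy = occupancy)
}

#' Occupancy-normalized spike-phase histogram
#'
#' Spikes falling in tracked (valid-cycle) time are binned by whisking phase;
#' each bin count is divided by the time the phase trace spends in that bin,
#' yielding a firing rate per phase bin in Hz. Bins with zero occupancy are
#' flagged and excluded from vector statistics.
#'
#' @param spikeTimes sorted spike times, seconds.
#' @param phase a [PhaseTrace-class].
#' @param nBins number of phase bins (default 16).
#' @return data.frame with `phase_mid_deg`, `n_spikes`, `occupancy_s`,
#'   `rate_hz` (NA for zero-occupancy bins).
#' @export
spikePhaseHistogram <- function(spikeTimes, phase, nBins = 16) {
  ctx <- trackedContext(spikeTimes, phase, nBins)
  spBins <- pmin(floor(ctx$P[ctx$pos] / (360 / nBins)) + 1, nBins)
  counts <- tabulate(spBins, nbins = nBins)
  rate <- ifelse(ctx$occupancy > 0, counts / ctx$occupancy, NA_real_)
  data.frame(phase_mid_deg = (seq_len(nBins) - 0.5) * 360 / nBins,
             n_spikes = counts, occupancy_s = ctx$occupancy, rate_hz = rate)
}

#' Rayleigh vector of circular observations
#'
#' Resultant of (optionally weighted) unit vectors at the observed phases,
#' divided by the total weight: length in \[0, 1\] (1 = all phases
#' identical), angle = preferred phase.
#'
#' @param phasesDeg phases in degrees.
#' @param weights optional non-negative weights (occupancy correction).
#' @return list with `length` and `angleDeg`.
#' @examples
#' rayleighVector(c(90, 90, 90))$length      # 1
#' rayleighVector(c(0, 180))$length          # 0
#' @export
rayleighVector <- function(phasesDeg, weights = NULL) {
  if (!length(phasesDeg)) stop("need at least one phase observation")
  if (is.null(weights)) weights <- rep(1, length(phasesDeg))
  r <- degToRad(phasesDeg)
  C <- sum(weights * cos(r)); S <- sum(weights * sin(r))
  list(length = sqrt(C^2 + S^2) / sum(weights),
       angleDeg = wrapDeg(radToDeg(atan2(S, C))))
}

# occupancy-weighted Rayleigh length for spike positions `pos` in the valid
# phase array P (weights = inverse occupancy of each spike's phase bin)
occupancyRayleigh <- function(pos, P, occupancy, nBins) {
  ph <- P[pos]
  b <- pmin(floor(ph / (360 / nBins)) + 1, nBins)
  w <- 1 / occupancy[b]
  w[!is.finite(w)] <- 0
  if (sum(w) <= 0) return(0)
  r <- degToRad(ph)
  sqrt(sum(w * cos(r))^2 + sum(w * sin(r))^2) / sum(w)
}

#' Circular time-shift shuffle test for phase locking
#'
#' The spike train is circularly shifted against the phase trace within the
#' concatenated tracked (valid-cycle) time, preserving the inter-spike
#' structure — the property that makes the test insensitive to spike count —
#' and the occupancy-weighted Rayleigh length is recomputed for each of
#' `nShuffles` random shifts. Returns the quantile of the original length
#' within the shuffle distribution; locking uses the 95 % level.
#'
#' @param spikeTimes sorted spike times, seconds.
#' @param phase a [PhaseTrace-class].
#' @param nShuffles number of random shifts (default 10000, as in the
#'   original procedure; 1000 is adequate for calibration work).
#' @param seed RNG seed.
#' @param nBins phase bins for the occupancy weighting.
#' @return list with `quantile`, `observed` (Rayleigh length), `nSpikes`
#'   (spikes in tracked time) and `shuffled` (the null lengths).
#' @export
shuffleTest <- function(spikeTimes, phase, nShuffles = 10000, seed = 1,
                        nBins = 16) {
  ctx <- trackedContext(spikeTimes, phase, nBins)
  M <- length(ctx$P)
  if (M < 0.25 * ctx$fs) stop("tracked span too short to shuffle")
  if (!length(ctx$pos)) stop("no spikes in tracked time")
  set.seed(seed)
  shifts <- sample.int(M, nShuffles, replace = TRUE)
  obs <- occupancyRayleigh(ctx$pos, ctx$P, ctx$occupancy, nBins)
  null <- vapply(shifts, function(k)
    occupancyRayleigh(((ctx$pos - 1 + k) %% M) + 1, ctx$P, ctx$occupancy,
                      nBins), numeric(1))
  list(quantile = mean(null <= obs), observed = obs,
       nSpikes = length(ctx$pos), shuffled = null)
}

#' Classify phase-locked units
#'
#' A unit is phase locked iff (i) it fired at least `minSpikes` spikes in
#' tracked time, (ii) its occupancy-weighted Rayleigh length exceeds
#' `rayleighMin`, and (iii) its original Rayleigh length reaches the
#' `1 - alpha` quantile of its shuffle distribution.
#'
#' @param units list of [UnitRecording-class].
#' @param phase a [PhaseTrace-class].
#' @param config an [AnalysisConfig-class] (supplies `minSpikes`,
#'   `rayleighMin`, `shuffleAlpha`, `nShuffles`, `phaseBins`, `seed`).
#' @return data.frame with one row per unit: `unit_id`,
#'   `n_spikes_in_tracked`, `rayleigh_length`, `preferred_phase_deg`,
#'   `shuffle_quantile`, `locked`.
#' @export
classifyPhaseLocked <- function(units, phase, config = analysisConfig()) {
  rows <- lapply(seq_along(units), function(i) {
    u <- units[[i]]
    ctx <- trackedContext(u@spikeTimes, phase, config@phaseBins)
    n <- length(ctx$pos)
    if (n == 0)
      return(data.frame(unit_id = u@unitId, n_spikes_in_tracked = 0L,
                        rayleigh_length = NA_real_,
                        preferred_phase_deg = NA_real_,
                        shuffle_quantile = NA_real_, locked = FALSE))
    ph <- ctx$P[ctx$pos]
    b <- pmin(floor(ph / (360 / config@phaseBins)) + 1, config@phaseBins)
    w <- 1 / ctx$occupancy[b]; w[!is.finite(w)] <- 0
    rv <- rayleighVector(ph, w)
    st <- shuffleTest(u@spikeTimes, phase, nShuffles = config@nShuffles,
                      seed = config@seed + i, nBins = config@phaseBins)
    data.frame(unit_id = u@unitId, n_spikes_in_tracked = n,
               rayleigh_length = rv$length,
               preferred_phase_deg = rv$angleDeg,
               shuffle_quantile = st$quantile,
               locked = n >= config@minSpikes &&
                 rv$length > config@rayleighMin &&
                 st$quantile >= 1 - config@shuffleAlpha)
  })
  do.call(rbind, rows)
}
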