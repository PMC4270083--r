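# Call-whisking coordination: phase-at-call sampling, Hodges-Ajne circular
# uniformity test, call-triggered whisking average, retraction/protraction
# split.

#' Whisking phase at call onsets
#'
#' Nearest-sample lookup of the whisking phase at each call onset. Onsets in
#' invalid (QC-rejected) cycles are flagged `valid = FALSE`; onsets outside
#' the phase-trace coverage are flagged `covered = FALSE` rather than
#' silently dropped. Only valid, covered samples should enter circular tests.
#'
#' @param phase a [PhaseTrace-class].
#' @param callOnsets call onset times, seconds.
#' @param role "emitter" or "partner": whose whisking the phase trace
#'   describes, relative to the calls.
#' @return data.frame with `call_id`, `onset_s`, `phase_deg`, `valid`,
#'   `covered`, `role`.
#' @export
phaseAtCalls <- function(phase, callOnsets, role = c("emitter", "partner")) {
  role <- match.arg(role)
  stopifnot(is(phase, "PhaseTrace"))
  n <- length(phase@times)
  if (!n) stop("empty phase trace")
  t0 <- phase@times[1]
  idx <- round((callOnsets - t0) * phase@sampleRate) + 1
  covered <- idx >= 1 & idx <= n
  idxc <- pmin(pmax(idx, 1), n)
  data.frame(call_id = seq_along(callOnsets), onset_s = callOnsets,
             phase_deg = ifelse(covered, phase@phase[idxc], NA_real_),
             valid = covered & phase@valid[idxc], covered = covered,
             role = role)
}

#' Hodges-Ajne test of circular uniformity
#'
#' The statistic m is the minimum number of observations contained in any
#' closed half-circle, found by enumerating the n half-circle boundaries at
#' the data points. The p-value uses the classical formula
#' p = (n - 2m) C(n, m) / 2^(n-1) (evaluated in log space), set to 1 when the
#' formula is non-positive (perfectly balanced data) and capped at 1.
#'
#' @param phasesDeg phases in degrees.
#' @return list with `n`, `m` and `p`.
#' @examples
#' hodgesAjne(c(10, 20, 30, 40, 50, 60, 70, 80, 85, 88))$p  # 10/512
#' @export
hodgesAjne <- function(phasesDeg) {
  phasesDeg <- phasesDeg[is.finite(phasesDeg)]
  n <- length(phasesDeg)
  if (n < 4) stop("insufficient samples for the Hodges-Ajne test (need >= 4)")
  m <- hodgesAjneStat(phasesDeg)
  list(n = n, m = m, p = hodgesAjneP(m, n))
}

# minimum count in any half-circle, boundaries at the data points
hodgesAjneStat <- function(phasesDeg) {
  th <- sort(wrapDeg(phasesDeg))
  n <- length(th)
  cnt <- vapply(th, function(b) sum(wrapDeg(th - b) < 180), numeric(1))
  as.integer(min(cnt, n - cnt))
}

hodgesAjneP <- function(m, n) {
  if (n - 2 * m <= 0) return(1)
  lp <- log(n - 2 * m) + lchoose(n, m) - (n - 1) * log(2)
  min(1, exp(lp))
}

#' Call-triggered whisking average
#'
#' All whisker-angle segments around call onsets are aligned at the onset and
#' averaged pointwise. Coherent calling at a fixed whisking phase preserves
#' the oscillation in the average; phase-random calling averages it out.
#'
#' @param traces a [FilteredTrace-class] or list of them.
#' @param callOnsets onset times (seconds) for a single trace, or a list of
#'   onset vectors parallel to `traces`.
#' @param window half-width of the segment around each onset, seconds.
#' @return list with `lag_s`, `mean_deg`, `sem_deg`, `n` (number of
#'   contributing segments, all with full window coverage).
#' @export
callTriggeredAverage <- function(traces, callOnsets, window = 0.5) {
  if (is(traces, "FilteredTrace")) {
    traces <- list(traces); callOnsets <- list(callOnsets)
  }
  stopifnot(length(traces) == length(callOnsets))
  fs <- traces[[1]]@sampleRate
  half <- round(window * fs)
  lag <- seq(-half, half) / fs
  segs <- list()
  for (k in seq_along(traces)) {
    tr <- traces[[k]]
    nT <- length(tr@times)
    for (on in callOnsets[[k]]) {
      i <- round((on - tr@times[1]) * fs) + 1
      if (i - half >= 1 && i + half <= nT)
        segs[[length(segs) + 1]] <- tr@angle[(i - half):(i + half)]
    }
  }
  if (length(segs) < 5)
    stop("fewer than 5 calls with full window coverage")
  m <- do.call(rbind, segs)
  list(lag_s = lag, mean_deg = colMeans(m),
       sem_deg = apply(m, 2, stats::sd) / sqrt(nrow(m)), n = nrow(m))
}

#' Retraction/protraction split of call-onset phases
#'
#' Counts valid call-onset phase samples falling in the retraction half
#' (0, 180\] versus the protraction half (everything else, including phase
#' exactly 0, the protraction peak), with an exact binomial test against an
#' even split.
#'
#' @param samples data.frame from [phaseAtCalls()] (or any with `phase_deg`
#'   and `valid`).
#' @return list with `nRetraction`, `nProtraction`, `p` (binomial, two-sided).
#' @export
retractionProtractionSplit <- function(samples) {
  ph <- samples$phase_deg[samples$valid]
  if (!length(ph)) stop("no valid phase samples")
  retr <- ph > 0 & ph <= 180
  nR <- sum(retr); nP <- sum(!retr)
  list(nRetraction = nR, nProtraction = nP,
       p = stats::binom.test(nR, nR + nP, 0.5)$p.value)
}
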