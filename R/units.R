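# Cell-type classification from spike-waveform widths and the permutation
# stability (drift) exclusion metric.

#' Spike-waveform width features
#'
#' Waveforms are normalized by peak voltage (the dominant deflection, either
#' sign, becomes 1). `full_width` is the time between the 25 %-of-peak
#' crossings on the rising and falling flanks (linear interpolation between
#' samples); `second_half_width` runs from the peak to the falling crossing.
#' Relative widths are scaled to the widest unit in the dataset, which is
#' assigned exactly 1.
#'
#' @param units list of [UnitRecording-class].
#' @param level crossing level as a fraction of peak amplitude.
#' @return data.frame with `unit_id`, `full_width_s`, `second_half_width_s`,
#'   `rel_full_width`, `rel_second_half_width`. Units with flat or degenerate
#'   waveforms are dropped with a message; their ids are in
#'   `attr(, "dropped")`.
#' @export
waveformFeatures <- function(units, level = 0.25) {
  stopifnot(length(units) >= 1)
  rows <- list(); dropped <- character(0)
  for (u in units) {
    w <- u@waveform
    fs <- u@waveformRate
    if (length(w) < 5 || max(abs(w)) <= 0 ||
        stats::sd(w) < 1e-12 * max(1, max(abs(w)))) {
      dropped <- c(dropped, u@unitId)
      message(sprintf("unit %s: flat waveform, excluded from classification",
                      u@unitId))
      next
    }
    pk <- which.max(abs(w))
    wn <- w / w[pk]  # peak-normalized: peak value 1, either original sign
    cross <- function(from, to) {
      # first crossing of `level` walking from `from` towards `to`
      idx <- if (from <= to) from:to else from:to
      for (j in idx) {
        if (wn[j] < level) {
          # interpolate between j and previous index towards the peak
          jp <- j - sign(to - from)
          if (jp < 1 || jp > length(wn)) return(NA_real_)
          frac <- (wn[jp] - level) / (wn[jp] - wn[j])
          return((jp - 1 + sign(to - from) * frac) / fs)
        }
      }
      NA_real_
    }
    tLeft <- cross(pk, 1)
    tRight <- cross(pk, length(wn))
    if (!is.finite(tLeft) || !is.finite(tRight)) {
      dropped <- c(dropped, u@unitId)
      message(sprintf("unit %s: no %d%% crossings, excluded", u@unitId,
                      round(level * 100)))
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      unit_id = u@unitId,
      full_width_s = tRight - tLeft,
      second_half_width_s = tRight - (pk - 1) / fs)
  }
  if (!length(rows)) stop("no unit with a measurable waveform")
  out <- do.call(rbind, rows)
  out$rel_full_width <- out$full_width_s / max(out$full_width_s)
  out$rel_second_half_width <-
    out$second_half_width_s / max(out$second_half_width_s)
  attr(out, "dropped") <- dropped
  out
}

#' Classify units into putative RS and FS classes
#'
#' k-means with two clusters on (relative full width, relative second-half
#' width), 10 restarts, best inertia, fixed seed. The cluster with the larger
#' mean full width is labeled RS (regular spiking), the other FS (fast
#' spiking). Degenerate feature sets (all identical) yield all-RS with a
#' warning.
#'
#' @param features data.frame from [waveformFeatures()].
#' @param seed RNG seed.
#' @return the feature table with a `cell_class` column added.
#' @export
classifyRsFs <- function(features, seed = 1) {
  stopifnot(nrow(features) >= 4)
  X <- as.matrix(features[, c("rel_full_width", "rel_second_half_width")])
  if (!all(is.finite(X))) stop("non-finite features")
  if (max(stats::dist(X)) < 1e-12) {
    warning("degenerate features (all identical): labelling all units RS")
    features$cell_class <- "RS"
    return(features)
  }
  set.seed(seed)
  km <- stats::kmeans(X, centers = 2, nstart = 10)
  wide <- which.max(tapply(X[, 1], km$cluster, mean))
  features$cell_class <- ifelse(km$cluster == wide, "RS", "FS")
  features
}

#' Recording-stability (drift) score of a unit
#'
#' For each of `nPerm` permutations, periods outside the interaction windows
#' are sampled, as many and as long as the interactions, uniformly placed and
#' non-overlapping. The firing rate in each period is correlated (Pearson)
#' against the period midpoint time; the stability score is the mean |R| over
#' permutations. Larger scores mean stronger rate drift across the session;
#' units scoring above `maxR` (0.4) are excluded from analysis.
#'
#' @param spikeTimes sorted spike times, seconds.
#' @param interactionWindows 2-column matrix of (start, end), seconds.
#' @param sessionSpan session length, seconds.
#' @param nPerm number of permutations (default 1000).
#' @param seed RNG seed.
#' @param maxR exclusion threshold on the mean |R|.
#' @return list with `meanAbsR`, `nPerm`, `excluded`, and `silent`
#'   (TRUE with score 0 for a unit with no spikes).
#' @export
unitStability <- function(spikeTimes, interactionWindows, sessionSpan,
                          nPerm = 1000, seed = 1, maxR = 0.4) {
  iw <- mergeWindows(interactionWindows)
  if (!nrow(iw)) stop("no interaction windows")
  if (max(iw[, 2]) > sessionSpan + 1e-9 || min(iw[, 1]) < -1e-9)
    stop("interaction windows outside the session span")
  if (!length(spikeTimes))
    return(list(meanAbsR = 0, nPerm = nPerm, excluded = FALSE, silent = TRUE))
  durations <- iw[, 2] - iw[, 1]
  free <- complementWindows(iw, 0, sessionSpan)
  if (totalWindowTime(free) < sum(durations))
    stop("insufficient non-interaction time")
  set.seed(seed)
  rs <- numeric(nPerm)
  for (p in seq_len(nPerm)) {
    placed <- placeMatchedPeriods(durations, free)
    if (is.null(placed)) stop("insufficient non-interaction time")
    mid <- (placed[, 1] + placed[, 2]) / 2
    rate <- vapply(seq_len(nrow(placed)), function(i)
      sum(spikeTimes >= placed[i, 1] & spikeTimes < placed[i, 2]) /
        (placed[i, 2] - placed[i, 1]), numeric(1))
    r <- if (stats::sd(rate) > 0 && stats::sd(mid) > 0)
      stats::cor(mid, rate) else 0
    rs[p] <- abs(r)
  }
  score <- mean(rs)
  list(meanAbsR = score, nPerm = nPerm, excluded = score > maxR,
       silent = FALSE)
}

# sequentially place windows of the given durations inside `free` segments,
# uniformly at random and without overlap; NULL after repeated failure
placeMatchedPeriods <- function(durations, free, maxAttempts = 1000) {
  for (attempt in seq_len(maxAttempts)) {
    segs <- free
    out <- matrix(NA_real_, nrow = length(durations), ncol = 2)
    ok <- TRUE
    for (k in order(durations, decreasing = TRUE)) {
      L <- durations[k]
      cap <- segs[, 2] - segs[, 1] - L
      fit <- which(cap >= 0)
      if (!length(fit)) { ok <- FALSE; break }
      # choose a segment weighted by the available start range
      wgt <- cap[fit] + 1e-12
      si <- fit[sample.int(length(fit), 1, prob = wgt)]
      start <- stats::runif(1, segs[si, 1], segs[si, 2] - L)
      out[k, ] <- c(start, start + L)
      # split the chosen free segment around the placed window
      newSegs <- rbind(segs[-si, , drop = FALSE],
                       c(segs[si, 1], start), c(start + L, segs[si, 2]))
      segs <- newSegs[newSegs[, 2] > newSegs[, 1], , drop = FALSE]
    }
    if (ok) return(out)
  }
  NULL
}
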