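# Internal signal-processing primitives. The installed signal stack provides
# filtering and spectrograms but neither a Welch PSD nor an analytic-signal
# (Hilbert) routine, so both are implemented here in their textbook form.

# Analytic signal x + i H(x) via the one-sided FFT spectrum. The input is
# zero-padded to a highly composite length (mixed-radix FFTs degrade to
# O(n^2) on awkward lengths); padding only perturbs the signal ends, which
# the cycle QC already treats as unreliable.
analyticSignal <- function(x) {
  n <- length(x)
  if (n < 2) return(complex(real = x, imaginary = 0))
  nfft <- stats::nextn(n, c(2, 3, 5))
  xp <- c(x, numeric(nfft - n))
  X <- stats::fft(xp)
  h <- numeric(nfft)
  if (nfft %% 2 == 0) {
    h[1] <- 1; h[nfft / 2 + 1] <- 1; h[2:(nfft / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((nfft + 1) / 2)] <- 2
  }
  (stats::fft(X * h, inverse = TRUE) / nfft)[seq_len(n)]
}

hannWindow <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

# Welch's averaged-periodogram PSD, one-sided, Hann window, per-segment mean
# removal. Density normalization: sum(psd) * df ~ var(x) for broadband input.
welchPsd <- function(x, fs, nperseg = NULL, overlap = 0.5) {
  n <- length(x)
  if (is.null(nperseg)) nperseg <- min(n, 2^floor(log2(max(n / 4, 8))))
  nperseg <- min(nperseg, n)
  if (nperseg < 8) stop("signal too short for Welch PSD")
  step <- max(1, floor(nperseg * (1 - overlap)))
  starts <- seq(1, n - nperseg + 1, by = step)
  w <- hannWindow(nperseg)
  wnorm <- sum(w^2)
  nf <- floor(nperseg / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg))^2 / (fs * wnorm)
    half <- sp[1:nf]
    # fold the two-sided spectrum into one side (all but DC/Nyquist doubled)
    if (nperseg %% 2 == 0) half[2:(nf - 1)] <- 2 * half[2:(nf - 1)]
    else half[2:nf] <- 2 * half[2:nf]
    acc <- acc + half
  }
  psd <- acc / length(starts)
  list(freq = seq(0, nf - 1) * fs / nperseg, psd = psd,
       resolution = fs / nperseg)
}

movingAverage <- function(x, k) {
  if (k <= 1 || length(x) < k) return(x)
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2)) -> y
  # edges: shrink the window instead of returning NA
  half <- floor(k / 2)
  n <- length(x)
  for (i in which(is.na(y))) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    y[i] <- mean(x[lo:hi])
  }
  y
}

# ---- interval (window) helpers; all windows are half-open [start, end) ----

# normalize an n x 2 matrix of windows: drop empties, sort, merge overlaps
mergeWindows <- function(w) {
  if (is.null(w) || !nrow(w)) return(matrix(numeric(0), ncol = 2))
  w <- w[w[, 2] > w[, 1], , drop = FALSE]
  if (!nrow(w)) return(matrix(numeric(0), ncol = 2))
  w <- w[order(w[, 1]), , drop = FALSE]
  out <- w[1, , drop = FALSE]
  for (i in seq_len(nrow(w))[-1]) {
    if (w[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], w[i, 2])
    } else out <- rbind(out, w[i, ])
  }
  out
}

# logical: which times fall inside any half-open window
inAnyWindow <- function(times, w) {
  if (is.null(w) || !nrow(w) || !length(times)) return(rep(FALSE, length(times)))
  idx <- findInterval(times, as.vector(t(w)))
  idx %% 2 == 1
}

totalWindowTime <- function(w) {
  if (is.null(w) || !nrow(w)) return(0)
  sum(w[, 2] - w[, 1])
}

# complement of windows within [lo, hi)
complementWindows <- function(w, lo, hi) {
  w <- mergeWindows(w)
  if (!nrow(w)) return(matrix(c(lo, hi), ncol = 2))
  w[, 1] <- pmax(w[, 1], lo); w[, 2] <- pmin(w[, 2], hi)
  w <- w[w[, 2] > w[, 1], , drop = FALSE]
  if (!nrow(w)) return(matrix(c(lo, hi), ncol = 2))
  starts <- c(lo, w[, 2]); ends <- c(w[, 1], hi)
  out <- cbind(starts, ends)
  out[out[, 2] > out[, 1], , drop = FALSE]
}

# intersection of two window sets
intersectWindows <- function(a, b) {
  a <- mergeWindows(a); b <- mergeWindows(b)
  if (!nrow(a) || !nrow(b)) return(matrix(numeric(0), ncol = 2))
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1], b[, 1]); hi <- pmin(a[i, 2], b[, 2])
    keep <- hi > lo
    if (any(keep)) out <- rbind(out, cbind(lo[keep], hi[keep]))
  }
  mergeWindows(out)
}

# count events (sorted or not) in each half-open window; returns total
countInWindows <- function(times, w) {
  if (!length(times) || is.null(w) || !nrow(w)) return(0L)
  sum(inAnyWindow(times, mergeWindows(w)))
}

# sample an inhomogeneous Poisson process with piecewise-constant rate.
# `breaks` (sorted, length m+1) and `rate` (length m) define the step function.
samplePiecewisePoisson <- function(breaks, rate) {
  stopifnot(length(breaks) == length(rate) + 1)
  out <- numeric(0)
  for (i in seq_along(rate)) {
    if (rate[i] <= 0) next
    len <- breaks[i + 1] - breaks[i]
    k <- stats::rpois(1, rate[i] * len)
    if (k > 0) out <- c(out, stats::runif(k, breaks[i], breaks[i + 1]))
  }
  sort(out)
}
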