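# Circular helpers (degrees throughout the user-facing surface).

degToRad <- function(d) d * pi / 180
radToDeg <- function(r) r * 180 / pi

wrapDeg <- function(d) ((d %% 360) + 360) %% 360

# weighted circular mean direction in degrees
circularMeanDeg <- function(deg, w = NULL) {
  if (!length(deg)) return(NA_real_)
  if (is.null(w)) w <- rep(1, length(deg))
  r <- degToRad(deg)
  wrapDeg(radToDeg(atan2(sum(w * sin(r)), sum(w * cos(r)))))
}

# smallest absolute angular difference in degrees
angularDiffDeg <- function(a, b) {
  d <- wrapDeg(a - b)
  pmin(d, 360 - d)
}

# von Mises sampler (Best & Fisher 1979 rejection scheme); mu, output degrees
rVonMisesDeg <- function(n, muDeg, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 360))
  mu <- degToRad(muDeg)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      theta <- mu + sign(u[3] - 0.5) * acos(f)
      out[i] <- theta
      i <- i + 1
    }
  }
  wrapDeg(radToDeg(out))
}

# von Mises density ratio f(phi)/max f, used for thinning acceptance
vonMisesAcceptRatio <- function(phiDeg, muDeg, kappa) {
  exp(kappa * (cos(degToRad(phiDeg - muDeg)) - 1))
}
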