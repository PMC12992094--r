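## Histogram thresholding.
##
## otsuThreshold works on the exact empirical histogram of the image
## (every distinct intensity is a candidate split), so the result equals
## a brute-force scan maximizing inter-class variance.  Ties go to the
## lowest qualifying split.

#' Otsu threshold(s) by exact inter-class variance maximization
#'
#' @param image numeric matrix or vector of intensities.
#' @param levels 1 for a single threshold (two classes), 2 for two
#'   thresholds (three classes).
#' @param maxBins cap on distinct candidate values for \code{levels = 2};
#'   richer histograms are binned.
#' @return threshold value(s); pixels strictly above a threshold fall in
#'   the class above it.  A constant image is degenerate: the constant is
#'   returned with attribute \code{degenerate = TRUE}.
#' @export
otsuThreshold <- function(image, levels = 1, maxBins = 256) {
  x <- as.numeric(image)
  x <- x[is.finite(x)]
  v <- sort(unique(x))
  if (length(v) < 2) {
    t <- if (length(v)) v[1] else NA_real_
    t <- rep(t, levels)
    attr(t, "degenerate") <- TRUE
    return(t)
  }
  if (levels == 2 && length(v) > maxBins) {
    br <- seq(min(x), max(x), length.out = maxBins + 1)
    mid <- (br[-1] + br[-length(br)]) / 2
    idx <- pmin(maxBins, pmax(1L, findInterval(x, br, rightmost.closed = TRUE)))
    x <- mid[idx]
    v <- sort(unique(x))
  }
  cnt <- tabulate(match(x, v), nbins = length(v))
  n <- length(x)
  w <- cumsum(cnt)                       # pixels <= v[i]
  s <- cumsum(cnt * v)                   # intensity sum <= v[i]
  tot <- s[length(s)]
  if (levels == 1) {
    k <- length(v) - 1                   # split after v[i], i = 1..k
    w0 <- w[1:k]; w1 <- n - w0
    m0 <- s[1:k] / w0; m1 <- (tot - s[1:k]) / w1
    sigma <- (w0 / n) * (w1 / n) * (m0 - m1)^2
    i <- which.max(sigma)                # first maximum on ties
    t <- (v[i] + v[i + 1]) / 2
    return(t)
  }
  if (levels != 2) stop("levels must be 1 or 2")
  k <- length(v)
  best <- -Inf; bi <- c(1L, 2L)
  for (i in 1:(k - 2)) {
    w0 <- w[i]; s0 <- s[i]
    j <- (i + 1):(k - 1)
    w1 <- w[j] - w0; s1 <- s[j] - s0
    w2 <- n - w[j]; s2 <- tot - s[j]
    mu <- tot / n
    sigma <- w0 * (s0 / w0 - mu)^2 + w1 * (s1 / w1 - mu)^2 + w2 * (s2 / w2 - mu)^2
    jj <- which.max(sigma)
    if (sigma[jj] > best) { best <- sigma[jj]; bi <- c(i, j[jj]) }
  }
  c((v[bi[1]] + v[bi[1] + 1]) / 2, (v[bi[2]] + v[bi[2] + 1]) / 2)
}

#' Threshold at the point of maximum concavity of the cumulative
#' intensity distribution (rotated-chord method)
#'
#' The cumulative histogram is normalised to the unit square; the chord
#' from its first to last point is drawn and the intensity at maximum
#' perpendicular distance below the chord is returned.
#'
#' @param image numeric matrix or vector.
#' @param nbins histogram resolution.
#' @export
concavityThreshold <- function(image, nbins = 256) {
  x <- as.numeric(image)
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2) {
    t <- unique(x)[1]
    attr(t, "degenerate") <- TRUE
    return(t)
  }
  br <- seq(min(x), max(x), length.out = nbins + 1)
  h <- graphics::hist(x, breaks = br, plot = FALSE)
  cdf <- cumsum(h$counts) / length(x)
  u <- seq(0, 1, length.out = nbins)     # normalised intensity axis
  ## maximum deviation from the chord through the cumulative curve's
  ## endpoints = the knee of the distribution
  chord <- cdf[1] + (cdf[nbins] - cdf[1]) * (u - u[1]) / (u[nbins] - u[1])
  i <- which.max(abs(cdf - chord))
  h$mids[i]
}
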