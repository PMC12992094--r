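## Shared fixture builders.  All fixtures are generated in code; no data
## files are read.

## binary disc mask in an H x W field
discMask <- function(H, W, cy, cx, r) {
  d <- sqrt(outer((seq_len(H) - cy)^2, (seq_len(W) - cx)^2, "+"))
  d <= r
}

## LabelMask with discs at given centres (later discs overwrite earlier)
discLabelMask <- function(H, W, centers, r) {
  lbl <- matrix(0L, H, W)
  for (i in seq_len(nrow(centers))) {
    lbl[discMask(H, W, centers[i, 1], centers[i, 2], r)] <- i
  }
  new("LabelMask", labels = lbl)
}

## brute-force nearest-mask-pixel distances and assignment; the oracle
## for cytoring construction (plain double loop over mask pixels)
bruteRing <- function(mask, innerrad, outerrad) {
  lbl <- labels(mask)
  H <- nrow(lbl); W <- ncol(lbl)
  ids <- sort(unique(lbl[lbl > 0]))
  coords <- lapply(ids, function(i) which(lbl == i, arr.ind = TRUE))
  out <- matrix(0L, H, W)
  for (y in seq_len(H)) for (x in seq_len(W)) {
    if (lbl[y, x] > 0) next
    dmin <- Inf; amin <- 0L
    for (k in seq_along(ids)) {
      co <- coords[[k]]
      d <- sqrt(min((co[, 1] - y)^2 + (co[, 2] - x)^2))
      if (d < dmin) { dmin <- d; amin <- ids[k] }
    }
    if (dmin > innerrad && dmin <= outerrad) out[y, x] <- amin
  }
  out
}

## brute-force Otsu: naive scan over all candidate splits maximizing
## inter-class variance; first maximum wins
bruteOtsu <- function(x) {
  v <- sort(unique(x))
  best <- -Inf; bt <- NA
  n <- length(x)
  for (i in seq_len(length(v) - 1)) {
    lo <- x[x <= v[i]]; hi <- x[x > v[i]]
    w0 <- length(lo) / n; w1 <- length(hi) / n
    s <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (s > best) { best <- s; bt <- (v[i] + v[i + 1]) / 2 }
  }
  bt
}

## "within k px" neighbourhood of a binary mask (Chebyshev distance)
binaryDilateTest <- function(mask, k) {
  out <- mask
  for (i in seq_len(k))
    out <- (as.matrix(EBImage::dilate(out * 1, matrix(1, 3, 3))) > 0)
  out
}

## minimal valid settings for quick construction
minimalSettings <- function(...) {
  ifSettings(file_name = "example",
             IF_imagesessions = "Round1",
             signals = list(c("DNA", "GFP")),
             maskIndex = 1, jitterIndex = 1, ...)
}
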