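## Low-level pixel utilities shared across the pipeline.
##
## Images are plain numeric matrices with rows = y (image row) and
## columns = x.  EBImage's morphology kernels are isotropic, so matrices
## can be passed through directly; results are converted back with
## as.matrix()/imageData().

#' Disc-shaped structuring element
#'
#' @param r radius in pixels; \code{r < 1} yields a 1x1 brush.
#' @return binary matrix of odd side length.
#' @keywords internal
discBrush <- function(r) {
  r <- floor(r)
  if (r < 1) return(matrix(1, 1, 1))
  EBImage::makeBrush(2L * r + 1L, shape = "disc")
}

#' Circular averaging filter (mean over a disc)
#'
#' @param m numeric matrix.
#' @param r disc radius in pixels; \code{r < 1} returns \code{m} unchanged.
#' @keywords internal
discAverage <- function(m, r) {
  if (is.null(r) || r < 1) return(m)
  b <- discBrush(r)
  b <- b / sum(b)
  as.matrix(EBImage::filter2(m, b, boundary = "replicate"))
}

#' Gaussian smoothing
#' @keywords internal
gaussianSmooth <- function(m, sigma) {
  if (is.null(sigma) || sigma <= 0) return(m)
  as.matrix(EBImage::gblur(m, sigma = sigma, boundary = "replicate"))
}

padMatrix <- function(m, p, value = 0, replicate = FALSE) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(value, H + 2 * p, W + 2 * p)
  out[(p + 1):(p + H), (p + 1):(p + W)] <- m
  if (replicate && p > 0) {
    ri <- c(rep(1L, p), seq_len(H), rep(H, p))
    ci <- c(rep(1L, p), seq_len(W), rep(W, p))
    out <- m[ri, ci, drop = FALSE]
  }
  out
}

unpadMatrix <- function(m, p, H, W) {
  m[(p + 1):(p + H), (p + 1):(p + W), drop = FALSE]
}

## disc offsets (dy, dx) with dy^2 + dx^2 <= r^2
.discOffsets <- function(r) {
  g <- seq(-r, r)
  off <- expand.grid(dy = g, dx = g)
  off[off$dy^2 + off$dx^2 <= r^2, , drop = FALSE]
}

## flat grayscale min/max filter over a disc, replicate-padded borders
.rankFilterDisc <- function(m, r, op = pmin) {
  r <- floor(r)
  if (r < 1) return(m)
  H <- nrow(m); W <- ncol(m)
  mp <- padMatrix(m, r, replicate = TRUE)
  off <- .discOffsets(r)
  out <- NULL
  for (k in seq_len(nrow(off))) {
    sub <- mp[(1 + r + off$dy[k]):(H + r + off$dy[k]),
              (1 + r + off$dx[k]):(W + r + off$dx[k]), drop = FALSE]
    out <- if (is.null(out)) sub else op(out, sub)
  }
  out
}

#' Grayscale morphological opening with a flat disc (erosion then
#' dilation), replicate-padded so the image border does not darken.
#' @keywords internal
grayOpening <- function(m, r) {
  r <- floor(r)
  if (r < 1) return(m)
  .rankFilterDisc(.rankFilterDisc(m, r, pmin), r, pmax)
}

#' White top-hat transform: image minus its opening.  Isolates bright
#' structures smaller than the disc.
#' @keywords internal
whiteTopHatDisc <- function(m, r) {
  m - grayOpening(m, r)
}

#' Binary closing with a disc; the field outside the image is background.
#' @keywords internal
binaryClosing <- function(mask, r) {
  r <- floor(r)
  if (r < 1) return(mask)
  H <- nrow(mask); W <- ncol(mask)
  p <- r + 1L
  mp <- padMatrix(mask * 1, p, value = 0)
  cl <- as.matrix(EBImage::closing(mp, discBrush(r)))
  unpadMatrix(cl, p, H, W) > 0
}

#' Binary dilation with a disc.
#' @keywords internal
binaryDilate <- function(mask, r) {
  r <- floor(r)
  if (r < 1) return(mask > 0)
  as.matrix(EBImage::dilate(mask * 1, discBrush(r))) > 0
}

#' Fill holes in a binary mask with selectable background connectivity.
#'
#' A hole is a background component not connected to the image border.
#' Connectivity 4 uses EBImage's 4-connected labelling of the background;
#' connectivity 8 floods the border-connected background iteratively with
#' a 3x3 kernel.
#' @keywords internal
fillHoles <- function(mask, connectivity = 4) {
  mask <- mask > 0
  bg <- !mask
  if (!any(bg)) return(mask)
  if (connectivity == 4) {
    lab <- as.matrix(EBImage::bwlabel(bg * 1))
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    border <- border[border > 0]
    holes <- bg & !(lab %in% border)
    dim(holes) <- dim(mask)
  } else {
    kern <- matrix(1, 3, 3)
    reach <- matrix(FALSE, nrow(mask), ncol(mask))
    reach[1, ] <- bg[1, ]; reach[nrow(mask), ] <- bg[nrow(mask), ]
    reach[, 1] <- bg[, 1]; reach[, ncol(mask)] <- bg[, ncol(mask)]
    repeat {
      grown <- (as.matrix(EBImage::dilate(reach * 1, kern)) > 0) & bg
      if (all(grown == reach)) break
      reach <- grown
    }
    holes <- bg & !reach
  }
  mask | holes
}

#' 4-connected labelling of a binary mask.
#' @keywords internal
labelComponents <- function(mask) {
  lab <- as.matrix(EBImage::bwlabel((mask > 0) * 1))
  storage.mode(lab) <- "integer"
  lab
}

#' Relabel positive ids to 1..N preserving the original id order.
#' @keywords internal
relabelSequential <- function(lbl) {
  ids <- sort(unique(lbl[lbl > 0]))
  if (length(ids) == 0) {
    out <- matrix(0L, nrow(lbl), ncol(lbl))
    return(out)
  }
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  out <- lbl
  pos <- lbl > 0
  out[pos] <- map[lbl[pos]]
  storage.mode(out) <- "integer"
  out
}

objectAreas <- function(lbl) {
  n <- max(lbl)
  if (n == 0) return(integer(0))
  tabulate(lbl[lbl > 0], nbins = n)
}

#' Per-object centroids in (y, x) pixel coordinates (1-based rows/cols).
#' @keywords internal
objectCentroids <- function(lbl) {
  n <- max(lbl)
  if (n == 0) return(cbind(y = numeric(0), x = numeric(0)))
  pos <- which(lbl > 0)
  ids <- lbl[pos]
  ys <- (pos - 1) %% nrow(lbl) + 1
  xs <- (pos - 1) %/% nrow(lbl) + 1
  cnt <- tabulate(ids, nbins = n)
  cbind(y = as.vector(rowsum(ys, ids)) / cnt,
        x = as.vector(rowsum(xs, ids)) / cnt)
}

## Count lattice points (pixel centres) inside the convex hull of a point
## set.  Used for solidity = object area / convex hull pixel area.
.hullPixelCount <- function(ys, xs) {
  n <- length(ys)
  if (n <= 2) return(n)
  h <- grDevices::chull(xs, ys)
  hx <- xs[h]; hy <- ys[h]
  if (length(h) <= 2) return(length(unique(paste(ys, xs))))
  ## candidate pixels: bounding box
  gy <- seq(min(hy), max(hy))
  gx <- seq(min(hx), max(hx))
  py <- rep(gy, times = length(gx))
  px <- rep(gx, each = length(gy))
  inside <- rep(TRUE, length(py))
  m <- length(h)
  ## chull returns vertices clockwise in (x, y); point is inside iff it is
  ## on the same side of every edge (tolerance for collinear boundaries)
  for (k in seq_len(m)) {
    k2 <- if (k == m) 1L else k + 1L
    cr <- (hx[k2] - hx[k]) * (py - hy[k]) - (hy[k2] - hy[k]) * (px - hx[k])
    inside <- inside & (cr <= 1e-9)
  }
  sum(inside)
}

#' Solidity (area / convex-hull pixel area) per labelled object.
#' @keywords internal
objectSolidity <- function(lbl) {
  n <- max(lbl)
  if (n == 0) return(numeric(0))
  pos <- which(lbl > 0)
  ids <- lbl[pos]
  ys <- (pos - 1) %% nrow(lbl) + 1
  xs <- (pos - 1) %/% nrow(lbl) + 1
  vapply(seq_len(n), function(i) {
    sel <- ids == i
    a <- sum(sel)
    if (a == 0) return(NA_real_)
    a / .hullPixelCount(ys[sel], xs[sel])
  }, numeric(1))
}

#' Percentile of a numeric vector on the 0-100 scale.
#' @keywords internal
percentileValue <- function(x, p) {
  unname(stats::quantile(x, probs = p / 100, na.rm = TRUE, names = FALSE))
}

#' Block-mean image downscale.
#'
#' @param m numeric matrix.
#' @param factor scale in (0, 1]; output is round(dim * factor) with each
#'   output pixel the mean of its source block.
#' @keywords internal
blockMeanScale <- function(m, factor) {
  if (factor == 1) return(m)
  H <- nrow(m); W <- ncol(m)
  outH <- max(1L, round(H * factor))
  outW <- max(1L, round(W * factor))
  ri <- pmin(outH, pmax(1L, ceiling(seq_len(H) * outH / H)))
  ci <- pmin(outW, pmax(1L, ceiling(seq_len(W) * outW / W)))
  sums <- t(rowsum(t(rowsum(m, ri)), ci))
  cnt <- outer(tabulate(ri, outH), tabulate(ci, outW))
  out <- sums / cnt
  dimnames(out) <- NULL
  out
}

#' Bilinear upsample of a coarse grid back to full image size.
#' Grid values are taken to sit at block centres.
#' @keywords internal
bilinearUpsample <- function(g, H, W) {
  gh <- nrow(g); gw <- ncol(g)
  ## block-centre positions of the coarse grid in target coordinates
  cy <- (seq_len(gh) - 0.5) * H / gh
  cx <- (seq_len(gw) - 0.5) * W / gw
  ty <- seq_len(H) - 0.5
  tx <- seq_len(W) - 0.5
  interpIdx <- function(centers, t) {
    i0 <- findInterval(t, centers)
    i0 <- pmin(pmax(i0, 1L), length(centers) - 1L)
    if (length(centers) == 1) return(list(i0 = rep(1L, length(t)), w = rep(0, length(t))))
    w <- (t - centers[i0]) / (centers[i0 + 1L] - centers[i0])
    w <- pmin(pmax(w, 0), 1)
    list(i0 = i0, w = w)
  }
  iy <- interpIdx(cy, ty); ix <- interpIdx(cx, tx)
  if (gh == 1 && gw == 1) return(matrix(g[1, 1], H, W))
  g00 <- g[iy$i0, ix$i0, drop = FALSE]
  g10 <- g[pmin(iy$i0 + 1L, gh), ix$i0, drop = FALSE]
  g01 <- g[iy$i0, pmin(ix$i0 + 1L, gw), drop = FALSE]
  g11 <- g[pmin(iy$i0 + 1L, gh), pmin(ix$i0 + 1L, gw), drop = FALSE]
  wy <- matrix(iy$w, H, W)
  wx <- matrix(ix$w, H, W, byrow = TRUE)
  g00 * (1 - wy) * (1 - wx) + g10 * wy * (1 - wx) +
    g01 * (1 - wy) * wx + g11 * wy * wx
}

## shift a matrix by integer (dy, dx); vacated pixels take `fill`
shiftMatrix <- function(m, dy, dx, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  sy <- max(1, 1 + dy):min(H, H + dy)
  sx <- max(1, 1 + dx):min(W, W + dx)
  if (length(sy) == 0 || length(sx) == 0) return(out)
  out[sy, sx] <- m[sy - dy, sx - dx, drop = FALSE]
  out
}
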