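## Spatial readouts: protein-of-interest (POI) values per cell, binned
## profiles along the tissue (crypt-villus) axis, marker positivity and
## round-to-round concordance.

#' Compute the per-cell protein-of-interest value
#'
#' @param table a \code{CellFeatureTable} or data.frame.
#' @param formula one of "nuc", "cyto", "nuc-cyto", "cyto-nuc".
#' @param nuc_col,cyto_col 1-based column indices into the feature table
#'   (as listed by the header sidecar).
#' @return numeric vector; missing inputs give missing POI values.
#' @export
computePOI <- function(table, formula = "nuc", nuc_col = 4, cyto_col = 5) {
  if (!formula %in% .POIFORMULAS)
    stop(sprintf("unknown POI formula '%s'", formula), call. = FALSE)
  d <- if (is(table, "CellFeatureTable")) tableData(table) else table
  pick <- function(i, what) {
    if (i < 1 || i > ncol(d))
      stop(sprintf("%s column index %d outside 1..%d", what, i, ncol(d)),
           call. = FALSE)
    as.numeric(d[[i]])
  }
  switch(formula,
    "nuc" = pick(nuc_col, "POI_nuc_col"),
    "cyto" = pick(cyto_col, "POI_cyto_col"),
    "nuc-cyto" = pick(nuc_col, "POI_nuc_col") - pick(cyto_col, "POI_cyto_col"),
    "cyto-nuc" = pick(cyto_col, "POI_cyto_col") - pick(nuc_col, "POI_nuc_col"))
}

#' Binned spatial profile of a per-cell value
#'
#' Cell positions are converted to micrometres (\code{y_px * pixelsize})
#' and grouped into contiguous bins \code{[k*w, (k+1)*w)}; per occupied
#' bin the mean and population SD are reported.  Cells with a missing
#' value are excluded.
#'
#' @param y_px per-cell row coordinate in pixels.
#' @param poi per-cell value.
#' @param pixelsize micrometres per pixel.
#' @param bin_width bin width in micrometres (default 20).
#' @return a \code{\linkS4class{SpatialProfile}}.
#' @export
binnedProfile <- function(y_px, poi, pixelsize, bin_width = 20) {
  if (pixelsize <= 0) stop("pixelsize must be positive", call. = FALSE)
  keep <- is.finite(poi)
  y <- y_px[keep] * pixelsize
  v <- poi[keep]
  if (!length(v))
    return(new("SpatialProfile", binCenters = numeric(0), mean = numeric(0),
               sd = numeric(0), n = integer(0), binWidth = bin_width))
  k <- floor(y / bin_width)
  ks <- sort(unique(k))
  mn <- vapply(ks, function(b) mean(v[k == b]), numeric(1))
  sdv <- vapply(ks, function(b) {
    x <- v[k == b]
    sqrt(mean((x - mean(x))^2))          # population SD
  }, numeric(1))
  nn <- vapply(ks, function(b) sum(k == b), integer(1))
  new("SpatialProfile", binCenters = (ks + 0.5) * bin_width, mean = mn,
      sd = sdv, n = nn, binWidth = bin_width)
}

#' Positive and negative concordance rates between consecutive rounds
#'
#' Positive rate = 100 x |positive in round N and in round N+1| /
#' |positive in round N|; the negative rate is the analogue over
#' negatives.  A zero denominator yields \code{NA}.  The measure is not
#' symmetric in the two rounds.
#'
#' @param flags_N,flags_N1 logical vectors over the same cell index set.
#' @return named numeric vector \code{c(positive, negative)} in percent.
#' @export
concordanceRates <- function(flags_N, flags_N1) {
  if (length(flags_N) != length(flags_N1))
    stop("flag vectors must cover the same cells", call. = FALSE)
  f1 <- as.logical(flags_N); f2 <- as.logical(flags_N1)
  pos <- if (sum(f1) == 0) NA_real_ else 100 * sum(f1 & f2) / sum(f1)
  neg <- if (sum(!f1) == 0) NA_real_ else 100 * sum(!f1 & !f2) / sum(!f1)
  c(positive = pos, negative = neg)
}

#' Binary marker call from per-cell values
#'
#' Default rule: positive above the Otsu threshold of the value
#' distribution; alternatively a fixed threshold.
#'
#' @param poi per-cell values.
#' @param threshold optional fixed threshold; \code{NULL} uses Otsu.
#' @export
markerPositive <- function(poi, threshold = NULL) {
  keep <- is.finite(poi)
  if (is.null(threshold)) {
    t <- otsuThreshold(poi[keep])
    threshold <- as.numeric(t)[1]
  }
  out <- rep(NA, length(poi))
  out[keep] <- poi[keep] > threshold
  out
}

#' Write the POI scatter and crypt-villus profile figures
#'
#' Figure 1: cell positions in micrometres colour-coded by POI value.
#' Figure 2: POI against the Y (crypt-villus) position with the binned
#' mean + SD drawn in red per 20 um bin.
#'
#' @param table a \code{CellFeatureTable}.
#' @param settings an \code{IFSettings} (uses pixelsize and POI fields).
#' @param out_dir output directory.
#' @param stem file stem for the two PNGs.
#' @return the profile as a \code{SpatialProfile}, invisibly.
#' @export
plotPOI <- function(table, settings, out_dir, stem = "POI") {
  p <- settings@params
  d <- tableData(table)
  poi <- computePOI(table, p$POI_formula, p$POI_nuc_col, p$POI_cyto_col)
  xum <- d$x * p$pixelsize
  yum <- d$y * p$pixelsize
  prof <- binnedProfile(d$y, poi, p$pixelsize)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  keep <- is.finite(poi)
  pal <- grDevices::hcl.colors(64, "viridis")
  idx <- if (any(keep)) {
    rng <- range(poi[keep])
    if (diff(rng) == 0) rep(1L, sum(keep))
    else pmin(64L, 1L + floor(63 * (poi[keep] - rng[1]) / diff(rng)))
  } else integer(0)
  grDevices::png(file.path(out_dir, paste0(stem, "_scatter.png")),
                 width = 720, height = 720, type = "cairo")
  plot(xum[keep], yum[keep], col = pal[idx], pch = 16, cex = 0.8,
       xlab = "X (µm)", ylab = "Y (µm)", ylim = rev(range(yum[keep], 0)),
       main = "POI intensity per cell")
  grDevices::dev.off()
  grDevices::png(file.path(out_dir, paste0(stem, "_profile.png")),
                 width = 720, height = 480, type = "cairo")
  plot(yum[keep], poi[keep], pch = 16, cex = 0.5, col = "grey50",
       xlab = "Y (µm)", ylab = "POI intensity",
       main = sprintf("POI along the tissue axis (%g µm bins)", prof@binWidth))
  if (length(prof@binCenters)) {
    graphics::lines(prof@binCenters, prof@mean, col = "red", lwd = 2)
    hasSD <- prof@sd > 0
    if (any(hasSD))
      graphics::arrows(prof@binCenters[hasSD], (prof@mean - prof@sd)[hasSD],
                       prof@binCenters[hasSD], (prof@mean + prof@sd)[hasSD],
                       angle = 90, code = 3, length = 0.03, col = "red")
  }
  grDevices::dev.off()
  invisible(prof)
}
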