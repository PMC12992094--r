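## Debug overlay images, written as PNGs.  These replace the interactive
## inspection pauses of a point-and-click workflow: nuclear/cytoring
## contours over the channel, E-cadherin area and per-cell labels,
## round-pair alignment overlays, the nuclear-area histogram and the
## top-hat image used to pick the puncta threshold.

.norm01 <- function(m) {
  mx <- max(m, na.rm = TRUE)
  if (mx <= 0) return(matrix(0, nrow(m), ncol(m)))
  pmin(pmax(m / mx, 0), 1)
}

## magenta rendering of a channel with contours of a label mask
writeContourOverlay <- function(image, mask, path, contourCol = "#00FF00") {
  g <- t(.norm01(image))
  rgb <- EBImage::rgbImage(red = g, green = 0 * g, blue = g)
  lbl <- EBImage::Image(t(labels(mask)))
  out <- EBImage::paintObjects(lbl, rgb, col = contourCol)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  EBImage::writeImage(out, path)
  invisible(path)
}

## channel in magenta with a translucent blue binary area
writeAreaOverlay <- function(image, area, path) {
  g <- t(.norm01(image))
  a <- t(area * 1)
  rgb <- EBImage::rgbImage(red = g, green = 0 * g,
                           blue = pmin(g + 0.5 * a, 1))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  EBImage::writeImage(rgb, path)
  invisible(path)
}

## per-cell labels in rainbow colours over the channel in white
writeLabelOverlay <- function(image, mask, path) {
  g <- t(.norm01(image))
  col <- EBImage::colorLabels(EBImage::Image(t(labels(mask))))
  base <- EBImage::rgbImage(red = g, green = g, blue = g)
  out <- 0.5 * base + 0.5 * col
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  EBImage::writeImage(out, path)
  invisible(path)
}

## round N in magenta vs round N+1 in green; aligned nuclei render white
writePairOverlay <- function(imageN, imageN1, path) {
  a <- t(.norm01(imageN)); b <- t(.norm01(imageN1))
  rgb <- EBImage::rgbImage(red = a, green = b, blue = a)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  EBImage::writeImage(rgb, path)
  invisible(path)
}

writeAreaHistogram <- function(mask, path, debrisarea = NULL,
                               boulderarea = NULL) {
  areas <- objectAreas(labels(mask))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  grDevices::png(path, width = 600, height = 400, type = "cairo")
  if (length(areas)) {
    graphics::hist(areas, breaks = 30, main = "Nuclear area",
                   xlab = "area (px)")
    if (!is.null(debrisarea)) graphics::abline(v = debrisarea, col = "red")
    if (!is.null(boulderarea)) graphics::abline(v = boulderarea, col = "red")
  } else {
    plot.new(); graphics::title("Nuclear area: no objects")
  }
  grDevices::dev.off()
  invisible(path)
}

writeGrayscale <- function(image, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  EBImage::writeImage(EBImage::Image(t(.norm01(image))), path)
  invisible(path)
}
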