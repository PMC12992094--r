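## E-cadherin (membrane marker) processing: edge detection, the
## E-cad-positive area used for epithelial classification, and
## boundary-derived cell segmentation.

.sobel <- function(m) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- as.matrix(EBImage::filter2(m, kx, boundary = "replicate"))
  gy <- as.matrix(EBImage::filter2(m, t(kx), boundary = "replicate"))
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

## Non-maximum suppression along one of four quantized gradient
## directions; keeps ridge-crest pixels of the gradient magnitude.
.nonMaxSuppress <- function(mag, gx, gy) {
  H <- nrow(mag); W <- ncol(mag)
  ang <- atan2(gy, gx)                  # gradient direction
  sector <- (round(ang / (pi / 4)) %% 4)  # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  pad <- padMatrix(mag, 1, value = 0)
  ctr <- pad[2:(H + 1), 2:(W + 1)]
  nb <- function(dy, dx) pad[2:(H + 1) + dy, 2:(W + 1) + dx]
  keep <- matrix(FALSE, H, W)
  ## neighbours along the gradient direction (dy = row, dx = col);
  ## gx varies along columns, gy along rows
  keep[sector == 0] <- (ctr >= nb(0, 1) & ctr >= nb(0, -1))[sector == 0]
  keep[sector == 1] <- (ctr >= nb(1, 1) & ctr >= nb(-1, -1))[sector == 1]
  keep[sector == 2] <- (ctr >= nb(1, 0) & ctr >= nb(-1, 0))[sector == 2]
  keep[sector == 3] <- (ctr >= nb(1, -1) & ctr >= nb(-1, 1))[sector == 3]
  keep & mag > 0
}

## grow `strong` through `weak` with 8-connectivity until stable
.hysteresis <- function(strong, weak) {
  kern <- matrix(1, 3, 3)
  cur <- strong & weak
  repeat {
    grown <- (as.matrix(EBImage::dilate(cur * 1, kern)) > 0) & weak
    if (all(grown == cur)) break
    cur <- grown
  }
  cur
}

#' Detect E-cadherin edges
#'
#' \code{method = "Canny"} (default): gradient magnitude of the smoothed
#' image, non-maximum suppression, then hysteresis with a strong
#' threshold set by Otsu on the nonzero gradient magnitudes and a weak
#' threshold at 0.4 x strong.  \code{method = "log"}: zero-crossings of
#' the Laplacian-of-Gaussian response with amplitude above a noise floor.
#'
#' @param ecad_image single-channel numeric matrix.
#' @param method "Canny" or "log".
#' @param Gaus_filter_sigma Gaussian smoothing SD applied first.
#' @param canny_low_frac weak threshold as a fraction of the strong one.
#' @return logical edge mask.
#' @export
detectEcadEdges <- function(ecad_image, method = "Canny",
                            Gaus_filter_sigma = 2, canny_low_frac = 0.4) {
  if (!method %in% .EDGEMETHODS)
    stop(sprintf("unknown edge detection method '%s'", method), call. = FALSE)
  sm <- gaussianSmooth(ecad_image, Gaus_filter_sigma)
  ## FFT-based smoothing leaves ~1e-13 ripple on flat images; anything
  ## below this relative floor is not signal
  flat <- function(x) max(x) <= 1e-8 * max(abs(sm), 1)
  if (method == "Canny") {
    g <- .sobel(sm)
    if (flat(g$mag)) return(matrix(FALSE, nrow(sm), ncol(sm)))
    crest <- .nonMaxSuppress(g$mag, g$gx, g$gy)
    hi <- otsuThreshold(g$mag[g$mag > 0])
    lo <- canny_low_frac * hi
    strong <- crest & g$mag >= hi
    weak <- crest & g$mag >= lo
    return(.hysteresis(strong, weak))
  }
  ## LoG zero crossings
  resp <- .logResponse(sm, max(1, Gaus_filter_sigma))
  if (flat(abs(resp))) return(matrix(FALSE, nrow(sm), ncol(sm)))
  H <- nrow(resp); W <- ncol(resp)
  floorAmp <- 0.75 * mean(abs(resp))
  zc <- matrix(FALSE, H, W)
  right <- resp[, -1] * resp[, -W] < 0 & abs(resp[, -1] - resp[, -W]) > floorAmp
  down <- resp[-1, ] * resp[-H, ] < 0 & abs(resp[-1, ] - resp[-H, ]) > floorAmp
  zc[, -W] <- zc[, -W] | right
  zc[, -1] <- zc[, -1] | right
  zc[-H, ] <- zc[-H, ] | down
  zc[-1, ] <- zc[-1, ] | down
  zc
}

#' Build the E-cadherin-positive cell area from an edge mask
#'
#' Edges are morphologically closed with a disc of radius
#' \code{R_strel_edge} (bridging staining gaps), holes are filled with
#' the configured pixel connectivity, and the result is closed again
#' with a disc of radius \code{R_strel_extended} so the area covers
#' whole cells.  The output area is monotone in both radii.
#'
#' @param edges logical edge mask.
#' @param R_strel_edge gap-closing disc radius (px).
#' @param Pixel_connectivity 4 or 8, hole-filling connectivity.
#' @param R_strel_extended cell-covering disc radius (px).
#' @return logical area mask.
#' @export
buildEcadPositiveArea <- function(edges, R_strel_edge = 2,
                                  Pixel_connectivity = 4,
                                  R_strel_extended = 4) {
  if (R_strel_edge < 0 || R_strel_extended < 0)
    stop("structuring radii must be nonnegative", call. = FALSE)
  closed <- binaryClosing(edges, R_strel_edge)
  filled <- fillHoles(closed, Pixel_connectivity)
  binaryClosing(filled, R_strel_extended)
}

#' Segment cells from E-cadherin edges alone
#'
#' Interior regions bounded by the closed edge mask (holes of the edge
#' image) become cell labels; regions smaller than \code{Max_pixels} are
#' removed and labels made contiguous.
#'
#' @param edges logical edge mask from \code{\link{detectEcadEdges}}.
#' @param R_strel_edge gap-closing disc radius (px).
#' @param Pixel_connectivity hole connectivity (4 or 8).
#' @param Max_pixels minimum pixel count of a valid cell region.
#' @return a \code{\linkS4class{LabelMask}} of cells.
#' @export
segmentCellsEcadOnly <- function(edges, R_strel_edge = 2,
                                 Pixel_connectivity = 4, Max_pixels = 50) {
  closed <- binaryClosing(edges, R_strel_edge)
  interiors <- fillHoles(closed, Pixel_connectivity) & !closed
  lbl <- labelComponents(interiors)
  if (max(lbl) == 0) return(new("LabelMask", labels = lbl))
  areas <- objectAreas(lbl)
  small <- which(areas < Max_pixels)
  lbl[lbl %in% small] <- 0L
  new("LabelMask", labels = relabelSequential(lbl))
}

#' Classify cells as E-cadherin positive or negative
#'
#' A cell is positive iff the fraction of its nuclear pixels lying inside
#' the E-cadherin-positive area reaches \code{overlap} (default 0.5; the
#' boundary case of exactly 50\% overlap is positive).
#'
#' @param nuclear_mask a \code{LabelMask}.
#' @param area logical E-cadherin-positive area mask.
#' @param overlap minimum overlap fraction.
#' @return logical vector, one flag per label id.
#' @export
classifyEcadStatus <- function(nuclear_mask, area, overlap = 0.5) {
  lbl <- labels(nuclear_mask)
  if (!all(dim(lbl) == dim(area)))
    stop("mask and area shapes disagree", call. = FALSE)
  n <- max(lbl)
  if (n == 0) return(logical(0))
  tot <- objectAreas(lbl)
  inside <- tabulate(lbl[lbl > 0 & area], nbins = n)
  frac <- ifelse(tot > 0, inside / tot, 0)
  frac >= overlap
}
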