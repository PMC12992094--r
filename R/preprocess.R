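## Per-channel preprocessing.  Fixed pipeline order, logged by runSite():
## camera (CMOS) correction -> software binning -> smoothing ->
## background subtraction -> bleed-through correction -> measurement.
## All arithmetic in floating point; negative residuals are preserved
## (no clipping) so downstream means stay unbiased.

#' Software binning by block mean
#'
#' @param image single-channel numeric matrix.
#' @param factor 0 for no binning (identity); otherwise a scale in
#'   (0, 1], e.g. 0.5 for 2x2 binning.  Output dimensions are
#'   \code{round(dim * factor)}; each output pixel is the mean of its
#'   source block.
#' @export
applyPostbin <- function(image, factor) {
  if (factor == 0) return(image)
  if (factor < 0 || factor > 1)
    stop("postbin factor must be 0 (off) or in (0, 1]", call. = FALSE)
  blockMeanScale(image, factor)
}

#' Subtract image background by one of five methods
#'
#' \describe{
#'   \item{none}{identity.}
#'   \item{global nuclear}{subtracts the \code{bgperctile}-th percentile
#'     of pixels outside the nuclear mask, computed on the
#'     \code{compression}-downscaled image.  With
#'     \code{foreground_flag = 1} the excluded mask is augmented with an
#'     Otsu foreground mask of the image itself.}
#'   \item{global cyto}{as above with the cytoplasmic mask (nuclei
#'     thickened) as the excluded foreground.}
#'   \item{tophat}{subtracts a morphological-opening background (disc of
#'     radius \code{2 * nucr}, large enough to treat nuclei as
#'     foreground).}
#'   \item{semi-local nuclear}{an 11x11 grid of blocks over the
#'     downscaled masked image; the per-block \code{bgperctile}
#'     percentile of non-foreground pixels is bilinearly upsampled and
#'     subtracted.}
#' }
#'
#' @param image single-channel numeric matrix.
#' @param method one of "global nuclear", "global cyto", "tophat",
#'   "semi-local nuclear", "none".
#' @param nuclear_mask \code{LabelMask} or binary matrix aligned to
#'   \code{image} (required by the mask-based methods).
#' @param foreground_flag 1 to augment the excluded mask with bright
#'   foreground (Otsu) pixels.
#' @param bgperctile percentile (0-100) of the background pixels.
#' @param compression downscale factor for the global/semi-local modes.
#' @param nucr average nuclear radius, sets the top-hat disc.
#' @param cyto_mask optional binary cytoplasm mask for "global cyto";
#'   defaults to the nuclei dilated by \code{2 * nucr}.
#' @return background-subtracted image (not clipped at zero).
#' @export
subtractBackground <- function(image, method, nuclear_mask = NULL,
                               foreground_flag = 0, bgperctile = 25,
                               compression = 4, nucr = 8, cyto_mask = NULL) {
  if (!method %in% .BGSUBMETHODS)
    stop(sprintf("unknown background subtraction method '%s'", method),
         call. = FALSE)
  if (method == "none") return(image)
  if (method == "tophat") return(whiteTopHatDisc(image, 2 * nucr))

  maskBin <- NULL
  if (!is.null(nuclear_mask)) {
    m <- if (is(nuclear_mask, "LabelMask")) labels(nuclear_mask) else nuclear_mask
    if (!all(dim(m) == dim(image)))
      stop("mask and image shapes disagree", call. = FALSE)
    maskBin <- m > 0
  }
  fg <- switch(method,
    "global nuclear" = maskBin,
    "global cyto" = if (!is.null(cyto_mask)) cyto_mask > 0
                    else if (!is.null(maskBin)) binaryDilate(maskBin, 2 * nucr)
                    else NULL,
    "semi-local nuclear" = maskBin)
  if (is.null(fg)) fg <- matrix(FALSE, nrow(image), ncol(image))
  if (foreground_flag > 0) {
    t <- otsuThreshold(image)
    if (is.null(attr(t, "degenerate"))) fg <- fg | (image > t)
  }
  f <- 1 / max(1, compression)
  small <- blockMeanScale(image, f)
  fgSmall <- blockMeanScale(fg * 1, f) > 0   # block contains any foreground

  if (method %in% c("global nuclear", "global cyto")) {
    bgpix <- small[!fgSmall]
    if (!length(bgpix)) bgpix <- as.numeric(small)
    return(image - percentileValue(bgpix, bgperctile))
  }
  ## semi-local nuclear: 11x11 block grid over the downscaled image
  gh <- min(11L, nrow(small)); gw <- min(11L, ncol(small))
  ri <- pmin(gh, pmax(1L, ceiling(seq_len(nrow(small)) * gh / nrow(small))))
  ci <- pmin(gw, pmax(1L, ceiling(seq_len(ncol(small)) * gw / ncol(small))))
  glob <- percentileValue(if (any(!fgSmall)) small[!fgSmall] else as.numeric(small),
                          bgperctile)
  grid <- matrix(glob, gh, gw)
  for (i in seq_len(gh)) for (j in seq_len(gw)) {
    sel <- small[ri == i, ci == j, drop = FALSE]
    keep <- !fgSmall[ri == i, ci == j, drop = FALSE]
    px <- sel[keep]
    if (length(px)) grid[i, j] <- percentileValue(px, bgperctile)
  }
  image - bilinearUpsample(grid, nrow(image), ncol(image))
}

#' Correct linear bleed-through of one channel into another
#'
#' @param target image receiving the contamination.
#' @param source contaminating channel image.
#' @param slope,offset mixing coefficients: the corrected image is
#'   \code{target - slope * source - offset}, elementwise.
#' @export
correctBleedthrough <- function(target, source, slope, offset = 0) {
  if (!all(dim(target) == dim(source)))
    stop("target and source images must have the same shape", call. = FALSE)
  if (slope < 0) stop("bleed-through slope must be nonnegative", call. = FALSE)
  target - slope * source - offset
}

## Background subtraction then bleed-through for all channels of a round.
applyBackgroundAndBleed <- function(round, settings, nuclear_mask,
                                    cyto_mask = NULL) {
  p <- settings@params
  r <- round@roundIndex
  px <- pixelData(round)
  C <- dim(px)[3]
  bg <- px
  for (k in seq_len(C)) {
    bg[, , k] <- subtractBackground(px[, , k],
      method = p$bgsubmethod[[r]][k], nuclear_mask = nuclear_mask,
      foreground_flag = p$signal_foreground[[r]][k],
      bgperctile = p$bgperctile[[r]][k], compression = p$compression,
      nucr = p$nucr, cyto_mask = cyto_mask)
  }
  out <- bg
  slope <- p$bleedthroughslope[[r]]
  off <- p$bleedthroughoff[[r]]
  for (k in seq_len(C)) {
    if (p$bleedthrough[[r]][k] == 0) next
    for (s in seq_len(C)) {
      if (s == k) next
      if (slope[s, k] != 0 || off[s, k] != 0)
        out[, , k] <- correctBleedthrough(out[, , k], bg[, , s],
                                          slope[s, k], off[s, k])
    }
  }
  new("RoundImage", pixels = out, channelNames = round@channelNames,
      roundIndex = round@roundIndex, siteIndex = round@siteIndex)
}
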