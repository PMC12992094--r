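## Multi-round registration: integer-pixel jitter between 4i rounds.
##
## The estimator is cross-correlation of mean-subtracted images computed
## with the FFT over the full (circularly wrapped) shift surface.  The
## global correlation peak is located; if it falls outside the +/- maxjit
## window the configured bound has been exceeded and the pipeline stops
## with "Max jitter too high".  Registration is integer-pixel by design:
## the jitter between rounds is a rigid translation of whole pixels.

#' Estimate the integer shift between two images
#'
#' Finds the (dy, dx) maximizing the correlation between \code{reference}
#' and \code{moving}, so that \code{moving[i + dy, j + dx]} matches
#' \code{reference[i, j]}.  Ties are broken toward the smaller
#' \code{|dy| + |dx|}, then lexicographically.
#'
#' @param reference,moving numeric matrices of identical shape.
#' @param maxjit maximum allowed shift magnitude per axis, in pixels;
#'   must be below half the image size.
#' @param blur_radius optional circular-averaging radius applied to both
#'   images before matching.
#' @return integer vector \code{c(dy, dx)}.
#' @section Errors: if the global correlation peak lies outside the
#'   window, the error message is "Max jitter too high".
#' @export
estimateJitter <- function(reference, moving, maxjit, blur_radius = 0) {
  if (!all(dim(reference) == dim(moving)))
    stop("reference and moving images must have the same shape", call. = FALSE)
  H <- nrow(reference); W <- ncol(reference)
  if (maxjit >= min(H, W) / 2)
    stop("maxjit must be below half the image size", call. = FALSE)
  a <- discAverage(reference, blur_radius)
  b <- discAverage(moving, blur_radius)
  a <- a - mean(a); b <- b - mean(b)
  cc <- Re(stats::fft(stats::fft(b) * Conj(stats::fft(a)), inverse = TRUE))
  peak <- max(cc)
  cand <- which(cc >= peak - 1e-9 * abs(peak))
  dy <- (cand - 1) %% H
  dx <- (cand - 1) %/% H
  dy <- ifelse(dy > H / 2, dy - H, dy)
  dx <- ifelse(dx > W / 2, dx - W, dx)
  ord <- order(abs(dy) + abs(dx), dy, dx)
  dy <- dy[ord[1]]; dx <- dx[ord[1]]
  if (abs(dy) > maxjit || abs(dx) > maxjit)
    stop("Max jitter too high", call. = FALSE)
  c(dy = as.integer(dy), dx = as.integer(dx))
}

#' Estimate jitter of every round against the reference round
#'
#' Uses each round's configured jitter channel, blurred with that
#' channel's \code{sigblur} radius; the reference round gets (0, 0).
#'
#' @param rounds list of \code{RoundImage}, one per round.
#' @param settings an \code{IFSettings}.
#' @return nRounds x 2 integer matrix of (dy, dx) offsets.
#' @export
estimateJitterAll <- function(rounds, settings) {
  p <- settings@params
  nR <- settings@nRounds
  ref <- rounds[[p$primaryMaskRound]]
  refCh <- getChannel(ref, p$jitterIndex[p$primaryMaskRound])
  off <- matrix(0L, nR, 2, dimnames = list(NULL, c("dy", "dx")))
  for (r in seq_len(nR)) {
    if (r == p$primaryMaskRound) next
    mov <- getChannel(rounds[[r]], p$jitterIndex[r])
    blur <- p$sigblur[[r]][p$jitterIndex[r]]
    off[r, ] <- estimateJitter(refCh, mov, p$maxjit, blur_radius = blur)
  }
  off
}

#' Align all rounds to the common field and crop
#'
#' The crop window is the intersection of all shifted fields in reference
#' coordinates; pixel (i, j) of every cropped round maps to the same
#' physical location.
#'
#' @param rounds list of \code{RoundImage}.
#' @param offsets nRounds x 2 matrix of (dy, dx) offsets as returned by
#'   \code{\link{estimateJitterAll}} (reference round = (0, 0)).
#' @param crop_save optional directory; when given, cropped stacks are
#'   written as \code{<crop_save>/<round folder>/<base>_<site>.tif}.
#' @param settings settings used for output naming (required with
#'   \code{crop_save}).
#' @return list with \code{rounds} (cropped \code{RoundImage} list) and
#'   \code{window} (rows/cols of the crop in reference coordinates).
#' @export
alignAndCrop <- function(rounds, offsets, crop_save = NULL, settings = NULL) {
  nR <- length(rounds)
  if (nrow(offsets) != nR)
    stop("offsets must cover every round", call. = FALSE)
  d <- dim(pixelData(rounds[[1]]))
  H <- d[1]; W <- d[2]
  rlo <- 1 - min(offsets[, 1], 0); rhi <- H - max(offsets[, 1], 0)
  clo <- 1 - min(offsets[, 2], 0); chi <- W - max(offsets[, 2], 0)
  if (rlo > rhi || clo > chi)
    stop("empty crop intersection: offsets too large for the image", call. = FALSE)
  rows <- rlo:rhi; cols <- clo:chi
  out <- vector("list", nR)
  for (r in seq_len(nR)) {
    px <- pixelData(rounds[[r]])
    cr <- px[rows + offsets[r, 1], cols + offsets[r, 2], , drop = FALSE]
    out[[r]] <- new("RoundImage", pixels = cr,
                    channelNames = rounds[[r]]@channelNames,
                    roundIndex = rounds[[r]]@roundIndex,
                    siteIndex = rounds[[r]]@siteIndex)
    if (!is.null(crop_save)) {
      stopifnot(!is.null(settings))
      folder <- file.path(crop_save,
                          basename(settings@params$IF_imagesessions[r]))
      writeRoundStack(cr, roundStackPath(folder, settings@params$file_name,
                                         rounds[[r]]@siteIndex))
    }
  }
  list(rounds = out, window = list(rows = range(rows), cols = range(cols)))
}
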