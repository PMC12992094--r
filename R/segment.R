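## Nuclear segmentation.  All methods share: blur (where applicable),
## method-specific detection, hole filling, labelling.  The returned mask
## holds candidate nuclei BEFORE area/solidity filtering
## (see filterObjects).

.segDefaults <- function(params) {
  d <- list(blurradius = 3, nucr = 8, blobthreshold = -0.02, split_mult = 1,
            Gaus_filter_sigma = 2, Edge_method = "Canny", R_strel_edge = 2,
            R_strel_extended = 4, Pixel_connectivity = 4, Max_pixels = 50)
  d[names(params)] <- params
  d
}

## Scale-normalised Laplacian-of-Gaussian response; bright blobs give
## negative responses at their centres.
.logResponse <- function(m, sigma) {
  s <- max(1, sigma)
  r <- ceiling(3 * s)
  g <- seq(-r, r)
  k <- outer(g, g, function(y, x) {
    (x^2 + y^2 - 2 * s^2) / (2 * pi * s^6) * exp(-(x^2 + y^2) / (2 * s^2))
  })
  k <- k - mean(k)
  s^2 * as.matrix(EBImage::filter2(m, k, boundary = "replicate"))
}

.watershedSplit <- function(mask) {
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  dm <- EBImage::distmap(mask * 1)
  lbl <- as.matrix(EBImage::watershed(dm, tolerance = 1))
  storage.mode(lbl) <- "integer"
  lbl
}

#' Segment nuclei by the configured method
#'
#' Implements the full method family: Otsu-threshold variants with and
#' without watershed splitting ('thresh', 'single', 'double',
#' 'double marker', 'multithresh'), histogram-concavity thresholding
#' ('concavity'), blob detection on log-scaled intensities ('log'),
#' LoG-seeded region growing ('log contour'), and the two
#' E-cadherin-assisted methods ('Nuc-Ecad boundary' separates
#' concatenated nuclei along membrane ridges; 'Ecad boundary' delegates
#' to cell segmentation from E-cadherin edges alone, so the returned
#' objects are cells, not nuclei).
#'
#' Holes are filled before labelling.  Objects touching the image border
#' are kept.  The result is unfiltered; apply \code{\link{filterObjects}}
#' for the area/solidity gate.
#'
#' @param nuclear_image single-channel numeric matrix.
#' @param ecad_image E-cadherin channel, required for the two E-cad
#'   methods.
#' @param method segmentation method name.
#' @param params named list overriding defaults: \code{blurradius} (3),
#'   \code{nucr}, \code{blobthreshold} (more negative = stricter),
#'   \code{split_mult}, and the E-cadherin edge parameters.
#' @return a \code{\linkS4class{LabelMask}} of candidate objects.
#' @export
segmentNuclei <- function(nuclear_image, ecad_image = NULL, method = "thresh",
                          params = list()) {
  if (!method %in% .SEGMETHODS)
    stop(sprintf("unknown segmentation method '%s'", method), call. = FALSE)
  p <- .segDefaults(params)
  needsEcad <- method %in% c("Nuc-Ecad boundary", "Ecad boundary")
  if (needsEcad && is.null(ecad_image))
    stop(sprintf("segmentation method '%s' requires an E-cadherin image", method),
         call. = FALSE)

  if (method == "Ecad boundary") {
    edges <- detectEcadEdges(ecad_image, method = p$Edge_method,
                             Gaus_filter_sigma = p$Gaus_filter_sigma)
    return(segmentCellsEcadOnly(edges, R_strel_edge = p$R_strel_edge,
                                Pixel_connectivity = p$Pixel_connectivity,
                                Max_pixels = p$Max_pixels))
  }

  blurred <- discAverage(nuclear_image, p$blurradius)
  lbl <- switch(method,
    "thresh" = , "Nuc-Ecad boundary" = {
      t <- otsuThreshold(blurred)
      labelComponents(fillHoles(blurred > t))
    },
    "single" = {
      t <- otsuThreshold(blurred)
      .watershedSplit(fillHoles(blurred > t))
    },
    "double" = {
      t1 <- otsuThreshold(blurred)
      m1 <- blurred > t1
      t2 <- if (any(m1)) otsuThreshold(blurred[m1]) else t1
      .watershedSplit(fillHoles(m1 | (blurred > t2)))
    },
    "double marker" = {
      t1 <- otsuThreshold(blurred)
      m1 <- fillHoles(blurred > t1)
      t2 <- if (any(m1)) otsuThreshold(blurred[m1]) else t1
      seeds <- labelComponents(blurred > t2)
      grown <- as.matrix(EBImage::propagate(blurred, seeds, mask = m1))
      storage.mode(grown) <- "integer"
      ## components of m1 without any bright core become fresh labels
      rest <- labelComponents(m1 & grown == 0)
      rest[rest > 0] <- rest[rest > 0] + max(grown)
      grown + rest
    },
    "multithresh" = {
      t <- otsuThreshold(blurred, levels = 2)
      .watershedSplit(fillHoles(blurred > t[1]))
    },
    "concavity" = {
      t <- concavityThreshold(blurred)
      labelComponents(fillHoles(blurred > t))
    },
    "log" = {
      L <- log1p(nuclear_image)
      mx <- max(L)
      if (mx > 0) L <- L / mx
      resp <- .logResponse(L, p$nucr / sqrt(2))
      labelComponents(fillHoles(resp <= p$blobthreshold))
    },
    "log contour" = {
      L <- log1p(nuclear_image)
      mx <- max(L)
      if (mx > 0) L <- L / mx
      resp <- .logResponse(L, p$nucr / sqrt(2))
      seeds <- labelComponents(resp <= p$blobthreshold)
      t <- otsuThreshold(blurred)
      region <- fillHoles(blurred > if (is.null(attr(t, "degenerate"))) t / 2 else t)
      if (max(seeds) == 0) seeds else {
        grown <- as.matrix(EBImage::propagate(blurred, seeds,
                                              mask = region | seeds > 0))
        storage.mode(grown) <- "integer"
        grown
      }
    },
    stop(sprintf("unknown segmentation method '%s'", method), call. = FALSE))

  mask <- new("LabelMask", labels = relabelSequential(lbl))
  if (method == "Nuc-Ecad boundary")
    mask <- splitByEcadBoundary(mask, ecad_image, split_mult = p$split_mult)
  mask
}

#' Separate concatenated nuclei along E-cadherin ridges
#'
#' An object is cut where the E-cadherin signal inside it exceeds
#' \code{split_mult} times the object's mean E-cadherin level (the
#' object-local baseline).  Cut pieces are relabelled with fresh ids;
#' ridge pixels are reassigned to the nearest piece.  With no qualifying
#' ridge the mask is returned unchanged; raising \code{split_mult}
#' removes ridge pixels monotonically, so the number of output labels
#' never increases with it.
#'
#' @param mask a \code{LabelMask} of candidate nuclei.
#' @param ecad_image E-cadherin channel aligned to the mask.
#' @param split_mult ridge-over-baseline threshold multiplier.
#' @export
splitByEcadBoundary <- function(mask, ecad_image, split_mult = 1) {
  lbl <- labels(mask)
  if (!all(dim(lbl) == dim(ecad_image)))
    stop("mask and E-cadherin image shapes disagree", call. = FALSE)
  n <- max(lbl)
  if (n == 0) return(mask)
  out <- lbl
  nextId <- n
  for (i in seq_len(n)) {
    pix <- lbl == i
    vals <- ecad_image[pix]
    base <- mean(vals)
    if (base <= 0) next
    ridge <- pix & (ecad_image > split_mult * base)
    if (!any(ridge)) next
    keep <- pix & !ridge
    comp <- labelComponents(keep)
    k <- max(comp)
    if (k < 2) next
    ## reassign ridge pixels to the nearest piece (Euclidean, low id wins)
    dmin <- NULL; amin <- NULL
    for (j in seq_len(k)) {
      dj <- as.matrix(EBImage::distmap(1 - (comp == j)))
      if (is.null(dmin)) { dmin <- dj; amin <- matrix(j, nrow(dj), ncol(dj)) }
      else { upd <- dj < dmin; dmin[upd] <- dj[upd]; amin[upd] <- j }
    }
    pieces <- comp
    pieces[ridge] <- amin[ridge]
    out[pix] <- nextId + pieces[pix]
    nextId <- nextId + k
  }
  new("LabelMask", labels = relabelSequential(out))
}

#' Filter labelled objects by area and solidity
#'
#' Removes objects with area below \code{debrisarea}, above
#' \code{boulderarea}, or solidity (area / convex-hull pixel area) below
#' \code{soliditythresh}; survivors are relabelled 1..N preserving their
#' original order.  Idempotent.
#'
#' @param mask a \code{LabelMask}.
#' @param debrisarea,boulderarea area bounds in pixels.
#' @param soliditythresh minimum solidity in [0, 1].
#' @export
filterObjects <- function(mask, debrisarea, boulderarea, soliditythresh = 0) {
  lbl <- labels(mask)
  n <- max(lbl)
  if (n == 0) return(mask)
  areas <- objectAreas(lbl)
  keep <- areas >= debrisarea & areas <= boulderarea
  if (soliditythresh > 0) {
    sol <- objectSolidity(lbl)
    keep <- keep & !is.na(sol) & sol >= soliditythresh
  }
  drop <- which(!keep)
  out <- lbl
  out[out %in% drop] <- 0L
  new("LabelMask", labels = relabelSequential(out))
}
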