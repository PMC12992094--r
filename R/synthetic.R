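## Deterministic synthetic-scene generator.
##
## Emulates the image structure of a multi-round 4i experiment on
## epithelium: a lattice of cells outlined by a membrane (E-cadherin)
## marker, nuclei rendered as radial-falloff disks (soft edges, so
## threshold/watershed methods behave as on real data rather than
## trivially), optional puncta, linear channel bleed-through, additive
## background (constant + ramp + fixed camera pattern), per-round integer
## jitter, Gaussian noise, and 16-bit quantization.  Rendering order:
## cells -> nuclei -> puncta -> bleed-through mixing -> background ->
## jitter shift -> noise -> quantization.

#' Default parameters for a synthetic scene
#'
#' @param ... overrides for any of the defaults.
#' @return named list of scene parameters.
#' @export
sceneParams <- function(...) {
  p <- list(
    width = 300, height = 300,
    nRounds = 2,
    ecadChannel = TRUE,          # add an "Ecad" membrane channel
    signalChannel = TRUE,        # add a "POI" signal channel
    nucleiLayout = "random",     # "random" or "cells" (one per lattice cell)
    nNuclei = 30,
    nucleusRadius = 8,
    nucleusIntensity = 3000,
    minSeparation = 24,          # centre-to-centre, px
    concatenatedPairs = 0,       # touching pairs bisected by a membrane line
    cellPitch = 40,              # lattice cell size, px
    ecadIntensity = 2000,
    ecadLineWidth = 2,
    ecadGaps = 0,                # number of gaps knocked into the lattice
    ecadGapWidth = 4,
    poiBase = 1500,              # nuclear POI amplitude at y = 0
    poiGradientPerPx = 0,        # amplitude change per pixel along y
    punctaPerCell = 0,           # scalar or one count per cell
    punctaAmplitude = 2000,
    punctaSigma = 1,
    punctaMinSep = 6,            # centre-to-centre spot separation, px
    punctaCompartment = "nuclear",  # or "cyto"
    thickenradius = 24,
    bleedSlope = 0,              # mixing of DNA channel into POI channel
    bleedOffset = 0,
    backgroundOffset = 100,
    rampPerPx = 0,               # background ramp along y, all channels
    cameraAmplitude = 0,         # fixed sinusoidal camera pattern
    noiseSD = 0,
    jitter = NULL                # nRounds x 2 (dy, dx); NULL = zeros
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop(sprintf("unknown scene parameter(s): %s",
                                paste(bad, collapse = ", ")), call. = FALSE)
  p[names(ov)] <- ov
  p
}

## soft-edged blob: A / (1 + (d/r)^8); near-top-hat with a gentle rim.
## Composed with pmax, as abutting stained nuclei plateau rather than add.
.addBlob <- function(img, cy, cx, r, A, exponent = 10) {
  H <- nrow(img); W <- ncol(img)
  ext <- ceiling(2 * r)
  rows <- max(1, floor(cy - ext)):min(H, ceiling(cy + ext))
  cols <- max(1, floor(cx - ext)):min(W, ceiling(cx + ext))
  d <- sqrt(outer((rows - cy)^2, (cols - cx)^2, "+"))
  img[rows, cols] <- pmax(img[rows, cols], A / (1 + (d / r)^exponent))
  img
}

.addGaussSpot <- function(img, cy, cx, A, sigma) {
  H <- nrow(img); W <- ncol(img)
  ext <- ceiling(3 * sigma)
  rows <- max(1, floor(cy - ext)):min(H, ceiling(cy + ext))
  cols <- max(1, floor(cx - ext)):min(W, ceiling(cx + ext))
  d2 <- outer((rows - cy)^2, (cols - cx)^2, "+")
  img[rows, cols] <- img[rows, cols] + A * exp(-d2 / (2 * sigma^2))
  img
}

## rasterize a segment of given width onto img (set to `value` by max)
.drawSegment <- function(img, y0, x0, y1, x1, width, value) {
  len <- sqrt((y1 - y0)^2 + (x1 - x0)^2)
  n <- max(2, ceiling(len * 4))
  t <- seq(0, 1, length.out = n)
  ys <- y0 + t * (y1 - y0); xs <- x0 + t * (x1 - x0)
  hw <- width / 2
  H <- nrow(img); W <- ncol(img)
  for (k in seq_len(n)) {
    rows <- seq_len(H)[abs(seq_len(H) - ys[k]) <= hw - 0.5 + 1e-9]
    cols <- seq_len(W)[abs(seq_len(W) - xs[k]) <= hw - 0.5 + 1e-9]
    if (length(rows) && length(cols))
      img[rows, cols] <- pmax(img[rows, cols], value)
  }
  img
}

.placeNuclei <- function(p) {
  H <- p$height; W <- p$width; r <- p$nucleusRadius
  nuclei <- data.frame(cy = numeric(0), cx = numeric(0), radius = numeric(0),
                       intensity = numeric(0), cell = integer(0),
                       concatenated = logical(0))
  if (p$nucleiLayout == "cells") {
    s <- p$cellPitch
    gy <- seq(s, H - s, by = s); gx <- seq(s, W - s, by = s)
    cy <- rep(gy - s / 2, times = length(gx)) + stats::runif(length(gy) * length(gx), -s * 0.1, s * 0.1)
    cx <- rep(gx - s / 2, each = length(gy)) + stats::runif(length(gy) * length(gx), -s * 0.1, s * 0.1)
    nuclei <- data.frame(cy = cy, cx = cx, radius = r,
                         intensity = p$nucleusIntensity,
                         cell = seq_along(cy), concatenated = FALSE)
  } else {
    margin <- r + 4
    tries <- 0
    while (nrow(nuclei) < p$nNuclei) {
      tries <- tries + 1
      if (tries > 400 * p$nNuclei)
        stop("geometric infeasibility: too many nuclei for the field size",
             call. = FALSE)
      cy <- stats::runif(1, margin, H - margin)
      cx <- stats::runif(1, margin, W - margin)
      if (nrow(nuclei) == 0 ||
          all(sqrt((nuclei$cy - cy)^2 + (nuclei$cx - cx)^2) >= p$minSeparation)) {
        nuclei <- rbind(nuclei, data.frame(cy = cy, cx = cx, radius = r,
                                           intensity = p$nucleusIntensity,
                                           cell = nrow(nuclei) + 1L,
                                           concatenated = FALSE))
      }
    }
  }
  if (p$concatenatedPairs > 0) {
    margin <- 3 * r
    for (k in seq_len(p$concatenatedPairs)) {
      repeat {
        cy <- stats::runif(1, margin, H - margin)
        cx <- stats::runif(1, margin, W - margin - 1.5 * r)
        d <- sqrt((nuclei$cy - cy)^2 + (nuclei$cx - cx)^2)
        if (!nrow(nuclei) || all(d >= p$minSeparation + 1.5 * r)) break
      }
      nuclei <- rbind(nuclei,
        data.frame(cy = c(cy, cy), cx = c(cx, cx + 1.5 * r), radius = r,
                   intensity = p$nucleusIntensity,
                   cell = max(nuclei$cell, 0L) + c(1L, 2L),
                   concatenated = TRUE))
    }
  }
  nuclei
}

#' Generate a deterministic synthetic multi-round scene
#'
#' @param params scene parameters from \code{\link{sceneParams}}.
#' @param seed integer seed; the same seed reproduces the scene exactly
#'   (byte-identical files on disk).
#' @param out_dir optional directory; when given, per-round folders
#'   \code{Round<r>} with \code{<file_name>_<site>.tif} stacks and a
#'   \code{scene_<site>.json} ground-truth file are written.
#' @param site site number used in file names.
#' @param file_name base image name.
#' @return list with \code{scene} (a \code{SyntheticScene}),
#'   \code{rounds} (quantized \code{RoundImage} list, identical to the
#'   files on disk), \code{clean} (per-round float arrays before noise
#'   and quantization) and \code{premix} (per-channel foreground truth
#'   before bleed-through, background and jitter).
#' @export
generateScene <- function(params = sceneParams(), seed = 1, out_dir = NULL,
                          site = 1, file_name = "synthetic") {
  p <- params
  set.seed(seed)
  H <- p$height; W <- p$width
  chNames <- c("DNA", if (p$ecadChannel) "Ecad", if (p$signalChannel) "POI")
  C <- length(chNames)

  nuclei <- .placeNuclei(p)
  n <- nrow(nuclei)

  ## ----- cells: membrane lattice -----
  ecad <- matrix(0, H, W)
  polys <- list()
  if (p$ecadChannel) {
    s <- p$cellPitch
    xs <- seq(0.5, W + 0.5, by = s); ys <- seq(0.5, H + 0.5, by = s)
    for (x in xs) ecad <- .drawSegment(ecad, 1, x, H, x, p$ecadLineWidth, p$ecadIntensity)
    for (y in ys) ecad <- .drawSegment(ecad, y, 1, y, W, p$ecadLineWidth, p$ecadIntensity)
    for (i in seq_len(length(ys) - 1)) for (j in seq_len(length(xs) - 1)) {
      polys[[length(polys) + 1]] <- cbind(y = c(ys[i], ys[i], ys[i + 1], ys[i + 1]),
                                          x = c(xs[j], xs[j + 1], xs[j + 1], xs[j]))
    }
    if (p$ecadGaps > 0) {
      for (g in seq_len(p$ecadGaps)) {
        onV <- stats::runif(1) < 0.5
        if (onV) {
          x <- sample(xs[xs > 1 & xs < W], 1)
          y <- stats::runif(1, 5, H - 5)
          rows <- max(1, round(y - p$ecadGapWidth / 2)):min(H, round(y + p$ecadGapWidth / 2))
          cols <- max(1, floor(x - p$ecadLineWidth)):min(W, ceiling(x + p$ecadLineWidth))
        } else {
          y <- sample(ys[ys > 1 & ys < H], 1)
          x <- stats::runif(1, 5, W - 5)
          cols <- max(1, round(x - p$ecadGapWidth / 2)):min(W, round(x + p$ecadGapWidth / 2))
          rows <- max(1, floor(y - p$ecadLineWidth)):min(H, ceiling(y + p$ecadLineWidth))
        }
        ecad[rows, cols] <- 0
      }
    }
  }
  ## separator lines through concatenated pairs
  if (any(nuclei$concatenated)) {
    idx <- which(nuclei$concatenated)
    for (k in seq(1, length(idx), by = 2)) {
      a <- idx[k]; b <- idx[k + 1]
      my <- (nuclei$cy[a] + nuclei$cy[b]) / 2
      mx <- (nuclei$cx[a] + nuclei$cx[b]) / 2
      r <- nuclei$radius[a]
      ecad <- .drawSegment(ecad, my - 2 * r, mx, my + 2 * r, mx,
                           p$ecadLineWidth, p$ecadIntensity)
    }
  }

  ## ----- nuclei -----
  dna <- matrix(0, H, W)
  for (i in seq_len(n))
    dna <- .addBlob(dna, nuclei$cy[i], nuclei$cx[i], nuclei$radius[i],
                    nuclei$intensity[i])

  ## ----- signal channel with optional gradient + puncta -----
  poi <- matrix(0, H, W)
  punctaDF <- data.frame(cy = numeric(0), cx = numeric(0),
                         amplitude = numeric(0), compartment = character(0),
                         cell = integer(0))
  if (p$signalChannel) {
    for (i in seq_len(n)) {
      A <- p$poiBase + p$poiGradientPerPx * nuclei$cy[i]
      poi <- .addBlob(poi, nuclei$cy[i], nuclei$cx[i], nuclei$radius[i], A)
    }
    if (any(p$punctaPerCell > 0)) {
      minSpotSep <- p$punctaMinSep
      perCell <- rep(p$punctaPerCell, length.out = n)
      for (i in seq_len(n)) {
        ## sequential rejection sampling can wedge itself; restart the
        ## cell's spot set when it does
        restart <- 0
        repeat {
        placed <- matrix(numeric(0), 0, 2)
        spotAcc <- list()
        k <- 0; tries <- 0
        while (k < perCell[i] && tries < 2000) {
          tries <- tries + 1
          if (p$punctaCompartment == "nuclear") {
            ang <- stats::runif(1, 0, 2 * pi)
            rad <- stats::runif(1, 0, 0.7 * nuclei$radius[i])
          } else {
            ang <- stats::runif(1, 0, 2 * pi)
            rad <- stats::runif(1, nuclei$radius[i] + 4,
                                max(nuclei$radius[i] + 5, 0.75 * p$thickenradius))
          }
          cy <- nuclei$cy[i] + rad * sin(ang)
          cx <- nuclei$cx[i] + rad * cos(ang)
          if (cy < 4 || cy > H - 4 || cx < 4 || cx > W - 4) next
          if (p$punctaCompartment == "cyto") {
            dAll <- sqrt((nuclei$cy - cy)^2 + (nuclei$cx - cx)^2)
            if (any(dAll <= nuclei$radius + 2)) next        # inside a nucleus
            if (which.min(dAll) != i) next                   # other cell closer
          }
          if (nrow(placed) &&
              any(sqrt((placed[, 1] - cy)^2 + (placed[, 2] - cx)^2) < minSpotSep)) next
          placed <- rbind(placed, c(cy, cx))
          k <- k + 1
          spotAcc[[k]] <- c(cy, cx)
        }
        if (k == perCell[i]) break
        restart <- restart + 1
        if (restart > 50)
          stop("geometric infeasibility: could not place puncta", call. = FALSE)
        }
        for (s in spotAcc) {
          poi <- .addGaussSpot(poi, s[1], s[2], p$punctaAmplitude, p$punctaSigma)
          punctaDF <- rbind(punctaDF,
            data.frame(cy = s[1], cx = s[2], amplitude = p$punctaAmplitude,
                       compartment = p$punctaCompartment, cell = i))
        }
      }
    }
  }

  premix <- stats::setNames(list(dna, if (p$ecadChannel) ecad, if (p$signalChannel) poi)[
    !vapply(list(dna, if (p$ecadChannel) ecad, if (p$signalChannel) poi), is.null, logical(1))],
    chNames)

  ## ----- per-round composition -----
  jit <- p$jitter
  if (is.null(jit)) jit <- matrix(0L, p$nRounds, 2)
  jit <- matrix(as.integer(jit), ncol = 2,
                dimnames = list(NULL, c("dy", "dx")))
  if (nrow(jit) != p$nRounds)
    stop("jitter must have one (dy, dx) row per round", call. = FALSE)
  camera <- p$cameraAmplitude *
    (1 + outer(sin(seq_len(H) / 17), cos(seq_len(W) / 23))) / 2
  rampBG <- p$backgroundOffset + p$rampPerPx * matrix(seq_len(H), H, W)

  slope <- matrix(0, C, C); offm <- matrix(0, C, C)
  if (p$signalChannel && (p$bleedSlope != 0 || p$bleedOffset != 0)) {
    src <- 1L; tgt <- which(chNames == "POI")
    slope[src, tgt] <- p$bleedSlope
    offm[src, tgt] <- p$bleedOffset
  }

  rounds <- vector("list", p$nRounds)
  clean <- vector("list", p$nRounds)
  for (r in seq_len(p$nRounds)) {
    px <- array(0, dim = c(H, W, C))
    for (k in seq_len(C)) px[, , k] <- premix[[k]]
    mixed <- px
    for (k in seq_len(C)) for (s2 in seq_len(C)) {
      if (s2 != k && (slope[s2, k] != 0 || offm[s2, k] != 0))
        mixed[, , k] <- mixed[, , k] + slope[s2, k] * px[, , s2] + offm[s2, k]
    }
    for (k in seq_len(C))
      mixed[, , k] <- mixed[, , k] + rampBG + camera
    for (k in seq_len(C))
      mixed[, , k] <- shiftMatrix(mixed[, , k], jit[r, 1], jit[r, 2],
                                  fill = p$backgroundOffset)
    clean[[r]] <- mixed
    if (p$noiseSD > 0)
      mixed <- mixed + array(stats::rnorm(length(mixed), 0, p$noiseSD),
                             dim = dim(mixed))
    quant <- round(pmin(pmax(mixed, 0), 65535))
    rounds[[r]] <- new("RoundImage", pixels = quant, channelNames = chNames,
                       roundIndex = as.integer(r), siteIndex = as.integer(site))
  }

  scene <- new("SyntheticScene", nuclei = nuclei, cellPolygons = polys,
               appliedJitter = jit,
               bleedParams = list(slope = slope, offset = offm),
               background = list(offset = p$backgroundOffset,
                                 rampPerPx = p$rampPerPx,
                                 cameraAmplitude = p$cameraAmplitude),
               puncta = punctaDF, seed = as.integer(seed), params = p)

  paths <- NULL
  if (!is.null(out_dir)) {
    for (r in seq_len(p$nRounds)) {
      folder <- file.path(out_dir, sprintf("Round%d", r))
      paths <- c(paths, writeRoundStack(pixelData(rounds[[r]]),
                                        roundStackPath(folder, file_name, site)))
    }
    gt <- list(seed = seed,
               nuclei = nuclei,
               jitter = lapply(seq_len(nrow(jit)), function(r)
                 list(round = r, dy = jit[r, 1], dx = jit[r, 2])),
               bleed = list(slope = p$bleedSlope, offset = p$bleedOffset),
               background = scene@background,
               puncta = punctaDF)
    jsonlite::write_json(gt, file.path(out_dir, sprintf("scene_%d.json", site)),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }

  invisible(list(scene = scene, rounds = rounds, clean = clean,
                 premix = premix, paths = paths))
}

#' Settings matching a generated scene's layout
#'
#' Convenience constructor: builds an \code{\linkS4class{IFSettings}}
#' whose folders, channel roles and geometry match the output of
#' \code{\link{generateScene}} written under \code{out_dir}.
#'
#' @param params the scene parameter list used for generation.
#' @param out_dir directory the scene was written to.
#' @param file_name base image name used for generation.
#' @param ... further overrides passed to \code{\link{ifSettings}}.
#' @export
sceneSettings <- function(params, out_dir, file_name = "synthetic", ...) {
  p <- params
  chNames <- c("DNA", if (p$ecadChannel) "Ecad", if (p$signalChannel) "POI")
  ecadIdx <- if (p$ecadChannel) which(chNames == "Ecad") else 0
  args <- list(
    file_name = file_name,
    data_path = file.path(out_dir, "out"),
    crop_save = file.path(out_dir, "crop"),
    mask_save = file.path(out_dir, "mask"),
    IF_imagesessions = file.path(out_dir, sprintf("Round%d", seq_len(p$nRounds))),
    signals = rep(list(chNames), p$nRounds),
    maskIndex = 1, jitterIndex = 1, EcadIndex = ecadIdx,
    nucr = p$nucleusRadius,
    debrisarea = round(0.3 * pi * p$nucleusRadius^2),
    boulderarea = round(6 * pi * p$nucleusRadius^2),
    thickenradius = p$thickenradius,
    punctatopsize = max(2, ceiling(2 * p$punctaSigma)),
    bgsubmethod = "global nuclear")
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(ifSettings, args)
}
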