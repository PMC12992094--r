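## Orchestration of a full site analysis and batch runs.

.withStage <- function(stage, round, site, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s | round %s | site %d] %s", stage,
                 if (is.null(round)) "-" else as.character(round), site,
                 conditionMessage(e)), call. = FALSE)
  })
}

.applySigblur <- function(round, settings) {
  p <- settings@params
  r <- round@roundIndex
  px <- pixelData(round)
  for (k in seq_len(dim(px)[3])) {
    b <- p$sigblur[[r]][k]
    if (b >= 1) px[, , k] <- discAverage(px[, , k], b)
  }
  new("RoundImage", pixels = px, channelNames = round@channelNames,
      roundIndex = round@roundIndex, siteIndex = round@siteIndex)
}

.segParamsFromSettings <- function(settings) {
  p <- settings@params
  list(blurradius = p$blurradius, nucr = p$nucr,
       blobthreshold = p$blobthreshold, split_mult = p$split_mult,
       Gaus_filter_sigma = p$Gaus_filter_sigma, Edge_method = p$Edge_method,
       R_strel_edge = p$R_strel_edge, R_strel_extended = p$R_strel_extended,
       Pixel_connectivity = p$Pixel_connectivity, Max_pixels = p$Max_pixels)
}

#' Run the full pipeline on one site
#'
#' Stages: read every round's stack -> camera correction and binning ->
#' jitter estimation against the reference round -> alignment and
#' cropping -> smoothing -> per-round nuclear segmentation (reference
#' mask defines cell identity) -> optional E-cadherin area and
#' classification -> background subtraction and bleed-through
#' correction -> per-cell measurement under the reference mask ->
#' feature table, masks, crops and (optionally) debug overlays written.
#'
#' @param settings an \code{IFSettings}.
#' @param site site (field of view) number.
#' @param debug write the debug overlay set under
#'   \code{<data_path>/debug_site<site>}.
#' @return (invisibly) a list with the \code{CellFeatureTable}, the
#'   jitter \code{offsets}, the reference \code{mask} and output paths.
#' @export
runSite <- function(settings, site, debug = FALSE) {
  stopifnot(is(settings, "IFSettings"))
  t0 <- Sys.time()
  p <- settings@params
  nR <- settings@nRounds
  site <- as.integer(site)

  rounds <- vector("list", nR)
  for (r in seq_len(nR)) {
    folder <- p$IF_imagesessions[r]
    if (!dir.exists(folder))
      stop(sprintf("[stage read | round %d | site %d] round folder not found: %s",
                   r, site, folder), call. = FALSE)
    rounds[[r]] <- .withStage("read", r, site,
      readRoundStack(folder, p$file_name, site, r, p$signals[[r]]))
  }
  cmos <- .withStage("camera-correction", NULL, site,
                     readCameraBackground(p$bgcmospath))
  ## smoothing (sigblur) is deferred until after alignment and cropping
  for (r in seq_len(nR))
    rounds[[r]] <- .withStage("preprocess", r, site,
      preprocessRoundNoSmooth(rounds[[r]], settings, cmos))

  offsets <- .withStage("jitter", NULL, site,
                        estimateJitterAll(rounds, settings))
  aligned <- .withStage("align-crop", NULL, site,
    alignAndCrop(rounds, offsets,
                 crop_save = if (nzchar(p$crop_save)) p$crop_save else NULL,
                 settings = settings))
  rounds <- lapply(aligned$rounds, .applySigblur, settings = settings)

  segPar <- .segParamsFromSettings(settings)
  masks <- vector("list", nR)
  for (r in seq_len(nR)) {
    masks[[r]] <- .withStage("segmentation", r, site, {
      nuc <- getChannel(rounds[[r]], p$maskIndex[r])
      ecad <- if (p$EcadIndex[r] > 0) getChannel(rounds[[r]], p$EcadIndex[r]) else NULL
      cand <- segmentNuclei(nuc, ecad, method = p$segmethod[r], params = segPar)
      filterObjects(cand, p$debrisarea[r], p$boulderarea, p$soliditythresh)
    })
    if (nzchar(p$mask_save))
      writeLabelMask(masks[[r]], p$mask_save, p$maskname, r, site)
  }
  refMask <- masks[[p$primaryMaskRound]]
  message(sprintf("site %d: %d cell(s) in reference round %d",
                  site, nObjects(refMask), p$primaryMaskRound))

  ecadFlags <- NULL
  ecadArea <- NULL
  rPrim <- p$primaryMaskRound
  if (p$EcadIndex[rPrim] > 0) {
    ecadRes <- .withStage("ecad-classification", rPrim, site, {
      ec <- getChannel(rounds[[rPrim]], p$EcadIndex[rPrim])
      edges <- detectEcadEdges(ec, method = p$Edge_method,
                               Gaus_filter_sigma = p$Gaus_filter_sigma)
      area <- buildEcadPositiveArea(edges, p$R_strel_edge,
                                    p$Pixel_connectivity,
                                    p$R_strel_extended)
      list(flags = classifyEcadStatus(refMask, area, p$ecad_overlap),
           area = area)
    })
    ecadFlags <- ecadRes$flags
    ecadArea <- ecadRes$area
  }

  rings <- .withStage("cytoring", NULL, site,
    buildCytoring(refMask, p$innerrad_cytoring, p$outerrad_cytoring))
  cytoMask <- binaryDilate(labels(refMask) > 0, p$thickenradius) &
    labels(refMask) == 0

  measures <- vector("list", nR)
  for (r in seq_len(nR)) {
    corrected <- .withStage("background-bleedthrough", r, site,
      applyBackgroundAndBleed(rounds[[r]], settings, refMask,
                              cyto_mask = cytoMask))
    measures[[r]] <- vector("list", settings@nChannels[r])
    for (c in seq_len(settings@nChannels[r])) {
      measures[[r]][[c]] <- .withStage("measurement", r, site, {
        ch <- getChannel(corrected, c)
        m <- list(nuc = measureNuclearSignal(ch, refMask))
        if (p$ringcalc[[r]][c] > 0)
          m$ring <- measureCytoringSignal(ch, rings, p$ringthresh[[r]][c],
                                          p$minringsize)
        if (p$punctacalc[[r]][c] > 0) {
          pk <- detectPuncta(ch, refMask, p$punctatopsize,
                             p$punctaThresh[[r]][c], p$cytopuncta[[r]][c],
                             p$thickenradius)
          m$pcount <- pk$count; m$pint <- pk$intensity
        }
        if (p$localbg[[r]][c] > 0)
          m$lbg <- measureLocalBackground(ch, refMask, p$bgperctile[[r]][c],
                                          p$nucr)
        m
      })
    }
  }

  table <- .withStage("assemble", NULL, site,
    assembleFeatureTable(refMask, measures, ecadFlags, settings, site))
  outDir <- if (nzchar(p$data_path)) p$data_path else "."
  paths <- writeFeatureTable(table, outDir)
  writeSettingsCompanion(settings, tableHeader(table), offsets,
                         file.path(outDir, sprintf("settings_IHC_%d.yaml", site)))

  if (debug) {
    dbg <- file.path(outDir, sprintf("debug_site%d", site))
    for (r in seq_len(nR)) {
      nuc <- getChannel(rounds[[r]], p$maskIndex[r])
      writeContourOverlay(nuc, masks[[r]],
                          file.path(dbg, sprintf("seg_round%d.png", r)))
      writeContourOverlay(nuc, refMask,
                          file.path(dbg, sprintf("refmask_round%d.png", r)))
      if (r < nR)
        writePairOverlay(getChannel(rounds[[r]], p$maskIndex[r]),
                         getChannel(rounds[[r + 1]], p$maskIndex[r + 1]),
                         file.path(dbg, sprintf("align_round%d_vs_%d.png", r, r + 1)))
    }
    writeAreaHistogram(refMask, file.path(dbg, "nuclear_area_hist.png"),
                       p$debrisarea[rPrim], p$boulderarea)
    if (!is.null(ecadArea)) {
      ec <- getChannel(rounds[[rPrim]], p$EcadIndex[rPrim])
      writeAreaOverlay(ec, ecadArea, file.path(dbg, "ecad_area.png"))
      edges <- detectEcadEdges(ec, method = p$Edge_method,
                               Gaus_filter_sigma = p$Gaus_filter_sigma)
      cells <- segmentCellsEcadOnly(edges, p$R_strel_edge,
                                    p$Pixel_connectivity, p$Max_pixels)
      writeLabelOverlay(ec, cells, file.path(dbg, "ecad_cells.png"))
    }
    writeContourOverlay(getChannel(rounds[[rPrim]], p$maskIndex[rPrim]),
                        rings, file.path(dbg, "cytoring.png"))
    anyPuncta <- any(unlist(p$punctacalc) > 0)
    if (anyPuncta) {
      r1c <- which(p$punctacalc[[1]] > 0)[1]
      if (!is.na(r1c))
        writeGrayscale(whiteTopHatDisc(getChannel(rounds[[1]], r1c),
                                       p$punctatopsize),
                       file.path(dbg, "puncta_tophat.png"))
    }
  }

  dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  message(sprintf("site %d completed in %.1f s", site, dt))
  invisible(list(table = table, offsets = offsets, mask = refMask,
                 masks = masks, paths = paths))
}

## camera correction + binning only (no smoothing)
preprocessRoundNoSmooth <- function(round, settings, cmos = NULL) {
  p <- settings@params
  r <- round@roundIndex
  px <- pixelData(round)
  C <- dim(px)[3]
  if (p$bgcmoscorrection > 0 && !is.null(cmos)) {
    if (!all(dim(cmos) == dim(px)[1:2]))
      stop(sprintf("camera background shape disagrees with round %d images", r),
           call. = FALSE)
    for (k in seq_len(C)) px[, , k] <- px[, , k] - cmos
  }
  f <- p$postbin[r]
  if (f != 0 && f != 1) {
    ch1 <- applyPostbin(px[, , 1], f)
    out <- array(0, dim = c(nrow(ch1), ncol(ch1), C))
    out[, , 1] <- ch1
    for (k in seq_len(C)[-1]) out[, , k] <- applyPostbin(px[, , k], f)
    px <- out
  }
  new("RoundImage", pixels = px, channelNames = round@channelNames,
      roundIndex = round@roundIndex, siteIndex = round@siteIndex)
}

#' Run the pipeline over multiple sites
#'
#' Sites are independent; a failure in one site is caught, reported at
#' the end, and does not affect the others.  Outputs are identical to
#' running \code{\link{runSite}} per site.
#'
#' @param settings an \code{IFSettings}.
#' @param sites integer vector of site numbers.
#' @param debug passed through to \code{\link{runSite}}.
#' @return list with \code{results} (per successful site) and
#'   \code{errors} (named character vector of failures).
#' @export
runBatch <- function(settings, sites, debug = FALSE) {
  results <- list()
  errors <- character(0)
  for (s in sites) {
    r <- tryCatch(runSite(settings, s, debug = debug), error = function(e) e)
    if (inherits(r, "error")) {
      errors[as.character(s)] <- conditionMessage(r)
    } else {
      results[[as.character(s)]] <- r
    }
  }
  if (length(errors))
    warning(sprintf("batch: %d site(s) failed: %s", length(errors),
                    paste(sprintf("site %s (%s)", names(errors), errors),
                          collapse = "; ")), call. = FALSE)
  invisible(list(results = results, errors = errors))
}
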