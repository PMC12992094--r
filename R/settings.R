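## Configuration ledger: defaults, normalisation and validation.
##
## The configuration is a flat key/value file (YAML) mirroring the
## pipeline's parameter ledger.  Parameters come in four shapes:
##   scalar            one value for the whole experiment
##   per-round         one value per 4i round (scalars are recycled)
##   per-round/channel one value per channel of each round
##   pair matrix       a C x C matrix per round (bleed-through mixing)

.SEGMETHODS <- c("log", "thresh", "single", "double", "double marker",
                 "multithresh", "concavity", "log contour",
                 "Nuc-Ecad boundary", "Ecad boundary")
.BGSUBMETHODS <- c("global nuclear", "global cyto", "tophat",
                   "semi-local nuclear", "none")
.EDGEMETHODS <- c("log", "Canny")
.POIFORMULAS <- c("nuc", "cyto", "nuc-cyto", "cyto-nuc")

## name = list(kind, default (NULL = required), enum = optional)
.settingsSchema <- function() list(
  file_name        = list(kind = "scalar", default = NULL),
  data_path        = list(kind = "scalar", default = "."),
  crop_save        = list(kind = "scalar", default = ""),
  mask_save        = list(kind = "scalar", default = ""),
  IF_imagesessions = list(kind = "special", default = NULL),
  bgcmospath       = list(kind = "scalar", default = ""),
  maskname         = list(kind = "scalar", default = "mask"),
  primaryMaskRound = list(kind = "scalar", default = 1),
  maskIndex        = list(kind = "round", default = NULL),
  EcadIndex        = list(kind = "round", default = 0),
  jitterIndex      = list(kind = "round", default = NULL),
  outerrad_cytoring = list(kind = "scalar", default = 5),
  innerrad_cytoring = list(kind = "scalar", default = 1),
  postbin          = list(kind = "round", default = 0),
  signals          = list(kind = "special", default = NULL),
  maxjit           = list(kind = "scalar", default = 20),
  sigblur          = list(kind = "rc", default = 0),
  signal_foreground = list(kind = "rc", default = 0),
  bleedthrough     = list(kind = "rc", default = 0),
  bleedthroughslope = list(kind = "pair", default = 0),
  bleedthroughoff  = list(kind = "pair", default = 0),
  ringcalc         = list(kind = "rc", default = 0),
  ringthresh       = list(kind = "rc", default = 0),
  punctacalc       = list(kind = "rc", default = 0),
  punctaThresh     = list(kind = "rc", default = 0),
  punctatopsize    = list(kind = "scalar", default = 2),
  cytopuncta       = list(kind = "rc", default = 0),
  thickenradius    = list(kind = "scalar", default = NA),
  localbg          = list(kind = "rc", default = 0),
  minringsize      = list(kind = "scalar", default = 10),
  bgcmoscorrection = list(kind = "scalar", default = 0),
  bgsubmethod      = list(kind = "rc", default = "none", enum = .BGSUBMETHODS),
  bgperctile       = list(kind = "rc", default = 25),
  segmethod        = list(kind = "round", default = "thresh", enum = .SEGMETHODS),
  nucr             = list(kind = "scalar", default = 8),
  debrisarea       = list(kind = "round", default = 20),
  boulderarea      = list(kind = "scalar", default = 10000),
  blobthreshold    = list(kind = "scalar", default = -0.02),
  blurradius       = list(kind = "scalar", default = 3),
  soliditythresh   = list(kind = "scalar", default = 0.5),
  compression      = list(kind = "scalar", default = 4),
  split_mult       = list(kind = "scalar", default = 1),
  Edge_method      = list(kind = "scalar", default = "Canny", enum = .EDGEMETHODS),
  R_strel_edge     = list(kind = "scalar", default = 2),
  R_strel_extended = list(kind = "scalar", default = 4),
  Pixel_connectivity = list(kind = "scalar", default = 4),
  Max_pixels       = list(kind = "scalar", default = 50),
  Gaus_filter_sigma = list(kind = "scalar", default = 2),
  ecad_overlap     = list(kind = "scalar", default = 0.5),
  pixelsize        = list(kind = "scalar", default = 1),
  POI_formula      = list(kind = "scalar", default = "nuc", enum = .POIFORMULAS),
  POI_nuc_col      = list(kind = "scalar", default = 4),
  POI_cyto_col     = list(kind = "scalar", default = 5)
)

.normalizeRound <- function(value, nR, field) {
  if (is.list(value)) value <- unlist(value)
  if (length(value) == 1) value <- rep(value, nR)
  if (length(value) != nR)
    stop(sprintf("settings field '%s': expected %d per-round value(s), got %d",
                 field, nR, length(value)), call. = FALSE)
  value
}

.normalizeRC <- function(value, nR, nC, field) {
  ## accepted: scalar; flat vector per round; list of per-round vectors
  if (!is.list(value)) {
    if (length(value) == 1) {
      value <- lapply(seq_len(nR), function(r) rep(value, nC[r]))
    } else if (length(value) == nR) {
      value <- lapply(seq_len(nR), function(r) rep(value[r], nC[r]))
    } else {
      stop(sprintf("settings field '%s': cannot map %d value(s) onto %d round(s)",
                   field, length(value), nR), call. = FALSE)
    }
  } else {
    if (length(value) != nR)
      stop(sprintf("settings field '%s': expected %d per-round entries, got %d",
                   field, nR, length(value)), call. = FALSE)
    value <- lapply(seq_len(nR), function(r) {
      v <- unlist(value[[r]])
      if (length(v) == 1) v <- rep(v, nC[r])
      if (length(v) != nC[r])
        stop(sprintf("settings field '%s', round %d: expected %d per-channel value(s), got %d",
                     field, r, nC[r], length(v)), call. = FALSE)
      v
    })
  }
  value
}

.normalizePair <- function(value, nR, nC, field) {
  if (!is.list(value) || is.data.frame(value)) {
    if (length(value) == 1 && is.numeric(value)) {
      return(lapply(seq_len(nR), function(r) matrix(value, nC[r], nC[r])))
    }
    stop(sprintf("settings field '%s': expected per-round channel-pair matrices",
                 field), call. = FALSE)
  }
  if (length(value) != nR)
    stop(sprintf("settings field '%s': expected %d per-round matrices, got %d",
                 field, nR, length(value)), call. = FALSE)
  lapply(seq_len(nR), function(r) {
    m <- value[[r]]
    if (is.list(m)) m <- do.call(rbind, lapply(m, unlist))
    m <- as.matrix(m)
    if (length(m) == 1) m <- matrix(as.numeric(m), nC[r], nC[r])
    if (!all(dim(m) == c(nC[r], nC[r])))
      stop(sprintf("settings field '%s', round %d: expected a %dx%d matrix",
                   field, r, nC[r], nC[r]), call. = FALSE)
    storage.mode(m) <- "double"
    m
  })
}

## Full structural validation.  Returns NULL when valid, else a message
## naming the offending field (and round/channel where applicable).
validateSettingsParams <- function(p, nR, nC) {
  chkEnum <- function(vals, allowed, field, round = NULL) {
    bad <- which(!(vals %in% allowed))
    if (length(bad)) {
      where <- if (is.null(round)) sprintf(" (entry %d)", bad[1])
               else sprintf(" (round %d, channel %d)", round, bad[1])
      return(sprintf("settings field '%s'%s: unknown value '%s'",
                     field, where, vals[bad[1]]))
    }
    NULL
  }
  if (length(p$IF_imagesessions) != nR)
    return("settings field 'IF_imagesessions': empty")
  if (length(p$signals) != nR)
    return(sprintf("settings field 'signals': expected %d per-round entries, got %d",
                   nR, length(p$signals)))
  for (f in c("maskIndex", "EcadIndex", "jitterIndex", "postbin",
              "segmethod", "debrisarea")) {
    if (length(p[[f]]) != nR)
      return(sprintf("settings field '%s': expected %d per-round value(s), got %d",
                     f, nR, length(p[[f]])))
  }
  for (f in c("sigblur", "signal_foreground", "bleedthrough", "ringcalc",
              "ringthresh", "punctacalc", "punctaThresh", "cytopuncta",
              "localbg", "bgsubmethod", "bgperctile")) {
    v <- p[[f]]
    if (length(v) != nR)
      return(sprintf("settings field '%s': expected %d per-round entries, got %d",
                     f, nR, length(v)))
    for (r in seq_len(nR)) {
      if (length(v[[r]]) != nC[r])
        return(sprintf("settings field '%s', round %d: expected %d per-channel value(s), got %d",
                       f, r, nC[r], length(v[[r]])))
    }
  }
  if (!(p$innerrad_cytoring >= 0 && p$innerrad_cytoring < p$outerrad_cytoring))
    return("settings fields 'innerrad_cytoring'/'outerrad_cytoring': require 0 <= inner < outer")
  if (!(p$maxjit > 0)) return("settings field 'maxjit': must be positive")
  if (!(p$primaryMaskRound >= 1 && p$primaryMaskRound <= nR))
    return(sprintf("settings field 'primaryMaskRound': %d outside 1..%d",
                   p$primaryMaskRound, nR))
  if (any(p$debrisarea >= p$boulderarea))
    return("settings fields 'debrisarea'/'boulderarea': require debrisarea < boulderarea")
  if (!(p$Pixel_connectivity %in% c(4, 8)))
    return("settings field 'Pixel_connectivity': must be 4 or 8")
  for (r in seq_len(nR)) {
    if (!(p$maskIndex[r] >= 1 && p$maskIndex[r] <= nC[r]))
      return(sprintf("settings field 'maskIndex' (round %d): channel %d outside 1..%d",
                     r, p$maskIndex[r], nC[r]))
    if (!(p$jitterIndex[r] >= 1 && p$jitterIndex[r] <= nC[r]))
      return(sprintf("settings field 'jitterIndex' (round %d): channel %d outside 1..%d",
                     r, p$jitterIndex[r], nC[r]))
    if (!(p$EcadIndex[r] >= 0 && p$EcadIndex[r] <= nC[r]))
      return(sprintf("settings field 'EcadIndex' (round %d): channel %d outside 0..%d",
                     r, p$EcadIndex[r], nC[r]))
    if (!(p$postbin[r] == 0 || (p$postbin[r] > 0 && p$postbin[r] <= 1)))
      return(sprintf("settings field 'postbin' (round %d): must be 0 or in (0, 1]", r))
    m <- chkEnum(p$segmethod[r], .SEGMETHODS, "segmethod"); if (!is.null(m)) return(m)
    m <- chkEnum(p$bgsubmethod[[r]], .BGSUBMETHODS, "bgsubmethod", r); if (!is.null(m)) return(m)
    if (p$segmethod[r] %in% c("Nuc-Ecad boundary", "Ecad boundary") &&
        p$EcadIndex[r] == 0)
      return(sprintf("settings field 'segmethod' (round %d): '%s' requires EcadIndex != 0",
                     r, p$segmethod[r]))
    for (f in c("bleedthroughslope", "bleedthroughoff")) {
      if (!all(dim(p[[f]][[r]]) == c(nC[r], nC[r])))
        return(sprintf("settings field '%s' (round %d): expected a %dx%d matrix",
                       f, r, nC[r], nC[r]))
    }
  }
  m <- chkEnum(p$Edge_method, .EDGEMETHODS, "Edge_method"); if (!is.null(m)) return(m)
  m <- chkEnum(p$POI_formula, .POIFORMULAS, "POI_formula"); if (!is.null(m)) return(m)
  if (!(p$pixelsize > 0)) return("settings field 'pixelsize': must be positive")
  if (p$nucr <= 0) return("settings field 'nucr': must be positive")
  NULL
}

#' Construct a validated settings object
#'
#' Missing optional fields take documented defaults (\code{blurradius} 3,
#' \code{compression} 4, \code{split_mult} 1, \code{Pixel_connectivity} 4,
#' \code{Edge_method} "Canny", among others); scalars given for per-round
#' or per-channel parameters are recycled.  Required fields:
#' \code{file_name}, \code{IF_imagesessions}, \code{signals},
#' \code{maskIndex}, \code{jitterIndex}.
#'
#' @param ... parameter name/value pairs, or a single named list.
#' @return an \code{\linkS4class{IFSettings}} object.
#' @examples
#' cfg <- ifSettings(file_name = "example",
#'                   IF_imagesessions = "Round1",
#'                   signals = list(c("DAPI", "GFP")),
#'                   maskIndex = 1, jitterIndex = 1)
#' nRounds(cfg)
#' @export
ifSettings <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.list(args[[1]]) && is.null(names(args)[1]))
    args <- args[[1]]
  schema <- .settingsSchema()
  unknown <- setdiff(names(args), names(schema))
  if (length(unknown))
    stop(sprintf("unknown settings field(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  p <- list()
  for (nm in names(schema)) {
    if (nm %in% names(args)) p[[nm]] <- args[[nm]]
    else if (is.null(schema[[nm]]$default))
      stop(sprintf("settings field '%s' is required", nm), call. = FALSE)
    else p[[nm]] <- schema[[nm]]$default
  }
  ## structure first: rounds and channels
  p$IF_imagesessions <- as.character(unlist(p$IF_imagesessions))
  nR <- length(p$IF_imagesessions)
  if (nR < 1) stop("settings field 'IF_imagesessions': empty", call. = FALSE)
  if (!is.list(p$signals)) p$signals <- list(as.character(p$signals))
  p$signals <- lapply(p$signals, function(s) as.character(unlist(s)))
  if (length(p$signals) == 1 && nR > 1) p$signals <- rep(p$signals, nR)
  if (length(p$signals) != nR)
    stop(sprintf("settings field 'signals': expected %d per-round entries, got %d",
                 nR, length(p$signals)), call. = FALSE)
  nC <- vapply(p$signals, length, integer(1))
  for (nm in names(schema)) {
    k <- schema[[nm]]$kind
    if (k == "round") p[[nm]] <- .normalizeRound(p[[nm]], nR, nm)
    else if (k == "rc") p[[nm]] <- .normalizeRC(p[[nm]], nR, nC, nm)
    else if (k == "pair") p[[nm]] <- .normalizePair(p[[nm]], nR, nC, nm)
  }
  if (is.na(p$thickenradius)) p$thickenradius <- 3 * p$nucr
  new("IFSettings", params = p, nRounds = nR, nChannels = nC)
}

#' Load settings from a YAML configuration file
#'
#' @param path path to a YAML file whose keys mirror the parameter ledger.
#' @return an \code{\linkS4class{IFSettings}} object with defaults filled
#'   and every invariant checked; a violation raises an error naming the
#'   offending field and index.
#' @export
loadSettings <- function(path) {
  if (!file.exists(path))
    stop(sprintf("settings file not found: %s", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(names(raw)))
    stop(sprintf("settings file did not parse to a named mapping: %s", path),
         call. = FALSE)
  ifSettings(raw)
}

#' Write a settings object to a YAML file
#' @param settings an \code{IFSettings} object.
#' @param path output path.
#' @export
writeSettings <- function(settings, path) {
  p <- settings@params
  p$bleedthroughslope <- lapply(p$bleedthroughslope, function(m)
    lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ])))
  p$bleedthroughoff <- lapply(p$bleedthroughoff, function(m)
    lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ])))
  yaml::write_yaml(p, path)
  invisible(path)
}

## Settings + header + jitter companion written beside each feature table
writeSettingsCompanion <- function(settings, header, offsets, path) {
  comp <- list(header = as.list(header),
               jitter_offsets = lapply(seq_len(nrow(offsets)), function(r)
                 list(round = r, dy = offsets[r, 1], dx = offsets[r, 2])),
               nRounds = settings@nRounds,
               signals = settings@params$signals)
  yaml::write_yaml(comp, path)
  invisible(path)
}
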