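#' @import methods
NULL

#' Validated parameter ledger for a multi-round 4i experiment
#'
#' Holds every tunable parameter of the pipeline: file layout, per-round
#' channel roles (nuclear, E-cadherin, jitter), preprocessing (binning,
#' blurring, background subtraction, bleed-through), segmentation,
#' cytoplasmic-ring geometry, puncta detection and plotting.  Constructed
#' with \code{\link{ifSettings}} or \code{\link{loadSettings}}; every
#' structural invariant is enforced by the class validity method, and a
#' violation names the offending field and round/channel index.
#'
#' @slot params named list of normalised parameter values; per-round
#'   parameters are vectors/lists of length \code{nRounds}, per-channel
#'   parameters are lists of per-round vectors.
#' @slot nRounds number of 4i rounds (length of \code{IF_imagesessions}).
#' @slot nChannels integer vector, channels per round.
#' @export
setClass("IFSettings",
  representation(params = "list", nRounds = "integer", nChannels = "integer"))

setValidity("IFSettings", function(object) {
  msg <- validateSettingsParams(object@params, object@nRounds, object@nChannels)
  if (is.null(msg)) TRUE else msg
})

#' One site's multi-channel image stack for one 4i round
#'
#' @slot pixels numeric H x W x C array of nonnegative intensities
#'   (12- or 16-bit origin; held in floating point).
#' @slot channelNames channel names matching the settings' \code{signals}.
#' @slot roundIndex,siteIndex 1-based round and site (field of view).
#' @export
setClass("RoundImage",
  representation(pixels = "array", channelNames = "character",
                 roundIndex = "integer", siteIndex = "integer"))

setValidity("RoundImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3) return("pixels must be an H x W x C array")
  if (d[3] < 1) return("at least one channel is required")
  if (length(object@channelNames) != d[3])
    return(sprintf("channelNames length (%d) != channel count (%d)",
                   length(object@channelNames), d[3]))
  if (any(object@pixels < 0)) return("intensities must be nonnegative")
  TRUE
})

#' Integer-labelled segmentation mask
#'
#' Pixels of object i carry value i; background is 0.  After filtering,
#' ids are contiguous 1..N.
#'
#' @slot labels H x W integer matrix.
#' @export
setClass("LabelMask", representation(labels = "matrix"))

setValidity("LabelMask", function(object) {
  l <- object@labels
  if (!is.numeric(l)) return("labels must be numeric")
  if (any(l < 0) || any(l != floor(l))) return("labels must be nonnegative integers")
  TRUE
})

#' Per-cell feature table
#'
#' One row per cell of the reference round: centroid (x, y), nuclear area,
#' then per round x channel the enabled measures, then the E-cadherin
#' positive/negative flag.  \code{header} holds a human-readable
#' description of every column in order.
#'
#' @slot data data.frame of measurements.
#' @slot header character vector, one entry per column.
#' @slot siteIndex site (field of view) number.
#' @export
setClass("CellFeatureTable",
  representation(data = "data.frame", header = "character",
                 siteIndex = "integer"))

setValidity("CellFeatureTable", function(object) {
  if (ncol(object@data) != length(object@header))
    return(sprintf("column count (%d) != header length (%d)",
                   ncol(object@data), length(object@header)))
  TRUE
})

#' Ground truth for a synthetic multi-round scene
#'
#' @slot nuclei data.frame: cy, cx, radius, intensity, concatenated flag.
#' @slot cellPolygons list of polygon vertex matrices (E-cadherin lines).
#' @slot appliedJitter nRounds x 2 matrix of (dy, dx) shifts.
#' @slot bleedParams list with slope/offset matrices per round.
#' @slot background list: offset, rampPerPx, cameraPattern.
#' @slot puncta data.frame: cy, cx, amplitude, compartment, cell.
#' @slot seed integer seed the scene was generated from.
#' @slot params full generator parameter list.
#' @export
setClass("SyntheticScene",
  representation(nuclei = "data.frame", cellPolygons = "list",
                 appliedJitter = "matrix", bleedParams = "list",
                 background = "list", puncta = "data.frame",
                 seed = "integer", params = "list"))

#' Binned spatial profile of a per-cell signal
#'
#' Mean and standard deviation of a protein-of-interest readout per
#' fixed-width bin along the tissue axis (default 20 micrometres).
#'
#' @slot binCenters bin centres in micrometres.
#' @slot mean,sd per-bin mean and population SD of the POI value.
#' @slot n cells per bin.
#' @slot binWidth bin width in micrometres.
#' @export
setClass("SpatialProfile",
  representation(binCenters = "numeric", mean = "numeric", sd = "numeric",
                 n = "integer", binWidth = "numeric"))

setValidity("SpatialProfile", function(object) {
  k <- length(object@binCenters)
  if (length(object@mean) != k || length(object@sd) != k || length(object@n) != k)
    return("binCenters, mean, sd and n must have equal length")
  if (any(object@n < 1)) return("reported bins must contain at least one cell")
  if (any(object@sd < 0)) return("sd must be nonnegative")
  TRUE
})
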