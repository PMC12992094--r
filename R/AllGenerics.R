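#' Number of 4i rounds described by a settings object
#' @param x an \code{IFSettings} object.
#' @export
setGeneric("nRounds", function(x) standardGeneric("nRounds"))

#' @rdname nRounds
#' @export
setMethod("nRounds", "IFSettings", function(x) x@nRounds)

#' Channels per round
#' @param x an \code{IFSettings} object.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname nChannels
#' @export
setMethod("nChannels", "IFSettings", function(x) x@nChannels)

#' Look up a parameter by name
#'
#' @param x an \code{IFSettings} object.
#' @param name parameter name as in the configuration file.
#' @return the normalised parameter value (per-round parameters come back
#'   as length-\code{nRounds} vectors/lists).
#' @export
setGeneric("param", function(x, name) standardGeneric("param"))

#' @rdname param
#' @export
setMethod("param", "IFSettings", function(x, name) {
  if (!name %in% names(x@params))
    stop(sprintf("unknown parameter '%s'", name))
  x@params[[name]]
})

#' @export
setMethod("$", "IFSettings", function(x, name) x@params[[name]])

#' Pixel data of a round image
#' @param x a \code{RoundImage}.
#' @export
setGeneric("pixelData", function(x) standardGeneric("pixelData"))

#' @rdname pixelData
#' @export
setMethod("pixelData", "RoundImage", function(x) x@pixels)

#' Extract one channel of a round image as a matrix
#' @param x a \code{RoundImage}.
#' @param channel channel index or name.
#' @export
setGeneric("getChannel", function(x, channel) standardGeneric("getChannel"))

#' @rdname getChannel
#' @export
setMethod("getChannel", "RoundImage", function(x, channel) {
  if (is.character(channel)) {
    channel <- match(channel, x@channelNames)
    if (is.na(channel)) stop("unknown channel name")
  }
  x@pixels[, , channel]
})

#' Label matrix of a mask
#' @param object a \code{LabelMask}.
#' @param ... ignored.
#' @export
setMethod("labels", "LabelMask", function(object, ...) object@labels)

#' Number of labelled objects
#' @param x a \code{LabelMask}.
#' @export
setGeneric("nObjects", function(x) standardGeneric("nObjects"))

#' @rdname nObjects
#' @export
setMethod("nObjects", "LabelMask", function(x) as.integer(max(x@labels)))

#' Feature table data and header
#' @param x a \code{CellFeatureTable}.
#' @export
setGeneric("tableData", function(x) standardGeneric("tableData"))

#' @rdname tableData
#' @export
setMethod("tableData", "CellFeatureTable", function(x) x@data)

#' @rdname tableData
#' @export
setGeneric("tableHeader", function(x) standardGeneric("tableHeader"))

#' @rdname tableData
#' @export
setMethod("tableHeader", "CellFeatureTable", function(x) x@header)

#' @export
setMethod("show", "IFSettings", function(object) {
  cat(sprintf("IFSettings: %d round(s); channels per round: %s\n",
              object@nRounds, paste(object@nChannels, collapse = ", ")))
  cat(sprintf("  reference round: %d; segmentation: %s\n",
              object@params$primaryMaskRound,
              paste(object@params$segmethod, collapse = ", ")))
  invisible(NULL)
})

#' @export
setMethod("show", "RoundImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("RoundImage: round %d, site %d, %dx%d px, %d channel(s): %s\n",
              object@roundIndex, object@siteIndex, d[1], d[2], d[3],
              paste(object@channelNames, collapse = ", ")))
  invisible(NULL)
})

#' @export
setMethod("show", "LabelMask", function(object) {
  cat(sprintf("LabelMask: %dx%d px, %d object(s)\n",
              nrow(object@labels), ncol(object@labels), max(object@labels)))
  invisible(NULL)
})

#' @export
setMethod("show", "CellFeatureTable", function(object) {
  cat(sprintf("CellFeatureTable: site %d, %d cell(s), %d column(s)\n",
              object@siteIndex, nrow(object@data), ncol(object@data)))
  invisible(NULL)
})

#' @export
setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf("SyntheticScene: %d nuclei, %d rounds, seed %d\n",
              nrow(object@nuclei), nrow(object@appliedJitter), object@seed))
  invisible(NULL)
})

#' @export
setMethod("show", "SpatialProfile", function(object) {
  cat(sprintf("SpatialProfile: %d bins of %g um\n",
              length(object@binCenters), object@binWidth))
  invisible(NULL)
})
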