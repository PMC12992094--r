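## TIFF and table I/O under the round/site naming convention:
## one subfolder per 4i round, identical base names across rounds, the
## site (field of view) number as a trailing suffix: <base>_<site>.tif.
## Multi-channel stacks are single multi-page files, page order = channel
## order.

roundStackPath <- function(round_folder, base_name, site) {
  file.path(round_folder, sprintf("%s_%d.tif", base_name, site))
}

.readTiffPages <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]   # collapse any colour planes
    storage.mode(p) <- "double"
    p
  })
}

#' Read one site's multi-page TIFF stack for one round
#'
#' @param round_folder folder holding the round's images.
#' @param base_name image base name (without site suffix).
#' @param site site (field of view) number appended as \code{_<site>}.
#' @param round_index 1-based round index recorded on the object.
#' @param channel_names optional channel names; when given, a page count
#'   disagreeing with \code{length(channel_names)} is an error.
#' @return a \code{\linkS4class{RoundImage}} with intensities unmodified.
#' @export
readRoundStack <- function(round_folder, base_name, site, round_index = 1L,
                           channel_names = NULL) {
  path <- roundStackPath(round_folder, base_name, site)
  if (!file.exists(path))
    stop(sprintf("round image not found: %s", path), call. = FALSE)
  pages <- .readTiffPages(path)
  C <- length(pages)
  if (!is.null(channel_names) && length(channel_names) != C)
    stop(sprintf("%s: %d page(s) but %d channel name(s) configured in 'signals'",
                 path, C, length(channel_names)), call. = FALSE)
  if (is.null(channel_names)) channel_names <- sprintf("channel%d", seq_len(C))
  px <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), C))
  for (k in seq_len(C)) px[, , k] <- pages[[k]]
  new("RoundImage", pixels = px, channelNames = as.character(channel_names),
      roundIndex = as.integer(round_index), siteIndex = as.integer(site))
}

#' Write a multi-page 16-bit TIFF stack
#'
#' Values are clipped to [0, 65535] and rounded; the round trip through
#' \code{\link{readRoundStack}} is bit-exact for integer inputs.
#'
#' @param pixels H x W x C array or a single matrix.
#' @param path output file path.
#' @export
writeRoundStack <- function(pixels, path) {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 1))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  pages <- lapply(seq_len(dim(pixels)[3]), function(k) {
    p <- round(pmin(pmax(pixels[, , k], 0), 65535))
    p / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read an optional camera-background image
#'
#' @param path TIFF path; the first page is used.
#' @return numeric matrix, or \code{NULL} when \code{path} is empty.
#' @export
readCameraBackground <- function(path) {
  if (is.null(path) || !nzchar(path)) return(NULL)
  if (!file.exists(path))
    stop(sprintf("camera background image not found: %s", path), call. = FALSE)
  .readTiffPages(path)[[1]]
}

#' Write a label mask as a 16-bit TIFF named `<maskname>_<round>_<site>.tif`
#'
#' @param mask a \code{LabelMask}.
#' @param mask_save output directory.
#' @param maskname file prefix.
#' @param round,site indices used in the file name.
#' @export
writeLabelMask <- function(mask, mask_save, maskname, round, site) {
  dir.create(mask_save, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(mask_save, sprintf("%s_%d_%d.tif", maskname, round, site))
  writeRoundStack(labels(mask), path)
  invisible(path)
}

#' Read a label mask written by \code{\link{writeLabelMask}}
#' @param path mask TIFF path.
#' @export
readLabelMask <- function(path) {
  m <- .readTiffPages(path)[[1]]
  storage.mode(m) <- "integer"
  new("LabelMask", labels = m)
}

#' Write a per-site feature table with its header sidecar
#'
#' The data file is CSV with one cell per row; the sidecar
#' \code{<stem>_header.txt} lists the human-readable description of every
#' column in order (x, y, nuclear area, then the enabled per-round/channel
#' measures, then the E-cadherin classification).
#'
#' @param table a \code{CellFeatureTable}.
#' @param out_dir output directory.
#' @param stem file stem; defaults to \code{IHCdata_<site>}.
#' @return paths of the files written.
#' @export
writeFeatureTable <- function(table, out_dir, stem = NULL) {
  if (is.null(stem)) stem <- sprintf("IHCdata_%d", table@siteIndex)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop(sprintf("cannot create output directory: %s", out_dir), call. = FALSE)
  dataPath <- file.path(out_dir, paste0(stem, ".csv"))
  headerPath <- file.path(out_dir, paste0(stem, "_header.txt"))
  utils::write.csv(table@data, dataPath, row.names = FALSE)
  writeLines(table@header, headerPath)
  invisible(c(data = dataPath, header = headerPath))
}

#' Read a feature table written by \code{\link{writeFeatureTable}}
#' @param data_path CSV path; the header sidecar is looked up next to it.
#' @param site site index to record.
#' @export
readFeatureTable <- function(data_path, site = 1L) {
  d <- utils::read.csv(data_path, check.names = FALSE)
  headerPath <- file.path(dirname(data_path),
    paste0(tools::file_path_sans_ext(basename(data_path)), "_header.txt"))
  header <- if (file.exists(headerPath)) readLines(headerPath) else colnames(d)
  new("CellFeatureTable", data = d, header = header, siteIndex = as.integer(site))
}
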