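## Per-cell measurement under the reference masks and feature-table
## assembly.  Statistic choices: mean for nuclear signal, median for the
## cytoplasmic ring (the median guards the narrow ring against bleed
## from bright neighbours); both documented, rings additionally gated by
## intensity and minimum size.

#' Mean signal per nucleus
#'
#' @param image preprocessed single-channel matrix.
#' @param mask a \code{LabelMask}.
#' @return numeric vector indexed by label id; a label with no pixels
#'   yields \code{NA}.
#' @export
measureNuclearSignal <- function(image, mask) {
  lbl <- labels(mask)
  if (!all(dim(lbl) == dim(image)))
    stop("mask and image shapes disagree", call. = FALSE)
  n <- max(lbl)
  if (n == 0) return(numeric(0))
  pos <- lbl > 0
  cnt <- tabulate(lbl[pos], nbins = n)
  sums <- as.vector(rowsum(image[pos], lbl[pos], reorder = TRUE))
  out <- rep(NA_real_, n)
  out[sort(unique(lbl[pos]))] <- sums / cnt[cnt > 0]
  out
}

#' Build cytoplasmic-ring labels around each nucleus
#'
#' The ring of nucleus i consists of pixels whose Euclidean distance to
#' i's mask lies in \code{(innerrad, outerrad]}, excluding pixels of any
#' nuclear mask and pixels closer to a different nucleus (nearest-nucleus
#' assignment; distance ties go to the lower label id).
#'
#' @param mask a \code{LabelMask} of nuclei.
#' @param innerrad,outerrad ring distances in pixels, outward from the
#'   nuclear mask, with \code{innerrad < outerrad}.
#' @return a \code{LabelMask} of rings sharing the nuclear ids.
#' @export
buildCytoring <- function(mask, innerrad = 1, outerrad = 5) {
  if (!(innerrad < outerrad))
    stop("innerrad must be smaller than outerrad", call. = FALSE)
  nn <- nearestNucleus(mask)
  lbl <- labels(mask)
  ring <- nn$dist > innerrad & nn$dist <= outerrad & lbl == 0
  out <- matrix(0L, nrow(lbl), ncol(lbl))
  out[ring] <- nn$assign[ring]
  new("LabelMask", labels = out)
}

## Running per-pixel (distance, id) of the nearest nucleus; exact
## Euclidean via one distance transform per label, ties to the lower id.
nearestNucleus <- function(mask) {
  lbl <- labels(mask)
  n <- max(lbl)
  H <- nrow(lbl); W <- ncol(lbl)
  dmin <- matrix(Inf, H, W)
  amin <- matrix(0L, H, W)
  for (i in seq_len(n)) {
    bin <- lbl == i
    if (!any(bin)) next
    di <- as.matrix(EBImage::distmap(1 - bin))
    upd <- di < dmin
    dmin[upd] <- di[upd]
    amin[upd] <- i
  }
  list(dist = dmin, assign = amin)
}

#' Median ring signal with intensity and size gating
#'
#' @param image single-channel matrix.
#' @param rings ring \code{LabelMask} from \code{\link{buildCytoring}}.
#' @param ringthresh minimum pixel intensity entering the median (0
#'   disables the gate).
#' @param minringsize minimum number of qualifying pixels; below it the
#'   cell's value is \code{NA}.
#' @return numeric vector indexed by ring id.
#' @export
measureCytoringSignal <- function(image, rings, ringthresh = 0,
                                  minringsize = 1) {
  lbl <- labels(rings)
  if (!all(dim(lbl) == dim(image)))
    stop("rings and image shapes disagree", call. = FALSE)
  n <- max(lbl)
  if (n == 0) return(numeric(0))
  out <- rep(NA_real_, n)
  pos <- which(lbl > 0)
  ids <- lbl[pos]
  vals <- image[pos]
  ok <- vals >= ringthresh
  for (i in seq_len(n)) {
    v <- vals[ids == i & ok]
    if (length(v) >= minringsize) out[i] <- stats::median(v)
  }
  out
}

#' Detect puncta per cell compartment
#'
#' A white top-hat with a disc of radius \code{punctatopsize} isolates
#' bright foci; pixels at or above \code{punctaThresh} form candidate
#' puncta (connected components).  Each punctum is assigned to the cell
#' whose compartment contains its peak pixel: the nucleus
#' (\code{cytopuncta = 0}) or the nucleus thickened by
#' \code{thickenradius} minus all nuclei (\code{cytopuncta = 1}).  Both
#' the punctum count and the integrated top-hat intensity are returned.
#'
#' @param image single-channel matrix.
#' @param nuclear_mask a \code{LabelMask}.
#' @param punctatopsize top-hat disc radius (px), > 0.
#' @param punctaThresh top-hat intensity threshold.
#' @param cytopuncta 0 = nuclear compartment, 1 = cytoplasmic.
#' @param thickenradius cytoplasm radius (px) for \code{cytopuncta = 1}.
#' @return list with numeric vectors \code{count} and \code{intensity},
#'   indexed by cell id.
#' @export
detectPuncta <- function(image, nuclear_mask, punctatopsize = 2,
                         punctaThresh = 0, cytopuncta = 0,
                         thickenradius = 24) {
  if (punctatopsize <= 0) stop("punctatopsize must be positive", call. = FALSE)
  lbl <- labels(nuclear_mask)
  n <- max(lbl)
  th <- whiteTopHatDisc(image, punctatopsize)
  compart <- if (cytopuncta > 0) {
    nn <- nearestNucleus(nuclear_mask)
    cy <- matrix(0L, nrow(lbl), ncol(lbl))
    sel <- nn$dist > 0 & nn$dist <= thickenradius & lbl == 0
    cy[sel] <- nn$assign[sel]
    cy
  } else lbl
  count <- rep(0, n)
  intensity <- rep(0, n)
  cand <- th >= punctaThresh & th > 0
  if (!any(cand) || n == 0)
    return(list(count = count, intensity = intensity))
  comp <- labelComponents(cand)
  for (k in seq_len(max(comp))) {
    pix <- which(comp == k)
    peak <- pix[which.max(th[pix])]
    cell <- compart[peak]
    if (cell > 0) {
      count[cell] <- count[cell] + 1
      intensity[cell] <- intensity[cell] + sum(th[pix])
    }
  }
  list(count = count, intensity = intensity)
}

#' Local background around each cell
#'
#' The \code{bgperctile}-th percentile of non-nuclear pixels inside a
#' square box of half-width \code{10 * nucr} centred on the cell.
#'
#' @param image single-channel matrix.
#' @param mask nuclear \code{LabelMask}.
#' @param bgperctile percentile (0-100).
#' @param nucr average nuclear radius (px).
#' @export
measureLocalBackground <- function(image, mask, bgperctile = 25, nucr = 8) {
  lbl <- labels(mask)
  n <- max(lbl)
  if (n == 0) return(numeric(0))
  cen <- objectCentroids(lbl)
  hw <- round(10 * nucr)
  fg <- lbl > 0
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    rows <- max(1, round(cen[i, "y"]) - hw):min(nrow(lbl), round(cen[i, "y"]) + hw)
    cols <- max(1, round(cen[i, "x"]) - hw):min(ncol(lbl), round(cen[i, "x"]) + hw)
    px <- image[rows, cols][!fg[rows, cols]]
    if (length(px)) out[i] <- percentileValue(px, bgperctile)
  }
  out
}

## Column plan for the feature table: measure keys, syntactic column
## names and human-readable header strings, derived from the settings.
featureColumnPlan <- function(settings) {
  p <- settings@params
  cols <- list(
    list(key = "x", name = "x", header = "x (nuclear centroid X, px)"),
    list(key = "y", name = "y", header = "y (nuclear centroid Y, px)"),
    list(key = "area", name = "nuclear_area",
         header = "nuclear area (pixels in each nuclear mask)"))
  for (r in seq_len(settings@nRounds)) {
    for (c in seq_len(settings@nChannels[r])) {
      sig <- p$signals[[r]][c]
      base <- sprintf("r%d_%s", r, gsub("[^A-Za-z0-9]", "_", sig))
      lab <- sprintf("%s round %d", sig, r)
      cols <- c(cols, list(list(key = sprintf("nuc_%d_%d", r, c),
                                name = paste0(base, "_nuc"),
                                header = paste(lab, "nuclear signal"))))
      if (p$ringcalc[[r]][c] > 0)
        cols <- c(cols, list(list(key = sprintf("ring_%d_%d", r, c),
                                  name = paste0(base, "_cytoring"),
                                  header = paste(lab, "cytoring signal"))))
      if (p$punctacalc[[r]][c] > 0)
        cols <- c(cols, list(
          list(key = sprintf("pcount_%d_%d", r, c),
               name = paste0(base, "_puncta_n"),
               header = paste(lab, "puncta count")),
          list(key = sprintf("pint_%d_%d", r, c),
               name = paste0(base, "_puncta_int"),
               header = paste(lab, "puncta integrated intensity"))))
      if (p$localbg[[r]][c] > 0)
        cols <- c(cols, list(list(key = sprintf("lbg_%d_%d", r, c),
                                  name = paste0(base, "_localbg"),
                                  header = paste(lab, "local background"))))
    }
  }
  c(cols, list(list(key = "ecad", name = "ecad_positive",
                    header = "E-cadherin positive/negative classification")))
}

#' Assemble the per-cell feature table
#'
#' One row per reference-round cell: centroid x/y, nuclear area, then per
#' round and channel the enabled measures in the documented header order,
#' then the E-cadherin flag.  Missing values are propagated as \code{NA},
#' never zeroed.
#'
#' @param mask reference nuclear \code{LabelMask}.
#' @param measures nested list \code{measures[[r]][[c]]} with components
#'   \code{nuc}, and optionally \code{ring}, \code{pcount}, \code{pint},
#'   \code{lbg}, each a vector indexed by cell id.
#' @param ecad_flags logical vector per cell (or \code{NULL}: all
#'   \code{NA}).
#' @param settings an \code{IFSettings}.
#' @param site site index recorded on the table.
#' @return a \code{\linkS4class{CellFeatureTable}}.
#' @export
assembleFeatureTable <- function(mask, measures, ecad_flags, settings,
                                 site = 1L) {
  lbl <- labels(mask)
  n <- max(lbl)
  cen <- objectCentroids(lbl)
  areas <- objectAreas(lbl)
  plan <- featureColumnPlan(settings)
  vals <- list(
    x = if (n) cen[, "x"] else numeric(0),
    y = if (n) cen[, "y"] else numeric(0),
    area = as.numeric(areas),
    ecad = if (is.null(ecad_flags)) rep(NA, n) else as.logical(ecad_flags))
  if (!is.null(ecad_flags) && length(ecad_flags) != n)
    stop("ecad flag count disagrees with the number of cells", call. = FALSE)
  getMeasure <- function(r, c, what) {
    v <- measures[[r]][[c]][[what]]
    if (is.null(v)) return(rep(NA_real_, n))
    if (length(v) != n)
      stop(sprintf("measure '%s' (round %d, channel %d) has %d value(s) for %d cell(s)",
                   what, r, c, length(v), n), call. = FALSE)
    v
  }
  df <- list()
  header <- character(0)
  for (col in plan) {
    key <- col$key
    v <- if (key %in% names(vals)) vals[[key]] else {
      parts <- strsplit(key, "_")[[1]]
      getMeasure(as.integer(parts[2]), as.integer(parts[3]), parts[1])
    }
    df[[col$name]] <- v
    header <- c(header, col$header)
  }
  data <- as.data.frame(df, optional = TRUE)
  if (n == 0) data <- data[0, , drop = FALSE]
  new("CellFeatureTable", data = data, header = header,
      siteIndex = as.integer(site))
}
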