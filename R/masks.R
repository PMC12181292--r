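#' Label connected foreground components
#'
#' Labels maximal connected components of a binary foreground with integers
#' `1..k` in raster-scan (row-major) discovery order. Pixel coordinates are
#' 0-based `(row, column)` throughout the package.
#'
#' @param binary a logical matrix (or anything coercible: positive values are
#'   foreground).
#' @param connectivity 4 or 8 (default 8, the convention for bright blobs on a
#'   dark background; 4 is exposed for sensitivity checks).
#' @return a [LabelMask].
#' @examples
#' b <- matrix(FALSE, 3, 3); b[1, 1] <- b[2, 2] <- TRUE
#' nRoi(connectedComponents(b, 8))  # 1: diagonal pixels touch
#' nRoi(connectedComponents(b, 4))  # 2
#' @export
connectedComponents <- function(binary, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  if (is(binary, "LabelMask")) binary <- maskData(binary) > 0L
  if (is(binary, "ChannelImage")) binary <- pixelData(binary) > 0L
  if (!is.matrix(binary)) stop("binary must be a matrix")
  if (!is.logical(binary)) binary <- binary > 0
  LabelMask(cc_label(binary, as.integer(connectivity)))
}

#' Per-ROI area and equivalent diameter table
#'
#' One row per positive label: the exact pixel count and the equivalent-area
#' circular diameter `2 * sqrt(area / pi)`. The mean equivalent diameter over
#' a training set is the natural `diameterPx` for a single-cell segmenter
#' backend (7.06 px for this workflow's single-cell model).
#'
#' @param mask a [LabelMask].
#' @return a data.frame with columns `label`, `area_px`,
#'   `equivalent_diameter_px`, ordered by label.
#' @export
roiTable <- function(mask) {
  stopifnot(is(mask, "LabelMask"))
  lb <- maskData(mask)
  counts <- tabulate(lb[lb > 0L])
  labels <- which(counts > 0L)
  data.frame(label = labels, area_px = counts[labels],
             equivalent_diameter_px = 2 * sqrt(counts[labels] / pi))
}

#' Retain ROIs within an area range
#'
#' Keeps ROIs whose pixel area lies in the inclusive interval
#' `[minPx, maxPx]` (original labels preserved) and zeroes all others. The
#' default bounds 500-15,000 px operationalise "microcolony": they are the
#' filter used to bootstrap a microcolony training set from single-cell
#' segmentations.
#'
#' @param mask a [LabelMask].
#' @param minPx,maxPx inclusive area bounds in pixels.
#' @return a [LabelMask] whose ROI set is a subset of the input's.
#' @export
filterByArea <- function(mask, minPx = 500L, maxPx = 15000L) {
  stopifnot(is(mask, "LabelMask"))
  if (minPx > maxPx) stop("minPx must not exceed maxPx")
  if (minPx < 0) stop("area bounds must be non-negative")
  lb <- maskData(mask)
  if (!any(lb > 0L)) return(LabelMask(lb))
  counts <- tabulate(lb[lb > 0L])
  keep <- which(counts >= minPx & counts <= maxPx)
  out <- lb
  out[!(lb %in% keep)] <- 0L
  LabelMask(out)
}

#' Zero image intensities under labelled regions
#'
#' Sets every pixel lying under a positive label to intensity 0 and leaves all
#' other pixels untouched. This is the interference-removal step of the
#' second quantification method: manually labelled disturbing regions and/or
#' segmented human cells are blanked before thresholding.
#'
#' @param img a [ChannelImage].
#' @param regions a [LabelMask] of the same shape.
#' @return a [ChannelImage]; provenance is preserved.
#' @export
subtractRegions <- function(img, regions) {
  stopifnot(is(img, "ChannelImage"), is(regions, "LabelMask"))
  if (!identical(dim(img), dim(regions)))
    stop("image and region mask shapes differ")
  px <- pixelData(img)
  px[maskData(regions) > 0L] <- 0L
  ChannelImage(px, bitDepth = bitDepth(img), provenance = provenance(img))
}

#' Combine two instance masks with overlap precedence
#'
#' Merges the predictions of two segmenters operating at different object
#' scales (a microcolony-scale mask and a single-cell-scale mask) into one
#' label mask. Every ROI of `primary` is kept; each ROI of `secondary` is
#' added only where it does not overlap primary foreground. Overlapping
#' pixels are assigned to the primary ROI; a secondary ROI entirely covered
#' by primary foreground is dropped; a secondary ROI that the subtraction
#' splits into several components keeps a single label (component integrity
#' is restored by the downstream manual-correction step). Output labels are
#' consecutive `1..k`, primary ROIs first.
#'
#' The combined foreground is always the exact pixel-set union of the two
#' input foregrounds, whichever mask takes precedence.
#'
#' @param primary the precedence-taking [LabelMask] (microcolony-scale role).
#' @param secondary the [LabelMask] filled in around it (single-cell role).
#' @param precedence `"primary"` (default) or `"secondary"`; the latter swaps
#'   the roles, since the overlap convention of the combination is not
#'   canonical and either is tolerated by manual correction.
#' @return a [LabelMask] with consecutive labels.
#' @export
combineMasks <- function(primary, secondary,
                         precedence = c("primary", "secondary")) {
  precedence <- match.arg(precedence)
  stopifnot(is(primary, "LabelMask"), is(secondary, "LabelMask"))
  if (!identical(dim(primary), dim(secondary)))
    stop("mask shapes differ")
  if (precedence == "secondary")
    return(combineMasks(secondary, primary, "primary"))
  pl <- maskData(primary)
  sl <- maskData(secondary)
  pLabels <- sort(unique(pl[pl > 0L]))
  out <- integer(length(pl))
  dim(out) <- dim(pl)
  sel <- pl > 0L
  out[sel] <- match(pl[sel], pLabels)
  slRem <- sl
  slRem[sel] <- 0L                      # overlap goes to the primary ROI
  sLabels <- sort(unique(slRem[slRem > 0L]))
  sel2 <- slRem > 0L
  out[sel2] <- length(pLabels) + match(slRem[sel2], sLabels)
  LabelMask(out)
}

#' Crop an image/mask pair into congruent tiles
#'
#' Non-overlapping `tile x tile` crops in raster order (row blocks first),
#' cropping image and mask congruently with labels preserved. Trailing
#' partial tiles are discarded, keeping exported tiles identically sized for
#' training-set use.
#'
#' @param img a [ChannelImage].
#' @param mask a [LabelMask] of the same shape.
#' @param tile tile side length in pixels (default 256, the training-tile
#'   size of the microcolony model).
#' @return a list of tiles, each a list with elements `image`
#'   ([ChannelImage]), `mask` ([LabelMask]) and 0-based offsets `row0`,
#'   `col0`.
#' @export
cropTiles <- function(img, mask, tile = 256L) {
  stopifnot(is(img, "ChannelImage"), is(mask, "LabelMask"))
  if (!identical(dim(img), dim(mask))) stop("image and mask shapes differ")
  tile <- as.integer(tile)
  d <- dim(img)
  if (tile < 1L) stop("tile size must be positive")
  if (tile > min(d)) stop("tile size exceeds image dimensions")
  px <- pixelData(img)
  lb <- maskData(mask)
  out <- list()
  for (br in seq_len(d[1] %/% tile) - 1L) {
    for (bc in seq_len(d[2] %/% tile) - 1L) {
      rows <- br * tile + seq_len(tile)
      cols <- bc * tile + seq_len(tile)
      out[[length(out) + 1L]] <- list(
        image = ChannelImage(px[rows, cols, drop = FALSE],
                             bitDepth = bitDepth(img),
                             provenance = provenance(img)),
        mask = LabelMask(lb[rows, cols, drop = FALSE]),
        row0 = br * tile, col0 = bc * tile)
    }
  }
  out
}
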