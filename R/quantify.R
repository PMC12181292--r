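#' Construct a coverage record
#'
#' One row of the coverage table: the per-image surface-coverage percentage
#' with its provenance (method used, pixel counts, persisted mask). The
#' invariant `coverage_pct == 100 * foreground_px / denominator_px` holds
#' exactly.
#'
#' @param imageId image identifier.
#' @param method quantification method, 1, 2 or 3.
#' @param foregroundPx number of pixels classified as microbial.
#' @param denominatorPx total number of pixels in the denominator.
#' @param maskPath path of the persisted mask (`NA` if not persisted).
#' @return a one-row data.frame with columns `image_id`, `method`,
#'   `coverage_pct`, `foreground_px`, `denominator_px`, `mask_path`.
#' @export
coverageRecord <- function(imageId, method, foregroundPx, denominatorPx,
                           maskPath = NA_character_) {
  if (!method %in% 1:3) stop("method must be 1, 2 or 3")
  if (denominatorPx <= 0) stop("denominator must be positive")
  if (foregroundPx < 0 || foregroundPx > denominatorPx)
    stop("foreground pixel count out of range")
  data.frame(image_id = as.character(imageId), method = as.integer(method),
             coverage_pct = 100 * foregroundPx / denominatorPx,
             foreground_px = as.integer(foregroundPx),
             denominator_px = as.integer(denominatorPx),
             mask_path = as.character(maskPath))
}

.persistMask <- function(mask, maskPath) {
  if (is.null(maskPath)) return(NA_character_)
  writeLabelMask(mask, maskPath)
  maskPath
}

#' Method 1: coverage by global thresholding
#'
#' For images entirely covered by biofilm, with no disturbing signals: pixels
#' with intensity strictly greater than `threshold` (default 50, 8-bit scale)
#' are classified as microorganisms and coverage is their fraction of all
#' image pixels. The thresholded foreground is labelled into ROIs so the
#' persisted mask can be corrected or re-ingested like any other.
#'
#' @param img a preprocessed 8-bit [ChannelImage].
#' @param threshold intensity threshold (strict; default 50).
#' @param imageId image identifier for the record.
#' @param maskPath optional path to persist the mask (16-bit TIFF).
#' @return a list with `record` (see [coverageRecord()]) and `mask`
#'   ([LabelMask]).
#' @export
quantifyThreshold <- function(img, threshold = 50L, imageId = "image",
                              maskPath = NULL) {
  mask <- builtinThresholdSegment(img, threshold)
  rec <- coverageRecord(imageId, 1L, sum(maskData(mask) > 0L),
                        length(pixelData(img)),
                        .persistMask(mask, maskPath))
  list(record = rec, mask = mask)
}

#' Method 2: interference subtraction, then thresholding
#'
#' For images with few disturbing signals (human cells, labelled background
#' artefacts): the interference regions — typically the union of manually
#' labelled areas and a human-cell segmenter's output, see
#' [buildInterferenceMask()] — are blanked to intensity 0, then the
#' thresholding of method 1 is applied. By default the denominator remains
#' the total pixel count: subtraction zeroes intensities rather than cropping
#' the field of view, so subtracted pixels count as non-microbial surface.
#' Set `excludeInterference = TRUE` to drop them from the denominator
#' instead.
#'
#' @param img a preprocessed 8-bit [ChannelImage].
#' @param interference a [LabelMask] of regions to blank, same shape.
#' @param threshold intensity threshold (strict; default 50).
#' @param imageId image identifier for the record.
#' @param maskPath optional path to persist the mask.
#' @param excludeInterference drop interference pixels from the denominator.
#' @return a list with `record` and `mask`, as [quantifyThreshold()]. With an
#'   empty interference mask the result is identical to method 1.
#' @export
quantifySubtracted <- function(img, interference, threshold = 50L,
                               imageId = "image", maskPath = NULL,
                               excludeInterference = FALSE) {
  cleaned <- subtractRegions(img, interference)
  mask <- builtinThresholdSegment(cleaned, threshold)
  denom <- length(pixelData(img)) -
    if (excludeInterference) sum(maskData(interference) > 0L) else 0L
  rec <- coverageRecord(imageId, 2L, sum(maskData(mask) > 0L), denom,
                        .persistMask(mask, maskPath))
  list(record = rec, mask = mask)
}

#' Union of manual interference regions and segmented human cells
#'
#' Builds the interference mask of method 2 from either or both sources: a
#' manually labelled mask (e.g. drawn in an external GUI) and the output of a
#' human-cell segmenter backend applied to the image.
#'
#' @param img the preprocessed [ChannelImage] (segmented only if
#'   `humanCellSpec` is given).
#' @param manualMask optional [LabelMask] of manually labelled regions.
#' @param humanCellSpec optional [SegmenterSpec] for a human-cell model.
#' @return a [LabelMask] covering the union of both sources.
#' @export
buildInterferenceMask <- function(img, manualMask = NULL,
                                  humanCellSpec = NULL) {
  if (is.null(manualMask) && is.null(humanCellSpec))
    stop("method 2 requires a manual interference mask, a human-cell ",
         "segmenter spec, or both")
  parts <- list()
  if (!is.null(manualMask)) parts <- c(parts, list(manualMask))
  if (!is.null(humanCellSpec))
    parts <- c(parts, list(segmentImage(img, humanCellSpec)))
  Reduce(combineMasks, parts)
}

#' Method 3: dual-model segmentation and mask combination
#'
#' For images with substantial background noise or many human cells: the
#' image is segmented twice, by a single-cell-scale backend and a
#' microcolony-scale backend, and the two predictions are merged with
#' [combineMasks()] (microcolony mask taking precedence on overlaps).
#' Coverage is computed from the combined mask, which is persisted for
#' external manual correction; after correction, re-ingest the edited mask
#' with [coverageFromMask()] — coverage is always recomputed from the final
#' mask file, so corrections flow through without special-casing.
#'
#' Coverage is invariant to swapping the two backends (the combined
#' foreground is the union either way); only label precedence differs.
#'
#' @param img a preprocessed 8-bit [ChannelImage].
#' @param smallSpec [SegmenterSpec] for the single-cell-scale model.
#' @param largeSpec [SegmenterSpec] for the microcolony-scale model.
#' @param imageId image identifier for the record.
#' @param maskPath optional path to persist the combined mask.
#' @param precedence overlap precedence of [combineMasks()]; default gives
#'   overlapping pixels to the microcolony mask.
#' @return a list with `record` and `mask` (the combined [LabelMask]).
#' @export
quantifyDualModel <- function(img, smallSpec, largeSpec, imageId = "image",
                              maskPath = NULL,
                              precedence = c("primary", "secondary")) {
  segSmall <- segmentImage(img, smallSpec)
  segLarge <- segmentImage(img, largeSpec)
  combined <- combineMasks(primary = segLarge, secondary = segSmall,
                           precedence = match.arg(precedence))
  rec <- coverageRecord(imageId, 3L, sum(maskData(combined) > 0L),
                        length(pixelData(img)),
                        .persistMask(combined, maskPath))
  list(record = rec, mask = combined)
}

#' Recompute coverage from a (corrected) mask
#'
#' First-class re-ingestion step for externally corrected masks: reads the
#' mask (or takes it directly) and recomputes the coverage record from its
#' foreground, with the total pixel count as denominator.
#'
#' @param mask a [LabelMask] or a path to a mask file.
#' @param imageId image identifier for the record.
#' @param method the method number to record (default 3, the usual source of
#'   corrected masks).
#' @return a one-row coverage record data.frame.
#' @export
coverageFromMask <- function(mask, imageId = "image", method = 3L) {
  maskPath <- NA_character_
  if (is.character(mask)) {
    maskPath <- mask
    mask <- readLabelMask(mask)
  }
  stopifnot(is(mask, "LabelMask"))
  coverageRecord(imageId, method, sum(maskData(mask) > 0L),
                 length(maskData(mask)), maskPath)
}

#' Bootstrap a microcolony training set from existing segmentations
#'
#' Turns corrected single-cell-era segmentations into training material for a
#' microcolony-scale model: each mask is filtered to ROIs in the microcolony
#' size range (500-15,000 px by default), the image/mask pairs are cut into
#' congruent tiles (256 px by default), and tiles whose mask is empty are
#' dropped. Splitting the exported tiles into training and testing subsets is
#' left to the caller.
#'
#' @param imgs list of [ChannelImage]s.
#' @param masks list of congruent [LabelMask]s, same length.
#' @param minPx,maxPx inclusive microcolony area bounds.
#' @param tile tile side length in pixels.
#' @param outDir optional directory; when given, tiles are written in the
#'   conventional training layout (`tile_<i>_<j>.tif` +
#'   `tile_<i>_<j>_masks.tif`).
#' @return (invisibly when `outDir` is given) a list of kept tiles, each a
#'   list with `image`, `mask`, `source` (input index), `row0`, `col0`.
#' @export
buildMicrocolonyTrainingSet <- function(imgs, masks, minPx = 500L,
                                        maxPx = 15000L, tile = 256L,
                                        outDir = NULL) {
  if (length(imgs) != length(masks))
    stop("imgs and masks must have the same length")
  out <- list()
  for (i in seq_along(imgs)) {
    filtered <- filterByArea(masks[[i]], minPx, maxPx)
    for (tl in cropTiles(imgs[[i]], filtered, tile)) {
      if (!any(maskData(tl$mask) > 0L)) next
      tl$source <- i
      out[[length(out) + 1L]] <- tl
    }
  }
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(out)) {
      tl <- out[[k]]
      base <- sprintf("tile_%03d_%d_%d", tl$source, tl$row0, tl$col0)
      writeChannelImage(tl$image, file.path(outDir, paste0(base, ".tif")))
      writeLabelMask(validateLabelMask(tl$mask),
                     file.path(outDir, paste0(base, "_masks.tif")))
    }
    return(invisible(out))
  }
  out
}

#' Describe a per-image method assignment
#'
#' The choice among the three quantification methods is made manually on an
#' image-by-image basis; this record is its durable encoding, used by
#' [runPipeline()]. Method 2 requires at least one interference source;
#' method 3 requires both segmenter specs.
#'
#' @param imageId image identifier, matching the run manifest.
#' @param method 1, 2 or 3.
#' @param threshold threshold for methods 1 and 2 (default 50).
#' @param interferenceMaskPath optional path to a manual interference mask
#'   (method 2).
#' @param humanCellSpec optional [SegmenterSpec] for a human-cell model
#'   (method 2).
#' @param smallSpec,largeSpec [SegmenterSpec]s for method 3.
#' @return a list of class `MethodAssignment`.
#' @export
methodAssignment <- function(imageId, method, threshold = 50L,
                             interferenceMaskPath = NULL,
                             humanCellSpec = NULL, smallSpec = NULL,
                             largeSpec = NULL) {
  if (!method %in% 1:3) stop("method must be 1, 2 or 3")
  if (method == 2L && is.null(interferenceMaskPath) && is.null(humanCellSpec))
    stop("method 2 requires interferenceMaskPath and/or humanCellSpec")
  if (method == 3L && (is.null(smallSpec) || is.null(largeSpec)))
    stop("method 3 requires both smallSpec and largeSpec")
  structure(list(imageId = as.character(imageId), method = as.integer(method),
                 threshold = as.integer(threshold),
                 interferenceMaskPath = interferenceMaskPath,
                 humanCellSpec = humanCellSpec, smallSpec = smallSpec,
                 largeSpec = largeSpec),
            class = "MethodAssignment")
}
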