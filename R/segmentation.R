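# Registry of external segmenter backends. A backend is a function
# (ChannelImage, SegmenterSpec) -> LabelMask-like; its raw output is always
# passed through validateLabelMask(), so adapters may return plain integer
# matrices.
.backendRegistry <- new.env(parent = emptyenv())

#' Register / list external segmenter backends
#'
#' The segmentation contract keeps neural-network segmenters (e.g. Cellpose
#' models: a custom single-cell model, a custom microcolony model, or the
#' pretrained human-cell model 'cyto2') outside the package: an adapter is
#' registered under the model name a [SegmenterSpec] refers to, takes the
#' image plus the spec (carrying `diameterPx` and opaque `extraParams`, such
#' as flow or cell-probability thresholds), and returns a label mask. Users
#' who train their own models typically do so externally with a
#' human-in-the-loop procedure; the adapter only performs inference.
#'
#' @param modelName name the backend is registered under (matched against
#'   `modelName` of a [SegmenterSpec]).
#' @param fun function `(img, spec)` returning a [LabelMask] or an integer
#'   matrix.
#' @return `registerSegmenterBackend` returns `modelName` invisibly;
#'   `registeredBackends` returns a character vector of registered names.
#' @export
registerSegmenterBackend <- function(modelName, fun) {
  stopifnot(is.character(modelName), length(modelName) == 1L, is.function(fun))
  assign(modelName, fun, envir = .backendRegistry)
  invisible(modelName)
}

#' @rdname registerSegmenterBackend
#' @export
registeredBackends <- function() sort(ls(.backendRegistry))

#' Validate and relabel an arbitrary label image
#'
#' Normalises any integer matrix into a valid [LabelMask]: negative values
#' become background, empty labels are dropped, and the remaining labels are
#' relabelled to consecutive `1..k` in increasing order of their original
#' value. External backend output is always passed through this validation.
#'
#' @param x an integer matrix, or a [LabelMask].
#' @return a [LabelMask] with consecutive labels `1..k`.
#' @export
validateLabelMask <- function(x) {
  if (is(x, "LabelMask")) x <- maskData(x)
  if (!is.matrix(x)) stop("expected a matrix of labels")
  if (anyNA(x)) stop("label matrix contains NA")
  x <- .roundHalfUp(x)
  storage.mode(x) <- "integer"
  x[x < 0L] <- 0L
  labels <- sort(unique(x[x > 0L]))
  if (length(labels) && !identical(labels, seq_along(labels))) {
    sel <- x > 0L
    x[sel] <- match(x[sel], labels)
  }
  LabelMask(x)
}

#' Reference segmenter: global threshold + connected components
#'
#' The package's built-in deterministic segmenter, reusing the workflow's
#' quantification threshold as a detector: pixels with intensity strictly
#' greater than `threshold` (on the 8-bit scale) are foreground, which is then
#' split into ROIs by connected-component labelling. It exists so that the
#' quantification methods and the evaluation suite are fully exercisable
#' without any neural-network dependency.
#'
#' @param img an 8-bit [ChannelImage].
#' @param threshold intensity threshold in `[0, 255]` (default 50; foreground
#'   is strictly greater).
#' @param connectivity 4 or 8 (default 8).
#' @return a [LabelMask].
#' @export
builtinThresholdSegment <- function(img, threshold = 50L, connectivity = 8L) {
  stopifnot(is(img, "ChannelImage"))
  if (bitDepth(img) != 8L)
    stop("the builtin segmenter expects an 8-bit image")
  if (threshold < 0 || threshold > 255)
    stop("threshold must lie in [0, 255]")
  connectedComponents(pixelData(img) > threshold, connectivity)
}

#' Segment an image through a backend specification
#'
#' Dispatches on the `backendId` of a [SegmenterSpec]. For
#' `"builtin-threshold"` the mask comes from [builtinThresholdSegment()],
#' optionally restricted by `minArea`/`maxArea` from `extraParams` (so two
#' builtin specs partitioned at an area cutoff can emulate the single-cell /
#' microcolony model pair). For `"external"` the registered backend adapter
#' named by `modelName` is invoked; a missing adapter is an explicit error,
#' never a silent fallback. All backend output passes through
#' [validateLabelMask()].
#'
#' @param img an 8-bit [ChannelImage].
#' @param spec a [SegmenterSpec].
#' @return a [LabelMask] of the same shape, labels consecutive `1..k`.
#' @export
segmentImage <- function(img, spec) {
  stopifnot(is(img, "ChannelImage"), is(spec, "SegmenterSpec"))
  validObject(spec)
  ep <- spec@extraParams
  if (spec@backendId == "builtin-threshold") {
    mask <- builtinThresholdSegment(img,
      threshold = ep$threshold %||% 50L,
      connectivity = ep$connectivity %||% 8L)
    minA <- ep$minArea %||% 1L
    maxA <- ep$maxArea %||% Inf
    if (minA > 1L || is.finite(maxA))
      mask <- filterByArea(mask, minA, maxA)
  } else {
    if (!exists(spec@modelName, envir = .backendRegistry, inherits = FALSE))
      stop("external segmentation backend '", spec@modelName,
           "' is not registered; see registerSegmenterBackend()")
    fun <- get(spec@modelName, envir = .backendRegistry)
    mask <- fun(img, spec)
  }
  out <- validateLabelMask(mask)
  if (!identical(dim(out), dim(img)))
    stop("backend returned a mask of shape ", paste(dim(out), collapse = "x"),
         " for an image of shape ", paste(dim(img), collapse = "x"))
  out
}
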