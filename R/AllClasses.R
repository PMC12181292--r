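#' @useDynLib micov, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

.maxIntensity <- function(bitDepth) 2^bitDepth - 1

#' ImageStack: a single-channel confocal z-stack
#'
#' Ordered 2-D intensity planes from one fluorescence channel of a confocal
#' z-stack, in acquisition z-order. All planes share one height x width;
#' intensities live on the integer scale of `bitDepth` (8 or 16 bit).
#'
#' @slot planes list of integer matrices (row-major pixel grids), one per
#'   optical section.
#' @slot channelName channel tag, e.g. `"green"` for a Syto9-type channel.
#' @slot bitDepth integer, 8 or 16.
#' @slot pixelSizeUm optional physical pixel size in micrometres (`NA` if
#'   unknown; nothing in the workflow requires it).
#'
#' @seealso [readImageStack()], [maxIntensityProjection()]
#' @export
setClass("ImageStack",
  representation(planes = "list", channelName = "character",
                 bitDepth = "integer", pixelSizeUm = "numeric"),
  prototype(channelName = "green", bitDepth = 8L, pixelSizeUm = NA_real_))

setValidity("ImageStack", function(object) {
  if (length(object@planes) < 1L) return("stack must contain at least one plane")
  if (!object@bitDepth %in% c(8L, 16L)) return("bitDepth must be 8 or 16")
  dims <- lapply(object@planes, dim)
  if (any(vapply(dims, is.null, logical(1))))
    return("every plane must be a matrix")
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    return("all planes must share identical dimensions")
  mx <- .maxIntensity(object@bitDepth)
  for (p in object@planes) {
    if (anyNA(p)) return("plane intensities must not contain NA")
    if (min(p) < 0 || max(p) > mx)
      return(sprintf("intensities must lie in [0, %d]", mx))
  }
  TRUE
})

#' @param planes list of integer matrices, one per z-plane.
#' @param channelName channel tag (default `"green"`).
#' @param bitDepth 8 or 16.
#' @param pixelSizeUm optional pixel size in micrometres.
#' @rdname ImageStack-class
#' @export
ImageStack <- function(planes, channelName = "green", bitDepth = 8L,
                       pixelSizeUm = NA_real_) {
  if (is.matrix(planes)) planes <- list(planes)
  planes <- lapply(planes, function(p) {
    storage.mode(p) <- "integer"
    p
  })
  new("ImageStack", planes = planes, channelName = channelName,
      bitDepth = as.integer(bitDepth), pixelSizeUm = as.numeric(pixelSizeUm))
}

#' ChannelImage: one 2-D intensity plane
#'
#' A single 2-D image, typically the composite produced by maximum-intensity
#' projection and subsequent preprocessing. The `provenance` tag records the
#' last processing step applied (`"raw"`, `"projected"`, `"flatfielded"` or
#' `"adjusted"`).
#'
#' @slot pixels integer matrix of intensities.
#' @slot bitDepth integer, 8 or 16.
#' @slot provenance processing-step tag.
#'
#' @seealso [preprocessImage()], [to8bit()]
#' @export
setClass("ChannelImage",
  representation(pixels = "matrix", bitDepth = "integer",
                 provenance = "character"),
  prototype(bitDepth = 8L, provenance = "raw"))

setValidity("ChannelImage", function(object) {
  if (!object@bitDepth %in% c(8L, 16L)) return("bitDepth must be 8 or 16")
  if (anyNA(object@pixels)) return("pixels must not contain NA")
  mx <- .maxIntensity(object@bitDepth)
  if (min(object@pixels) < 0 || max(object@pixels) > mx)
    return(sprintf("pixel values must lie in [0, %d]", mx))
  TRUE
})

#' @param pixels integer matrix.
#' @param bitDepth 8 or 16.
#' @param provenance processing-step tag.
#' @rdname ChannelImage-class
#' @export
ChannelImage <- function(pixels, bitDepth = 8L, provenance = "raw") {
  storage.mode(pixels) <- "integer"
  new("ChannelImage", pixels = pixels, bitDepth = as.integer(bitDepth),
      provenance = provenance)
}

#' LabelMask: instance-labelled 2-D mask
#'
#' Integer image in which 0 is background and each positive integer labels one
#' region of interest (ROI): a single microorganism, a chain, a microcolony or
#' a human cell. Labels need not be consecutive but identify one nonempty
#' pixel set each.
#'
#' @slot labels non-negative integer matrix.
#'
#' @seealso [connectedComponents()], [roiTable()], [validateLabelMask()]
#' @export
setClass("LabelMask", representation(labels = "matrix"))

setValidity("LabelMask", function(object) {
  if (anyNA(object@labels)) return("labels must not contain NA")
  if (!is.integer(object@labels)) return("labels must be stored as integers")
  if (length(object@labels) && min(object@labels) < 0)
    return("labels must be non-negative")
  TRUE
})

#' @param labels non-negative integer matrix.
#' @rdname LabelMask-class
#' @export
LabelMask <- function(labels) {
  storage.mode(labels) <- "integer"
  new("LabelMask", labels = labels)
}

#' Preprocessing parameters
#'
#' Parameters of the preprocessing chain: the Gaussian scale of the flatfield
#' shading estimate and the saturation fractions of the percentile contrast
#' stretch.
#'
#' @slot sigma Gaussian scale in pixels for the shading estimate (default 50).
#' @slot lowSaturationFrac fraction of pixels saturated to black (default 0.01).
#' @slot highSaturationFrac fraction of pixels saturated to white (default 0.01).
#'
#' @seealso [preprocessImage()]
#' @export
setClass("PreprocessParams",
  representation(sigma = "numeric", lowSaturationFrac = "numeric",
                 highSaturationFrac = "numeric"),
  prototype(sigma = 50, lowSaturationFrac = 0.01, highSaturationFrac = 0.01))

setValidity("PreprocessParams", function(object) {
  if (object@sigma <= 0) return("sigma must be positive")
  lo <- object@lowSaturationFrac; hi <- object@highSaturationFrac
  if (lo < 0 || lo >= 0.5 || hi < 0 || hi >= 0.5)
    return("saturation fractions must lie in [0, 0.5)")
  if (lo + hi >= 1) return("saturation fractions must sum to less than 1")
  TRUE
})

#' @param sigma Gaussian scale in pixels.
#' @param lowSaturationFrac,highSaturationFrac saturation fractions in [0, 0.5).
#' @rdname PreprocessParams-class
#' @export
preprocessParams <- function(sigma = 50, lowSaturationFrac = 0.01,
                             highSaturationFrac = 0.01) {
  new("PreprocessParams", sigma = sigma,
      lowSaturationFrac = lowSaturationFrac,
      highSaturationFrac = highSaturationFrac)
}

#' Segmenter backend specification
#'
#' Describes how an image is to be segmented into a label mask. The
#' `"builtin-threshold"` backend is the package's deterministic reference
#' segmenter (global intensity threshold + connected components, with optional
#' ROI-area limits). The `"external"` backend dispatches to a registered
#' neural-network segmenter (e.g. Cellpose-style models in the roles of a
#' single-cell model, a microcolony model, or a pretrained human-cell model);
#' `modelName` selects the registered backend and `diameterPx` carries the
#' expected object diameter (the workflow's single-cell role uses 7.06 px, the
#' mean ROI equivalent diameter of its training data).
#'
#' @slot backendId `"builtin-threshold"` or `"external"`.
#' @slot modelName backend model identifier (required for `"external"`).
#' @slot diameterPx optional expected object diameter in pixels.
#' @slot extraParams opaque named list passed to the backend. The builtin
#'   backend honours `threshold` (default 50), `connectivity` (4 or 8) and
#'   `minArea`/`maxArea` ROI-size limits.
#'
#' @seealso [segmentImage()], [registerSegmenterBackend()]
#' @export
setClass("SegmenterSpec",
  representation(backendId = "character", modelName = "character",
                 diameterPx = "numeric", extraParams = "list"),
  prototype(backendId = "builtin-threshold", modelName = NA_character_,
            diameterPx = NA_real_, extraParams = list()))

setValidity("SegmenterSpec", function(object) {
  if (!object@backendId %in% c("builtin-threshold", "external"))
    return("backendId must be 'builtin-threshold' or 'external'")
  if (object@backendId == "external" &&
      (is.na(object@modelName) || !nzchar(object@modelName)))
    return("external backend requires a modelName")
  if (!is.na(object@diameterPx) && object@diameterPx <= 0)
    return("diameterPx must be positive")
  TRUE
})

#' @param backendId `"builtin-threshold"` or `"external"`.
#' @param modelName model identifier for external backends.
#' @param diameterPx expected object diameter in pixels.
#' @param extraParams named list of backend parameters.
#' @rdname SegmenterSpec-class
#' @export
segmenterSpec <- function(backendId = "builtin-threshold",
                          modelName = NA_character_, diameterPx = NA_real_,
                          extraParams = list()) {
  new("SegmenterSpec", backendId = backendId,
      modelName = as.character(modelName), diameterPx = as.numeric(diameterPx),
      extraParams = extraParams)
}

# ---- accessor generics -------------------------------------------------------

#' @rdname ImageStack-class
#' @param x,object a micov object.
#' @export
setGeneric("planes", function(x) standardGeneric("planes"))
#' @rdname ImageStack-class
#' @export
setMethod("planes", "ImageStack", function(x) x@planes)

#' @rdname ImageStack-class
#' @export
setGeneric("channelName", function(x) standardGeneric("channelName"))
#' @rdname ImageStack-class
#' @export
setMethod("channelName", "ImageStack", function(x) x@channelName)

#' @rdname ImageStack-class
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))
#' @rdname ImageStack-class
#' @export
setMethod("bitDepth", "ImageStack", function(x) x@bitDepth)
#' @rdname ChannelImage-class
#' @export
setMethod("bitDepth", "ChannelImage", function(x) x@bitDepth)

#' @rdname ChannelImage-class
#' @export
setGeneric("pixelData", function(x) standardGeneric("pixelData"))
#' @rdname ChannelImage-class
#' @export
setMethod("pixelData", "ChannelImage", function(x) x@pixels)

#' @rdname ChannelImage-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname ChannelImage-class
#' @export
setMethod("provenance", "ChannelImage", function(x) x@provenance)

#' @rdname LabelMask-class
#' @export
setGeneric("maskData", function(x) standardGeneric("maskData"))
#' @rdname LabelMask-class
#' @export
setMethod("maskData", "LabelMask", function(x) x@labels)

#' @rdname LabelMask-class
#' @export
setGeneric("nRoi", function(x) standardGeneric("nRoi"))
#' @rdname LabelMask-class
#' @export
setMethod("nRoi", "LabelMask", function(x) {
  length(unique(x@labels[x@labels > 0L]))
})

#' @rdname ImageStack-class
#' @export
setMethod("dim", "ImageStack", function(x) dim(x@planes[[1L]]))
#' @rdname ChannelImage-class
#' @export
setMethod("dim", "ChannelImage", function(x) dim(x@pixels))
#' @rdname LabelMask-class
#' @export
setMethod("dim", "LabelMask", function(x) dim(x@labels))

# ---- show methods ------------------------------------------------------------

setMethod("show", "ImageStack", function(object) {
  d <- dim(object)
  cat(sprintf("ImageStack: %d plane(s) of %dx%d, channel '%s', %d-bit\n",
              length(object@planes), d[1], d[2], object@channelName,
              object@bitDepth))
})

setMethod("show", "ChannelImage", function(object) {
  d <- dim(object)
  cat(sprintf("ChannelImage: %dx%d, %d-bit, provenance '%s', range [%d, %d]\n",
              d[1], d[2], object@bitDepth, object@provenance,
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "LabelMask", function(object) {
  d <- dim(object)
  cat(sprintf("LabelMask: %dx%d, %d ROI(s), %d foreground px\n",
              d[1], d[2], nRoi(object), sum(object@labels > 0L)))
})

setMethod("show", "SegmenterSpec", function(object) {
  cat(sprintf("SegmenterSpec: backend '%s'%s%s\n", object@backendId,
              if (!is.na(object@modelName))
                sprintf(", model '%s'", object@modelName) else "",
              if (!is.na(object@diameterPx))
                sprintf(", diameter %.2f px", object@diameterPx) else ""))
  if (length(object@extraParams))
    cat("  extraParams:", paste(names(object@extraParams), collapse = ", "),
        "\n")
})

setMethod("show", "PreprocessParams", function(object) {
  cat(sprintf(
    "PreprocessParams: sigma = %g px, saturation fractions %g / %g\n",
    object@sigma, object@lowSaturationFrac, object@highSaturationFrac))
})
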