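#' Read a single-channel z-stack from TIFF
#'
#' Reads a multi-page TIFF (or a directory of per-plane TIFF files, sorted by
#' file name) into an [ImageStack]. Planes are returned in acquisition
#' z-order. Multi-sample (RGB) pages are reduced to the requested channel;
#' single-sample pages are used as-is regardless of `channel`.
#'
#' Vendor container formats (e.g. Leica LIF) are out of scope: convert the
#' stack to TIFF first, for instance with a reader such as `aicsimageio` /
#' Bio-Formats (`bfconvert in.lif out.tif`).
#'
#' @param path a multi-page TIFF file or a directory of per-plane TIFFs.
#' @param channel channel to extract from RGB pages: `"red"`, `"green"` or
#'   `"blue"` (default `"green"`).
#' @return an [ImageStack]; bit depth is read from the file.
#' @examples
#' f <- tempfile(fileext = ".tif")
#' st <- ImageStack(list(matrix(0:15, 4, 4), matrix(15:0, 4, 4)))
#' writeImageStack(st, f)
#' readImageStack(f)
#' @export
readImageStack <- function(path, channel = "green") {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  chanIdx <- match(channel, c("red", "green", "blue"))
  if (is.na(chanIdx)) stop("unknown channel: ", channel)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (!length(files)) stop("no TIFF files found in directory: ", path)
    pages <- lapply(files, function(f) tiff::readTIFF(f, as.is = TRUE))
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  }
  bits <- 8L
  planes <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] < chanIdx)
        stop("channel '", channel, "' not present in file")
      p <- p[, , chanIdx]
    }
    if (max(p) > 255L) bits <<- 16L
    p
  })
  dims <- vapply(planes, function(p) paste(dim(p), collapse = "x"), character(1))
  if (length(unique(dims)) != 1L)
    stop("inconsistent plane shapes across pages: ", paste(unique(dims),
         collapse = ", "))
  # Prefer the declared sample depth when the reader exposes it.
  info <- attr(pages[[1L]], "bits.per.sample")
  if (!is.null(info) && info %in% c(8L, 16L)) bits <- as.integer(info)
  ImageStack(planes, channelName = channel, bitDepth = bits)
}

#' Write an ImageStack as a multi-page TIFF
#'
#' @param stack an [ImageStack].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeImageStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  mx <- .maxIntensity(bitDepth(stack))
  tiff::writeTIFF(lapply(planes(stack), function(p) p / mx), path,
                  bits.per.sample = bitDepth(stack))
  invisible(path)
}

#' Write a ChannelImage as single-page TIFF
#'
#' @param img a [ChannelImage].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeChannelImage <- function(img, path) {
  stopifnot(is(img, "ChannelImage"))
  mx <- .maxIntensity(bitDepth(img))
  tiff::writeTIFF(pixelData(img) / mx, path, bits.per.sample = bitDepth(img))
  invisible(path)
}

#' Read a ChannelImage from a single-page TIFF or PNG
#'
#' @param path input file; RGB images are reduced to the green channel.
#' @return a [ChannelImage] with provenance `"raw"`.
#' @export
readChannelImage <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  p <- .readRaster(path)
  bits <- if (max(p) > 255L) 16L else 8L
  ChannelImage(p, bitDepth = bits, provenance = "raw")
}

.readRaster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  p <- if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    # png maps to [0,1]; recover the integer scale from the file's bit depth
    bd <- attr(img, "info")$bit.depth %||% 8L
    round(img * (2^bd - 1))
  } else {
    tiff::readTIFF(path, as.is = TRUE)
  }
  if (length(dim(p)) == 3L) p <- p[, , min(2L, dim(p)[3])]
  storage.mode(p) <- "integer"
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round-trip label masks through 16-bit TIFF/PNG
#'
#' Label masks are exchanged with external tools (e.g. a GUI used for manual
#' correction of segmentations) as lossless 16-bit single-channel rasters:
#' label values are preserved exactly, so `readLabelMask(writeLabelMask(m))`
#' is the identity. Masks holding labels above 65535 cannot be represented;
#' relabel them (e.g. with [validateLabelMask()]) first.
#'
#' @param mask a [LabelMask] with labels in `[0, 65535]`.
#' @param path file path ending in `.tif`/`.tiff` or `.png`.
#' @return `writeLabelMask` returns `path` invisibly; `readLabelMask` returns
#'   a [LabelMask].
#' @examples
#' f <- tempfile(fileext = ".tif")
#' m <- LabelMask(matrix(c(0L, 1L, 2L, 2L), 2, 2))
#' writeLabelMask(m, f)
#' identical(maskData(readLabelMask(f)), maskData(m))
#' @export
writeLabelMask <- function(mask, path) {
  stopifnot(is(mask, "LabelMask"))
  lb <- maskData(mask)
  if (length(lb) && max(lb) > 65535L)
    stop("labels exceed the 16-bit range (max ", max(lb),
         "); relabel to consecutive integers first, e.g. with ",
         "validateLabelMask()")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    # PNG output is 8-bit greyscale; use TIFF for masks with > 255 labels.
    if (length(lb) && max(lb) > 255L)
      stop("PNG masks support at most 255 labels; write a 16-bit TIFF or ",
           "relabel with validateLabelMask()")
    png::writePNG(lb / 255, path)
  } else {
    tiff::writeTIFF(lb / 65535, path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' @rdname writeLabelMask
#' @export
readLabelMask <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  p <- if (ext == "png") {
    round(png::readPNG(path) * 255)
  } else {
    tiff::readTIFF(path, as.is = TRUE)
  }
  if (length(dim(p)) == 3L) stop("label masks must be single-channel")
  storage.mode(p) <- "integer"
  LabelMask(p)
}

#' Convert an image to the 8-bit working scale
#'
#' The quantification threshold (intensity greater than 50) is defined on an
#' 8-bit scale, so all preprocessing operates on 8-bit images. 8-bit input is
#' returned unchanged; 16-bit input is rescaled by 255/65535 with
#' round-half-up. The mapping is monotone, so intensity order is preserved.
#'
#' @param img a [ChannelImage] of bit depth 8 or 16.
#' @return an 8-bit [ChannelImage]; provenance is preserved.
#' @examples
#' im <- ChannelImage(matrix(32768L, 2, 2), bitDepth = 16L)
#' pixelData(to8bit(im))[1, 1]  # 128
#' @export
to8bit <- function(img) {
  stopifnot(is(img, "ChannelImage"))
  if (bitDepth(img) == 8L) return(img)
  if (bitDepth(img) != 16L) stop("unsupported bit depth: ", bitDepth(img))
  px <- floor(pixelData(img) * (255 / 65535) + 0.5)
  ChannelImage(px, bitDepth = 8L, provenance = provenance(img))
}
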