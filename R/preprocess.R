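#' Maximum-intensity projection of a z-stack
#'
#' Collapses a z-stack to a single composite image by transferring the highest
#' pixel intensity along z into each (x, y) position.
#'
#' @param stack an [ImageStack].
#' @return a [ChannelImage] with provenance `"projected"` and the stack's bit
#'   depth.
#' @examples
#' st <- ImageStack(list(matrix(c(0L, 5L, 10L, 5L), 2, 2),
#'                       matrix(c(3L, 9L, 2L, 1L), 2, 2)))
#' pixelData(maxIntensityProjection(st))
#' @export
maxIntensityProjection <- function(stack) {
  stopifnot(is(stack, "ImageStack"))
  validObject(stack)
  px <- Reduce(pmax, planes(stack))
  ChannelImage(px, bitDepth = bitDepth(stack), provenance = "projected")
}

# One-dimensional convolution matrix for a truncated, renormalised Gaussian
# with edge-replicate padding folded into the boundary rows: out = A %*% x.
# Clamping out-of-range taps onto the nearest edge sample reproduces replicate
# padding exactly for any kernel radius, including radii wider than the image.
.gaussConvMatrix <- function(n, sigma) {
  r <- ceiling(3 * sigma)
  w <- exp(-(( -r:r)^2) / (2 * sigma^2))
  w <- w / sum(w)
  A <- matrix(0, n, n)
  i <- seq_len(n)
  for (k in seq_along(w)) {
    j <- pmin(pmax(i + (k - r - 1L), 1L), n)
    idx <- cbind(i, j)
    A[idx] <- A[idx] + w[k]
  }
  A
}

# Separable Gaussian blur with replicate padding, in double precision.
.gaussBlur <- function(px, sigma) {
  Ar <- .gaussConvMatrix(nrow(px), sigma)
  Ac <- if (ncol(px) == nrow(px)) Ar else .gaussConvMatrix(ncol(px), sigma)
  Ar %*% px %*% t(Ac)
}

.clip255 <- function(x) pmin(pmax(x, 0), 255)
.roundHalfUp <- function(x) floor(x + 0.5)

#' Flatfield (shading) correction
#'
#' Removes smooth illumination/shading variation, e.g. the uneven background
#' signal produced by non-specific dye binding to a titanium surface. The
#' shading field `S` is estimated by a Gaussian blur of the image at scale
#' `sigma` (edge-replicate padding, kernel truncated at 3 sigma and
#' renormalised), floored at a small positive epsilon, and the image is
#' rescaled by `mean(S)/S` so that a shading-free image is a fixed point:
#' `out = clip(img * mean(S)/S, 0, 255)`, computed in floating point and then
#' rounded half-up to integers.
#'
#' Near image borders the shading estimate of a strongly sloped background
#' flattens (a consequence of replicate padding), so residual deviation is
#' larger there than in the interior; see the package vignette.
#'
#' @param img an 8-bit [ChannelImage].
#' @param sigma positive Gaussian scale in pixels (default 50, the scale used
#'   throughout this workflow).
#' @return an 8-bit [ChannelImage] with provenance `"flatfielded"`.
#' @export
flatfieldCorrect <- function(img, sigma = 50) {
  stopifnot(is(img, "ChannelImage"))
  if (bitDepth(img) != 8L)
    stop("flatfield correction operates on the 8-bit working scale; ",
         "call to8bit() first")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a single positive number")
  px <- pixelData(img)
  S <- .gaussBlur(px, sigma)
  S <- pmax(S, 1e-6)
  out <- .roundHalfUp(.clip255(px * (mean(S) / S)))
  ChannelImage(out, bitDepth = 8L, provenance = "flatfielded")
}

#' Percentile contrast stretch
#'
#' Linear contrast enhancement in the style of intensity-window adjustment:
#' the input window `[low_in, high_in]` is chosen from the intensity
#' histogram and mapped linearly onto `[0, 255]`, clipping outside. `low_in`
#' is the smallest occupied intensity whose cumulative pixel fraction reaches
#' `lowFrac`; `high_in` is the smallest intensity whose cumulative fraction
#' reaches `1 - highFrac`. With both fractions 0 the window is the image's
#' full occupied range, so an image already spanning 0..255 is unchanged. In
#' the degenerate case `low_in == high_in` (e.g. a constant image) pixels
#' below the window map to 0 and pixels at or above it to 255.
#'
#' @param img an 8-bit [ChannelImage].
#' @param lowFrac,highFrac saturation fractions in `[0, 0.5)` (defaults 0.01,
#'   the conventional default of this adjustment).
#' @return an 8-bit [ChannelImage] with provenance `"adjusted"`.
#' @export
adjustContrast <- function(img, lowFrac = 0.01, highFrac = 0.01) {
  stopifnot(is(img, "ChannelImage"))
  if (bitDepth(img) != 8L) stop("contrast stretch expects an 8-bit image")
  if (lowFrac < 0 || lowFrac >= 0.5 || highFrac < 0 || highFrac >= 0.5)
    stop("saturation fractions must lie in [0, 0.5)")
  px <- pixelData(img)
  counts <- tabulate(as.vector(px) + 1L, nbins = 256L)
  cumFrac <- cumsum(counts) / length(px)
  lowIn <- min(which(cumFrac >= lowFrac & cumsum(counts) > 0)) - 1L
  highIn <- min(which(cumFrac >= 1 - highFrac)) - 1L
  if (lowIn == highIn) {
    out <- ifelse(px >= highIn, 255L, 0L)
    dim(out) <- dim(px)
  } else {
    out <- .roundHalfUp(.clip255((px - lowIn) * (255 / (highIn - lowIn))))
  }
  ChannelImage(out, bitDepth = 8L, provenance = "adjusted")
}

#' Full preprocessing chain for a z-stack
#'
#' Projection, scale conversion, flatfield correction and contrast stretch, in
#' that order: `adjustContrast(flatfieldCorrect(to8bit(maxIntensityProjection
#' (stack))))`. This is the preparation step shared by all three
#' quantification methods; it removes the need for per-image manual threshold
#' or contrast tuning.
#'
#' @param stack an [ImageStack].
#' @param params a [PreprocessParams] object (defaults: sigma 50, saturation
#'   fractions 0.01/0.01).
#' @return an 8-bit [ChannelImage] with provenance `"adjusted"`.
#' @export
preprocessImage <- function(stack, params = preprocessParams()) {
  stopifnot(is(params, "PreprocessParams"))
  validObject(params)
  img <- to8bit(maxIntensityProjection(stack))
  img <- flatfieldCorrect(img, sigma = params@sigma)
  adjustContrast(img, lowFrac = params@lowSaturationFrac,
                 highFrac = params@highSaturationFrac)
}
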