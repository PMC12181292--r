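#' Specification of a synthetic confocal-like scene
#'
#' Parameters of the synthetic-image generator, which emulates the content of
#' single-channel ("green") confocal maximum-projection scenes of microbial
#' colonization on an implant surface: individual bacteria of ~7 px
#' equivalent diameter, short chains sharing one ROI label, microcolonies of
#' 500-15,000 px, large dim human cells, smooth multiplicative background
#' shading and additive pixel noise. Human cells are deliberately dimmer than
#' bacteria but still above the quantification threshold, mirroring the core
#' difficulty that non-specific DNA dyes stain both cell types: thresholding
#' alone cannot separate them, only the interference-subtraction or
#' dual-model logic can.
#'
#' @slot height,width image size in pixels (default 1024).
#' @slot nPlanes number of z-planes (>= 1).
#' @slot nSingles number of individual bacteria.
#' @slot nChains number of bacterial chains (each one ROI).
#' @slot chainLengthRange integer pair, cells per chain.
#' @slot singleDiameterPx equivalent diameter of a single bacterium
#'   (default 7.06 px, the mean ROI equivalent diameter this workflow's
#'   single-cell model was trained at).
#' @slot nColonies number of microcolonies.
#' @slot colonyAreaRangePx integer pair, colony area drawn uniformly from
#'   this inclusive range (default 500-15,000 px, the microcolony regime).
#' @slot nHumanCells number of human cells (labelled only in the human
#'   ground truth).
#' @slot humanCellDiameterPx human cell diameter (default 80 px).
#' @slot bacteriaIntensity,humanCellIntensity,backgroundBase 8-bit
#'   intensities (defaults 180, 90, 20).
#' @slot shadingAmplitude relative amplitude of the smooth multiplicative
#'   shading field (0 disables).
#' @slot noiseSd standard deviation of additive Gaussian pixel noise
#'   (0 disables).
#' @slot seed integer seed; scenes are bit-reproducible given the seed.
#' @seealso [generateScene()], [generateBenchmarkSuite()]
#' @export
setClass("SceneSpec",
  representation(height = "integer", width = "integer", nPlanes = "integer",
                 nSingles = "integer", nChains = "integer",
                 chainLengthRange = "integer", singleDiameterPx = "numeric",
                 nColonies = "integer", colonyAreaRangePx = "integer",
                 nHumanCells = "integer", humanCellDiameterPx = "numeric",
                 bacteriaIntensity = "integer", humanCellIntensity = "integer",
                 backgroundBase = "integer", shadingAmplitude = "numeric",
                 noiseSd = "numeric", seed = "integer"))

setValidity("SceneSpec", function(object) {
  if (object@height < 16L || object@width < 16L)
    return("image must be at least 16x16")
  if (object@nPlanes < 1L) return("nPlanes must be >= 1")
  counts <- c(object@nSingles, object@nChains, object@nColonies,
              object@nHumanCells)
  if (any(counts < 0L)) return("object counts must be >= 0")
  if (length(object@chainLengthRange) != 2L ||
      object@chainLengthRange[1] < 1L ||
      diff(object@chainLengthRange) < 0L)
    return("chainLengthRange must be an increasing pair of positive integers")
  if (length(object@colonyAreaRangePx) != 2L ||
      object@colonyAreaRangePx[1] < 1L ||
      diff(object@colonyAreaRangePx) < 0L)
    return("colonyAreaRangePx must be an increasing pair of positive integers")
  if (object@colonyAreaRangePx[2] > object@height * object@width)
    return("colony area range exceeds the image area")
  ints <- c(object@bacteriaIntensity, object@humanCellIntensity,
            object@backgroundBase)
  if (any(ints < 0L) || any(ints > 255L))
    return("intensities must lie in [0, 255]")
  if (object@singleDiameterPx <= 0 || object@humanCellDiameterPx <= 0)
    return("diameters must be positive")
  if (object@shadingAmplitude < 0 || object@shadingAmplitude >= 1)
    return("shadingAmplitude must lie in [0, 1)")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})

#' @param height,width,nPlanes,nSingles,nChains,chainLengthRange,singleDiameterPx,nColonies,colonyAreaRangePx,nHumanCells,humanCellDiameterPx,bacteriaIntensity,humanCellIntensity,backgroundBase,shadingAmplitude,noiseSd,seed see slots.
#' @rdname SceneSpec-class
#' @export
sceneSpec <- function(height = 1024L, width = 1024L, nPlanes = 3L,
                      nSingles = 40L, nChains = 10L,
                      chainLengthRange = c(2L, 3L), singleDiameterPx = 7.06,
                      nColonies = 3L, colonyAreaRangePx = c(500L, 15000L),
                      nHumanCells = 3L, humanCellDiameterPx = 80,
                      bacteriaIntensity = 180L, humanCellIntensity = 90L,
                      backgroundBase = 20L, shadingAmplitude = 0.15,
                      noiseSd = 2, seed = 1L) {
  new("SceneSpec", height = as.integer(height), width = as.integer(width),
      nPlanes = as.integer(nPlanes), nSingles = as.integer(nSingles),
      nChains = as.integer(nChains),
      chainLengthRange = as.integer(chainLengthRange),
      singleDiameterPx = as.numeric(singleDiameterPx),
      nColonies = as.integer(nColonies),
      colonyAreaRangePx = as.integer(colonyAreaRangePx),
      nHumanCells = as.integer(nHumanCells),
      humanCellDiameterPx = as.numeric(humanCellDiameterPx),
      bacteriaIntensity = as.integer(bacteriaIntensity),
      humanCellIntensity = as.integer(humanCellIntensity),
      backgroundBase = as.integer(backgroundBase),
      shadingAmplitude = as.numeric(shadingAmplitude),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(paste0(
    "SceneSpec: %dx%d, %d plane(s), seed %d\n",
    "  %d singles (d=%.2f px), %d chains (%d-%d cells), %d colonies ",
    "(%d-%d px), %d human cells (d=%.0f px)\n",
    "  intensities: bacteria %d, human %d, background %d; shading %.2f, ",
    "noise sd %.1f\n"),
    object@height, object@width, object@nPlanes, object@seed,
    object@nSingles, object@singleDiameterPx, object@nChains,
    object@chainLengthRange[1], object@chainLengthRange[2], object@nColonies,
    object@colonyAreaRangePx[1], object@colonyAreaRangePx[2],
    object@nHumanCells, object@humanCellDiameterPx,
    object@bacteriaIntensity, object@humanCellIntensity,
    object@backgroundBase, object@shadingAmplitude, object@noiseSd))
})

# Run expr under a local, seeded RNG stream; the caller's stream is restored.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# ---- rasterizers: pixel offsets (dr, dc) relative to an object centre ------

.rasterEllipse <- function(r0, aspect = 1, theta = 0) {
  a <- r0 * sqrt(aspect)
  b <- r0 / sqrt(aspect)
  m <- ceiling(a) + 1L
  dr <- rep(-m:m, times = 2L * m + 1L)
  dc <- rep(-m:m, each = 2L * m + 1L)
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  cbind(dr[inside], dc[inside])
}

# A chain of touching circular cells along a common axis; one ROI.
.rasterChain <- function(len, r0, theta = 0) {
  spacing <- 1.1 * r0
  off <- lapply(seq_len(len) - 1L, function(k) {
    e <- .rasterEllipse(r0, 1, 0)
    cbind(e[, 1] + round(k * spacing * cos(theta)),
          e[, 2] + round(k * spacing * sin(theta)))
  })
  unique(do.call(rbind, off))
}

# A connected random blob of exactly `area` pixels: pixels nearest to a
# random-walk skeleton, taken in order of distance (ties broken by index),
# so the result is the union of overlapping disks around the skeleton and
# stays connected.
.rasterBlob <- function(area) {
  npts <- 8L
  step <- 0.8 * sqrt(area) / npts
  ang <- cumsum(c(stats::runif(1, 0, 2 * pi),
                  stats::runif(npts - 1L, -0.8, 0.8)))
  pr <- cumsum(c(0, step * cos(ang[-1])))
  pc <- cumsum(c(0, step * sin(ang[-1])))
  L <- step * (npts - 1L)
  dmax <- (-L + sqrt(L^2 + pi * area)) / pi * 1.5 + 2
  repeat {
    rr <- floor(min(pr) - dmax):ceiling(max(pr) + dmax)
    cc <- floor(min(pc) - dmax):ceiling(max(pc) + dmax)
    gr <- rep(rr, times = length(cc))
    gc <- rep(cc, each = length(rr))
    D <- rep(Inf, length(gr))
    for (k in seq_len(npts))
      D <- pmin(D, (gr - pr[k])^2 + (gc - pc[k])^2)
    if (sum(is.finite(D)) >= area && sum(D <= dmax^2) >= area) break
    dmax <- dmax * 1.5
  }
  ord <- order(D, seq_along(D))[seq_len(area)]
  pts <- cbind(gr[ord], gc[ord])
  ctr <- round(colMeans(pts))
  cbind(pts[, 1] - ctr[1], pts[, 2] - ctr[2])
}

# Place an object (pixel offsets) at a uniform random free position, keeping
# a 2-px dilated margin around every placed object so distinct objects never
# touch. Returns linear indices, or NULL after maxTries failures.
.placeObject <- function(offsets, occ, H, W, maxTries = 200L) {
  rRange <- range(offsets[, 1]); cRange <- range(offsets[, 2])
  rLo <- 1L - rRange[1]; rHi <- H - rRange[2]
  cLo <- 1L - cRange[1]; cHi <- W - cRange[2]
  if (rLo > rHi || cLo > cHi) return(NULL)
  for (i in seq_len(maxTries)) {
    r0 <- rLo + sample.int(rHi - rLo + 1L, 1L) - 1L
    c0 <- cLo + sample.int(cHi - cLo + 1L, 1L) - 1L
    idx <- (offsets[, 2] + c0 - 1L) * H + offsets[, 1] + r0
    if (!any(occ[idx])) return(idx)
  }
  NULL
}

.dilateIdx <- function(idx, H, W, by = 2L) {
  r <- (idx - 1L) %% H + 1L
  c <- (idx - 1L) %/% H + 1L
  sh <- expand.grid(dr = -by:by, dc = -by:by)
  rr <- rep(r, nrow(sh)) + rep(sh$dr, each = length(r))
  cc <- rep(c, nrow(sh)) + rep(sh$dc, each = length(c))
  ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
  unique((cc[ok] - 1L) * H + rr[ok])
}

#' Generate a synthetic scene with ground truth
#'
#' Renders a confocal-like z-stack and its paired ground-truth label masks,
#' deterministically for a given seed. Microbial objects (singles, chains,
#' colonies) are labelled in `gtMicrobes` — a chain is a single ROI, matching
#' the convention that clusters or chains of bacteria form one region of
#' interest — and human cells only in `gtHuman`. Objects are placed by
#' rejection sampling with a 2-px separation margin and never overlap; if the
#' requested content cannot be placed, an explicit infeasible-placement error
#' is raised. Intensities are object value times a smooth multiplicative
#' shading field plus Gaussian noise, clipped to `[0, 255]`; z-planes
#' replicate the scene with per-plane attenuation (the first plane is
#' unattenuated), so the maximum-intensity projection recovers the brightest
#' rendering exactly.
#'
#' The true coverage is computed from `gtMicrobes`, so e.g. a spec with a
#' single colony of exactly 1,000 px and no other objects has true coverage
#' `100 * 1000 / (height * width)` exactly.
#'
#' @param spec a [SceneSpec].
#' @return a list: `stack` ([ImageStack]), `gtMicrobes` and `gtHuman`
#'   ([LabelMask]s), `trueCoveragePct`, and `spec`.
#' @export
generateScene <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  H <- spec@height; W <- spec@width
  r0 <- spec@singleDiameterPx / 2

  # Coarse feasibility bound before attempting placement.
  expected <- spec@nColonies * mean(spec@colonyAreaRangePx) +
    spec@nHumanCells * pi * (spec@humanCellDiameterPx / 2)^2 +
    (spec@nSingles + spec@nChains * spec@chainLengthRange[2]) * pi * r0^2
  if (expected * 2 > H * W)
    stop("infeasible placement: requested object area (~", round(expected),
         " px) exceeds the capacity of a ", H, "x", W, " image")

  .withSeed(spec@seed, {
    gtM <- matrix(0L, H, W)
    gtH <- matrix(0L, H, W)
    occ <- matrix(FALSE, H, W)
    mLab <- 0L; hLab <- 0L

    put <- function(offsets, human = FALSE) {
      idx <- .placeObject(offsets, occ, H, W)
      if (is.null(idx))
        stop("infeasible placement: could not place an object of ",
             nrow(offsets), " px after repeated attempts")
      if (human) {
        hLab <<- hLab + 1L; gtH[idx] <<- hLab
      } else {
        mLab <<- mLab + 1L; gtM[idx] <<- mLab
      }
      occ[.dilateIdx(idx, H, W)] <<- TRUE
    }

    # Largest objects first to keep rejection sampling cheap.
    for (i in seq_len(spec@nColonies)) {
      rng <- spec@colonyAreaRangePx
      area <- rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
      put(.rasterBlob(area))
    }
    for (i in seq_len(spec@nHumanCells))
      put(.rasterEllipse(spec@humanCellDiameterPx / 2), human = TRUE)
    for (i in seq_len(spec@nChains)) {
      rng <- spec@chainLengthRange
      len <- rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
      put(.rasterChain(len, r0, stats::runif(1, 0, 2 * pi)))
    }
    for (i in seq_len(spec@nSingles))
      put(.rasterEllipse(r0, stats::runif(1, 1, 2),
                         stats::runif(1, 0, 2 * pi)))

    scene <- matrix(as.numeric(spec@backgroundBase), H, W)
    scene[gtM > 0L] <- spec@bacteriaIntensity
    scene[gtH > 0L] <- spec@humanCellIntensity

    if (spec@shadingAmplitude > 0) {
      kr <- stats::runif(1, 0.5, 1.5); kc <- stats::runif(1, 0.5, 1.5)
      phase <- stats::runif(1, 0, 2 * pi)
      field <- sin(2 * pi * (kr * (row(scene) - 1) / H +
                             kc * (col(scene) - 1) / W) + phase)
      scene <- scene * (1 + spec@shadingAmplitude * field)
    }
    if (spec@noiseSd > 0)
      scene <- scene + stats::rnorm(length(scene), 0, spec@noiseSd)

    atten <- seq(1, 0.55, length.out = spec@nPlanes)
    planes <- lapply(atten, function(a) .roundHalfUp(.clip255(scene * a)))

    list(stack = ImageStack(planes, channelName = "green", bitDepth = 8L),
         gtMicrobes = LabelMask(gtM), gtHuman = LabelMask(gtH),
         trueCoveragePct = 100 * sum(gtM > 0L) / (H * W),
         spec = spec)
  })
}

#' Generate a reproducible benchmark suite of scenes
#'
#' Generates `nImages` scenes from a base specification, deriving the i-th
#' scene's seed as `seed + i` so suites are reproducible piecewise. When
#' `outDir` is given, each scene's stack and ground-truth masks are written
#' (multi-page TIFF + 16-bit TIFF masks) together with a `manifest.csv`;
#' otherwise the scenes are returned in memory.
#'
#' @param baseSpec a [SceneSpec] (its own seed is ignored).
#' @param nImages number of scenes (>= 1).
#' @param seed base seed.
#' @param outDir optional output directory.
#' @return a list with `manifest` (data.frame: `scene_id`, `seed`,
#'   `true_coverage_pct`, `n_microbe_rois`, `n_human_rois`, and file paths if
#'   written) and `scenes` (list of [generateScene()] results, `NULL` when
#'   written to disk).
#' @export
generateBenchmarkSuite <- function(baseSpec, nImages, seed, outDir = NULL) {
  stopifnot(is(baseSpec, "SceneSpec"), nImages >= 1L)
  write <- !is.null(outDir)
  if (write) dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  scenes <- if (write) NULL else vector("list", nImages)
  rows <- vector("list", nImages)
  for (i in seq_len(nImages)) {
    sp <- baseSpec
    sp@seed <- as.integer(seed + i)
    sc <- generateScene(sp)
    row <- data.frame(scene_id = sprintf("scene_%03d", i), seed = sp@seed,
                      true_coverage_pct = sc$trueCoveragePct,
                      n_microbe_rois = nRoi(sc$gtMicrobes),
                      n_human_rois = nRoi(sc$gtHuman))
    if (write) {
      base <- file.path(outDir, row$scene_id)
      row$stack_path <- paste0(base, ".tif")
      row$gt_microbes_path <- paste0(base, "_gt_microbes.tif")
      row$gt_human_path <- paste0(base, "_gt_human.tif")
      writeImageStack(sc$stack, row$stack_path)
      writeLabelMask(sc$gtMicrobes, row$gt_microbes_path)
      writeLabelMask(sc$gtHuman, row$gt_human_path)
    } else {
      scenes[[i]] <- sc
    }
    rows[[i]] <- row
  }
  manifest <- do.call(rbind, rows)
  if (write)
    utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                     row.names = FALSE)
  list(manifest = manifest, scenes = scenes)
}
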