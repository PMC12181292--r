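test_that("threshold quantification computes the exact pixel ratio", {
  expect_identical(quantifyThreshold(ChannelImage(matrix(0L, 32, 32)))$
                     record$coverage_pct, 0)
  expect_identical(quantifyThreshold(ChannelImage(matrix(255L, 32, 32)))$
                     record$coverage_pct, 100)
  px <- matrix(0L, 64, 64); px[seq_len(1024)] <- 200L   # exactly 25%
  res <- quantifyThreshold(ChannelImage(px), imageId = "q")
  expect_identical(res$record$coverage_pct, 25)
  expect_identical(res$record$foreground_px, 1024L)
  expect_identical(res$record$method, 1L)
  expect_identical(res$record$image_id, "q")
})

test_that("interference subtraction reduces to method 1 when empty", {
  set.seed(79)
  for (rep in 1:10) {
    px <- matrix(as.integer(sample(0:255, 1024, TRUE)), 32, 32)
    img <- ChannelImage(px)
    m1 <- quantifyThreshold(img)
    m2 <- quantifySubtracted(img, LabelMask(matrix(0L, 32, 32)))
    expect_identical(maskData(m1$mask), maskData(m2$mask))
    expect_identical(m1$record$coverage_pct, m2$record$coverage_pct)
  }
})

test_that("interference subtraction removes covered foreground from the count", {
  # one 100-px bright blob, 40 px of it under interference
  px <- matrix(0L, 32, 32); px[1:10, 1:10] <- 200L
  interf <- matrix(0L, 32, 32); interf[1:4, 1:10] <- 1L
  res <- quantifySubtracted(ChannelImage(px), LabelMask(interf))
  expect_identical(res$record$foreground_px, 60L)
  expect_identical(res$record$denominator_px, 1024L)
  # full-cover interference -> 0 %
  expect_identical(quantifySubtracted(ChannelImage(px),
                                      LabelMask(matrix(1L, 32, 32)))$
                     record$coverage_pct, 0)
  # optional denominator exclusion
  resX <- quantifySubtracted(ChannelImage(px), LabelMask(interf),
                             excludeInterference = TRUE)
  expect_identical(resX$record$denominator_px, 1024L - 40L)
  expect_error(quantifySubtracted(ChannelImage(px),
                                  LabelMask(matrix(0L, 3, 3))), "shape")
})

test_that("dual-model quantification combines partitioned builtin backends", {
  # one 2,000-px blob and five 20-px blobs; partition at 500 px
  px <- matrix(0L, 256, 256)
  px <- stampRect(px, 11, 11, 40, 50, 200L)             # 2000 px
  for (k in 0:4) px <- stampRect(px, 100, 11 + 30 * k, 4, 5, 200L)  # 5 x 20 px
  img <- ChannelImage(px)
  small <- segmenterSpec(extraParams = list(maxArea = 499))
  large <- segmenterSpec(extraParams = list(minArea = 500))
  res <- quantifyDualModel(img, small, large, imageId = "fig")
  expect_identical(nRoi(res$mask), 6L)
  expect_equal(res$record$coverage_pct, 2100 / (256 * 256) * 100,
               tolerance = 1e-12)
  expect_identical(res$record$method, 3L)

  # empty backends -> empty mask, 0 %
  res0 <- quantifyDualModel(ChannelImage(matrix(0L, 32, 32)), small, large)
  expect_identical(res0$record$coverage_pct, 0)
  expect_identical(nRoi(res0$mask), 0L)

  # coverage is invariant to swapping which backend is small vs large
  resSwap <- quantifyDualModel(img, large, small)
  expect_identical(resSwap$record$coverage_pct, res$record$coverage_pct)
})

test_that("coverage records hold the exact ratio invariant and persist masks", {
  set.seed(83)
  d <- withr::local_tempdir()
  for (rep in 1:10) {
    px <- matrix(as.integer(sample(0:255, 4096, TRUE)), 64, 64)
    f <- file.path(d, sprintf("m%d.tif", rep))
    res <- quantifyThreshold(ChannelImage(px), imageId = "x", maskPath = f)
    r <- res$record
    expect_true(r$coverage_pct >= 0 && r$coverage_pct <= 100)
    expect_equal(r$coverage_pct, 100 * r$foreground_px / r$denominator_px,
                 tolerance = 1e-12)
    # re-ingestion from the persisted file reproduces the coverage
    r2 <- coverageFromMask(f, "x", 1L)
    expect_identical(r2$coverage_pct, r$coverage_pct)
  }
  expect_error(coverageRecord("a", 5L, 1, 10), "method")
  expect_error(coverageRecord("a", 1L, 11, 10), "out of range")
})

test_that("corrected-mask re-ingestion recomputes coverage from the final mask", {
  px <- matrix(0L, 32, 32); px[1:8, 1:8] <- 200L
  d <- withr::local_tempdir()
  f <- file.path(d, "mask.tif")
  res <- quantifyThreshold(ChannelImage(px), imageId = "im1", maskPath = f)
  # simulate a manual correction: remove half of the object
  lb <- maskData(res$mask); lb[1:4, 1:8] <- 0L
  writeLabelMask(LabelMask(lb), f)
  r2 <- coverageFromMask(f, "im1")
  expect_identical(r2$foreground_px, 32L)
  expect_identical(r2$coverage_pct, 100 * 32 / 1024)
})

test_that("microcolony training-set bootstrap filters, tiles and drops empties", {
  img <- ChannelImage(matrix(0L, 512, 512))
  # only ROI is 400 px -> filtered out, no tiles survive
  lb <- matrix(0L, 512, 512); lb[1:20, 1:20] <- 1L
  expect_length(buildMicrocolonyTrainingSet(list(img), list(LabelMask(lb))),
                0L)
  # single 1,000-px ROI inside one tile -> exactly one tile
  lb2 <- matrix(0L, 512, 512); lb2[11:50, 11:35] <- 1L
  tiles <- buildMicrocolonyTrainingSet(list(img), list(LabelMask(lb2)))
  expect_length(tiles, 1L)
  expect_identical(sum(maskData(tiles[[1]]$mask) > 0L), 1000L)
  expect_identical(dim(tiles[[1]]$image), c(256L, 256L))
  # written layout pairs images with _masks files
  d <- withr::local_tempdir()
  buildMicrocolonyTrainingSet(list(img), list(LabelMask(lb2)), outDir = d)
  files <- list.files(d)
  expect_length(files, 2L)
  expect_true(any(grepl("_masks\\.tif$", files)))
  expect_error(buildMicrocolonyTrainingSet(list(img), list()), "length")
})

test_that("method assignments validate their per-method requirements", {
  expect_error(methodAssignment("i", 2L), "method 2")
  expect_error(methodAssignment("i", 3L, smallSpec = segmenterSpec()),
               "method 3")
  a <- methodAssignment("i", 3L, smallSpec = segmenterSpec(),
                        largeSpec = segmenterSpec())
  expect_s3_class(a, "MethodAssignment")
  expect_error(buildInterferenceMask(ChannelImage(matrix(0L, 4, 4))),
               "requires")
})
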