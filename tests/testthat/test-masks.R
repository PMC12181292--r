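test_that("connected components honour connectivity and raster label order", {
  b <- matrix(FALSE, 3, 3); b[1, 1] <- b[2, 2] <- TRUE
  expect_identical(nRoi(connectedComponents(b, 8)), 1L)
  expect_identical(nRoi(connectedComponents(b, 4)), 2L)
  expect_identical(nRoi(connectedComponents(matrix(FALSE, 5, 5))), 0L)

  # labels appear 1..k in row-major discovery order
  b2 <- matrix(FALSE, 4, 6)
  b2[1, 5] <- TRUE; b2[2, 2] <- TRUE; b2[4, 1] <- TRUE
  lab <- maskData(connectedComponents(b2, 8))
  expect_identical(lab[1, 5], 1L)
  expect_identical(lab[2, 2], 2L)
  expect_identical(lab[4, 1], 3L)
})

test_that("connected components agree with a flood-fill reference on random masks", {
  set.seed(19)
  for (rep in 1:20) {
    b <- randomBinary(24, 24, 0.4)
    got <- maskData(connectedComponents(b, 8))
    want <- floodLabel(b)
    # same partition and same number of components
    expect_identical(max(got), max(want))
    expect_identical(got == 0L, want == 0L)
    agree <- table(got[got > 0L], want[want > 0L])
    expect_true(all(rowSums(agree > 0) == 1) && all(colSums(agree > 0) == 1))
  }
})

test_that("connected components agree with EBImage bwlabel partitions", {
  skip_if_not_installed("EBImage")
  set.seed(23)
  for (rep in 1:10) {
    b <- randomBinary(32, 32, 0.35)
    got <- maskData(connectedComponents(b, 4))   # bwlabel is 4-connected
    ref <- EBImage::bwlabel(b)
    expect_identical(max(got), as.integer(max(ref)))
    agree <- table(got[got > 0L], ref[ref > 0])
    expect_true(all(rowSums(agree > 0) == 1) && all(colSums(agree > 0) == 1))
  }
})

test_that("roiTable reports exact areas and equivalent diameters", {
  lb <- matrix(0L, 20, 20)
  lb[1:10, 1:10] <- 5L                      # 100 px, non-consecutive label
  tab <- roiTable(LabelMask(lb))
  expect_identical(tab$label, 5L)
  expect_identical(tab$area_px, 100L)
  expect_equal(tab$equivalent_diameter_px, 2 * sqrt(100 / pi),
               tolerance = 1e-12)

  # rasterized disk of radius 10: diameter recovered within 3% of 20
  d <- outer(-12:12, -12:12, function(r, c) r^2 + c^2) <= 100
  tab2 <- roiTable(connectedComponents(d, 8))
  expect_equal(tab2$equivalent_diameter_px, 20, tolerance = 0.03)

  expect_identical(nrow(roiTable(LabelMask(matrix(0L, 4, 4)))), 0L)
})

test_that("roiTable areas sum to the total foreground", {
  set.seed(31)
  for (rep in 1:10) {
    m <- randomMask(32, 32)
    expect_identical(sum(roiTable(m)$area_px), sum(maskData(m) > 0L))
  }
})

test_that("area filtering is inclusive at both bounds and never creates pixels", {
  # four ROIs with areas 499, 500, 15000, 15001 on one mask
  lb <- matrix(0L, 260, 300)
  lb[1, 1:249] <- 1L; lb[2, 1:250] <- 1L            # 499
  lb[4, 1:250] <- 2L; lb[5, 1:250] <- 2L            # 500
  lb[10:59, 1:300] <- 3L                            # 15000
  lb[70:119, 1:300] <- 4L; lb[120, 1] <- 4L         # 15001
  m <- LabelMask(lb)
  areas <- roiTable(m)$area_px
  expect_identical(areas, c(499L, 500L, 15000L, 15001L))
  kept <- filterByArea(m, 500L, 15000L)
  expect_identical(sort(unique(maskData(kept)[maskData(kept) > 0L])),
                   c(2L, 3L))
  # identity bounds and empty input
  expect_identical(maskData(filterByArea(m, 1L, Inf)), lb)
  expect_identical(maskData(filterByArea(LabelMask(matrix(0L, 4, 4)), 1, 2)),
                   matrix(0L, 4, 4))
  expect_error(filterByArea(m, 10L, 5L), "minPx")
  # output ROI set is a subset with pixels untouched
  set.seed(13)
  for (rep in 1:10) {
    rm <- randomMask(24, 24)
    f <- filterByArea(rm, 3L, 20L)
    expect_true(all(maskData(f) == maskData(rm) | maskData(f) == 0L))
  }
})

test_that("region subtraction zeroes exactly the labelled pixels", {
  px <- matrix(77L, 4, 4)
  img <- ChannelImage(px)
  empty <- LabelMask(matrix(0L, 4, 4))
  expect_identical(pixelData(subtractRegions(img, empty)), px)

  reg <- matrix(0L, 4, 4); reg[2:3, 2:3] <- 1L
  out <- pixelData(subtractRegions(img, LabelMask(reg)))
  expect_identical(sum(out == 0L), 4L)
  expect_identical(sum(out == 77L), 12L)

  full <- LabelMask(matrix(1L, 4, 4))
  expect_true(all(pixelData(subtractRegions(img, full)) == 0L))
  expect_error(subtractRegions(img, LabelMask(matrix(0L, 3, 3))), "shape")
})

test_that("mask combination keeps primary precedence and exact union foreground", {
  # disjoint masks: plain union, 5 ROIs
  a <- matrix(0L, 10, 10); a[1:2, 1:2] <- 1L; a[5:6, 5:6] <- 2L
  b <- matrix(0L, 10, 10); b[9, 1] <- 1L; b[9, 5] <- 2L; b[1, 9] <- 3L
  comb <- combineMasks(LabelMask(a), LabelMask(b))
  expect_identical(nRoi(comb), 5L)
  expect_identical(maskData(comb) > 0L, a > 0L | b > 0L)

  # secondary ROI fully inside primary disappears
  inner <- matrix(0L, 10, 10); inner[2, 2] <- 1L
  comb2 <- combineMasks(LabelMask(a), LabelMask(inner))
  expect_identical(nRoi(comb2), 2L)
  expect_identical(maskData(comb2) > 0L, a > 0L)

  # 40% overlap: both ROIs present, overlap pixels carry the primary label
  p <- matrix(0L, 16, 16); p[1:5, 1:4] <- 1L          # 20 px primary
  s <- matrix(0L, 16, 16); s[4:5, 3:7] <- 1L          # 10 px, 4 overlap
  c3 <- combineMasks(LabelMask(p), LabelMask(s))
  expect_identical(nRoi(c3), 2L)
  expect_identical(sum(maskData(c3) > 0L), sum(p > 0L | s > 0L))
  expect_true(all(maskData(c3)[p > 0L] == 1L))
  expect_identical(sum(maskData(c3) == 2L), 6L)       # non-overlap remainder

  # secondary precedence swaps the roles
  c4 <- combineMasks(LabelMask(p), LabelMask(s), precedence = "secondary")
  expect_identical(sum(maskData(c4) > 0L), sum(p > 0L | s > 0L))
  expect_true(all(maskData(c4)[s > 0L] == maskData(c4)[4, 3]))
})

test_that("combination foreground equals the set union on random masks", {
  set.seed(29)
  for (rep in 1:30) {
    a <- randomMask(24, 24, 0.3)
    b <- randomMask(24, 24, 0.3)
    comb <- combineMasks(a, b)
    expect_identical(maskData(comb) > 0L,
                     maskData(a) > 0L | maskData(b) > 0L)
    lb <- maskData(comb)
    labs <- sort(unique(lb[lb > 0L]))
    expect_identical(labs, seq_along(labs))   # consecutive labels
  }
})

test_that("tiling is congruent, raster-ordered, and drops partial tiles", {
  px <- matrix(seq_len(300 * 300) %% 251L, 300, 300)
  storage.mode(px) <- "integer"
  lb <- matrix(0L, 300, 300); lb[270:280, 270:280] <- 4L
  img <- ChannelImage(px)
  m <- LabelMask(lb)
  tiles <- cropTiles(img, m, 256L)
  expect_length(tiles, 1L)
  expect_identical(dim(tiles[[1]]$image), c(256L, 256L))

  big <- cropTiles(ChannelImage(matrix(0L, 1024, 1024)),
                   LabelMask(matrix(0L, 1024, 1024)), 256L)
  expect_length(big, 16L)
  expect_identical(big[[2]]$col0, 256L)   # raster order: row block 0 first
  expect_identical(big[[2]]$row0, 0L)

  t64 <- cropTiles(img, m, 100L)
  expect_identical(tiles[[1]]$image@pixels, px[1:256, 1:256])
  expect_identical(t64[[9]]$mask@labels, lb[201:300, 201:300])
  expect_error(cropTiles(img, m, 0L), "positive")
  expect_error(cropTiles(img, m, 301L), "exceeds")
})
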