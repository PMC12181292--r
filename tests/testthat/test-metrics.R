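test_that("coverage is the exact foreground pixel fraction", {
  expect_identical(coverage(matrix(0L, 4, 4)), 0)
  expect_identical(coverage(matrix(1L, 4, 4)), 100)
  lb <- matrix(0L, 1024, 1024); lb[seq_len(262144)] <- 1L
  expect_identical(coverage(LabelMask(lb)), 25)
  expect_error(coverage(matrix(0L, 0, 0)), "empty")
})

test_that("pixel accuracy implements TP/(TP+FP+FN) with the empty convention", {
  g <- matrix(rep(c(1L, 0L), 50), 10, 10)
  expect_identical(pixelAccuracy(g, g), 1)
  # disjoint nonempty masks
  a <- matrix(0L, 4, 4); a[1, 1] <- 1L
  b <- matrix(0L, 4, 4); b[4, 4] <- 1L
  expect_identical(pixelAccuracy(a, b), 0)
  # 100 gt px, 50 predicted of them -> 50/(50+0+50)
  gt <- matrix(0L, 20, 20); gt[1:10, 1:10] <- 1L
  pr <- matrix(0L, 20, 20); pr[1:5, 1:10] <- 1L
  expect_identical(pixelAccuracy(pr, gt), 0.5)
  # both empty -> 1
  expect_identical(pixelAccuracy(matrix(0L, 3, 3), matrix(0L, 3, 3)), 1)
  expect_error(pixelAccuracy(a, matrix(0L, 3, 3)), "shape")
})

test_that("pixel accuracy is symmetric, Jaccard-equal, and 1 iff identical", {
  set.seed(61)
  for (rep in 1:20) {
    a <- randomMask(32, 32); b <- randomMask(32, 32)
    pa <- pixelAccuracy(a, b)
    expect_identical(pa, pixelAccuracy(b, a))
    A <- which(maskData(a) > 0L); B <- which(maskData(b) > 0L)
    jac <- if (!length(union(A, B))) 1 else
      length(intersect(A, B)) / length(union(A, B))
    expect_equal(pa, jac, tolerance = 1e-12)
    expect_identical(pa == 1, identical(maskData(a) > 0L, maskData(b) > 0L))
  }
})

test_that("IoU matrix matches set arithmetic", {
  sq <- matrix(0L, 20, 20); sq[1:10, 1:10] <- 1L
  expect_identical(iouMatrix(LabelMask(sq), LabelMask(sq))[1, 1], 1)
  # shifted square overlapping on 60 px -> 60 / (100 + 100 - 60)
  sh <- matrix(0L, 20, 20); sh[5:14, 1:10] <- 1L
  expect_equal(iouMatrix(LabelMask(sq), LabelMask(sh))[1, 1], 60 / 140,
               tolerance = 1e-12)
  # disjoint ROIs -> zeros
  dj <- matrix(0L, 20, 20); dj[16:20, 16:20] <- 1L
  expect_identical(as.vector(iouMatrix(LabelMask(sq), LabelMask(dj))), 0)
  # random masks vs direct set computation per pair
  set.seed(67)
  a <- randomMask(24, 24); b <- randomMask(24, 24)
  iou <- iouMatrix(a, b)
  for (i in seq_len(nrow(iou))) for (j in seq_len(ncol(iou))) {
    A <- which(maskData(a) == as.integer(rownames(iou)[i]))
    B <- which(maskData(b) == as.integer(colnames(iou)[j]))
    expect_equal(iou[i, j],
                 length(intersect(A, B)) / length(union(A, B)),
                 tolerance = 1e-12)
  }
})

test_that("object matching solves small instances exactly", {
  id2 <- diag(2)
  m <- matchObjects(id2, 0.5)
  expect_identical(c(m$tp, m$fp, m$fn), c(2L, 0L, 0L))

  one <- matrix(0.6, 1, 1)
  expect_identical(matchObjects(one, 0.5)$tp, 1L)
  m75 <- matchObjects(one, 0.75)
  expect_identical(c(m75$tp, m75$fp, m75$fn), c(0L, 1L, 1L))
  # exactly at the threshold is not admissible (strict inequality)
  expect_identical(matchObjects(matrix(0.5, 1, 1), 0.5)$tp, 0L)
  expect_error(matchObjects(one, 1), "\\(0, 1\\)")
})

test_that("object matching equals exhaustive assignment search on random matrices", {
  set.seed(71)
  for (rep in 1:60) {
    n <- sample(1:6, 1); m <- sample(1:6, 1)
    iou <- matrix(stats::runif(n * m) * stats::rbinom(n * m, 1, 0.6), n, m)
    for (t in c(0.3, 0.5, 0.75)) {
      got <- matchObjects(iou, t)
      want <- matchOracle(iou, t)
      expect_identical(got$tp, as.integer(want$tp))
      expect_equal(sum(got$matched_pairs$iou), want$total_iou,
                   tolerance = 1e-9)
      expect_identical(got$tp + got$fp, n)
      expect_identical(got$tp + got$fn, m)
      if (n <= 3 && m <= 3) {
        tiny <- matchOracleTiny(iou, t)
        expect_equal(want$tp, tiny$tp)
        expect_equal(want$total_iou, tiny$total_iou, tolerance = 1e-9)
      }
    }
  }
})

test_that("average precision follows matching and the empty-mask convention", {
  sq <- LabelMask(stampRect(matrix(0L, 20, 20), 1, 1, 10, 10, 1L))
  expect_identical(unname(averagePrecision(sq, sq)), c(1, 1))

  # single pair at IoU 0.6: AP 1 at 0.5, 0 at 0.75
  sh <- LabelMask(stampRect(matrix(0L, 20, 20), 3, 1, 10, 10, 1L))
  iou <- iouMatrix(sq, sh)[1, 1]
  expect_gt(iou, 0.5); expect_lt(iou, 0.75)
  ap <- averagePrecision(sq, sh)
  expect_identical(unname(ap), c(1, 0))

  empty <- LabelMask(matrix(0L, 20, 20))
  expect_identical(unname(averagePrecision(empty, empty)), c(1, 1))
  expect_identical(unname(averagePrecision(sq, empty)), c(0, 0))

  # 5 gt ROIs; prediction misses one and splits another -> oracle-checked
  gt <- matrix(0L, 40, 40)
  gt[1:5, 1:5] <- 1L; gt[1:5, 11:15] <- 2L; gt[11:15, 1:5] <- 3L
  gt[11:15, 11:15] <- 4L; gt[21:30, 21:30] <- 5L
  pr <- gt
  pr[gt == 2L] <- 0L                       # missed ROI
  pr[21:30, 21:25] <- 6L                   # ROI 5 split in two
  pr <- validateLabelMask(pr)
  iouM <- iouMatrix(pr, LabelMask(gt))
  want <- matchOracle(iouM, 0.5)
  ap5 <- averagePrecision(pr, LabelMask(gt), 0.5)
  nP <- nRoi(pr); nG <- 5L
  expect_equal(unname(ap5),
               want$tp / (want$tp + (nP - want$tp) + (nG - want$tp)),
               tolerance = 1e-12)
})

test_that("AP is monotone non-increasing in the IoU threshold", {
  set.seed(73)
  for (rep in 1:15) {
    a <- randomMask(32, 32); b <- randomMask(32, 32)
    ap <- averagePrecision(a, b, c(0.3, 0.5, 0.75, 0.9))
    expect_true(all(diff(unname(ap)) <= 1e-12))
  }
})

test_that("size-stratified evaluation splits at the area cutoff", {
  # one 50-px and one 500-px reference ROI; prediction hits the large one
  # exactly and misses the small one
  gt <- matrix(0L, 60, 60)
  gt[1:5, 1:10] <- 1L                       # 50 px (small at cutoff 101)
  gt[21:40, 21:45] <- 2L                    # 500 px (large)
  pr <- matrix(0L, 60, 60)
  pr[21:40, 21:45] <- 1L
  rep3 <- stratifiedEval(LabelMask(pr), LabelMask(gt), cutoff = 101L)
  expect_identical(rep3$small$n_gt, 1L)
  expect_identical(rep3$small$n_pred, 0L)
  expect_identical(unname(rep3$small$ap_by_threshold), c(0, 0))
  expect_identical(rep3$large$pixel_accuracy, 1)
  expect_identical(unname(rep3$large$ap_by_threshold), c(1, 1))
  expect_equal(rep3$all$pixel_accuracy, 500 / 550, tolerance = 1e-12)

  # cutoff 1: everything is "large"; all-small gt mirrors the full report
  repC <- stratifiedEval(LabelMask(pr), LabelMask(gt), cutoff = 1L)
  expect_identical(repC$large$pixel_accuracy, repC$all$pixel_accuracy)
  expect_identical(repC$small$n_gt, 0L)

  gtSmall <- matrix(0L, 30, 30); gtSmall[1:3, 1:3] <- 1L; gtSmall[10, 10] <- 2L
  prSmall <- gtSmall
  repS <- stratifiedEval(LabelMask(prSmall), LabelMask(gtSmall), cutoff = 101L)
  expect_identical(repS$small$pixel_accuracy, repS$all$pixel_accuracy)
  expect_identical(repS$small$n_gt, repS$all$n_gt)
  expect_error(stratifiedEval(LabelMask(pr), LabelMask(gt), cutoff = 0L),
               "cutoff")
})

test_that("coverage summaries report group means and n-1 standard deviations", {
  rec <- rbind(
    coverageRecord("a1", 1, 10, 100), coverageRecord("a2", 1, 20, 100),
    coverageRecord("a3", 1, 30, 100), coverageRecord("b1", 1, 50, 100))
  rec$day <- c("d2", "d2", "d2", "d8")
  s <- summarizeCoverage(rec, "day")
  expect_identical(nrow(s), 2L)
  d2 <- s[s$group == "d2", ]
  expect_identical(d2$n, 3L)
  expect_identical(d2$mean_pct, 20)
  expect_identical(d2$sd_pct, 10)
  d8 <- s[s$group == "d8", ]
  expect_identical(d8$n, 1L)
  expect_identical(d8$sd_pct, 0)   # degenerate group flagged by n = 1
  expect_error(summarizeCoverage(rec[0, ], "day"), "no coverage")
})
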