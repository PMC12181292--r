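.binary <- function(x) {
  if (is(x, "LabelMask")) return(maskData(x) > 0L)
  if (is(x, "ChannelImage")) return(pixelData(x) > 0L)
  if (is.matrix(x)) return(x > 0)
  stop("expected a LabelMask, ChannelImage or matrix")
}

#' Microbial surface coverage (percent)
#'
#' The workflow's central read-out: the percentage of image pixels classified
#' as microbial,
#' `cov = 100 * (pixels belonging to microorganisms) / (total pixels)`.
#'
#' @param mask a [LabelMask], binary/logical matrix or [ChannelImage]
#'   (positive pixels are foreground).
#' @return coverage in percent, a number in `[0, 100]`.
#' @examples
#' coverage(matrix(c(1, 0, 0, 0), 2, 2))  # 25
#' @export
coverage <- function(mask) {
  fg <- .binary(mask)
  if (!length(fg)) stop("empty image")
  100 * sum(fg) / length(fg)
}

#' Pixel-level segmentation accuracy (Jaccard)
#'
#' Binarizes both masks and scores `TP / (TP + FP + FN)` where a true
#' positive is a pixel correctly identified as belonging to a microorganism,
#' a false positive a predicted pixel absent from the reference and a false
#' negative a missed reference pixel. This equals the Jaccard index
#' `|A ∩ B| / |A ∪ B|` of the two foregrounds and is symmetric. If both
#' masks are empty the score is 1 by convention.
#'
#' @param pred,gt predicted and reference masks ([LabelMask] or matrix), same
#'   shape.
#' @return accuracy in `[0, 1]`; 1 exactly when the binarized masks are
#'   identical.
#' @export
pixelAccuracy <- function(pred, gt) {
  p <- .binary(pred); g <- .binary(gt)
  if (!identical(dim(p), dim(g))) stop("mask shapes differ")
  tp <- sum(p & g)
  fp <- sum(p & !g)
  fn <- sum(!p & g)
  if (tp + fp + fn == 0L) return(1)
  tp / (tp + fp + fn)
}

#' Pairwise IoU matrix between predicted and reference ROIs
#'
#' Entry `(i, j)` is the intersection-over-union
#' `|pred_i ∩ gt_j| / |pred_i ∪ gt_j|` between the i-th predicted and j-th
#' reference ROI: 1 for perfectly overlapping objects, 0 for disjoint ones.
#' Row/column names carry the ROI labels.
#'
#' @param pred,gt [LabelMask]s of the same shape.
#' @return a numeric matrix, `nRoi(pred)` rows by `nRoi(gt)` columns.
#' @export
iouMatrix <- function(pred, gt) {
  stopifnot(is(pred, "LabelMask"), is(gt, "LabelMask"))
  if (!identical(dim(pred), dim(gt))) stop("mask shapes differ")
  pl <- maskData(pred); gl <- maskData(gt)
  pLab <- sort(unique(pl[pl > 0L])); gLab <- sort(unique(gl[gl > 0L]))
  iou <- matrix(0, length(pLab), length(gLab),
                dimnames = list(pLab, gLab))
  if (!length(pLab) || !length(gLab)) return(iou)
  pArea <- tabulate(pl[pl > 0L]); gArea <- tabulate(gl[gl > 0L])
  sel <- pl > 0L & gl > 0L
  if (any(sel)) {
    inter <- table(factor(pl[sel], levels = pLab),
                   factor(gl[sel], levels = gLab))
    inter <- matrix(as.numeric(inter), nrow = length(pLab))
    uni <- outer(pArea[pLab], gArea[gLab], "+") - inter
    iou[] <- inter / uni
  }
  iou
}

#' Match predicted to reference ROIs at an IoU threshold
#'
#' One-to-one matching in the style of the standard instance-segmentation
#' evaluation: among all one-to-one assignments of predicted to reference
#' ROIs using only pairs with `iou > threshold` (strictly), the matching
#' maximizes the number of matched pairs, breaking ties by larger total IoU.
#' Matched pairs count as true positives; unmatched predicted ROIs are false
#' positives and unmatched reference ROIs false negatives.
#'
#' Internally the optimum is found by maximum-weight bipartite matching over
#' the admissible pairs with cardinality-dominant weights, an equivalent
#' formulation of the optimal-assignment approach used by reference
#' implementations.
#'
#' @param iou an IoU matrix from [iouMatrix()] (rows = predicted ROIs,
#'   columns = reference ROIs).
#' @param threshold IoU threshold in `(0, 1)`; a pair at exactly the
#'   threshold is not admissible.
#' @return an object of class `MatchResult`: a list with `iou_threshold`,
#'   counts `tp`, `fp`, `fn`, and `matched_pairs` (data.frame of
#'   `pred_label`, `gt_label`, `iou`, ordered by predicted label).
#' @export
matchObjects <- function(iou, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  iou <- as.matrix(iou)
  nP <- nrow(iou); nG <- ncol(iou)
  pLab <- rownames(iou) %||% as.character(seq_len(nP))
  gLab <- colnames(iou) %||% as.character(seq_len(nG))
  adm <- which(iou > threshold, arr.ind = TRUE)
  pairs <- data.frame(pred_label = integer(0), gt_label = integer(0),
                      iou = numeric(0))
  if (nrow(adm)) {
    # Bipartite graph over admissible pairs; weights 1 + iou/K with
    # K > number of admissible edges make cardinality dominate total IoU.
    K <- nrow(adm) + 1
    edges <- rbind(adm[, 1L], nP + adm[, 2L])
    g <- igraph::make_bipartite_graph(c(rep(FALSE, nP), rep(TRUE, nG)),
                                      as.vector(edges))
    w <- 1 + iou[adm] / K
    m <- igraph::max_bipartite_match(g, weights = w)$matching
    mi <- which(!is.na(m[seq_len(nP)]))
    if (length(mi)) {
      gj <- m[mi] - nP
      pairs <- data.frame(pred_label = as.integer(pLab[mi]),
                          gt_label = as.integer(gLab[gj]),
                          iou = iou[cbind(mi, gj)])
      pairs <- pairs[order(pairs$pred_label), , drop = FALSE]
      rownames(pairs) <- NULL
    }
  }
  structure(list(iou_threshold = threshold, tp = nrow(pairs),
                 fp = nP - nrow(pairs), fn = nG - nrow(pairs),
                 matched_pairs = pairs),
            class = "MatchResult")
}

#' @export
print.MatchResult <- function(x, ...) {
  cat(sprintf("MatchResult @ IoU > %g: TP = %d, FP = %d, FN = %d\n",
              x$iou_threshold, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Average precision at IoU thresholds
#'
#' Object-level counterpart of [pixelAccuracy()]: for each IoU threshold,
#' ROIs are matched one-to-one by [matchObjects()] and
#' `AP = TP / (TP + FP + FN)`. The customary reporting thresholds are 0.5
#' and 0.75. If both masks are empty, AP is 1 by convention. AP is monotone
#' non-increasing in the threshold.
#'
#' @param pred,gt [LabelMask]s of the same shape.
#' @param thresholds numeric vector of IoU thresholds in `(0, 1)`.
#' @return a named numeric vector, one AP value per threshold.
#' @export
averagePrecision <- function(pred, gt, thresholds = c(0.5, 0.75)) {
  iou <- iouMatrix(pred, gt)
  vapply(thresholds, function(t) {
    m <- matchObjects(iou, t)
    denom <- m$tp + m$fp + m$fn
    if (denom == 0L) 1 else m$tp / denom
  }, numeric(1)) |> stats::setNames(as.character(thresholds))
}

#' Size-stratified segmentation evaluation
#'
#' Evaluates a prediction separately for small and large objects, splitting
#' reference ROIs by pixel area at `cutoff` (small: area < cutoff; large:
#' area >= cutoff; default 101 px, the boundary between the single-cell and
#' microcolony regimes). Each predicted ROI is assigned to the stratum of
#' the reference ROI it overlaps most; predicted ROIs overlapping no
#' reference ROI are assigned by their own area. Pixel accuracy and AP are
#' then computed within each stratum, alongside the unstratified report.
#'
#' @param pred,gt [LabelMask]s of the same shape.
#' @param cutoff positive area cutoff in pixels (default 101).
#' @param thresholds IoU thresholds for the AP entries.
#' @return a named list of three reports (`all`, `small`, `large`), each a
#'   list with `stratum`, `size_cutoff_px`, `pixel_accuracy`,
#'   `ap_by_threshold`, `n_gt`, `n_pred`.
#' @export
stratifiedEval <- function(pred, gt, cutoff = 101L,
                           thresholds = c(0.5, 0.75)) {
  stopifnot(is(pred, "LabelMask"), is(gt, "LabelMask"))
  if (cutoff < 1L) stop("cutoff must be at least 1")
  if (!identical(dim(pred), dim(gt))) stop("mask shapes differ")
  pl <- maskData(pred); gl <- maskData(gt)
  pLab <- sort(unique(pl[pl > 0L])); gLab <- sort(unique(gl[gl > 0L]))
  gArea <- tabulate(gl[gl > 0L]); pArea <- tabulate(pl[pl > 0L])
  gSmall <- gLab[gArea[gLab] < cutoff]

  # Assign each predicted ROI to a stratum via its best-overlap reference ROI.
  pSmall <- integer(0)
  if (length(pLab)) {
    sel <- pl > 0L & gl > 0L
    best <- rep(NA_integer_, max(pLab))
    if (any(sel)) {
      ov <- table(factor(pl[sel], levels = pLab),
                  factor(gl[sel], levels = gLab))
      ov <- matrix(as.numeric(ov), nrow = length(pLab))
      hit <- rowSums(ov) > 0
      best[pLab[hit]] <- gLab[max.col(ov[hit, , drop = FALSE],
                                      ties.method = "first")]
    }
    ownSmall <- pArea[pLab] < cutoff
    inSmall <- ifelse(is.na(best[pLab]), ownSmall, best[pLab] %in% gSmall)
    pSmall <- pLab[inSmall]
  }

  restrict <- function(m, keep) {
    lb <- maskData(m)
    lb[!(lb %in% keep)] <- 0L
    LabelMask(lb)
  }
  report <- function(p, g, stratum) {
    list(stratum = stratum, size_cutoff_px = as.integer(cutoff),
         pixel_accuracy = pixelAccuracy(p, g),
         ap_by_threshold = averagePrecision(p, g, thresholds),
         n_gt = nRoi(g), n_pred = nRoi(p))
  }
  list(
    all = report(pred, gt, "all"),
    small = report(restrict(pred, pSmall), restrict(gt, gSmall), "small"),
    large = report(restrict(pred, setdiff(pLab, pSmall)),
                   restrict(gt, setdiff(gLab, gSmall)), "large"))
}

#' Group-wise summary of coverage records
#'
#' Arithmetic mean and sample (n-1) standard deviation of `coverage_pct` per
#' group, the conventional "mean (± sd)" reporting for biological replicates.
#' Groups with a single record report `sd_pct = 0`; their `n` column flags
#' the degeneracy.
#'
#' @param records a data.frame of coverage records (see [coverageRecord()])
#'   containing `coverage_pct` and the grouping column.
#' @param groupKey name of the grouping column.
#' @return a data.frame with columns `group`, `n`, `mean_pct`, `sd_pct`.
#' @export
summarizeCoverage <- function(records, groupKey) {
  if (!is.data.frame(records) || !nrow(records)) stop("no coverage records")
  if (!groupKey %in% names(records))
    stop("grouping column '", groupKey, "' not found")
  if (!"coverage_pct" %in% names(records))
    stop("records must contain a coverage_pct column")
  groups <- split(records$coverage_pct, records[[groupKey]])
  out <- data.frame(
    group = names(groups),
    n = vapply(groups, length, integer(1)),
    mean_pct = vapply(groups, mean, numeric(1)),
    sd_pct = vapply(groups, function(x)
      if (length(x) < 2L) 0 else stats::sd(x), numeric(1)))
  rownames(out) <- NULL
  out
}
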