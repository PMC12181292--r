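# Independent oracles and fixture builders used across the suite.
# Oracles deliberately avoid the package's own code paths.

# Random label mask: threshold smoothed uniform noise, then label components
# with a plain flood fill (not the package's labeller).
randomBinary <- function(h = 32L, w = 32L, density = 0.35) {
  x <- matrix(stats::runif(h * w), h, w)
  # cheap smoothing: average with 4-neighbour shifts to create blobs
  s <- x
  s[-1, ] <- s[-1, ] + x[-h, ]
  s[-h, ] <- s[-h, ] + x[-1, ]
  s[, -1] <- s[, -1] + x[, -w]
  s[, -w] <- s[, -w] + x[, -1]
  s >= stats::quantile(s, 1 - density)
}

# Flood-fill component labelling, 8-connectivity, used as a slow reference.
floodLabel <- function(bin) {
  h <- nrow(bin); w <- ncol(bin)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (!bin[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= h && c >= 1 && c <= w &&
            bin[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

randomMask <- function(h = 32L, w = 32L, density = 0.35) {
  LabelMask(floodLabel(randomBinary(h, w, density)))
}

# Exhaustive assignment-search oracle for object matching: maximises matched
# pair count, then total IoU, over all one-to-one assignments of admissible
# pairs (iou strictly above the threshold). Bitmask dynamic programme == full
# enumeration for the <= 6x6 matrices it is used on.
matchOracle <- function(iou, threshold) {
  n <- nrow(iou); m <- ncol(iou)
  best <- new.env(parent = emptyenv())
  assign("0", c(0, 0), envir = best)   # mask of used gt cols -> c(count, iou)
  better <- function(a, b) a[1] > b[1] || (a[1] == b[1] && a[2] > b[2] + 1e-12)
  for (i in seq_len(n)) {
    nxt <- new.env(parent = emptyenv())
    for (key in ls(best)) {
      val <- get(key, envir = best)
      mask <- as.integer(key)
      upd <- function(k, v) {
        kk <- as.character(k)
        if (!exists(kk, envir = nxt) || better(v, get(kk, envir = nxt)))
          assign(kk, v, envir = nxt)
      }
      upd(mask, val)                       # leave pred i unmatched
      for (j in seq_len(m)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(mask, bit) == 0L && iou[i, j] > threshold)
          upd(bitwOr(mask, bit), val + c(1, iou[i, j]))
      }
    }
    best <- nxt
  }
  out <- c(0, 0)
  for (key in ls(best)) {
    v <- get(key, envir = best)
    if (better(v, out)) out <- v
  }
  list(tp = out[1], total_iou = out[2])
}

# Literal permutation enumeration for tiny matrices, cross-checking the DP.
matchOracleTiny <- function(iou, threshold) {
  n <- nrow(iou); m <- ncol(iou)
  stopifnot(n <= 3L, m <= 3L)
  cols <- c(seq_len(m), rep(0L, n))      # 0 = unmatched
  grid <- do.call(expand.grid, rep(list(cols), n))
  bestTp <- 0; bestIou <- 0
  for (k in seq_len(nrow(grid))) {
    a <- as.integer(grid[k, ])
    used <- a[a > 0L]
    if (anyDuplicated(used)) next
    ok <- vapply(seq_len(n), function(i)
      a[i] == 0L || iou[i, a[i]] > threshold, logical(1))
    if (!all(ok)) next
    tp <- sum(a > 0L)
    tot <- sum(vapply(seq_len(n), function(i)
      if (a[i] > 0L) iou[i, a[i]] else 0, numeric(1)))
    if (tp > bestTp || (tp == bestTp && tot > bestIou)) {
      bestTp <- tp; bestIou <- tot
    }
  }
  list(tp = bestTp, total_iou = bestIou)
}

# Dense direct Gaussian convolution with replicate padding (independent of
# the package's separable band-matrix route); small images only.
denseGaussBlur <- function(px, sigma) {
  r <- ceiling(3 * sigma)
  w <- exp(-((-r:r)^2) / (2 * sigma^2)); w <- w / sum(w)
  K <- outer(w, w)
  h <- nrow(px); wd <- ncol(px)
  padIdxR <- pmin(pmax(seq(1 - r, h + r), 1), h)
  padIdxC <- pmin(pmax(seq(1 - r, wd + r), 1), wd)
  P <- px[padIdxR, padIdxC]
  out <- matrix(0, h, wd)
  for (i in seq_len(h)) for (j in seq_len(wd))
    out[i, j] <- sum(P[i:(i + 2 * r), j:(j + 2 * r)] * K)
  out
}

# Reference flatfield built on the dense oracle blur.
denseFlatfield <- function(px, sigma) {
  S <- pmax(denseGaussBlur(px, sigma), 1e-6)
  floor(pmin(pmax(px * mean(S) / S, 0), 255) + 0.5)
}

# A rectangle-stamping image/mask builder for constructed fixtures.
stampRect <- function(mat, r0, c0, h, w, value) {
  mat[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- value
  mat
}
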