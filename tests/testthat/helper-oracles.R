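# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the IoU oracle counts unit pixels on a grid, the
# AP oracle walks the cumulative precision/recall sequence point by point.

# IoU of two integer-coordinate corner boxes by rasterising unit pixels.
rasterIoU <- function(ax1, ay1, ax2, ay2, bx1, by1, bx2, by2) {
  xs <- min(ax1, bx1):(max(ax2, bx2) - 1L)
  ys <- min(ay1, by1):(max(ay2, by2) - 1L)
  inA <- outer(ys >= ay1 & ys < ay2, xs >= ax1 & xs < ax2, "&")
  inB <- outer(ys >= by1 & ys < by2, xs >= bx1 & bx2 > xs, "&")
  sum(inA & inB) / sum(inA | inB)
}

# Random valid integer-coordinate corner box within [0, lim]^2.
randomIntBox <- function(lim = 40L) {
  x <- sort(sample(0:lim, 2))
  y <- sort(sample(0:lim, 2))
  while (x[1] == x[2]) x <- sort(sample(0:lim, 2))
  while (y[1] == y[2]) y <- sort(sample(0:lim, 2))
  c(x1 = x[1], y1 = y[1], x2 = x[2], y2 = y[2])
}

randomBBox <- function(lim = 40L) {
  b <- randomIntBox(lim)
  bboxFromCorners(b["x1"], b["y1"], b["x2"], b["y2"])
}

# Brute-force average precision: enumerate every prefix of the
# confidence-sorted detections, record (recall, precision), then integrate
# recall steps against the running max precision to the right -- all with
# explicit loops, no shared code with the package.
bruteAP <- function(isTP, nTruth) {
  if (nTruth == 0L) return(NA_real_)
  n <- length(isTP)
  if (n == 0L) return(0)
  rec <- numeric(n); prec <- numeric(n)
  tp <- 0
  for (i in seq_len(n)) {
    tp <- tp + isTP[i]
    prec[i] <- tp / i
    rec[i] <- tp / nTruth
  }
  ap <- 0
  prevR <- 0
  for (i in seq_len(n)) {
    maxP <- 0
    for (j in i:n) if (prec[j] > maxP) maxP <- prec[j]
    ap <- ap + (rec[i] - prevR) * maxP
    prevR <- rec[i]
  }
  ap
}

# A tiny random single-class, single-frame detection instance: n boxes drawn
# near k truths so that TP/FP outcomes vary.
randomEvalInstance <- function(maxBoxes = 6L) {
  k <- sample(1:3, 1)
  tr <- do.call(rbind, lapply(seq_len(k), function(i) {
    c(cx = runif(1, 10, 90), cy = runif(1, 10, 90),
      w = runif(1, 5, 20), h = runif(1, 5, 20))
  }))
  truths <- groundTruths(rep("f1", k), rep("seed", k),
                         tr[, "cx"], tr[, "cy"], tr[, "w"], tr[, "h"])
  n <- sample(1:maxBoxes, 1)
  src <- sample(seq_len(k), n, replace = TRUE)
  jit <- matrix(runif(4 * n, -8, 8), n, 4)
  dets <- detections(rep("f1", n), rep("seed", n),
                     tr[src, "cx"] + jit[, 1], tr[src, "cy"] + jit[, 2],
                     pmax(1, tr[src, "w"] + jit[, 3]),
                     pmax(1, tr[src, "h"] + jit[, 4]),
                     confidence = round(runif(n), 3))
  list(dets = dets, truths = truths)
}

# Plain-arithmetic IoU for the helper matcher (center-form rows).
helperIoU <- function(a, b) {
  ax1 <- a["cx"] - a["w"] / 2; ax2 <- a["cx"] + a["w"] / 2
  ay1 <- a["cy"] - a["h"] / 2; ay2 <- a["cy"] + a["h"] / 2
  bx1 <- b["cx"] - b["w"] / 2; bx2 <- b["cx"] + b["w"] / 2
  by1 <- b["cy"] - b["h"] / 2; by2 <- b["cy"] + b["h"] / 2
  iw <- max(0, min(ax2, bx2) - max(ax1, bx1))
  ih <- max(0, min(ay2, by2) - max(ay1, by1))
  inter <- iw * ih
  unname(inter / (a["w"] * a["h"] + b["w"] * b["h"] - inter))
}

# Fully independent single-class AP: greedy best-IoU matching in confidence
# order, then bruteAP over the TP flags.
bruteMatchAP <- function(dets, truths, thr = 0.5) {
  ord <- order(-dets$confidence)
  matched <- rep(FALSE, nrow(truths))
  isTP <- integer(length(ord))
  for (pos in seq_along(ord)) {
    i <- ord[pos]
    bestIoU <- -1; bestJ <- 0L
    for (j in seq_len(nrow(truths))) {
      if (matched[j] || truths$frameId[j] != dets$frameId[i]) next
      v <- helperIoU(unlist(dets[i, c("cx", "cy", "w", "h")]),
                     unlist(truths[j, c("cx", "cy", "w", "h")]))
      if (v > bestIoU) { bestIoU <- v; bestJ <- j }
    }
    if (bestJ > 0L && bestIoU >= thr) {
      matched[bestJ] <- TRUE
      isTP[pos] <- 1L
    }
  }
  bruteAP(isTP, nrow(truths))
}
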