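#' @include AllClasses.R AllGenerics.R
NULL

# ---- internal fast path ----------------------------------------------------
# A box travels internally as numeric c(cx, cy, w, h); the S4 surface wraps
# these for user-facing calls while the regression harness and the evaluator
# stay allocation-light.

.EPS <- 1e-9

.asVec <- function(b) c(b@cx, b@cy, b@w, b@h)

.vecCorners <- function(b) {
  c(b[1] - b[3] / 2, b[2] - b[4] / 2, b[1] + b[3] / 2, b[2] + b[4] / 2)
}

.checkVec <- function(b) {
  if (any(!is.finite(b)) || b[3] <= 0 || b[4] <= 0)
    stop("invalid box: width and height must be strictly positive and finite")
  invisible(b)
}

.iouVec <- function(a, b) {
  ca <- .vecCorners(a); cb <- .vecCorners(b)
  iw <- min(ca[3], cb[3]) - max(ca[1], cb[1])
  ih <- min(ca[4], cb[4]) - max(ca[2], cb[2])
  inter <- max(0, iw) * max(0, ih)
  union <- a[3] * a[4] + b[3] * b[4] - inter
  inter / union
}

# All geometric terms and the six losses for one (pred, truth) pair.
.lossTerms <- function(pred, truth) {
  cp <- .vecCorners(pred); ct <- .vecCorners(truth)
  iw <- min(cp[3], ct[3]) - max(cp[1], ct[1])
  ih <- min(cp[4], ct[4]) - max(cp[2], ct[2])
  inter <- max(0, iw) * max(0, ih)
  union <- pred[3] * pred[4] + truth[3] * truth[4] - inter
  iouv <- inter / union

  cw <- max(cp[3], ct[3]) - min(cp[1], ct[1])
  ch <- max(cp[4], ct[4]) - min(cp[2], ct[2])
  if (cw <= 0 || ch <= 0)
    stop("degenerate enclosing box: boxes must have positive extent")
  c2 <- cw^2 + ch^2
  rho2 <- (pred[1] - truth[1])^2 + (pred[2] - truth[2])^2

  # aspect-ratio consistency and its trade-off weight
  v <- (4 / pi^2) * (atan(truth[3] / truth[4]) - atan(pred[3] / pred[4]))^2
  alpha <- if (v == 0) 0 else v / ((1 - iouv) + v + .EPS)

  cArea <- cw * ch
  giou <- iouv - (cArea - union) / cArea

  edgeH <- (pred[4] - truth[4])^2 / ch^2
  edgeW <- (pred[3] - truth[3])^2 / cw^2

  lossCiou <- 1 - iouv + rho2 / c2 + alpha * v
  list(
    iou = iouv, rho2 = rho2, c2 = c2, cw = cw, ch = ch, v = v, alpha = alpha,
    lossIou = 1 - iouv,
    lossGiou = 1 - giou,
    lossDiou = 1 - iouv + rho2 / c2,
    lossCiou = lossCiou,
    lossEiou = 1 - iouv + rho2 / c2 + edgeH + edgeW,
    lossEciou = lossCiou + edgeH + edgeW
  )
}

.LOSS_NAMES <- c("iou", "giou", "diou", "ciou", "eiou", "eciou")

.lossValueVec <- function(lossName, pred, truth) {
  t <- .lossTerms(pred, truth)
  switch(lossName,
    iou = t$lossIou, giou = t$lossGiou, diou = t$lossDiou,
    ciou = t$lossCiou, eiou = t$lossEiou, eciou = t$lossEciou,
    stop(sprintf("unknown loss '%s'; choose one of %s", lossName,
                 paste(.LOSS_NAMES, collapse = ", ")))
  )
}

# ---- constructors ----------------------------------------------------------

#' Construct a bounding box
#'
#' `bbox()` builds a [BBox-class] from center form; `bboxFromCorners()`
#' from corner form `(x1, y1, x2, y2)` with `x1 < x2`, `y1 < y2`.
#'
#' @param cx,cy box center (pixels).
#' @param w,h box width and height (pixels, > 0).
#' @param x1,y1,x2,y2 corner coordinates (pixels).
#' @return A [BBox-class].
#' @examples
#' b <- bbox(cx = 1, cy = 1, w = 2, h = 2)
#' corners(b)
#' bboxFromCorners(0, 0, 2, 2)
#' @export
bbox <- function(cx, cy, w, h) {
  new("BBox", cx = as.numeric(cx), cy = as.numeric(cy),
      w = as.numeric(w), h = as.numeric(h))
}

#' @rdname bbox
#' @export
bboxFromCorners <- function(x1, y1, x2, y2) {
  bbox((x1 + x2) / 2, (y1 + y2) / 2, x2 - x1, y2 - y1)
}

# ---- accessors and show ----------------------------------------------------

#' @rdname accessors
setMethod("boxCenter", "BBox", function(x) c(cx = x@cx, cy = x@cy))

#' @rdname accessors
setMethod("boxWidth", "BBox", function(x) x@w)

#' @rdname accessors
setMethod("boxHeight", "BBox", function(x) x@h)

#' @rdname accessors
setMethod("corners", "BBox", function(x) {
  v <- .vecCorners(.asVec(x))
  names(v) <- c("x1", "y1", "x2", "y2")
  v
})

setMethod("show", "BBox", function(object) {
  cat(sprintf("BBox center (%.6g, %.6g), %0.6g x %0.6g px\n",
              object@cx, object@cy, object@w, object@h))
})

#' @rdname accessors
setMethod("lossValues", "LossBreakdown", function(x) {
  c(iou = x@lossIou, giou = x@lossGiou, diou = x@lossDiou,
    ciou = x@lossCiou, eiou = x@lossEiou, eciou = x@lossEciou)
})

setMethod("show", "LossBreakdown", function(object) {
  cat("LossBreakdown\n")
  cat(sprintf("  IoU %.4f | rho2 %.4g / c2 %.4g | v %.4g (alpha %.4g)\n",
              object@iou, object@rho2Center, object@c2, object@v, object@alpha))
  lv <- lossValues(object)
  cat("  losses:", paste(sprintf("%s=%.4f", names(lv), lv), collapse = " "), "\n")
})

# ---- operations ------------------------------------------------------------

#' @rdname iou
setMethod("iou", signature("BBox", "BBox"), function(a, b) {
  .iouVec(.checkVec(.asVec(a)), .checkVec(.asVec(b)))
})

#' Geometric terms and the six IoU-family losses for a box pair
#'
#' Computes, for a predicted and a true box, the overlap ratio, the squared
#' center distance, the smallest enclosing box, the aspect-ratio term
#' `v = (4/pi^2) (arctan(w_gt/h_gt) - arctan(w/h))^2` with trade-off weight
#' `alpha = v / ((1 - IoU) + v)` (0 when `v = 0`), and from them the IoU,
#' GIoU, DIoU, CIoU, EIoU and ECIoU losses. ECIoU augments CIoU with the
#' separated width/height penalties of EIoU,
#' `(h - h_gt)^2 / ch^2 + (w - w_gt)^2 / cw^2`, so that both edges can be
#' optimised directly rather than only their ratio.
#'
#' @param pred,truth [BBox-class] prediction and ground truth.
#' @return A [LossBreakdown-class].
#' @examples
#' lb <- lossBreakdown(bboxFromCorners(0, 0, 2, 2), bboxFromCorners(2, 2, 6, 6))
#' lossValues(lb)["eciou"]  # 1.25 + 2/9
#' @export
setMethod("lossBreakdown", signature("BBox", "BBox"), function(pred, truth) {
  p <- .checkVec(.asVec(pred)); tr <- .checkVec(.asVec(truth))
  t <- .lossTerms(p, tr)
  new("LossBreakdown",
      iou = t$iou, rho2Center = t$rho2, c2 = t$c2, cw = t$cw, ch = t$ch,
      v = t$v, alpha = t$alpha,
      lossIou = t$lossIou, lossGiou = t$lossGiou, lossDiou = t$lossDiou,
      lossCiou = t$lossCiou, lossEiou = t$lossEiou, lossEciou = t$lossEciou)
})

#' Evaluate a single named box-regression loss
#'
#' Convenience wrapper around [lossBreakdown()] returning one scalar.
#'
#' @param pred,truth [BBox-class] prediction and ground truth.
#' @param loss one of `"iou"`, `"giou"`, `"diou"`, `"ciou"`, `"eiou"`,
#'   `"eciou"`.
#' @return The loss value (nonnegative; 0 iff the boxes coincide).
#' @export
boxLoss <- function(pred, truth, loss = c("iou", "giou", "diou", "ciou", "eiou", "eciou")) {
  loss <- match.arg(loss)
  .lossValueVec(loss, .checkVec(.asVec(pred)), .checkVec(.asVec(truth)))
}

#' Detection-head feature-map size and minimum detectable target
#'
#' For a detection head of a given stride on a square input, the feature map
#' side is `input_size / stride` and the smallest target the head can
#' resolve is `stride x stride` pixels. A stride-4 head on a 640-px input
#' yields a 160x160 map resolving targets of 4x4 px and larger -- the
#' small-target head that makes early radicles detectable; stride-8, -16 and
#' -32 heads give the standard 80x80, 40x40 and 20x20 maps.
#'
#' @param stride feature-map stride; one of 4, 8, 16, 32.
#' @param inputSize square input side in pixels; must be divisible by
#'   `stride`.
#' @return Named numeric: `featureMapSide`, `minTargetSide`.
#' @examples
#' minDetectableSize(4, 640)   # 160x160 map, 4x4 minimum target
#' @export
minDetectableSize <- function(stride, inputSize = 640) {
  if (!stride %in% c(4, 8, 16, 32))
    stop("stride must be one of 4, 8, 16, 32")
  if (inputSize %% stride != 0)
    stop("inputSize must be divisible by the stride")
  c(featureMapSide = inputSize / stride, minTargetSide = stride)
}
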