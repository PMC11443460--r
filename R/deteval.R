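#' @include boxgeom.R
NULL

#' Object-class vocabulary
#'
#' The three labels used throughout: `seed` (ungerminated seed body),
#' `S_root` (radicle shorter than half the seed length) and `L_root`
#' (radicle at least half the seed length -- the germination standard).
#' `L_root` detections drive all vigor statistics.
#'
#' @return Character vector of the three class names, in the fixed index
#'   order used by the YOLO text format (seed = 0, S_root = 1, L_root = 2).
#' @export
classVocabulary <- function() c("seed", "S_root", "L_root")

.checkLabels <- function(label) {
  bad <- setdiff(unique(label), classVocabulary())
  if (length(bad))
    stop(sprintf("unknown class label(s): %s (vocabulary: %s)",
                 paste(bad, collapse = ", "),
                 paste(classVocabulary(), collapse = ", ")))
  invisible(label)
}

#' Build detection and ground-truth tables
#'
#' Detections and ground truths travel as plain data.frames with one row per
#' box: columns `frameId`, `label`, `cx`, `cy`, `w`, `h` and, for
#' detections, `confidence` in `[0, 1]`. These constructors validate the
#' vocabulary and geometry.
#'
#' @param frameId image identifier (character or coercible).
#' @param label class label, from [classVocabulary()].
#' @param cx,cy,w,h box geometry in pixels (center form).
#' @param confidence detection score in `[0, 1]`.
#' @return A data.frame in the detection (resp. ground-truth) contract.
#' @export
detections <- function(frameId, label, cx, cy, w, h, confidence) {
  .checkLabels(label)
  if (any(confidence < 0 | confidence > 1))
    stop("confidence must lie in [0, 1]")
  if (any(w <= 0 | h <= 0)) stop("invalid box: nonpositive width or height")
  data.frame(frameId = as.character(frameId), label = label,
             cx = cx, cy = cy, w = w, h = h, confidence = confidence,
             stringsAsFactors = FALSE)
}

#' @rdname detections
#' @export
groundTruths <- function(frameId, label, cx, cy, w, h) {
  .checkLabels(label)
  if (any(w <= 0 | h <= 0)) stop("invalid box: nonpositive width or height")
  data.frame(frameId = as.character(frameId), label = label,
             cx = cx, cy = cy, w = w, h = h, stringsAsFactors = FALSE)
}

.emptyDetections <- function() {
  detections(character(0), character(0), numeric(0), numeric(0),
             numeric(0), numeric(0), numeric(0))
}

# IoU of row i of df against all rows of df2 (center-form columns).
.iouRows <- function(a, B) {
  ax1 <- a$cx - a$w / 2; ay1 <- a$cy - a$h / 2
  ax2 <- a$cx + a$w / 2; ay2 <- a$cy + a$h / 2
  bx1 <- B$cx - B$w / 2; by1 <- B$cy - B$h / 2
  bx2 <- B$cx + B$w / 2; by2 <- B$cy + B$h / 2
  iw <- pmax(0, pmin(ax2, bx2) - pmax(ax1, bx1))
  ih <- pmax(0, pmin(ay2, by2) - pmax(ay1, by1))
  inter <- iw * ih
  inter / (a$w * a$h + B$w * B$h - inter)
}

#' Non-maximum suppression
#'
#' Greedy suppression per class and frame: detections are visited in order
#' of decreasing confidence (ties broken by input order, so the procedure is
#' stable and deterministic) and kept unless their IoU with an already-kept
#' detection of the same class in the same frame exceeds the threshold.
#'
#' @param dets detection data.frame (see [detections()]).
#' @param iouThreshold suppression threshold in `(0, 1]`; default 0.7, the
#'   reference training configuration.
#' @return The retained subset of `dets`, in the original row order.
#' @export
nms <- function(dets, iouThreshold = 0.7) {
  if (iouThreshold <= 0 || iouThreshold > 1)
    stop("iouThreshold must lie in (0, 1]")
  if (nrow(dets) == 0L) return(dets)
  keep <- logical(nrow(dets))
  for (grp in split(seq_len(nrow(dets)),
                    list(dets$frameId, dets$label), drop = TRUE)) {
    ord <- grp[order(-dets$confidence[grp])]  # stable: ties keep input order
    kept <- integer(0)
    for (i in ord) {
      if (length(kept) == 0L ||
          all(.iouRows(dets[i, ], dets[kept, , drop = FALSE]) <= iouThreshold)) {
        kept <- c(kept, i)
      }
    }
    keep[kept] <- TRUE
  }
  dets[keep, , drop = FALSE]
}

# AP by all-point interpolation: sum over recall steps of delta-recall times
# the maximum precision at or to the right of that recall.
.apAllPoint <- function(recall, precision) {
  if (length(recall) == 0L) return(0)
  env <- rev(cummax(rev(precision)))  # non-increasing precision envelope
  r0 <- c(0, recall[-length(recall)])
  sum((recall - r0) * env)
}

#' Match detections to ground truth and score precision/recall/AP/mAP
#'
#' Per class: detections are sorted by decreasing confidence (stable);
#' each is a true positive if its best-IoU not-yet-matched ground truth of
#' the same class in the same frame reaches the IoU threshold (that truth is
#' then consumed), otherwise a false positive. Unmatched truths are false
#' negatives. The cumulative precision/recall sequence defines the PR curve;
#' AP is its area under the all-point-interpolated (non-increasing)
#' precision envelope, and mAP is the unweighted mean of the per-class APs.
#' Matching never crosses frames or class labels.
#'
#' Precision is `TP / (TP + FP)` and recall `TP / (TP + FN)`, both reported
#' as 0 when their denominator is 0.
#'
#' @param dets detection data.frame (see [detections()]); normally already
#'   NMS-filtered.
#' @param truths ground-truth data.frame (see [groundTruths()]).
#' @param iouThreshold matching threshold; default 0.5 (the mAP50 setting).
#' @param classes classes to score; defaults to [classVocabulary()].
#' @return List with `perClass` (data.frame of TP/FP/FN counts, precision,
#'   recall, AP per class; AP is `NA` for classes absent from the ground
#'   truth), `map50` (mean AP over the classes present), and `prCurves`
#'   (per-class data.frames of the cumulative PR points).
#' @export
matchAndScore <- function(dets, truths, iouThreshold = 0.5,
                          classes = classVocabulary()) {
  .checkLabels(dets$label); .checkLabels(truths$label)
  perClass <- list(); prCurves <- list()
  for (cl in classes) {
    d <- dets[dets$label == cl, , drop = FALSE]
    g <- truths[truths$label == cl, , drop = FALSE]
    d <- d[order(-d$confidence), , drop = FALSE]
    nG <- nrow(g)
    matched <- logical(nG)
    tp <- integer(nrow(d))
    for (i in seq_len(nrow(d))) {
      cand <- which(!matched & g$frameId == d$frameId[i])
      if (length(cand)) {
        ious <- .iouRows(d[i, ], g[cand, , drop = FALSE])
        j <- which.max(ious)
        if (ious[j] >= iouThreshold) {
          matched[cand[j]] <- TRUE
          tp[i] <- 1L
        }
      }
    }
    cumTP <- cumsum(tp)
    cumFP <- cumsum(1L - tp)
    prec <- if (nrow(d)) cumTP / (cumTP + cumFP) else numeric(0)
    rec <- if (nG > 0) cumTP / nG else rep(0, nrow(d))
    # classes absent from the ground truth carry no AP and are excluded
    # from the mAP mean (the usual VOC/COCO convention)
    ap <- if (nG == 0) NA_real_ else .apAllPoint(rec, prec)
    TP <- sum(tp); FP <- nrow(d) - TP; FN <- nG - TP
    perClass[[cl]] <- data.frame(
      class = cl, TP = TP, FP = FP, FN = FN,
      precision = if (TP + FP > 0) TP / (TP + FP) else 0,
      recall = if (TP + FN > 0) TP / (TP + FN) else 0,
      AP = ap, stringsAsFactors = FALSE)
    prCurves[[cl]] <- data.frame(confidence = d$confidence,
                                 recall = rec, precision = prec)
  }
  perClass <- do.call(rbind, perClass)
  rownames(perClass) <- NULL
  list(perClass = perClass, map50 = mean(perClass$AP, na.rm = TRUE),
       prCurves = prCurves)
}

#' Read and write YOLO-format annotation text
#'
#' One text file per image; each line is `class_idx cx cy w h` for ground
#' truth, with a sixth `confidence` column for predictions. Coordinates are
#' normalised to the image size. `readYolo()` returns the package's
#' detection/ground-truth data.frame in pixel units; `readYoloDir()` reads
#' every `.txt` file in a directory, using file names (minus extension) as
#' frame ids.
#'
#' @param file path to a YOLO txt file.
#' @param imageWidth,imageHeight image size in pixels used to de-normalise.
#' @param frameId frame identifier to attach.
#' @param predictions `TRUE` when files carry a confidence column.
#' @param dir directory of txt files for `readYoloDir()`.
#' @return A detection or ground-truth data.frame.
#' @export
readYolo <- function(file, imageWidth, imageHeight, frameId = basename(file),
                     predictions = FALSE) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(if (predictions) .emptyDetections()
           else groundTruths(character(0), character(0), numeric(0),
                             numeric(0), numeric(0), numeric(0)))
  }
  mat <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  lab <- classVocabulary()[mat[, 1] + 1L]
  cx <- mat[, 2] * imageWidth; cy <- mat[, 3] * imageHeight
  w <- mat[, 4] * imageWidth; h <- mat[, 5] * imageHeight
  if (predictions) {
    conf <- if (ncol(mat) >= 6) mat[, 6] else rep(1, nrow(mat))
    detections(frameId, lab, cx, cy, w, h, conf)
  } else {
    groundTruths(frameId, lab, cx, cy, w, h)
  }
}

#' @rdname readYolo
#' @export
readYoloDir <- function(dir, imageWidth, imageHeight, predictions = FALSE) {
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  out <- lapply(files, function(f)
    readYolo(f, imageWidth, imageHeight,
             frameId = sub("\\.txt$", "", basename(f)),
             predictions = predictions))
  do.call(rbind, out)
}

#' Write evaluation metrics and PR curves as CSV
#'
#' @param result output of [matchAndScore()].
#' @param file path for the per-class metrics table.
#' @param prFile optional path for the concatenated PR-curve points.
#' @return `file`, invisibly.
#' @export
writeMetricsCsv <- function(result, file, prFile = NULL) {
  utils::write.csv(result$perClass, file, row.names = FALSE)
  if (!is.null(prFile)) {
    pr <- do.call(rbind, lapply(names(result$prCurves), function(cl) {
      d <- result$prCurves[[cl]]
      if (nrow(d)) cbind(class = cl, d) else NULL
    }))
    if (is.null(pr)) pr <- data.frame(class = character(0),
                                      confidence = numeric(0),
                                      recall = numeric(0),
                                      precision = numeric(0))
    utils::write.csv(pr, prFile, row.names = FALSE)
  }
  invisible(file)
}
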