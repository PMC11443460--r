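#' @include render.R deteval.R
NULL

#' Classical reference detector for rendered tray frames
#'
#' A deterministic, training-free detector that closes the pipeline on
#' synthetic frames: (1) global threshold halfway between background and
#' radicle level; (2) morphological opening with a disc sized to the seed
#' minor axis separates seed bodies (which survive) from protruding
#' radicles (which do not); (3) radicle pixels are the foreground left after
#' masking a small dilation of the bodies; (4) connected components of
#' bodies become `seed` detections and components of radicle pixels become
#' root detections. Root length is measured as the component's extent along
#' its principal axis plus a fixed geometric compensation for the stroke
#' width and the masked overlap at the seed boundary; the class is `L_root`
#' when the measured length reaches half the seed length, else `S_root`.
#' Confidence is the component's mean intensity contrast against the
#' background, clipped to `[0, 1]` -- a deterministic function of the
#' pixels. The output is NMS-ready.
#'
#' @param image `H x W` numeric matrix in `[0, 1]` (from [renderFrames()] or
#'   the same imaging model).
#' @param scene the [SceneSpec-class] describing the imaging model
#'   (levels, calibration, seed geometry).
#' @param frameId frame identifier attached to the detections.
#' @param minComponentPx components smaller than this many pixels are
#'   treated as noise and discarded.
#' @return A detection data.frame (see [detections()]); possibly empty.
#' @export
referenceDetect <- function(image, scene, frameId = "frame", minComponentPx = 8L) {
  thr <- (scene@background + scene@rootLevel) / 2
  bw <- image > thr
  if (!any(bw)) return(.emptyDetections())

  minorPx <- scene@seedWidthMm / scene@mmPerPixel
  brushSize <- max(3L, 2L * floor(minorPx * 0.35) + 1L)   # odd, ~70% of minor axis
  bwImg <- EBImage::Image(t(bw) * 1)
  body <- EBImage::opening(bwImg, EBImage::makeBrush(brushSize, "disc"))
  bodyDil <- EBImage::dilate(body, EBImage::makeBrush(3L, "disc"))
  roots <- bwImg * (1 - bodyDil)

  out <- list()
  halfSeedMm <- scene@seedLengthMm / 2

  bodyLab <- EBImage::bwlabel(body)
  bodyDat <- t(EBImage::imageData(bodyLab))   # back to row = y
  nb <- max(bodyDat)
  if (nb > 0) {
    px <- which(bodyDat > 0)
    lab <- bodyDat[px]
    rr <- (px - 1) %% nrow(bodyDat) + 1
    cc <- (px - 1) %/% nrow(bodyDat) + 1
    for (i in seq_len(nb)) {
      sel <- lab == i
      if (sum(sel) < minComponentPx) next
      y <- rr[sel]; x <- cc[sel]
      conf <- min(1, max(0, (mean(image[cbind(y, x)]) - scene@background) /
                              (scene@seedLevel - scene@background)))
      out[[length(out) + 1L]] <- data.frame(
        frameId = frameId, label = "seed",
        cx = (min(x) + max(x)) / 2 - 0.5, cy = (min(y) + max(y)) / 2 - 0.5,
        w = max(x) - min(x) + 1, h = max(y) - min(y) + 1,
        confidence = conf, stringsAsFactors = FALSE)
    }
  }

  rootLab <- EBImage::bwlabel(roots)
  rootDat <- t(EBImage::imageData(rootLab))
  nr <- max(rootDat)
  if (nr > 0) {
    px <- which(rootDat > 0)
    lab <- rootDat[px]
    rr <- (px - 1) %% nrow(rootDat) + 1
    cc <- (px - 1) %/% nrow(rootDat) + 1
    for (i in seq_len(nr)) {
      sel <- lab == i
      if (sum(sel) < minComponentPx) next
      y <- rr[sel]; x <- cc[sel]
      # extent along the principal axis of the pixel cloud
      pts <- cbind(x, y)
      ctr <- colMeans(pts)
      cv <- stats::cov(pts)
      ev <- eigen(cv, symmetric = TRUE)$vectors[, 1]
      proj <- (pts[, 1] - ctr[1]) * ev[1] + (pts[, 2] - ctr[2]) * ev[2]
      extentPx <- diff(range(proj))
      # compensate the stroke radius at the far end and the pixels hidden
      # under the dilated seed body at the near end
      lengthPx <- extentPx - scene@rootStrokePx + 3
      lengthMm <- lengthPx * scene@mmPerPixel
      if (lengthMm < 1) next   # below the radicle visibility floor
      conf <- min(1, max(0, (mean(image[cbind(y, x)]) - scene@background) /
                              (scene@seedLevel - scene@background)))
      # pad the box by the masked margin at the seed boundary so it covers
      # the radicle stretch hidden under the body mask
      pad <- 1
      out[[length(out) + 1L]] <- data.frame(
        frameId = frameId,
        label = if (lengthMm >= halfSeedMm) "L_root" else "S_root",
        cx = (min(x) + max(x)) / 2 - 0.5, cy = (min(y) + max(y)) / 2 - 0.5,
        w = max(x) - min(x) + 1 + 2 * pad, h = max(y) - min(y) + 1 + 2 * pad,
        confidence = conf, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(.emptyDetections())
  do.call(rbind, out)
}

#' Run the full synthetic pipeline for one tray
#'
#' simulate -> render -> detect -> NMS -> timeline: simulates a tray,
#' renders frames at the given times, runs [referenceDetect()] and
#' [nms()] on each, and assembles the detector-derived
#' [GerminationTimeline-class] alongside the simulator's ground truth.
#'
#' @param config an [ExperimentConfig-class].
#' @param model a [GrowthModel-class].
#' @param scene a [SceneSpec-class].
#' @param conc NaCl concentration (mmol/L).
#' @param seed RNG seed (drives the simulation and the pixel noise).
#' @param times acquisition times (hours); defaults to the full schedule of
#'   `config`.
#' @param trayId tray identifier.
#' @param noise add pixel noise (default `TRUE`).
#' @return List with `timeline` (detector-derived), `truth` (simulated
#'   ground truth), `tray` (the simulation), and `frames` (per-frame
#'   detections after NMS).
#' @export
runTrayPipeline <- function(config, model, scene, conc, seed,
                            times = NULL, trayId = "tray1", noise = TRUE) {
  if (is.null(times))
    times <- seq(config@intervalH, config@durationH, by = config@intervalH)
  tray <- simulateTray(config, model, conc, seed = seed, trayId = trayId)
  frames <- renderFrames(tray, scene, times,
                         noiseSeed = if (noise) seed + 7919L else NULL)
  dets <- vector("list", length(frames))
  names(dets) <- as.character(times)
  for (i in seq_along(frames)) {
    d <- referenceDetect(frames[[i]]$image, scene,
                         frameId = frames[[i]]$record$imageId)
    dets[[i]] <- nms(d, iouThreshold = 0.7)
  }
  timeline <- buildTimeline(dets, nTotal = nrow(tray$trajectories),
                            mmPerPixel = scene@mmPerPixel,
                            trayId = trayId, concentration = conc)
  list(timeline = timeline, truth = groundTruthTimeline(tray, times),
       tray = tray, frames = dets)
}
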