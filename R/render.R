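#' @include AllClasses.R simulate.R dataset.R
NULL

#' Construct a rendering specification
#'
#' Defaults draw a 972 x 972 px grayscale tray (9 x 9 cells of 108 px) at
#' 0.25 mm/px: an 8 x 3.5 mm seed ellipse (32 x 14 px) at each cell center,
#' radicles as gently curved strokes (sagitta 5% of length, half-width 1.5
#' px) growing from the seed tip toward a cell corner, background 0.10,
#' seed body 0.85, radicle 0.55, additive Gaussian noise sd 0.02.
#'
#' @param imageSize canvas side (px).
#' @param mmPerPixel calibration (mm/px).
#' @param seedLengthMm,seedWidthMm seed ellipse axes (mm).
#' @param rootStrokePx radicle stroke half-width (px).
#' @param curvature radicle sagitta as a fraction of its length.
#' @param background,seedLevel,rootLevel gray levels in `[0, 1]`.
#' @param noiseSd Gaussian pixel-noise standard deviation.
#' @return A [SceneSpec-class].
#' @export
sceneSpec <- function(imageSize = 972L, mmPerPixel = 0.25,
                      seedLengthMm = 8, seedWidthMm = 3.5,
                      rootStrokePx = 1.5, curvature = 0.05,
                      background = 0.10, seedLevel = 0.85, rootLevel = 0.55,
                      noiseSd = 0.02) {
  new("SceneSpec", imageSize = as.integer(imageSize), mmPerPixel = mmPerPixel,
      seedLengthMm = seedLengthMm, seedWidthMm = seedWidthMm,
      rootStrokePx = rootStrokePx, curvature = curvature,
      background = background, seedLevel = seedLevel, rootLevel = rootLevel,
      noiseSd = noiseSd)
}

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec: %dx%d px at %g mm/px, seed %gx%g mm, noise sd %g\n",
              object@imageSize, object@imageSize, object@mmPerPixel,
              object@seedLengthMm, object@seedWidthMm, object@noiseSd))
})

# quadratic Bezier samples for a radicle of chord length lenPx starting at
# p0 along unit direction d, bent sideways by curvature * length
.radiclePath <- function(p0, theta, lenPx, curvature) {
  d <- c(cos(theta), sin(theta))
  nv <- c(-sin(theta), cos(theta))
  p2 <- p0 + lenPx * d
  p1 <- p0 + lenPx / 2 * d + curvature * lenPx * nv
  s <- seq(0, 1, length.out = max(2L, ceiling(lenPx / 0.5) + 1L))
  cbind(x = (1 - s)^2 * p0[1] + 2 * s * (1 - s) * p1[1] + s^2 * p2[1],
        y = (1 - s)^2 * p0[2] + 2 * s * (1 - s) * p1[2] + s^2 * p2[2])
}

# stamp a disc of radius r (px) at each path point into the canvas
.stampPath <- function(canvas, pts, r, level) {
  H <- nrow(canvas); W <- ncol(canvas)
  span <- ceiling(r)
  offs <- expand.grid(dy = -span:span, dx = -span:span)
  offs <- offs[offs$dx^2 + offs$dy^2 <= r^2 + 0.26, ]
  rr <- floor(pts[, "y"]) + 1L
  cc <- floor(pts[, "x"]) + 1L
  allR <- rep(rr, each = nrow(offs)) + offs$dy
  allC <- rep(cc, each = nrow(offs)) + offs$dx
  ok <- allR >= 1 & allR <= H & allC >= 1 & allC <= W
  canvas[cbind(allR[ok], allC[ok])] <- level
  canvas
}

#' Render annotated frames of a simulated tray
#'
#' Draws one grayscale frame per requested time: seed ellipses at the cell
#' centers (major axis along the eventual root direction) and radicles as
#' curved strokes from the seed tip, plus per-frame ground-truth boxes. Seed
#' boxes enclose the ellipse; root boxes enclose the rendered stroke (so
#' for measurable roots the box diagonal tracks the rendered chord); root
#' objects are annotated once at least 1 mm of radicle is rendered, labelled
#' `S_root`/`L_root` by the true simulated length against the half-seed
#' standard. Radicles are clipped at their cell boundary (one summary
#' warning per call). With `noiseSeed` set, Gaussian noise is added
#' reproducibly (a per-frame seed is derived from it); `NULL` renders
#' noiseless frames.
#'
#' @param tray output of [simulateTray()].
#' @param scene a [SceneSpec-class].
#' @param times acquisition times in hours.
#' @param noiseSeed integer seed for the pixel noise, or `NULL` for
#'   noiseless frames.
#' @param gridRows,gridCols tray grid (defaults 9 x 9; must match the
#'   simulated trajectories).
#' @return List of frames; each is a list with `time`, `image` (`H x W`
#'   matrix in `[0, 1]`) and `record` (an [annotationRecord()]).
#' @export
renderFrames <- function(tray, scene, times, noiseSeed = NULL,
                         gridRows = max(tray$trajectories$row),
                         gridCols = max(tray$trajectories$col)) {
  S <- scene@imageSize
  cellW <- S / gridCols; cellH <- S / gridRows
  a <- scene@seedLengthMm / 2 / scene@mmPerPixel
  b <- scene@seedWidthMm / 2 / scene@mmPerPixel
  halfSeed <- tray$seedLengthMm / 2
  minRootPx <- 1 / scene@mmPerPixel  # annotate roots once >= 1 mm rendered
  traj <- tray$trajectories
  nClipped <- 0L
  frames <- vector("list", length(times))

  for (fi in seq_along(times)) {
    t <- times[fi]
    canvas <- matrix(scene@background, S, S)
    lens <- tray$rootLengthAt(t)
    objs <- list()

    for (k in seq_len(nrow(traj))) {
      cx <- (traj$col[k] - 0.5) * cellW
      cy <- (traj$row[k] - 0.5) * cellH
      theta <- if (traj$germinates[k]) traj$rootDir[k] else traj$orientJitter[k]
      lenPx <- lens[k] / scene@mmPerPixel

      if (lenPx >= 1) {
        # radicle first, so the seed body overdraws the buried part
        tip <- c(cx + (a - 2) * cos(theta), cy + (a - 2) * sin(theta))
        pts <- .radiclePath(tip, theta, lenPx, scene@curvature)
        inCell <- pts[, "x"] >= (traj$col[k] - 1) * cellW + 3 &
                  pts[, "x"] <= traj$col[k] * cellW - 3 &
                  pts[, "y"] >= (traj$row[k] - 1) * cellH + 3 &
                  pts[, "y"] <= traj$row[k] * cellH - 3
        if (!all(inCell)) {
          nClipped <- nClipped + 1L
          cut <- which(!inCell)[1]
          pts <- pts[seq_len(max(2L, cut - 1L)), , drop = FALSE]
        }
        canvas <- .stampPath(canvas, pts, scene@rootStrokePx, scene@rootLevel)
        if (lenPx >= minRootPx) {
          # a 1 px margin around the centerline: tight enough that the box
          # diagonal tracks the chord of measurable roots, wide enough to
          # cover the stroke core
          objs[[length(objs) + 1L]] <- data.frame(
            label = if (lens[k] >= halfSeed) "L_root" else "S_root",
            x1 = min(pts[, "x"]) - 1, y1 = min(pts[, "y"]) - 1,
            x2 = max(pts[, "x"]) + 1, y2 = max(pts[, "y"]) + 1)
        }
      }

      # seed ellipse over a cell-sized window
      r0 <- max(1L, floor(cy - a)); r1 <- min(S, ceiling(cy + a))
      c0 <- max(1L, floor(cx - a)); c1 <- min(S, ceiling(cx + a))
      ys <- (r0:r1) - 0.5; xs <- (c0:c1) - 0.5
      dx <- outer(rep(1, length(ys)), xs - cx)
      dy <- outer(ys - cy, rep(1, length(xs)))
      u <- dx * cos(theta) + dy * sin(theta)
      vv <- -dx * sin(theta) + dy * cos(theta)
      mask <- (u / a)^2 + (vv / b)^2 <= 1
      sub <- canvas[r0:r1, c0:c1]
      sub[mask] <- scene@seedLevel
      canvas[r0:r1, c0:c1] <- sub

      ex <- sqrt((a * cos(theta))^2 + (b * sin(theta))^2)
      ey <- sqrt((a * sin(theta))^2 + (b * cos(theta))^2)
      objs[[length(objs) + 1L]] <- data.frame(
        label = "seed", x1 = cx - ex, y1 = cy - ey,
        x2 = cx + ex, y2 = cy + ey)
    }

    objects <- do.call(rbind, objs)
    objects$x1 <- pmax(objects$x1, 0); objects$y1 <- pmax(objects$y1, 0)
    objects$x2 <- pmin(objects$x2, S); objects$y2 <- pmin(objects$y2, S)

    if (!is.null(noiseSeed) && scene@noiseSd > 0) {
      set.seed(noiseSeed + fi)
      canvas <- pmin(pmax(canvas +
        matrix(stats::rnorm(S * S, sd = scene@noiseSd), S, S), 0), 1)
    }

    frames[[fi]] <- list(
      time = t, image = canvas,
      record = annotationRecord(sprintf("%s_t%05.1fh", tray$trayId, t),
                                S, S, objects))
  }
  if (nClipped > 0)
    warning(sprintf("%d radicle(s) reached their cell boundary and were clipped",
                    nClipped))
  frames
}

#' Ground-truth table from an annotation record
#'
#' @param record an [annotationRecord()].
#' @param frameId frame identifier (defaults to the record's image id).
#' @return A ground-truth data.frame (see [groundTruths()]).
#' @export
recordToTruths <- function(record, frameId = record$imageId) {
  ob <- record$objects
  if (!nrow(ob))
    return(groundTruths(character(0), character(0), numeric(0), numeric(0),
                        numeric(0), numeric(0)))
  groundTruths(frameId, ob$label, (ob$x1 + ob$x2) / 2, (ob$y1 + ob$y2) / 2,
               ob$x2 - ob$x1, ob$y2 - ob$y1)
}
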