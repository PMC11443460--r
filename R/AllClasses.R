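#' Axis-aligned bounding box
#'
#' A box in continuous pixel coordinates (origin top-left, y increasing
#' downward), stored in center form. Corner form `(x1, y1, x2, y2)` is
#' derived as `(cx - w/2, cy - h/2, cx + w/2, cy + h/2)` and round-trips
#' losslessly. All loss and evaluation math in the package consumes this
#' class.
#'
#' @slot cx horizontal center (pixels)
#' @slot cy vertical center (pixels)
#' @slot w box width (pixels, > 0)
#' @slot h box height (pixels, > 0)
#'
#' @seealso [bbox()], [bboxFromCorners()], [iou()], [lossBreakdown()]
#' @export
setClass("BBox",
  representation(cx = "numeric", cy = "numeric", w = "numeric", h = "numeric")
)

setValidity("BBox", function(object) {
  vals <- c(object@cx, object@cy, object@w, object@h)
  if (length(object@cx) != 1L || length(object@cy) != 1L ||
      length(object@w) != 1L || length(object@h) != 1L)
    return("cx, cy, w, h must each be a single number")
  if (any(!is.finite(vals)))
    return("box coordinates must be finite")
  if (object@w <= 0 || object@h <= 0)
    return("invalid box: width and height must be strictly positive")
  TRUE
})

#' Geometric breakdown of the IoU-family losses for one box pair
#'
#' Holds every geometric term shared by the IoU-family regression losses --
#' the overlap ratio, the squared center distance, the smallest enclosing
#' box (squared diagonal, width, height), the aspect-ratio consistency term
#' `v` and its trade-off weight `alpha` -- together with the six scalar
#' losses computed from them (IoU, GIoU, DIoU, CIoU, EIoU, ECIoU).
#'
#' The CIoU loss is `1 - IoU + rho2/c2 + alpha * v`; the ECIoU loss adds the
#' separated edge penalties `(h - h_gt)^2 / ch^2 + (w - w_gt)^2 / cw^2` on
#' top of it, so `lossEciou >= lossCiou` always.
#'
#' @slot iou overlap ratio in `[0, 1]`
#' @slot rho2Center squared distance between box centers (pixels^2)
#' @slot c2 squared diagonal of the smallest enclosing box (pixels^2)
#' @slot cw enclosing-box width (pixels)
#' @slot ch enclosing-box height (pixels)
#' @slot v aspect-ratio consistency term (dimensionless, >= 0)
#' @slot alpha trade-off weight of `v` (dimensionless, >= 0)
#' @slot lossIou,lossGiou,lossDiou,lossCiou,lossEiou,lossEciou scalar losses
#'
#' @seealso [lossBreakdown()], [boxLoss()]
#' @export
setClass("LossBreakdown",
  representation(
    iou = "numeric", rho2Center = "numeric", c2 = "numeric",
    cw = "numeric", ch = "numeric", v = "numeric", alpha = "numeric",
    lossIou = "numeric", lossGiou = "numeric", lossDiou = "numeric",
    lossCiou = "numeric", lossEiou = "numeric", lossEciou = "numeric"
  )
)

setValidity("LossBreakdown", function(object) {
  if (object@iou < -1e-12 || object@iou > 1 + 1e-12)
    return("iou must lie in [0, 1]")
  if (object@v < 0) return("v must be nonnegative")
  if (object@rho2Center > object@c2 + 1e-9)
    return("center distance cannot exceed the enclosing-box diagonal")
  if (object@lossGiou < -1e-12 || object@lossGiou > 2 + 1e-12)
    return("GIoU loss must lie in [0, 2]")
  TRUE
})

#' Trace of one gradient-descent box-regression run
#'
#' @slot lossName which objective was minimised (one of `iou`, `giou`,
#'   `diou`, `ciou`, `eiou`, `eciou`)
#' @slot iterations number of descent steps taken
#' @slot lossValues objective value at every step, length `iterations + 1`
#'   (the initial value is included)
#' @slot finalBox the fitted [BBox-class] after the last step
#' @slot converged `TRUE` when the final loss fell below the tolerance
#'
#' @seealso [fitBox()], [compareLosses()]
#' @export
setClass("RegressionTrace",
  representation(
    lossName = "character", iterations = "integer",
    lossValues = "numeric", finalBox = "BBox", converged = "logical"
  )
)

setValidity("RegressionTrace", function(object) {
  if (length(object@lossValues) != object@iterations + 1L)
    return("lossValues must have length iterations + 1")
  TRUE
})

#' Injectable weights of a coordinate-attention block
#'
#' The block reduces `C` channels to `C/r`, applies a nonlinearity, and
#' expands back to `C` separately for the height and width attention paths.
#' Weights are plain matrices so the forward pass is testable without any
#' training machinery.
#'
#' @slot reduce `(C/r) x C` matrix of the shared 1x1 reduction transform
#' @slot reduceBias length-`C/r` bias of the reduction
#' @slot expandH `C x (C/r)` matrix producing the height-attention logits
#' @slot expandW `C x (C/r)` matrix producing the width-attention logits
#' @slot expandHBias,expandWBias length-`C` biases of the expansions
#' @slot r reduction ratio (must divide `C`)
#'
#' @seealso [caWeights()], [coordinateAttention()]
#' @export
setClass("CAWeights",
  representation(
    reduce = "matrix", reduceBias = "numeric",
    expandH = "matrix", expandW = "matrix",
    expandHBias = "numeric", expandWBias = "numeric",
    r = "integer"
  )
)

setValidity("CAWeights", function(object) {
  cr <- nrow(object@reduce); C <- ncol(object@reduce)
  if (C %% object@r != 0L) return("r must divide the channel count C")
  if (cr != C %/% object@r) return("reduce must map C channels to C/r")
  if (length(object@reduceBias) != cr) return("reduceBias must have length C/r")
  for (nm in c("expandH", "expandW")) {
    m <- slot(object, nm)
    if (nrow(m) != C || ncol(m) != cr)
      return(sprintf("%s must be a C x C/r matrix", nm))
  }
  if (length(object@expandHBias) != C || length(object@expandWBias) != C)
    return("expansion biases must have length C")
  TRUE
})

#' Germination-experiment configuration
#'
#' Describes one salt-stress germination run: the tray grid, the NaCl
#' treatments, replication, and the image-acquisition schedule. The default
#' constructor [experimentConfig()] reproduces the reference design: a 9x9
#' grid (81 seeds per tray), concentrations 0 (deionised-water control),
#' 30, 60, 90, 120 and 150 mmol/L, three replicate trays per concentration,
#' images every 0.5 h for 48 h at 26 +/- 1 degrees C.
#'
#' @slot gridRows,gridCols seeds per tray axis
#' @slot concentrations NaCl concentrations in mmol/L (0 = control)
#' @slot replicates trays per concentration
#' @slot intervalH image-acquisition interval (hours)
#' @slot durationH experiment duration (hours); must be a multiple of
#'   `intervalH`
#' @slot temperatureC incubation temperature (degrees C, metadata only)
#'
#' @seealso [experimentConfig()], [acquisitionSchedule()], [simulateTray()]
#' @export
setClass("ExperimentConfig",
  representation(
    gridRows = "integer", gridCols = "integer",
    concentrations = "numeric", replicates = "integer",
    intervalH = "numeric", durationH = "numeric", temperatureC = "numeric"
  )
)

setValidity("ExperimentConfig", function(object) {
  if (object@gridRows < 1L || object@gridCols < 1L)
    return("tray grid must have at least one row and one column")
  if (any(object@concentrations < 0))
    return("concentrations must be nonnegative")
  if (object@replicates < 0L) return("replicates must be nonnegative")
  if (object@intervalH <= 0 || object@durationH <= 0)
    return("interval and duration must be positive")
  k <- object@durationH / object@intervalH
  if (abs(k - round(k)) > 1e-9)
    return("acquisition interval must divide the experiment duration")
  TRUE
})

#' Stochastic growth model for seed germination under salt stress
#'
#' Defines, per NaCl concentration, the probability that a seed germinates
#' within the observation window, the distribution of radicle-emergence
#' times, and the (linear) radicle elongation rate. The default profile
#' encodes the qualitative dose response observed for cucumber: mild
#' promotion at 30 mmol/L, monotone inhibition above, and no germination at
#' all at or above 160 mmol/L.
#'
#' @slot pGerm function of concentration (mmol/L) returning a germination
#'   probability in `[0, 1]`; must return 0 at or above `zeroConcThreshold`
#' @slot tEmergeMean,tEmergeSd mean and standard deviation (hours) of the
#'   radicle-emergence time, truncated to positive values
#' @slot growthRate function of concentration returning the radicle
#'   elongation rate (mm/h)
#' @slot seedLengthMm nominal seed length (mm); a root longer than half of
#'   it marks the seed as germinated (the L-root criterion)
#' @slot zeroConcThreshold concentration (mmol/L) at and above which
#'   `pGerm` is 0
#'
#' @seealso [growthModel()], [simulateTray()]
#' @export
setClass("GrowthModel",
  representation(
    pGerm = "function", tEmergeMean = "numeric", tEmergeSd = "numeric",
    growthRate = "function", seedLengthMm = "numeric",
    zeroConcThreshold = "numeric"
  )
)

setValidity("GrowthModel", function(object) {
  if (object@tEmergeMean <= 0 || object@tEmergeSd <= 0)
    return("emergence-time parameters must be positive")
  if (object@seedLengthMm <= 0) return("seed length must be positive")
  probe <- c(0, 30, 60, 90, 120, 150, object@zeroConcThreshold, 300)
  p <- vapply(probe, object@pGerm, numeric(1))
  if (any(p < 0 | p > 1)) return("pGerm must return probabilities in [0, 1]")
  if (any(p[probe >= object@zeroConcThreshold] > 0))
    return("pGerm must be 0 at and above zeroConcThreshold")
  TRUE
})

#' Rendering specification for synthetic tray frames
#'
#' Geometry and imaging parameters used to draw grayscale tray frames:
#' canvas size, pixel calibration, seed-ellipse shape, radicle stroke and
#' curvature, and background/noise levels. Seeds sit at the centers of a
#' regular grid of cells; radicles grow from a seed tip toward a cell
#' corner with gentle curvature so that rendered root length in pixels
#' tracks true length to within a few percent.
#'
#' @slot imageSize canvas side in pixels (square frames)
#' @slot mmPerPixel calibration (mm per pixel, > 0)
#' @slot seedLengthMm,seedWidthMm seed ellipse major/minor axes (mm)
#' @slot rootStrokePx radicle stroke half-width in pixels
#' @slot curvature sagitta of the radicle arc as a fraction of its length
#' @slot background background gray level in `[0, 1]`
#' @slot seedLevel,rootLevel foreground gray levels of seed body and radicle
#' @slot noiseSd standard deviation of additive Gaussian pixel noise
#'
#' @seealso [sceneSpec()], [renderFrames()], [referenceDetect()]
#' @export
setClass("SceneSpec",
  representation(
    imageSize = "integer", mmPerPixel = "numeric",
    seedLengthMm = "numeric", seedWidthMm = "numeric",
    rootStrokePx = "numeric", curvature = "numeric",
    background = "numeric", seedLevel = "numeric", rootLevel = "numeric",
    noiseSd = "numeric"
  )
)

setValidity("SceneSpec", function(object) {
  if (object@imageSize < 32L) return("imageSize is too small to render a tray")
  if (object@mmPerPixel <= 0) return("mmPerPixel must be positive")
  if (object@seedLengthMm <= 0 || object@seedWidthMm <= 0)
    return("seed axes must be positive")
  if (object@noiseSd < 0) return("noiseSd must be nonnegative")
  TRUE
})

#' Per-tray germination time series
#'
#' The container from which the vigor statistics are computed: cumulative
#' germinated counts (seeds whose radicle has reached the L-root standard,
#' i.e. half the seed length), first-time germinations per interval, and the
#' individual root lengths measured at each acquisition time.
#'
#' @slot trayId tray identifier
#' @slot concentration NaCl concentration (mmol/L)
#' @slot times ordered acquisition timestamps (hours, strictly increasing)
#' @slot nTotal total seeds on the tray
#' @slot germinatedCounts cumulative germinated count per time
#'   (non-decreasing, bounded by `nTotal`)
#' @slot newGerminations first-time germinations in the interval ending at
#'   each time; cumulative sums reproduce `germinatedCounts`
#' @slot rootLengths list (one element per time) of individual root lengths
#'   in mm of the L-root detections in that frame
#'
#' @seealso [buildTimeline()], [germinationRate()], [germinationIndex()],
#'   [meanRootLength()]
#' @export
setClass("GerminationTimeline",
  representation(
    trayId = "character", concentration = "numeric", times = "numeric",
    nTotal = "integer", germinatedCounts = "integer",
    newGerminations = "integer", rootLengths = "list"
  )
)

setValidity("GerminationTimeline", function(object) {
  nt <- length(object@times)
  if (nt > 1 && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (length(object@germinatedCounts) != nt ||
      length(object@newGerminations) != nt ||
      length(object@rootLengths) != nt)
    return("counts and root lengths must align with times")
  if (nt > 0) {
    if (any(diff(object@germinatedCounts) < 0))
      return("germinatedCounts must be non-decreasing")
    if (any(object@germinatedCounts > object@nTotal))
      return("germinatedCounts cannot exceed nTotal")
    if (any(cumsum(object@newGerminations) != object@germinatedCounts))
      return("newGerminations must accumulate to germinatedCounts")
  }
  TRUE
})
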