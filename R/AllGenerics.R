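#' @include AllClasses.R
NULL

#' Intersection over union of two boxes
#'
#' Area of the intersection divided by area of the union; the basic
#' similarity measure between a predicted and a true box, in `[0, 1]` and
#' symmetric in its arguments.
#'
#' @param a,b [BBox-class] objects.
#' @return A number in `[0, 1]`.
#' @examples
#' iou(bboxFromCorners(0, 0, 2, 2), bboxFromCorners(1, 1, 3, 3)) # 1/7
#' @export
setGeneric("iou", function(a, b) standardGeneric("iou"))

#' @rdname lossBreakdown
#' @export
setGeneric("lossBreakdown", function(pred, truth) standardGeneric("lossBreakdown"))

#' @rdname coordinateAttention
#' @export
setGeneric("coordinateAttention", function(x, w) standardGeneric("coordinateAttention"))

#' @rdname germinationRate
#' @export
setGeneric("germinationRate", function(timeline, t) standardGeneric("germinationRate"))

#' @rdname germinationIndex
#' @export
setGeneric("germinationIndex", function(timeline) standardGeneric("germinationIndex"))

#' @rdname meanRootLength
#' @export
setGeneric("meanRootLength", function(timeline, t, mmPerPixel) standardGeneric("meanRootLength"))

#' Accessors for box and timeline objects
#'
#' `boxCenter()`, `boxWidth()`, `boxHeight()` and `corners()` read a
#' [BBox-class]; `lossValues()` collects the six losses of a
#' [LossBreakdown-class] into a named vector; `timelineTimes()`,
#' `germinatedCounts()` and `totalSeeds()` read a
#' [GerminationTimeline-class].
#'
#' @param x the object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("boxCenter", function(x) standardGeneric("boxCenter"))

#' @rdname accessors
#' @export
setGeneric("boxWidth", function(x) standardGeneric("boxWidth"))

#' @rdname accessors
#' @export
setGeneric("boxHeight", function(x) standardGeneric("boxHeight"))

#' @rdname accessors
#' @export
setGeneric("corners", function(x) standardGeneric("corners"))

#' @rdname accessors
#' @export
setGeneric("lossValues", function(x) standardGeneric("lossValues"))

#' @rdname accessors
#' @export
setGeneric("timelineTimes", function(x) standardGeneric("timelineTimes"))

#' @rdname accessors
#' @export
setGeneric("germinatedCounts", function(x) standardGeneric("germinatedCounts"))

#' @rdname accessors
#' @export
setGeneric("totalSeeds", function(x) standardGeneric("totalSeeds"))
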