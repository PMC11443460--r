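#' @include AllClasses.R AllGenerics.R boxgeom.R
NULL

#' Root length from a detection-box diagonal
#'
#' The radicle length is approximated by the diagonal of its detection box,
#' `sqrt(w^2 + h^2)`, converted from pixels to millimetres by the imaging
#' calibration. A 30 x 40 px box at 0.1 mm/px therefore measures 5.0 mm.
#'
#' @param box a [BBox-class] (an L-root detection box), or a data.frame with
#'   `w` and `h` columns for vectorised use.
#' @param mmPerPixel calibration scale (mm per pixel, > 0).
#' @return Root length(s) in millimetres.
#' @export
rootLengthFromBox <- function(box, mmPerPixel) {
  if (mmPerPixel <= 0) stop("mmPerPixel must be positive")
  if (is(box, "BBox")) {
    sqrt(box@w^2 + box@h^2) * mmPerPixel
  } else {
    sqrt(box$w^2 + box$h^2) * mmPerPixel
  }
}

#' Assemble a germination timeline from per-frame detections
#'
#' Counts, at each acquisition time, the L-root detections (the germination
#' standard: radicle at least half the seed length) and measures their root
#' lengths via the box diagonal. Two repairs make the series a valid
#' cumulative record: counts are capped at the number of seeds on the tray
#' (duplicate detections cannot create seeds) and forced non-decreasing by a
#' running maximum (germination is irreversible; a dip is detector flicker).
#' First-time germinations per interval are obtained by differencing the
#' repaired cumulative series.
#'
#' @param frames named list of detection data.frames (see [detections()]),
#'   one per acquisition, whose names are the timestamps in hours; times
#'   must be strictly increasing.
#' @param nTotal seeds on the tray (81 for the default 9 x 9 grid).
#' @param mmPerPixel imaging calibration for root lengths.
#' @param trayId tray identifier.
#' @param concentration NaCl concentration of the tray (mmol/L).
#' @return A [GerminationTimeline-class].
#' @export
buildTimeline <- function(frames, nTotal = 81L, mmPerPixel = 1,
                          trayId = "tray1", concentration = 0) {
  times <- as.numeric(names(frames))
  if (length(times) && (any(is.na(times)) || any(diff(times) <= 0)))
    stop("frame timestamps must be numeric and strictly increasing")
  counts <- integer(length(times))
  lens <- vector("list", length(times))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    lr <- f[f$label == "L_root", , drop = FALSE]
    counts[i] <- min(nrow(lr), nTotal)
    lens[[i]] <- if (nrow(lr)) rootLengthFromBox(lr, mmPerPixel) else numeric(0)
  }
  counts <- as.integer(cummax(counts))      # germination is irreversible
  newG <- as.integer(diff(c(0L, counts)))
  new("GerminationTimeline", trayId = as.character(trayId),
      concentration = concentration, times = times,
      nTotal = as.integer(nTotal), germinatedCounts = counts,
      newGerminations = newG, rootLengths = lens)
}

setMethod("show", "GerminationTimeline", function(object) {
  n <- length(object@times)
  cat(sprintf("GerminationTimeline %s (%g mmol/L): %d/%d seeds germinated over %d times%s\n",
              object@trayId, object@concentration,
              if (n) object@germinatedCounts[n] else 0L, object@nTotal, n,
              if (n) sprintf(" (%.1f-%.1f h)", object@times[1], object@times[n]) else ""))
})

#' @rdname accessors
setMethod("timelineTimes", "GerminationTimeline", function(x) x@times)

#' @rdname accessors
setMethod("germinatedCounts", "GerminationTimeline", function(x) x@germinatedCounts)

#' @rdname accessors
setMethod("totalSeeds", "GerminationTimeline", function(x) x@nTotal)

.timeIndex <- function(timeline, t) {
  i <- which(abs(timeline@times - t) < 1e-8)
  if (length(i) != 1L)
    stop(sprintf("time %g h was not sampled in this timeline", t))
  i
}

#' Germination rate at a sampled time
#'
#' Percentage of seeds germinated by time `t`:
#' `N_s / N x 100`, where `N_s` is the cumulative number of seeds whose
#' radicle has reached the L-root standard by `t` and `N` the seeds on the
#' tray.
#'
#' @param timeline a [GerminationTimeline-class].
#' @param t a timestamp present in the timeline (hours).
#' @return Germination rate in percent.
#' @examples
#' tl <- new("GerminationTimeline", trayId = "t", concentration = 0,
#'           times = 24, nTotal = 81L, germinatedCounts = 27L,
#'           newGerminations = 27L, rootLengths = list(numeric(0)))
#' germinationRate(tl, 24)  # 33.33...
#' @export
setMethod("germinationRate", "GerminationTimeline", function(timeline, t) {
  i <- .timeIndex(timeline, t)
  timeline@germinatedCounts[i] / timeline@nTotal * 100
})

#' Germination index of a timeline
#'
#' Speed-weighted germination summary `sum_t G_t / D_t`, where `G_t` is the
#' number of first-time germinations in the interval ending at `t` and `D_t`
#' is the elapsed time `t` in hours. Early germinations weigh more, so the
#' index separates fast-germinating treatments from slow ones even at equal
#' final rates. Reported unitless.
#'
#' @param timeline a [GerminationTimeline-class].
#' @return The index value (>= 0).
#' @export
setMethod("germinationIndex", "GerminationTimeline", function(timeline) {
  if (!length(timeline@times)) return(0)
  sum(timeline@newGerminations / timeline@times)
})

#' Mean root length at a sampled time
#'
#' Total root length of the germinated (L-root) seeds divided by their
#' number, at the frame acquired at `t`; 0 mm by convention when no seed has
#' germinated. Root lengths are cross-sectional per frame -- individual
#' roots are not tracked across frames.
#'
#' @param timeline a [GerminationTimeline-class] built with the desired
#'   calibration.
#' @param t a sampled timestamp (hours).
#' @param mmPerPixel unused when the timeline already stores lengths in mm;
#'   kept for symmetry with [rootLengthFromBox()] (default `NULL`).
#' @return Mean root length in millimetres.
#' @export
setMethod("meanRootLength", "GerminationTimeline", function(timeline, t, mmPerPixel) {
  i <- .timeIndex(timeline, t)
  lens <- timeline@rootLengths[[i]]
  if (!length(lens)) return(0)
  mean(lens)
})

#' Tidy vigor table from a set of timelines
#'
#' One row per (tray, time): germination rate, cumulative germination index
#' up to that time, and mean root length.
#'
#' @param timelines list of [GerminationTimeline-class] objects.
#' @return data.frame with columns `tray`, `concentration`, `time_h`,
#'   `germination_rate_pct`, `germination_index_cum`,
#'   `mean_root_length_mm`.
#' @export
vigorTable <- function(timelines) {
  rows <- lapply(timelines, function(tl) {
    idx <- seq_along(tl@times)
    cumIdx <- cumsum(tl@newGerminations / tl@times)
    data.frame(
      tray = tl@trayId, concentration = tl@concentration,
      time_h = tl@times,
      germination_rate_pct = tl@germinatedCounts / tl@nTotal * 100,
      germination_index_cum = cumIdx,
      mean_root_length_mm = vapply(idx, function(i) {
        l <- tl@rootLengths[[i]]; if (length(l)) mean(l) else 0
      }, numeric(1)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
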