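#' @include AllClasses.R
NULL

#' Construct an experiment configuration
#'
#' Defaults reproduce the reference salt-stress design: 9 x 9 = 81 seeds per
#' tray, NaCl at 0 (deionised-water control), 30, 60, 90, 120 and 150
#' mmol/L, three replicate trays per concentration (18 trays, 1458 seeds),
#' one image per tray every 0.5 h for 48 h (96 frames per tray, 1728 images
#' in total) at 26 degrees C.
#'
#' @param gridRows,gridCols seeds per tray axis.
#' @param concentrations NaCl concentrations in mmol/L.
#' @param replicates trays per concentration.
#' @param intervalH acquisition interval in hours.
#' @param durationH experiment duration in hours.
#' @param temperatureC incubation temperature (metadata).
#' @return An [ExperimentConfig-class].
#' @export
experimentConfig <- function(gridRows = 9L, gridCols = 9L,
                             concentrations = c(0, 30, 60, 90, 120, 150),
                             replicates = 3L, intervalH = 0.5,
                             durationH = 48, temperatureC = 26) {
  new("ExperimentConfig", gridRows = as.integer(gridRows),
      gridCols = as.integer(gridCols), concentrations = concentrations,
      replicates = as.integer(replicates), intervalH = intervalH,
      durationH = durationH, temperatureC = temperatureC)
}

setMethod("show", "ExperimentConfig", function(object) {
  cat(sprintf("ExperimentConfig: %dx%d seeds/tray, [%s] mmol/L x %d replicates, every %g h for %g h\n",
              object@gridRows, object@gridCols,
              paste(object@concentrations, collapse = ", "),
              object@replicates, object@intervalH, object@durationH))
})

#' Read/write an experiment configuration as YAML
#'
#' @param file YAML path with keys `grid_rows`, `grid_cols`,
#'   `concentrations`, `replicates`, `interval_h`, `duration_h`,
#'   `temperature_c` (missing keys take the defaults of
#'   [experimentConfig()]).
#' @param config an [ExperimentConfig-class] for the writer.
#' @return The configuration (reader) or `file` invisibly (writer).
#' @export
readExperimentConfig <- function(file) {
  y <- yaml::read_yaml(file)
  dflt <- experimentConfig()
  experimentConfig(
    gridRows = y$grid_rows %||% dflt@gridRows,
    gridCols = y$grid_cols %||% dflt@gridCols,
    concentrations = unlist(y$concentrations) %||% dflt@concentrations,
    replicates = y$replicates %||% dflt@replicates,
    intervalH = y$interval_h %||% dflt@intervalH,
    durationH = y$duration_h %||% dflt@durationH,
    temperatureC = y$temperature_c %||% dflt@temperatureC)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname readExperimentConfig
#' @export
writeExperimentConfig <- function(config, file) {
  yaml::write_yaml(list(
    grid_rows = config@gridRows, grid_cols = config@gridCols,
    concentrations = as.list(config@concentrations),
    replicates = config@replicates, interval_h = config@intervalH,
    duration_h = config@durationH, temperature_c = config@temperatureC), file)
  invisible(file)
}

# ---- annotation records ----------------------------------------------------

#' Per-image annotation record
#'
#' A lightweight list describing one labelled image: `imageId`,
#' `imageWidth`/`imageHeight` in pixels, and `objects`, a data.frame with
#' columns `label`, `x1`, `y1`, `x2`, `y2` (corner-form pixel boxes, origin
#' top-left). Corner coordinates are treated as 0-based continuous
#' positions.
#'
#' @param imageId image identifier.
#' @param imageWidth,imageHeight image size in pixels.
#' @param objects data.frame of labelled corner boxes.
#' @return An object of class `AnnotationRecord` (a list).
#' @export
annotationRecord <- function(imageId, imageWidth, imageHeight,
                             objects = data.frame(label = character(0),
                                                  x1 = numeric(0), y1 = numeric(0),
                                                  x2 = numeric(0), y2 = numeric(0))) {
  .checkLabels(objects$label)
  if (nrow(objects) && any(objects$x1 >= objects$x2 | objects$y1 >= objects$y2))
    stop("invalid box: corners must satisfy x1 < x2 and y1 < y2")
  structure(list(imageId = as.character(imageId),
                 imageWidth = imageWidth, imageHeight = imageHeight,
                 objects = objects),
            class = "AnnotationRecord")
}

#' @export
print.AnnotationRecord <- function(x, ...) {
  cat(sprintf("AnnotationRecord %s (%dx%d px), %d object(s)\n",
              x$imageId, x$imageWidth, x$imageHeight, nrow(x$objects)))
  invisible(x)
}

#' Read and write Pascal-VOC XML annotations
#'
#' The on-disk layout follows the LabelImg convention: `<annotation>` with
#' `<filename>`, `<size>` (`width`, `height`) and one `<object>` per box
#' carrying `<name>` and `<bndbox>` (`xmin`, `ymin`, `xmax`, `ymax`).
#'
#' @param file XML path.
#' @param record an [annotationRecord()] for the writer.
#' @return The record (reader) or `file` invisibly (writer).
#' @export
readVocXml <- function(file) {
  doc <- xml2::read_xml(file)
  w <- as.numeric(xml2::xml_text(xml2::xml_find_first(doc, ".//size/width")))
  h <- as.numeric(xml2::xml_text(xml2::xml_find_first(doc, ".//size/height")))
  id <- xml2::xml_text(xml2::xml_find_first(doc, ".//filename"))
  objs <- xml2::xml_find_all(doc, ".//object")
  getnum <- function(node, xp)
    as.numeric(xml2::xml_text(xml2::xml_find_first(node, xp)))
  objects <- do.call(rbind, lapply(objs, function(o) data.frame(
    label = xml2::xml_text(xml2::xml_find_first(o, "./name")),
    x1 = getnum(o, "./bndbox/xmin"), y1 = getnum(o, "./bndbox/ymin"),
    x2 = getnum(o, "./bndbox/xmax"), y2 = getnum(o, "./bndbox/ymax"),
    stringsAsFactors = FALSE)))
  if (is.null(objects))
    objects <- data.frame(label = character(0), x1 = numeric(0),
                          y1 = numeric(0), x2 = numeric(0), y2 = numeric(0))
  annotationRecord(id, w, h, objects)
}

#' @rdname readVocXml
#' @export
writeVocXml <- function(record, file) {
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", record$imageId)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(record$imageWidth))
  xml2::xml_add_child(size, "height", as.character(record$imageHeight))
  xml2::xml_add_child(size, "depth", "1")
  for (i in seq_len(nrow(record$objects))) {
    o <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(o, "name", record$objects$label[i])
    bb <- xml2::xml_add_child(o, "bndbox")
    xml2::xml_add_child(bb, "xmin", format(record$objects$x1[i], digits = 10))
    xml2::xml_add_child(bb, "ymin", format(record$objects$y1[i], digits = 10))
    xml2::xml_add_child(bb, "xmax", format(record$objects$x2[i], digits = 10))
    xml2::xml_add_child(bb, "ymax", format(record$objects$y2[i], digits = 10))
  }
  xml2::write_xml(doc, file)
  invisible(file)
}

#' Convert between VOC corner annotations and YOLO text lines
#'
#' `vocToYolo()` emits one line per object, `class_idx cx cy w h`, with
#' center/size normalised by the image dimensions and printed with six
#' decimals; class indices follow the fixed vocabulary order (seed = 0,
#' S_root = 1, L_root = 2). `yoloToVoc()` inverts the mapping. The two
#' compose to the identity within 1e-4 normalised units (six-decimal
#' rounding).
#'
#' @param record an [annotationRecord()].
#' @param lines character vector of YOLO lines.
#' @param imageId,imageWidth,imageHeight image metadata for `yoloToVoc()`.
#' @return Character vector of lines, or an annotation record.
#' @export
vocToYolo <- function(record) {
  if (!nrow(record$objects)) return(character(0))
  ob <- record$objects
  eps <- 1e-6
  if (any(ob$x1 < -eps | ob$y1 < -eps |
          ob$x2 > record$imageWidth + eps | ob$y2 > record$imageHeight + eps))
    stop("annotation box extends outside the image")
  idx <- match(ob$label, classVocabulary()) - 1L
  cx <- (ob$x1 + ob$x2) / 2 / record$imageWidth
  cy <- (ob$y1 + ob$y2) / 2 / record$imageHeight
  w <- (ob$x2 - ob$x1) / record$imageWidth
  h <- (ob$y2 - ob$y1) / record$imageHeight
  sprintf("%d %.6f %.6f %.6f %.6f", idx, cx, cy, w, h)
}

#' @rdname vocToYolo
#' @export
yoloToVoc <- function(lines, imageId, imageWidth, imageHeight) {
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(annotationRecord(imageId, imageWidth, imageHeight))
  mat <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  cx <- mat[, 2] * imageWidth; cy <- mat[, 3] * imageHeight
  w <- mat[, 4] * imageWidth; h <- mat[, 5] * imageHeight
  annotationRecord(imageId, imageWidth, imageHeight, data.frame(
    label = classVocabulary()[mat[, 1] + 1L],
    x1 = cx - w / 2, y1 = cy - h / 2, x2 = cx + w / 2, y2 = cy + h / 2,
    stringsAsFactors = FALSE))
}

# ---- augmentation ----------------------------------------------------------

.clipObjects <- function(objects, W, H) {
  if (!nrow(objects)) return(objects)
  objects$x1 <- pmax(objects$x1, 0); objects$y1 <- pmax(objects$y1, 0)
  objects$x2 <- pmin(objects$x2, W); objects$y2 <- pmin(objects$y2, H)
  gone <- objects$x2 - objects$x1 <= 0 | objects$y2 - objects$y1 <= 0
  if (any(gone))
    warning(sprintf("%d object(s) fell fully outside the canvas and were dropped",
                    sum(gone)))
  objects[!gone, , drop = FALSE]
}

#' Box-aware image augmentation
#'
#' Applies one enhancement to an image and its annotation record, keeping
#' boxes consistent with the pixels. Images are `H x W` numeric matrices in
#' `[0, 1]`. Operations:
#' \describe{
#'   \item{`hflip`}{mirror about the vertical axis; `cx` maps to `W - cx`.}
#'   \item{`rotate`}{rotation by `angle` degrees about the image center on a
#'     fixed canvas; each box's four corners are rotated and re-enclosed in
#'     an axis-aligned box (detection-style, so non-axis angles inflate the
#'     area), then clipped.}
#'   \item{`scale`}{content resized by `factor` about the origin on the same
#'     canvas; boxes multiply by `factor` and are clipped.}
#'   \item{`noise`}{additive Gaussian pixel noise with standard deviation
#'     `sigma`, seeded and reproducible; boxes unchanged.}
#'   \item{`flip_rotate`}{`hflip` followed by `rotate` -- the extra,
#'     explicitly labelled combination op.}
#' }
#' Objects falling entirely outside the canvas are dropped with a warning.
#'
#' @param image `H x W` numeric matrix.
#' @param record matching [annotationRecord()].
#' @param op one of `"hflip"`, `"rotate"`, `"scale"`, `"noise"`,
#'   `"flip_rotate"`.
#' @param angle rotation angle in degrees (counter-clockwise).
#' @param factor scale factor (> 0).
#' @param sigma noise standard deviation.
#' @param seed RNG seed for `noise`.
#' @return List with transformed `image` and `record`.
#' @export
augment <- function(image, record,
                    op = c("hflip", "rotate", "scale", "noise", "flip_rotate"),
                    angle = 90, factor = 0.8, sigma = 0.02, seed = 1L) {
  op <- match.arg(op)
  H <- nrow(image); W <- ncol(image)
  stopifnot(record$imageWidth == W, record$imageHeight == H)
  ob <- record$objects
  out <- switch(op,
    hflip = {
      img <- image[, W:1, drop = FALSE]
      if (nrow(ob)) {
        x1 <- W - ob$x2; x2 <- W - ob$x1
        ob$x1 <- x1; ob$x2 <- x2
      }
      list(image = img, objects = ob)
    },
    rotate = {
      img <- .rotateImage(image, angle)
      if (nrow(ob)) ob <- .rotateObjects(ob, angle, W, H)
      list(image = img, objects = .clipObjects(ob, W, H))
    },
    scale = {
      img <- .scaleImage(image, factor)
      if (nrow(ob)) {
        ob$x1 <- ob$x1 * factor; ob$x2 <- ob$x2 * factor
        ob$y1 <- ob$y1 * factor; ob$y2 <- ob$y2 * factor
      }
      list(image = img, objects = .clipObjects(ob, W, H))
    },
    noise = {
      old <- .Random.seed.safe()
      set.seed(seed)
      img <- image + matrix(stats::rnorm(H * W, sd = sigma), H, W)
      .restoreSeed(old)
      list(image = pmin(pmax(img, 0), 1), objects = ob)
    },
    flip_rotate = {
      tmp <- augment(image, record, "hflip")
      return(augment(tmp$image, tmp$record, "rotate", angle = angle))
    }
  )
  list(image = out$image,
       record = annotationRecord(record$imageId, W, H, out$objects))
}

.Random.seed.safe <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.restoreSeed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# rotate image about its center on the same canvas (EBImage convention:
# transposed storage, so go through an EBImage Image and back)
.rotateImage <- function(image, angle) {
  img <- EBImage::Image(t(image))
  bg <- as.numeric(stats::median(image))
  rot <- EBImage::rotate(img, angle, output.dim = c(ncol(image), nrow(image)),
                         bg.col = bg)
  t(EBImage::imageData(rot))
}

.scaleImage <- function(image, factor) {
  H <- nrow(image); W <- ncol(image)
  img <- EBImage::Image(t(image))
  res <- EBImage::resize(img, w = max(1, round(W * factor)),
                         h = max(1, round(H * factor)))
  dat <- t(EBImage::imageData(res))
  bg <- as.numeric(stats::median(image))
  canvas <- matrix(bg, H, W)
  hh <- min(H, nrow(dat)); ww <- min(W, ncol(dat))
  canvas[seq_len(hh), seq_len(ww)] <- dat[seq_len(hh), seq_len(ww)]
  canvas
}

.rotateObjects <- function(ob, angle, W, H) {
  th <- angle * pi / 180
  cxm <- W / 2; cym <- H / 2
  for (i in seq_len(nrow(ob))) {
    xs <- c(ob$x1[i], ob$x2[i], ob$x1[i], ob$x2[i]) - cxm
    ys <- c(ob$y1[i], ob$y1[i], ob$y2[i], ob$y2[i]) - cym
    # screen coordinates (y down): visually clockwise rotation by th
    xr <- xs * cos(th) - ys * sin(th) + cxm
    yr <- xs * sin(th) + ys * cos(th) + cym
    ob$x1[i] <- min(xr); ob$x2[i] <- max(xr)
    ob$y1[i] <- min(yr); ob$y2[i] <- max(yr)
  }
  ob
}

# ---- splitting and scheduling ----------------------------------------------

#' Split image ids into train/validation/test sets
#'
#' Seeded random partition at the given ratios. Validation and test sizes
#' are floors of their ratio shares; the remainder goes to the training set,
#' so 1000 ids at 7:2:1 give 700/200/100. The three sets are disjoint and
#' exhaustive, and the same seed always reproduces the same partition.
#'
#' @param ids character or numeric vector of image identifiers (nonempty).
#' @param ratios length-3 positive weights for train/val/test (default
#'   `c(7, 2, 1)`; any positive weights work, they are normalised).
#' @param seed RNG seed.
#' @return List with elements `train`, `val`, `test`.
#' @export
splitDataset <- function(ids, ratios = c(7, 2, 1), seed = 1L) {
  if (!length(ids)) stop("ids must be nonempty")
  if (length(ratios) != 3L || any(ratios <= 0))
    stop("ratios must be three positive numbers")
  p <- ratios / sum(ratios)
  n <- length(ids)
  nVal <- floor(n * p[2]); nTest <- floor(n * p[3])
  nTrain <- n - nVal - nTest
  old <- .Random.seed.safe()
  set.seed(seed)
  perm <- sample(ids)
  .restoreSeed(old)
  list(train = perm[seq_len(nTrain)],
       val = perm[nTrain + seq_len(nVal)],
       test = perm[nTrain + nVal + seq_len(nTest)])
}

#' Image-acquisition schedule for an experiment
#'
#' One image per tray at every multiple of the interval in `(0, duration]`
#' (first frame at `t = interval`), so a 48 h run at 0.5 h gives 96 frames
#' per tray, and the default 6 concentrations x 3 replicates give 18 trays
#' and 1728 images.
#'
#' @param config an [ExperimentConfig-class].
#' @return data.frame with columns `trayId`, `concentration`, `replicate`,
#'   `time_h`, one row per acquisition.
#' @export
acquisitionSchedule <- function(config) {
  times <- seq(config@intervalH, config@durationH, by = config@intervalH)
  rows <- list()
  for (conc in config@concentrations) {
    for (rep in seq_len(config@replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        trayId = sprintf("c%03d_r%d", conc, rep),
        concentration = conc, replicate = rep, time_h = times,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(trayId = character(0), concentration = numeric(0),
                      replicate = integer(0), time_h = numeric(0)))
  do.call(rbind, rows)
}
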