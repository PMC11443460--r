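test_that("the default experiment configuration matches the reference design", {
  cfg <- experimentConfig()
  expect_equal(cfg@gridRows * cfg@gridCols, 81L)
  nTrays <- length(cfg@concentrations) * cfg@replicates
  expect_equal(nTrays, 18L)
  expect_equal(cfg@gridRows * cfg@gridCols * nTrays, 1458L)  # seeds in total
  expect_error(experimentConfig(intervalH = 0.7), "divide")
  expect_error(experimentConfig(concentrations = c(-5, 30)), "nonnegative")
})

test_that("experiment configuration round-trips through YAML", {
  cfg <- experimentConfig(concentrations = c(0, 45), replicates = 2L,
                          intervalH = 1, durationH = 12)
  f <- tempfile(fileext = ".yaml")
  writeExperimentConfig(cfg, f)
  back <- readExperimentConfig(f)
  expect_equal(back@concentrations, c(0, 45))
  expect_equal(back@replicates, 2L)
  expect_equal(back@durationH, 12)
  unlink(f)
})

test_that("voc to yolo emits fixed six-decimal normalised lines", {
  rec <- annotationRecord("img1", 640, 640, data.frame(
    label = c("seed", "L_root"),
    x1 = c(0, 0), y1 = c(0, 0), x2 = c(320, 640), y2 = c(320, 640)))
  lines <- vocToYolo(rec)
  expect_equal(lines[1], "0 0.250000 0.250000 0.500000 0.500000")
  expect_equal(lines[2], "2 0.500000 0.500000 1.000000 1.000000")

  outside <- annotationRecord("img2", 100, 100, data.frame(
    label = "seed", x1 = -20, y1 = 10, x2 = 50, y2 = 60))
  expect_error(vocToYolo(outside), "outside")
})

test_that("yolo and voc conversions invert each other", {
  set.seed(6)
  for (i in 1:20) {
    x <- sort(runif(2, 0, 640)); y <- sort(runif(2, 0, 480))
    rec <- annotationRecord("img", 640, 480, data.frame(
      label = sample(classVocabulary(), 1), x1 = x[1], y1 = y[1],
      x2 = x[2], y2 = y[2]))
    back <- yoloToVoc(vocToYolo(rec), "img", 640, 480)
    expect_equal(back$objects$label, rec$objects$label)
    for (cl in c("x1", "y1", "x2", "y2"))
      expect_lt(abs(back$objects[[cl]] - rec$objects[[cl]]) / 640, 1e-4)
    # and the printed line itself is reproduced exactly
    expect_identical(vocToYolo(back), vocToYolo(rec))
  }
})

test_that("voc xml files round-trip through the LabelImg layout", {
  rec <- annotationRecord("tray_12.png", 972, 972, data.frame(
    label = c("seed", "S_root"), x1 = c(10.5, 200), y1 = c(20, 300.25),
    x2 = c(42.5, 230), y2 = c(34, 348)))
  f <- tempfile(fileext = ".xml")
  writeVocXml(rec, f)
  back <- readVocXml(f)
  expect_equal(back$imageId, "tray_12.png")
  expect_equal(back$imageWidth, 972)
  expect_equal(back$objects$label, rec$objects$label)
  expect_equal(back$objects$x2, rec$objects$x2)
  unlink(f)
})

test_that("horizontal flip mirrors boxes and pixels consistently", {
  img <- matrix(0, 100, 100); img[40:60, 10:30] <- 1
  rec <- annotationRecord("i", 100, 100, data.frame(
    label = "seed", x1 = 9, y1 = 39, x2 = 30, y2 = 60))
  out <- augment(img, rec, "hflip")
  expect_equal(out$record$objects$x1, 70)
  expect_equal(out$record$objects$x2, 91)
  expect_equal(out$record$objects$y1, 39)   # y untouched
  expect_equal(sum(out$image), sum(img))
  expect_equal(out$image[50, 80], 1)
  # normalized center cx = 0.25 maps to 0.75
  cx <- with(out$record$objects, (x1 + x2) / 2) / 100
  expect_equal(cx, 1 - (9 + 30) / 2 / 100)
})

test_that("rotation by 90 degrees re-encloses corners exactly", {
  img <- matrix(0, 640, 640); img[1:320, 1:320] <- 1
  rec <- annotationRecord("i", 640, 640, data.frame(
    label = "seed", x1 = 0, y1 = 0, x2 = 320, y2 = 320))
  out <- augment(img, rec, "rotate", angle = 90)
  ob <- out$record$objects
  expect_equal(c(ob$x1, ob$y1, ob$x2, ob$y2), c(320, 0, 640, 320))
  expect_equal(ob$label, "seed")
  # pixels moved to the same quadrant as the box
  expect_gt(mean(out$image[1:320, 321:640]), 0.95)
  expect_lt(mean(out$image[321:640, 1:320]), 0.05)
})

test_that("scaling multiplies boxes and clips them to the canvas", {
  img <- matrix(0, 200, 200); img[81:120, 81:120] <- 1
  rec <- annotationRecord("i", 200, 200, data.frame(
    label = "L_root", x1 = 80, y1 = 80, x2 = 120, y2 = 120))
  half <- augment(img, rec, "scale", factor = 0.5)
  expect_equal(unlist(half$record$objects[, c("x1", "y1", "x2", "y2")]),
               c(x1 = 40, y1 = 40, x2 = 60, y2 = 60))
  big <- augment(img, rec, "scale", factor = 2)
  expect_equal(big$record$objects$x2, 200)  # clipped at the canvas edge

  corner <- annotationRecord("i", 200, 200, data.frame(
    label = "seed", x1 = 150, y1 = 150, x2 = 180, y2 = 180))
  expect_warning(out <- augment(img, corner, "scale", factor = 3), "dropped")
  expect_equal(nrow(out$record$objects), 0)

  far <- augment(img, corner, "rotate", angle = 45)
  expect_true(all(far$record$objects$x2 <= 200 & far$record$objects$x1 >= 0))
  expect_equal(far$record$objects$label, "seed")
})

test_that("noise is reproducible, bounded and leaves boxes alone", {
  set.seed(99)
  img <- matrix(runif(50 * 50, 0.2, 0.8), 50, 50)
  rec <- annotationRecord("i", 50, 50, data.frame(
    label = "seed", x1 = 5, y1 = 5, x2 = 20, y2 = 20))
  a <- augment(img, rec, "noise", sigma = 0.05, seed = 42)
  b <- augment(img, rec, "noise", sigma = 0.05, seed = 42)
  c2 <- augment(img, rec, "noise", sigma = 0.05, seed = 43)
  expect_identical(a$image, b$image)
  expect_false(identical(a$image, c2$image))
  expect_identical(a$record$objects, rec$objects)
  expect_true(all(a$image >= 0 & a$image <= 1))
})

test_that("the labelled extra op flips then rotates", {
  img <- matrix(0, 100, 100); img[1:20, 1:20] <- 1
  rec <- annotationRecord("i", 100, 100, data.frame(
    label = "seed", x1 = 0, y1 = 0, x2 = 20, y2 = 20))
  out <- augment(img, rec, "flip_rotate", angle = 90)
  # hflip moves the box to the top-right; rotating 90 cw sends it bottom-right
  ob <- out$record$objects
  expect_equal(c(ob$x1, ob$y1, ob$x2, ob$y2), c(80, 80, 100, 100))
})

test_that("dataset splitting is exact, seeded and exhaustive", {
  ids <- sprintf("img%04d", 1:1000)
  sp <- splitDataset(ids, c(7, 2, 1), seed = 5)
  expect_equal(lengths(sp), c(train = 700L, val = 200L, test = 100L))
  expect_equal(sort(unname(unlist(sp))), sort(ids))
  expect_equal(length(intersect(sp$train, sp$val)), 0)

  sp10 <- splitDataset(as.character(1:10), c(7, 2, 1), seed = 1)
  expect_equal(lengths(sp10), c(train = 7L, val = 2L, test = 1L))

  again <- splitDataset(ids, c(7, 2, 1), seed = 5)
  expect_identical(sp, again)
  other <- splitDataset(ids, c(7, 2, 1), seed = 6)
  expect_false(identical(sp$train, other$train))
  expect_error(splitDataset(character(0)), "nonempty")
  expect_error(splitDataset(ids, c(1, 1)), "three positive")
})

test_that("the acquisition schedule covers (0, duration] at the interval", {
  one <- acquisitionSchedule(experimentConfig(
    concentrations = 0, replicates = 1L, intervalH = 0.5, durationH = 1))
  expect_equal(one$time_h, c(0.5, 1))

  full <- acquisitionSchedule(experimentConfig())
  expect_equal(nrow(full), 1728L)
  expect_equal(length(unique(full$trayId)), 18L)
  expect_equal(max(full$time_h), 48)
  expect_equal(min(full$time_h), 0.5)

  none <- acquisitionSchedule(experimentConfig(replicates = 0L))
  expect_equal(nrow(none), 0)
})
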