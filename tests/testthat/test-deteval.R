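test_that("nms keeps the high scorer among overlapping same-class boxes", {
  d <- detections(c("f", "f"), c("seed", "seed"), c(10, 10), c(10, 10),
                  c(4, 4), c(4, 4), c(0.9, 0.8))
  kept <- nms(d, 0.7)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$confidence, 0.9)

  disj <- detections(c("f", "f"), c("seed", "seed"), c(10, 100), c(10, 100),
                     c(4, 4), c(4, 4), c(0.9, 0.8))
  expect_equal(nrow(nms(disj, 0.7)), 2)
})

test_that("nms follows the greedy procedure on a three-box chain", {
  # A overlaps B at IoU 0.8 (suppressed), C at 0.1 (kept); conf A > B > C
  a <- c(cx = 10, cy = 10, w = 10, h = 10)
  b <- c(cx = 10, cy = 10 + 10 / 9, w = 10, h = 10)     # IoU(A,B) = 0.8
  stopifnot(abs(iou(bbox(10, 10, 10, 10), bbox(b["cx"], b["cy"], 10, 10)) - 0.8) < 1e-9)
  cc <- c(cx = 10, cy = 26.4, w = 10, h = 10)           # IoU(A,C) ~ 0.1
  d <- detections(rep("f", 3), rep("seed", 3),
                  c(a["cx"], b["cx"], cc["cx"]), c(a["cy"], b["cy"], cc["cy"]),
                  rep(10, 3), rep(10, 3), c(0.9, 0.8, 0.7))
  kept <- nms(d, 0.7)
  expect_equal(kept$confidence, c(0.9, 0.7))
  expect_equal(nrow(nms(d[0, ], 0.7)), 0)
  expect_error(nms(d, 0), "iouThreshold")
})

test_that("nms never suppresses across classes or frames", {
  d <- detections(c("f1", "f1", "f2"), c("seed", "L_root", "seed"),
                  rep(10, 3), rep(10, 3), rep(4, 3), rep(4, 3),
                  c(0.9, 0.8, 0.7))
  expect_equal(nrow(nms(d, 0.5)), 3)
})

test_that("a perfect detector scores ones across the board", {
  t <- groundTruths(c("f1", "f1", "f2"), c("seed", "L_root", "seed"),
                    c(10, 30, 50), c(10, 30, 50), c(8, 6, 8), c(8, 12, 8))
  d <- detections(t$frameId, t$label, t$cx, t$cy, t$w, t$h, rep(1, 3))
  r <- matchAndScore(d, t, 0.5)
  pc <- r$perClass
  expect_equal(pc$precision[pc$class == "seed"], 1)
  expect_equal(pc$recall[pc$class == "seed"], 1)
  expect_equal(pc$AP[pc$class == "seed"], 1)
  expect_equal(r$map50, 1)
  expect_true(is.na(pc$AP[pc$class == "S_root"]))
})

test_that("a confident hit followed by a spurious box keeps AP at one", {
  t <- groundTruths("f1", "seed", 10, 10, 8, 8)
  d <- detections(c("f1", "f1"), c("seed", "seed"), c(10, 60), c(10, 60),
                  c(8, 8), c(8, 8), c(0.9, 0.5))
  r <- matchAndScore(d, t, 0.5)
  pc <- r$perClass[r$perClass$class == "seed", ]
  expect_equal(pc$precision, 0.5)
  expect_equal(pc$recall, 1)
  expect_equal(pc$AP, 1)   # the PR curve reaches (1, 1) before the FP
})

test_that("missing everything scores zero", {
  t <- groundTruths("f1", "seed", 10, 10, 8, 8)
  none <- detections(character(0), character(0), numeric(0), numeric(0),
                     numeric(0), numeric(0), numeric(0))
  r <- matchAndScore(none, t, 0.5)
  pc <- r$perClass[r$perClass$class == "seed", ]
  expect_equal(pc$precision, 0)
  expect_equal(pc$recall, 0)
  expect_equal(pc$AP, 0)
  expect_error(matchAndScore(
    data.frame(frameId = "f", label = "weed", cx = 1, cy = 1, w = 1, h = 1,
               confidence = 0.5), t), "unknown class")
})

test_that("AP equals the brute-force PR-enumeration oracle on random instances", {
  set.seed(101)
  for (i in 1:60) {
    inst <- randomEvalInstance(maxBoxes = 6L)
    r <- matchAndScore(inst$dets, inst$truths, 0.5, classes = "seed")
    want <- bruteMatchAP(inst$dets, inst$truths, 0.5)
    expect_lt(abs(r$perClass$AP[1] - want), 1e-9)
    # counting conservation
    pc <- r$perClass[1, ]
    expect_equal(pc$TP + pc$FN, nrow(inst$truths))
    expect_equal(pc$TP + pc$FP, nrow(inst$dets))
    # the interpolated precision envelope is non-increasing in recall
    pr <- r$prCurves$seed
    env <- rev(cummax(rev(pr$precision)))
    expect_true(all(diff(env) <= 1e-12))
  }
})

test_that("yolo text round-trips through reader and writer conventions", {
  dir <- tempfile(); dir.create(dir)
  writeLines(c("0 0.250000 0.250000 0.500000 0.500000",
               "2 0.500000 0.500000 0.100000 0.200000"),
             file.path(dir, "frameA.txt"))
  writeLines("1 0.5 0.5 0.25 0.25 0.77", file.path(dir, "frameB.txt"))

  g <- readYolo(file.path(dir, "frameA.txt"), 640, 640, frameId = "frameA")
  expect_equal(g$label, c("seed", "L_root"))
  expect_equal(g$cx, c(160, 320))
  expect_equal(g$w, c(320, 64))

  d <- readYoloDir(dir, 640, 640, predictions = TRUE)
  expect_equal(nrow(d), 3)
  expect_equal(d$confidence[d$frameId == "frameB"], 0.77)
  expect_equal(sort(unique(d$frameId)), c("frameA", "frameB"))
  unlink(dir, recursive = TRUE)
})

test_that("metrics tables are written as CSV", {
  t <- groundTruths("f1", "seed", 10, 10, 8, 8)
  d <- detections("f1", "seed", 10, 10, 8, 8, 1)
  r <- matchAndScore(d, t, 0.5)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writeMetricsCsv(r, f1, f2)
  m <- read.csv(f1)
  expect_equal(nrow(m), 3)
  expect_equal(m$AP[m$class == "seed"], 1)
  expect_true(file.exists(f2))
  unlink(c(f1, f2))
})
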