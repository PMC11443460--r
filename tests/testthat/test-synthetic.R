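# growth model with hard-wired germination probability, handy below
constModel <- function(p, rate = 2, ...) {
  growthModel(pGerm = function(conc) if (conc >= 160) 0 else p,
              growthRate = function(conc) rate, ...)
}

smallConfig <- function() experimentConfig(concentrations = c(0, 160),
                                           replicates = 1L, intervalH = 4,
                                           durationH = 48)

test_that("no seed germinates at or above the zero-germination threshold", {
  cfg <- smallConfig()
  tray <- simulateTray(cfg, growthModel(), conc = 160, seed = 1)
  expect_false(any(tray$trajectories$germinates))
  expect_true(all(tray$classAt(48) == "seed"))
  tl <- groundTruthTimeline(tray, seq(4, 48, by = 4))
  expect_true(all(germinatedCounts(tl) == 0))
  expect_equal(growthModel()@pGerm(200), 0)
})

test_that("saturated germination reaches one hundred percent by the end", {
  cfg <- smallConfig()
  tray <- simulateTray(cfg, constModel(1), conc = 0, seed = 2)
  expect_true(all(tray$trajectories$germinates))
  expect_true(all(tray$classAt(48) == "L_root"))
  tl <- groundTruthTimeline(tray, seq(4, 48, by = 4))
  expect_equal(germinationRate(tl, 48), 100)
})

test_that("simulation is deterministic given its seed", {
  cfg <- smallConfig()
  a <- simulateTray(cfg, growthModel(), 60, seed = 7)
  b <- simulateTray(cfg, growthModel(), 60, seed = 7)
  expect_identical(a$trajectories, b$trajectories)
  c2 <- simulateTray(cfg, growthModel(), 60, seed = 8)
  expect_false(identical(a$trajectories, c2$trajectories))
})

test_that("seed classes follow the half-seed-length standard over time", {
  cfg <- smallConfig()
  tray <- simulateTray(cfg, constModel(1, rate = 0.4), conc = 0, seed = 3)
  tr <- tray$trajectories
  t <- 30
  len <- tray$rootLengthAt(t)
  cls <- tray$classAt(t)
  expect_true(all(cls[len == 0] == "seed"))
  expect_true(all(cls[len > 0 & len < 4] == "S_root"))
  expect_true(all(cls[len >= 4] == "L_root"))
  # default dose response: mild promotion at 30, monotone decline above
  gm <- growthModel()
  p <- vapply(c(0, 30, 60, 90, 120, 150), gm@pGerm, numeric(1))
  expect_gt(p[2], p[1])
  expect_true(all(diff(p[-1]) < 0))
})

test_that("ungerminated trays render exactly eighty-one seed objects", {
  cfg <- smallConfig()
  tray <- simulateTray(cfg, growthModel(), conc = 160, seed = 4)
  fr <- renderFrames(tray, sceneSpec(), times = c(24, 48), noiseSeed = NULL)
  for (f in fr) {
    expect_equal(nrow(f$record$objects), 81)
    expect_true(all(f$record$objects$label == "seed"))
    # the annotations satisfy the converter contract
    lines <- vocToYolo(f$record)
    expect_equal(length(lines), 81)
    back <- yoloToVoc(lines, f$record$imageId, 972, 972)
    expect_equal(nrow(back$objects), 81)
  }
})

test_that("a straight diagonal radicle measures its true chord length", {
  pts <- germkit:::.radiclePath(c(100, 100), atan2(3, 4), lenPx = 50,
                                curvature = 0)
  dx <- diff(range(pts[, "x"])); dy <- diff(range(pts[, "y"]))
  expect_lt(abs(sqrt(dx^2 + dy^2) - 50), 1)
  expect_lt(abs(dx - 40), 0.5)   # 3-4-5 triangle
  expect_lt(abs(dy - 30), 0.5)
  # with the default gentle curvature the chord shortfall stays within 2%
  bent <- germkit:::.radiclePath(c(100, 100), atan2(3, 4), lenPx = 50,
                                 curvature = 0.05)
  seg <- sum(sqrt(diff(bent[, "x"])^2 + diff(bent[, "y"])^2))
  expect_lt(abs(seg - 50) / 50, 0.02)
})

test_that("rendered root boxes track measurable radicles within 15 percent", {
  scene <- sceneSpec(noiseSd = 0)
  # one seed per render, sweeping direction and root length >= 6 mm
  # (lengths kept within the cell so no radicle is clipped)
  for (ang in c(35, 45, 55, 135, 225, 315) * pi / 180) {
    for (lenMm in c(6, 8, 10)) {
      lenPx <- lenMm / scene@mmPerPixel
      tray <- list(
        trajectories = data.frame(seedId = 1L, row = 5L, col = 5L,
                                  germinates = TRUE, tEmerge = 0, rate = 1,
                                  rootDir = ang, orientJitter = 0),
        conc = 0, trayId = "one", seedLengthMm = 8,
        rootLengthAt = function(t) lenMm,
        classAt = function(t) "L_root")
      fr <- renderFrames(tray, scene, times = 1, noiseSeed = NULL,
                         gridRows = 9L, gridCols = 9L)
      ob <- fr[[1]]$record$objects
      ro <- ob[ob$label == "L_root", ]
      expect_equal(nrow(ro), 1)
      dg <- sqrt((ro$x2 - ro$x1)^2 + (ro$y2 - ro$y1)^2)
      expect_lt(abs(dg - lenPx) / lenPx, 0.15)
    }
  }
})

test_that("the reference detector sees seeds, roots and empty frames correctly", {
  cfg <- smallConfig()
  scene <- sceneSpec(noiseSd = 0)

  blank <- matrix(scene@background, 972, 972)
  expect_equal(nrow(referenceDetect(blank, scene)), 0)

  dormant <- simulateTray(cfg, growthModel(), conc = 160, seed = 6)
  fr <- renderFrames(dormant, scene, times = 24, noiseSeed = NULL)
  d <- referenceDetect(fr[[1]]$image, scene)
  expect_equal(sum(d$label == "seed"), 81)
  expect_equal(sum(d$label != "seed"), 0)
  expect_true(all(d$confidence > 0.8))

  # one long radicle: exactly one L-root detection overlapping its truth
  grid <- expand.grid(row = 1:9, col = 1:9)
  lens <- c(8, rep(0, 80))   # only the first seed has a root (8 mm)
  one <- list(
    trajectories = data.frame(seedId = 1:81, row = grid$row, col = grid$col,
                              germinates = lens > 0, tEmerge = 20, rate = 0.5,
                              rootDir = pi / 4, orientJitter = 0),
    conc = 0, trayId = "one", seedLengthMm = 8,
    rootLengthAt = function(t) lens,
    classAt = function(t) ifelse(lens >= 4, "L_root",
                                 ifelse(lens > 0, "S_root", "seed")))
  fr <- renderFrames(one, scene, times = 36, noiseSeed = NULL)
  d <- referenceDetect(fr[[1]]$image, scene, frameId = "f")
  expect_equal(sum(d$label == "L_root"), 1)
  truthL <- recordToTruths(fr[[1]]$record, "f")
  truthL <- truthL[truthL$label == "L_root", ]
  got <- d[d$label == "L_root", ]
  expect_gte(iou(bbox(got$cx, got$cy, got$w, got$h),
                 bbox(truthL$cx, truthL$cy, truthL$w, truthL$h)), 0.5)
})

test_that("the closed pipeline recovers the simulated germination exactly or nearly", {
  cfg <- experimentConfig(concentrations = c(0, 90), replicates = 1L,
                          intervalH = 12, durationH = 48)
  res <- suppressWarnings(runTrayPipeline(cfg, growthModel(), sceneSpec(),
                                          conc = 90, seed = 12,
                                          times = c(24, 36, 48)))
  got <- tail(germinatedCounts(res$timeline), 1)
  want <- tail(germinatedCounts(res$truth), 1)
  expect_lte(abs(got - want), 2)
  expect_s4_class(res$timeline, "GerminationTimeline")
  expect_true(validObject(res$timeline))
})
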