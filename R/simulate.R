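#' @include AllClasses.R dataset.R phenotype.R
NULL

#' Construct a growth model
#'
#' The default dose-response profile encodes the qualitative cucumber
#' findings: germination probability 0.85 in deionised water, mildly
#' promoted to 0.92 at 30 mmol/L NaCl, monotone inhibition above (0.75,
#' 0.55, 0.30, 0.10 at 60-150 mmol/L) and zero at or above 160 mmol/L;
#' radicle emergence around 24 h (Normal, mean 26 h, sd 4 h); linear root
#' elongation at 0.40 mm/h in the control, slightly faster (0.44 mm/h) at
#' 30 mmol/L, declining with concentration to 0.18 mm/h at 150 mmol/L.
#' Intermediate concentrations are linearly interpolated. The nominal seed
#' length is 8 mm, so the L-root germination standard is a 4 mm radicle.
#'
#' @param pGerm function(concentration) -> probability; default as above.
#' @param tEmergeMean,tEmergeSd emergence-time distribution (hours).
#' @param growthRate function(concentration) -> elongation rate (mm/h).
#' @param seedLengthMm nominal seed length (mm).
#' @param zeroConcThreshold concentration at/above which `pGerm` is 0
#'   (mmol/L).
#' @return A [GrowthModel-class].
#' @export
growthModel <- function(pGerm = NULL, tEmergeMean = 26, tEmergeSd = 4,
                        growthRate = NULL, seedLengthMm = 8,
                        zeroConcThreshold = 160) {
  if (is.null(pGerm)) {
    anchors <- data.frame(
      conc = c(0, 30, 60, 90, 120, 150, zeroConcThreshold),
      p = c(0.85, 0.92, 0.75, 0.55, 0.30, 0.10, 0))
    pGerm <- function(conc) {
      if (conc >= zeroConcThreshold) return(0)
      stats::approx(anchors$conc, anchors$p, xout = conc, rule = 2)$y
    }
  }
  if (is.null(growthRate)) {
    ranchors <- data.frame(conc = c(0, 30, 150, 200),
                           rate = c(0.40, 0.44, 0.18, 0.10))
    growthRate <- function(conc)
      stats::approx(ranchors$conc, ranchors$rate, xout = conc, rule = 2)$y
  }
  new("GrowthModel", pGerm = pGerm, tEmergeMean = tEmergeMean,
      tEmergeSd = tEmergeSd, growthRate = growthRate,
      seedLengthMm = seedLengthMm, zeroConcThreshold = zeroConcThreshold)
}

setMethod("show", "GrowthModel", function(object) {
  cc <- c(0, 30, 60, 90, 120, 150)
  p <- vapply(cc, object@pGerm, numeric(1))
  cat(sprintf("GrowthModel: p_germ(%s) = %s; emergence N(%g, %g) h; seed %g mm\n",
              paste(cc, collapse = "/"), paste(format(p), collapse = "/"),
              object@tEmergeMean, object@tEmergeSd, object@seedLengthMm))
})

# truncated-normal draw on (lo, hi) via inverse CDF
.rtnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Simulate one tray of germinating seeds
#'
#' Each seed on the grid independently germinates with probability
#' `pGerm(conc)`. Germinating seeds draw a radicle-emergence time from the
#' model's normal distribution, truncated to times at which the L-root
#' standard (half the seed length) is still reachable before the end of the
#' experiment -- the germination probability is thus the probability of
#' germinating within the observation window. After emergence the root
#' elongates linearly at `growthRate(conc)` mm/h. A seed's class at time `t`
#' is `seed` before emergence, `S_root` while the root is shorter than half
#' the seed length, and `L_root` from then on. Rendering geometry (root
#' direction, chosen toward a cell corner with jitter) is drawn here so that
#' downstream rendering is deterministic. Fully reproducible given `seed`.
#'
#' @param config an [ExperimentConfig-class] (tray grid, duration).
#' @param model a [GrowthModel-class].
#' @param conc NaCl concentration of this tray (mmol/L).
#' @param seed RNG seed.
#' @param trayId tray identifier.
#' @return List with `trajectories` (data.frame: `seedId`, `row`, `col`,
#'   `germinates`, `tEmerge`, `rate`, `rootDir`, `orientJitter`), `conc`,
#'   `trayId`, and the closures `rootLengthAt(t)` / `classAt(t)` returning
#'   per-seed lengths (mm) and classes at time `t`.
#' @seealso [groundTruthTimeline()], [renderFrames()]
#' @export
simulateTray <- function(config, model, conc, seed, trayId = "tray1") {
  n <- config@gridRows * config@gridCols
  rate <- model@growthRate(conc)
  halfSeed <- model@seedLengthMm / 2
  set.seed(seed)
  p <- model@pGerm(conc)
  germinates <- stats::runif(n) < p
  # latest emergence that still reaches the L-root standard in-window
  tMax <- config@durationH - halfSeed / rate - 0.25
  if (tMax <= 1) germinates[] <- FALSE
  tEmerge <- rep(NA_real_, n)
  if (any(germinates))
    tEmerge[germinates] <- .rtnorm(sum(germinates), model@tEmergeMean,
                                   model@tEmergeSd, 1, tMax)
  grid <- expand.grid(row = seq_len(config@gridRows),
                      col = seq_len(config@gridCols))
  traj <- data.frame(
    seedId = seq_len(n), row = grid$row, col = grid$col,
    germinates = germinates, tEmerge = tEmerge, rate = rate,
    rootDir = (sample(0:3, n, replace = TRUE) * 90 + 45 +
               stats::runif(n, -15, 15)) * pi / 180,
    orientJitter = stats::runif(n, 0, pi))
  rootLengthAt <- function(t) {
    len <- ifelse(traj$germinates & t > traj$tEmerge,
                  (t - traj$tEmerge) * traj$rate, 0)
    ifelse(is.na(len), 0, len)
  }
  classAt <- function(t) {
    len <- rootLengthAt(t)
    ifelse(len <= 0, "seed", ifelse(len < halfSeed, "S_root", "L_root"))
  }
  list(trajectories = traj, conc = conc, trayId = trayId,
       seedLengthMm = model@seedLengthMm,
       rootLengthAt = rootLengthAt, classAt = classAt)
}

#' Ground-truth germination timeline of a simulated tray
#'
#' Evaluates the simulated trajectories at the given times, with true root
#' lengths (no detector, no rendering) -- the reference against which the
#' detector-derived timeline is compared.
#'
#' @param tray output of [simulateTray()].
#' @param times acquisition times in hours.
#' @return A [GerminationTimeline-class].
#' @export
groundTruthTimeline <- function(tray, times) {
  halfSeed <- tray$seedLengthMm / 2
  counts <- integer(length(times))
  lens <- vector("list", length(times))
  for (i in seq_along(times)) {
    l <- tray$rootLengthAt(times[i])
    isL <- l >= halfSeed
    counts[i] <- sum(isL)
    lens[[i]] <- l[isL]
  }
  counts <- as.integer(cummax(counts))
  new("GerminationTimeline", trayId = tray$trayId,
      concentration = tray$conc, times = as.numeric(times),
      nTotal = nrow(tray$trajectories), germinatedCounts = counts,
      newGerminations = as.integer(diff(c(0L, counts))), rootLengths = lens)
}
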