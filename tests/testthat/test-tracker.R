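test_that("assignment equals the brute-force permutation minimum (n <= 6)", {
  set.seed(33)
  for (i in 1:30) {
    n <- sample(2:6, 1)
    C <- matrix(runif(n * n, 0, 100), n, n)
    expect_equal(solveAssignment(C)$cost, bruteAssignmentCost(C))
  }
  # diag-dominant: identity matching
  C <- matrix(10, 3, 3); diag(C) <- 0
  expect_equal(solveAssignment(C)$assignment, 1:3)
})

test_that("rectangular assignment picks the cheapest columns", {
  set.seed(8)
  C <- matrix(runif(12), 3, 4)
  sol <- solveAssignment(C)
  # oracle: min over all ordered choices of 3 distinct columns
  combos <- expand.grid(1:4, 1:4, 1:4)
  combos <- combos[apply(combos, 1, function(r) length(unique(r)) == 3), ]
  best <- min(apply(combos, 1, function(r) sum(C[cbind(1:3, as.integer(r))])))
  expect_equal(sol$cost, best)
})

test_that("gating demotes distant pairs and handles empty inputs", {
  pred <- rbind(c(0, 0), c(100, 100))
  det <- rbind(c(1, 1), c(300, 300))
  asg <- assignDetections(pred, det, gate = 10)
  expect_equal(asg$matches, matrix(c(1L, 1L), 1, 2))
  expect_equal(asg$unmatchedTracks, 2L)
  expect_equal(asg$unmatchedDetections, 2L)
  none <- assignDetections(pred, matrix(numeric(), 0, 2), gate = 10)
  expect_equal(nrow(none$matches), 0)
  expect_equal(none$unmatchedTracks, 1:2)
})

test_that("track lifecycle: extension, deletion after maxAge, fresh IDs", {
  p <- trackParams(gate = 10, maxAge = 2)
  det <- function(r, c, f) data.frame(frame = f, row = r, col = c, area = 25)
  st <- trackStep(NULL, det(10, 10, 0), 0, p)
  expect_equal(length(st$tracks), 1)
  st <- trackStep(st, det(11, 10, 1), 1, p)
  expect_equal(st$tracks[[1]]$hits, 2L)
  none <- det(0, 0, 0)[0, ]
  for (f in 2:4) st <- trackStep(st, none, f, p)
  expect_equal(st$tracks[[1]]$status, "deleted")
  # a detection after deletion spawns a new, never-reused ID
  st <- trackStep(st, det(12, 10, 5), 5, p)
  ids <- vapply(st$tracks, function(t) t$id, 0L)
  expect_equal(ids, c(1L, 2L))
})

test_that("noise-free constant-velocity tracking predicts exactly", {
  p <- trackParams(gate = 20, Q = matrix(0, 4, 4), R = 1e-12 * diag(2),
                   P0 = diag(c(0, 0, 10, 10)))
  st <- NULL
  for (f in 0:10) {
    d <- data.frame(frame = f, row = 5 + 2 * f, col = 10 + 3 * f, area = 25)
    if (f >= 2) {
      # prediction before this update must already equal the detection
      k <- kalmanPredict(st$tracks[[1]]$kalman)
      expect_equal(kalmanPosition(k), c(5 + 2 * f, 10 + 3 * f),
                   tolerance = 1e-6)
    }
    st <- trackStep(st, d, f, p)
  }
  expect_equal(st$tracks[[1]]$hits, 11L)
})

test_that("a single synthetic swimmer yields exactly one full-length track", {
  cfg <- swimmerScene(speed = 20, seed = 41, frames = 90)
  sim <- simulateVideo(cfg)
  ts <- trackVideo(sim$frames, thresholdDetector(level = sceneLevel(cfg)),
                   trackParams(calibration = calibration(sim$frames)))
  expect_equal(length(ts), 1)
  sc <- scoreTracks(ts, sim$truth)
  expect_equal(sc$Ft, 90L)
  expect_equal(sc$Rt, 100)
})

test_that("tracking a seeded scene twice is deterministic", {
  cfg <- smallScene(seed = 13)
  run <- function() {
    sim <- simulateVideo(cfg)
    ts <- trackVideo(sim$frames, thresholdDetector(),
                     trackParams(calibration = calibration(sim$frames)))
    trackTable(ts)
  }
  expect_identical(run(), run())
})

test_that("IDs survive a close pass when paths stay a gate apart", {
  # two parallel swimmers separated by ~3x the gate at closest approach
  p <- trackParams(gate = 8, maxAge = 3)
  st <- NULL
  for (f in 0:30) {
    d <- data.frame(frame = f, row = c(40, 65), col = c(10 + 3 * f, 100 - 3 * f),
                    area = 25)
    st <- trackStep(st, d, f, p)
  }
  ids <- vapply(st$tracks, function(t) t$id, 0L)
  expect_equal(length(ids), 2)
  expect_true(all(vapply(st$tracks, function(t) t$hits, 0L) == 31L))
  # each track stays on its own row
  expect_equal(sort(vapply(st$tracks, function(t) t$rows[31], 0)), c(40, 65))
})

test_that("blank video produces no tracks", {
  set.seed(2)
  fr <- lapply(1:10, function(i) matrix(round(rnorm(32 * 32, 20, 2)), 32, 32))
  x <- FrameSequence(fr, Calibration(0.5, 30))
  ts <- trackVideo(x, thresholdDetector(level = 0.45),
                   trackParams(calibration = calibration(x)))
  expect_equal(length(ts), 0)
  expect_equal(nrow(trackTable(ts)), 0)
})

test_that("tracking rate and its summaries follow the Ft/Fw definition", {
  expect_equal(trackingRate(55, 90), 61.11)
  expect_equal(trackingRate(72, 72), 100)
  expect_equal(trackingRate(11, 62), 17.74)
  expect_error(trackingRate(5, 0), "Fw")
  expect_error(trackingRate(10, 5), "Ft")
  s <- summarizeTracking(100)
  expect_equal(s, list(meanRate = 100, frac100 = 100, fracBelow50 = 0))
  expect_error(summarizeTracking(numeric(0)), "empty")
})
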