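test_that("the same seed reproduces frames and truth bit for bit", {
  cfg <- smallScene(seed = 99)
  a <- simulateVideo(cfg)
  b <- simulateVideo(cfg)
  expect_identical(frames(a$frames), frames(b$frames))
  expect_identical(a$truth$positions, b$truth$positions)
  c <- simulateVideo(smallScene(seed = 100))
  expect_false(identical(frames(a$frames), frames(c$frames)))
})

test_that("zero objects give blank noisy frames and empty truth", {
  cfg <- sceneConfig(width = 64, height = 64, frames = 5, nProgressive = 0,
                     nNonprogressive = 0, nImmotile = 0, nDebris = 0,
                     seed = 1)
  sim <- simulateVideo(cfg)
  expect_equal(nrow(sim$truth$objects), 0)
  expect_equal(sim$truth$perFrameCount, rep(0L, 5))
  expect_true(all(abs(sim$frames[[1]] - cfg$bgIntensity) < 20))
})

test_that("objects larger than the frame are rejected", {
  expect_error(simulateVideo(sceneConfig(width = 10, height = 10,
                                         headLength = 20, seed = 1)),
               "larger than frame")
})

test_that("rendered object count matches truth on noise-free frames", {
  cfg <- smallScene(seed = 55, noiseSd = 0, frames = 10)
  sim <- simulateVideo(cfg)
  counts <- countFrames(sim$frames)
  expect_equal(counts$count, sim$truth$perFrameCount)
})

test_that("truth kinematics are exact for designed motion", {
  cfg <- swimmerScene(speed = 25, seed = 19)
  sim <- simulateVideo(cfg)
  tk <- sim$truth$kinematics
  expect_equal(tk$VCL, 25, tolerance = 1e-9)
  expect_equal(tk$VSL, 25, tolerance = 1e-9)
  expect_equal(tk$LIN, 100)
  # immotile: zero velocity, grade D
  cfgI <- sceneConfig(width = 96, height = 96, frames = 20,
                      nProgressive = 0, nNonprogressive = 0, nImmotile = 1,
                      nDebris = 0, seed = 2)
  tkI <- simulateVideo(cfgI)$truth$kinematics
  expect_equal(tkI$VCL, 0)
  expect_equal(tkI$GRADE, "D")
})

test_that("sampled zigzag truth VCL equals the closed-form polyline length", {
  cfg <- sceneConfig(width = 256, height = 256, frames = 31,
                     nProgressive = 1, nNonprogressive = 0, nImmotile = 0,
                     nDebris = 0, progressiveSpeed = c(20, 20),
                     zigzagAmplitude = 2, zigzagPeriod = 10, noiseSd = 0,
                     seed = 77)
  sim <- simulateVideo(cfg)
  # independent oracle: segment-sum over the generating equations
  t <- 0:30
  step <- 20 / cfg$fps                      # um per frame along the mean path
  lat <- 2 * sin(2 * pi * t / 10)           # lateral um
  seg <- sqrt(step^2 + diff(lat)^2)
  Lum <- sum(seg)
  T <- 30 / cfg$fps
  expect_equal(sim$truth$kinematics$VCL, Lum / T, tolerance = 1e-9)
  expect_lt(sim$truth$kinematics$VSL, sim$truth$kinematics$VCL)
})

test_that("debris stays below the impurity-area threshold", {
  cfg <- smallScene(seed = 3, noiseSd = 0)
  sim <- simulateVideo(cfg)
  cal <- calibration(sim$frames)
  # without opening, the default area threshold alone removes 1-px debris
  res <- countSperm(sim$frames[[1]], openRadius = 0, calibration = cal)
  expect_equal(res$count, sim$truth$perFrameCount[1])
  # with neither opening nor area filter, debris is counted
  withDebris <- countSperm(sim$frames[[1]], openRadius = 0, minArea = 0,
                           calibration = cal)
  expect_gte(withDebris$count, res$count + 1)
})
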