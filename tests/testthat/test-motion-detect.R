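test_that("initialization puts all weight on the first component", {
  f <- matrix(50, 8, 8)
  m <- initBackground(f, gmmParams(K = 3))
  expect_true(all(m@w[, 1] == 1))
  expect_true(all(m@w[, 2:3] == 0))
  expect_true(all(m@mu[, 1] == 50))
  expect_error(initBackground(f, list(K = 0)), "K")
  two <- matrix(c(10, 200), 4, 4)
  m2 <- initBackground(two, gmmParams())
  expect_equal(m2@mu[, 1], as.vector(two))
})

test_that("weights stay normalized and variances respect the floor", {
  set.seed(3)
  p <- gmmParams()
  m <- initBackground(matrix(runif(64, 0, 255), 8, 8), p)
  for (i in 1:30) {
    up <- updateBackground(m, matrix(runif(64, 0, 255), 8, 8))
    m <- up$model
    expect_true(all(abs(rowSums(m@w) - 1) < 1e-9))
    expect_true(all(m@v >= p$varMin - 1e-12))
  }
})

test_that("a static scene converges to all-background", {
  f <- matrix(50, 16, 16)
  m <- initBackground(f, gmmParams())
  frac <- NA
  for (i in 1:50) {
    up <- updateBackground(m, f)
    m <- up$model
    frac <- mean(up$mask)
  }
  expect_equal(frac, 0)
})

test_that("a sudden global change is classified all-foreground", {
  f <- matrix(50, 12, 12)
  m <- initBackground(f, gmmParams())
  for (i in 1:100) m <- updateBackground(m, f)$model
  up <- updateBackground(m, matrix(200, 12, 12))
  expect_equal(mean(up$mask), 1)
  expect_error(updateBackground(m, matrix(0, 5, 5)), "shape mismatch")
})

test_that("a moving blob is covered by the foreground mask after burn-in", {
  cfg <- sceneConfig(width = 96, height = 96, frames = 25, nProgressive = 1,
                     nNonprogressive = 0, nImmotile = 0, nDebris = 0,
                     progressiveSpeed = c(40, 40), noiseSd = 0, seed = 9)
  sim <- simulateVideo(cfg)
  dm <- detectMotion(sim$frames)
  # after burn-in the blob must be detected near its true position
  for (t in 15:25) {
    det <- dm$detections[dm$detections$frame == t - 1, ]
    truth <- sim$truth$positions[[1]][t, ]
    d <- sqrt((det$row - truth$row)^2 + (det$col - truth$col)^2)
    expect_true(any(d < 4))
  }
})

test_that("centroids are pixel-coordinate means, 0-based, (row, col) sorted", {
  m <- matrix(0, 30, 40)
  m[11:15, 21:25] <- 1
  det <- extractDetections(m, 3L, 1)
  expect_equal(det$row, 12)
  expect_equal(det$col, 22)
  expect_equal(det$area, 25L)
  expect_equal(det$frame, 3L)
  m[25:26, 2:3] <- 1
  det2 <- extractDetections(m, 0L, 1)
  expect_equal(nrow(det2), 2)
  expect_true(det2$row[1] < det2$row[2])
  expect_equal(nrow(extractDetections(matrix(0, 5, 5), 0L, 1)), 0)
})
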