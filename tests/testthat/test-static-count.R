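test_that("Otsu returns the plateau midpoint on a two-level image", {
  img <- matrix(c(rep(0, 50), rep(255, 50)), 10, 10)
  expect_equal(otsuThreshold(img), 127 / 255)
})

test_that("Otsu matches the exhaustive-search oracle on random images", {
  set.seed(101)
  for (i in 1:100) {
    img <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32)
    expect_equal(otsuThreshold(img), otsuOracle(img))
  }
})

test_that("constant images give a degenerate-histogram error", {
  expect_error(otsuThreshold(matrix(7, 5, 5)), "degenerate histogram")
})

test_that("binarize follows the bright-object > level*255 rule", {
  expect_equal(sum(binarize(matrix(0, 4, 4), 0.5)), 0)
  cb <- matrix(c(0, 255), 4, 4)
  expect_equal(binarize(cb, 0.5), (cb == 255) + 0)
  ramp <- matrix(0:255, 1, 256)
  m <- binarize(ramp, 0.6235)     # threshold 158.99: values >= 159 set
  expect_equal(which(m == 1), 160:256)
})

test_that("hole filling and opening behave as constructed", {
  sq <- matrix(0, 12, 12); sq[3:9, 3:9] <- 1; sq[6, 6] <- 0
  expect_equal(fillHoles(sq)[6, 6], 1)
  # two 9x9 squares joined by a 1-px bridge: opening with radius 1 splits
  m <- matrix(0, 15, 25)
  m[4:12, 3:11] <- 1; m[4:12, 15:23] <- 1; m[8, 12:14] <- 1
  opened <- morphOpen(m, 1)
  expect_equal(max(labelComponents(opened)), 2)
  expect_equal(morphOpen(matrix(0, 8, 8), 1), matrix(0, 8, 8))
})

test_that("labelComponents joins diagonal neighbours (8-connectivity)", {
  m <- matrix(0, 6, 6)
  m[2, 2] <- 1; m[3, 3] <- 1; m[4, 2] <- 1    # zigzag diagonal chain
  m[6, 6] <- 1
  L <- labelComponents(m)
  expect_equal(max(L), 2)
  expect_equal(L[2, 2], L[3, 3])
  expect_equal(L[3, 3], L[4, 2])
})

test_that("removeSmall filters by area with identity edge cases", {
  m <- matrix(0, 40, 40)
  m[2:21, 2:11] <- 1          # 200 px
  m[30:35, 30:34] <- 1        # 30 px
  out <- removeSmall(m, 70)
  expect_equal(sum(out), 200)
  expect_equal(removeSmall(m, 0), m)
  expect_equal(sum(removeSmall(m, 1000)), 0)
})

test_that("counting matches ground truth and is monotone in minArea", {
  cfg <- smallScene(seed = 31, nDebris = 3)
  sim <- simulateVideo(cfg)
  cal <- calibration(sim$frames)
  res <- countSperm(sim$frames[[1]], calibration = cal)
  expect_equal(res$count, sim$truth$perFrameCount[1])
  expect_equal(res$count, nrow(res$detections))
  # debris pixels are present but below the area threshold
  expect_gt(cfg$nDebris, 0)
  counts <- vapply(c(0, 2, 50, 200, 1e5), function(a)
    countSperm(sim$frames[[1]], minArea = a, calibration = cal)$count, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("a blank noisy frame counts zero objects", {
  set.seed(5)
  blank <- matrix(pmax(0, round(rnorm(64 * 64, 30, 3))), 64, 64)
  res <- countSperm(blank, level = 0.45, calibration = Calibration(0.5, 30))
  expect_equal(res$count, 0)
})
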