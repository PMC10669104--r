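test_that("curvilinear length sums segments", {
  line <- cbind(0:10, 0)
  expect_equal(curvilinearLength(line), 10)
  zig <- apply(rbind(c(0, 0),
                     matrix(rep(c(1, 1, 1, -1), 5), ncol = 2, byrow = TRUE)),
               2, cumsum)
  expect_equal(curvilinearLength(zig), 10 * sqrt(2))
  expect_equal(curvilinearLength(rbind(c(2, 2), c(2, 2))), 0)
})

test_that("average path: identity at window 1, fixed point on lines", {
  zig <- cbind(0:9, rep(c(0, 1), 5))
  expect_equal(averagePath(zig, 1), zig)
  line <- cbind(0:9, 2 * (0:9))
  expect_equal(averagePath(line, 5), line)
  # window-5 moving average, hand-evaluated on the zigzag
  sm <- averagePath(zig, 5)
  expect_equal(sm[1, ], zig[1, ])                       # shrunk to width 1
  expect_equal(sm[2, ], colMeans(zig[1:3, ]))           # width 3
  expect_equal(sm[5, ], colMeans(zig[3:7, ]))           # full width 5
  expect_error(averagePath(zig, 4), "window")
})

test_that("kinematics of straight and zigzag trajectories", {
  straight <- cbind(0:10, 0)                  # 1 um/frame at 1 fps
  k <- computeKinematics(straight, fps = 1, window = 1)
  expect_equal(k$VCL, 1); expect_equal(k$VSL, 1); expect_equal(k$VAP, 1)
  expect_equal(k$LIN, 100); expect_equal(k$STR, 100); expect_equal(k$WOB, 100)
  zig <- apply(rbind(c(0, 0),
                     matrix(rep(c(1, 1, 1, -1), 5), ncol = 2, byrow = TRUE)),
               2, cumsum)
  kz <- computeKinematics(zig, fps = 1, window = 1)
  expect_equal(kz$VSL, 1)
  expect_equal(kz$VCL, sqrt(2))
  expect_equal(kz$LIN, 70.71)
  expect_error(computeKinematics(cbind(1, 1), 30), "2 points")
})

test_that("ratio descriptors reproduce a self-consistent published record", {
  r <- kinematicRatios(13.63, 6.02, 8.63)
  expect_equal(r$LIN, 44.17)
  expect_equal(r$STR, 69.76)
  expect_equal(r$WOB, 63.32)
})

test_that("velocity grade rule and edge values", {
  expect_equal(gradeMotility(27.42), "B")
  expect_equal(gradeMotility(5.86), "D")
  expect_equal(gradeMotility(0), "D")
  expect_equal(gradeMotility(c(50, 49.99, 25, 6, 5.999)),
               c("A", "B", "B", "C", "D"))
  expect_equal(gradeMotility(30, c(A = 35, B = 20, C = 5)), "B")
})

test_that("kinematic invariants hold on simulated cohorts", {
  cfg <- smallScene(seed = 17, frames = 40)
  sim <- simulateVideo(cfg)
  ts <- trackVideo(sim$frames, thresholdDetector(),
                   trackParams(calibration = calibration(sim$frames)))
  rec <- analyzeTracks(ts)
  ok <- rec[rec$status == "ok", ]
  expect_gt(nrow(ok), 0)
  expect_true(all(ok$VSL <= ok$VCL + 1e-9))
  expect_true(all(ok$VAP <= ok$VCL + 1e-9))
  expect_true(all(abs(ok$LIN - ok$STR * ok$WOB / 100) < 0.05, na.rm = TRUE))
  # window = 1 makes VAP equal VCL exactly
  rec1 <- analyzeTracks(ts, window = 1)
  ok1 <- rec1[rec1$status == "ok", ]
  expect_equal(ok1$VAP, ok1$VCL)
})

test_that("short tracks are flagged insufficient", {
  tab <- data.frame(track_id = 1, frame = 0:5, row = 0:5, col = 0)
  rec <- analyzeTracks(tab, Calibration(1, 1), minFrames = 15)
  expect_equal(rec$status, "insufficient")
  expect_true(is.na(rec$VCL))
})

test_that("cohort summary counts grades and normalizes percentages", {
  rec <- data.frame(VCL = c(30, 3), VSL = c(10, 1), VAP = c(15, 2),
                    LIN = c(33, 33), STR = c(66, 50), WOB = c(50, 66),
                    GRADE = c("B", "D"))
  s <- summarizeCohort(rec)
  expect_equal(s$counts, c(A = 0L, B = 1L, C = 0L, D = 1L))
  expect_equal(unname(s$percentages), c(0, 50, 0, 50))
  expect_equal(sum(s$percentages), 100)
  one <- summarizeCohort(data.frame(VCL = 1, VSL = 1, VAP = 1, LIN = 100,
                                    STR = 100, WOB = 100, GRADE = "D"))
  expect_equal(unname(one$percentages["D" == names(one$percentages)]), 100)
  expect_error(summarizeCohort(rec[0, ]), "empty cohort")
})
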