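#' Tracking parameters
#'
#' @param gate maximum association distance in px; default 50 px at the
#'   0.074 um/px reference pitch, rescaled linearly by calibration.
#' @param maxAge consecutive unmatched frames before a track is deleted.
#' @param minHits minimum matched frames before a track is reported.
#' @param Q,R,P0 Kalman covariances, see [kalmanInit()].
#' @param calibration a [Calibration-class] used for the default gate.
#' @return parameter list.
#' @export
trackParams <- function(gate = NULL, maxAge = 5, minHits = 1,
                        Q = 0.01 * diag(4), R = diag(2),
                        P0 = diag(c(1, 1, 10, 10)),
                        calibration = Calibration()) {
  if (is.null(gate)) gate <- scaleDistance(50, umPerPx(calibration))
  stopifnot(gate > 0, maxAge >= 0, minHits >= 1)
  list(gate = gate, maxAge = maxAge, minHits = minHits, Q = Q, R = R, P0 = P0)
}

#' Gated nearest-assignment of detections to predicted track positions
#'
#' Minimum-total-Euclidean-cost one-to-one assignment via the Hungarian
#' algorithm; any matched pair farther apart than `gate` is demoted to
#' unmatched.
#'
#' @param predicted matrix/data.frame of predicted (row, col), one row per
#'   track.
#' @param detected matrix/data.frame of detected (row, col).
#' @param gate gating distance in px (> 0).
#' @return list `matches` (two-column matrix: track index, detection index),
#'   `unmatchedTracks`, `unmatchedDetections` (integer indices).
#' @export
assignDetections <- function(predicted, detected, gate) {
  stopifnot(gate > 0)
  predicted <- as.matrix(predicted); detected <- as.matrix(detected)
  nt <- nrow(predicted); nd <- nrow(detected)
  if (nt == 0 || nd == 0) {
    return(list(matches = matrix(integer(), 0, 2),
                unmatchedTracks = seq_len(nt),
                unmatchedDetections = seq_len(nd)))
  }
  cost <- outer(seq_len(nt), seq_len(nd), function(i, j) {
    sqrt((predicted[i, 1] - detected[j, 1])^2 +
         (predicted[i, 2] - detected[j, 2])^2)
  })
  sol <- solveAssignment(cost)
  matches <- matrix(integer(), 0, 2)
  for (i in seq_len(nt)) {
    j <- sol$assignment[i]
    if (!is.na(j) && cost[i, j] <= gate)
      matches <- rbind(matches, c(i, j))
  }
  list(matches = matches,
       unmatchedTracks = setdiff(seq_len(nt), matches[, 1]),
       unmatchedDetections = setdiff(seq_len(nd), matches[, 2]))
}

newTrack <- function(id, frameIndex, row, col, area, params) {
  list(id = id,
       kalman = kalmanInit(c(row, col), P0 = params$P0,
                           Q = params$Q, R = params$R),
       frames = frameIndex, rows = row, cols = col, areas = area,
       appear = frameIndex, lastSeen = frameIndex,
       misses = 0L, hits = 1L, status = "active")
}

#' One tracking step: predict, associate, update lifecycle
#'
#' Active tracks are Kalman-predicted; detections of the current frame are
#' associated by gated Hungarian assignment. Matched tracks are
#' Kalman-updated and their centroid history extended; unmatched tracks keep
#' the prediction, accumulate a miss, and are deleted after more than
#' `maxAge` consecutive misses; unmatched detections spawn new tracks with
#' fresh, monotonically increasing IDs.
#'
#' @param state tracker state list (`tracks`, `nextId`) or `NULL` to start.
#' @param detections data.frame from [extractDetections()] for one frame.
#' @param frameIndex 0-based frame index of the detections.
#' @param params list from [trackParams()].
#' @return updated tracker state.
#' @export
trackStep <- function(state, detections, frameIndex, params = trackParams()) {
  if (is.null(state)) state <- list(tracks = list(), nextId = 1L)
  tracks <- state$tracks
  activeIdx <- which(vapply(tracks, function(t) t$status == "active", TRUE))

  for (i in activeIdx) tracks[[i]]$kalman <- kalmanPredict(tracks[[i]]$kalman)
  predicted <- do.call(rbind, lapply(activeIdx, function(i)
    kalmanPosition(tracks[[i]]$kalman)))
  if (is.null(predicted)) predicted <- matrix(numeric(), 0, 2)
  detMat <- if (nrow(detections)) cbind(detections$row, detections$col)
            else matrix(numeric(), 0, 2)

  asg <- assignDetections(predicted, detMat, params$gate)

  if (nrow(asg$matches)) for (m in seq_len(nrow(asg$matches))) {
    i <- activeIdx[asg$matches[m, 1]]
    j <- asg$matches[m, 2]
    z <- c(detections$row[j], detections$col[j])
    tracks[[i]]$kalman <- kalmanUpdate(tracks[[i]]$kalman, z)
    tracks[[i]]$frames <- c(tracks[[i]]$frames, frameIndex)
    tracks[[i]]$rows <- c(tracks[[i]]$rows, z[1])
    tracks[[i]]$cols <- c(tracks[[i]]$cols, z[2])
    tracks[[i]]$areas <- c(tracks[[i]]$areas, detections$area[j])
    tracks[[i]]$lastSeen <- frameIndex
    tracks[[i]]$misses <- 0L
    tracks[[i]]$hits <- tracks[[i]]$hits + 1L
  }
  for (k in asg$unmatchedTracks) {
    i <- activeIdx[k]
    tracks[[i]]$misses <- tracks[[i]]$misses + 1L
    if (tracks[[i]]$misses > params$maxAge) tracks[[i]]$status <- "deleted"
  }
  for (j in asg$unmatchedDetections) {
    tracks[[length(tracks) + 1]] <-
      newTrack(state$nextId, frameIndex, detections$row[j],
               detections$col[j], detections$area[j], params)
    state$nextId <- state$nextId + 1L
  }
  state$tracks <- tracks
  state
}

#' Set of sperm tracks from one video
#'
#' @slot tracks list of per-track records (id, centroid history, lifecycle).
#' @slot table data.frame of all observed centroids: `track_id`, `frame`
#'   (0-based), `row`, `col` (0-based px), `area`.
#' @slot params tracking parameters used.
#' @slot calibration the recording's [Calibration-class].
#' @name TrackSet-class
#' @aliases TrackSet-class
#' @exportClass TrackSet
setClass("TrackSet",
         representation(tracks = "list", table = "data.frame",
                        params = "list", calibration = "Calibration"))

setMethod("show", "TrackSet", function(object) {
  cat(sprintf("TrackSet: %d track(s), %d observation(s)\n",
              length(object@tracks), nrow(object@table)))
})

#' @describeIn TrackSet centroid table (track_id, frame, row, col, area).
#' @param x a TrackSet.
#' @export
trackTable <- function(x) x@table

#' @describeIn TrackSet IDs of reported tracks.
#' @export
trackIds <- function(x) vapply(x@tracks, function(t) t$id, 0L)

#' @export
setMethod("length", "TrackSet", function(x) length(x@tracks))

#' Intensity-threshold detector
#'
#' Per-frame static detection via the counting chain ([countSperm()]):
#' detects moving and stationary objects alike from frame 0. `level = NULL`
#' runs Otsu on every frame.
#'
#' @param level fixed normalized threshold or `NULL` for per-frame Otsu.
#' @param openRadius,minArea see [countSperm()].
#' @return a detector `function(frame, frameIndex, calibration)` returning a
#'   detection data.frame.
#' @export
thresholdDetector <- function(level = NULL, openRadius = 1, minArea = NULL) {
  function(frame, frameIndex, calibration) {
    res <- tryCatch(
      countSperm(frame, level = level, openRadius = openRadius,
                 minArea = minArea, calibration = calibration),
      error = function(e) {
        if (grepl("degenerate histogram", conditionMessage(e)))
          return(NULL)                   # constant frame: nothing to detect
        stop(e)
      })
    if (is.null(res))
      return(extractDetections(matrix(0, nrow(frame), ncol(frame)),
                               frameIndex, 1))
    det <- res$detections
    if (nrow(det)) det$frame <- frameIndex
    det
  }
}

#' Gaussian-mixture motion detector
#'
#' Stateful detector around [initBackground()] / [updateBackground()]: frame
#' 0 initializes the model (no detections); later frames return centroids of
#' foreground blobs. Moving sperm only; stationary cells are absorbed into
#' the background.
#'
#' @param params list from [gmmParams()].
#' @param minBlobArea minimum foreground blob area (px); default 40 px at
#'   the reference pitch, rescaled by calibration.
#' @return a stateful detector function (same signature as
#'   [thresholdDetector()]).
#' @export
gmmDetector <- function(params = gmmParams(), minBlobArea = NULL) {
  model <- NULL
  function(frame, frameIndex, calibration) {
    if (is.null(minBlobArea))
      minBlobArea <<- scaleArea(40, umPerPx(calibration))
    if (is.null(model)) {
      model <<- initBackground(frame, params)
      return(extractDetections(matrix(0, nrow(frame), ncol(frame)),
                               frameIndex, minBlobArea))
    }
    up <- updateBackground(model, frame)
    model <<- up$model
    extractDetections(removeSmall(up$mask, minBlobArea),
                      frameIndex, minBlobArea)
  }
}

#' Track all sperm through a video
#'
#' Full orbit of detection plus per-frame [trackStep()] over every frame.
#' Tracks with fewer than `minHits` observations are dropped from the
#' result.
#'
#' @param x a [FrameSequence-class].
#' @param detector a detector function (see [thresholdDetector()],
#'   [gmmDetector()]) or a precomputed detection data.frame with a `frame`
#'   column.
#' @param params list from [trackParams()].
#' @return a [TrackSet-class].
#' @export
trackVideo <- function(x, detector = gmmDetector(),
                       params = trackParams(calibration = calibration(x))) {
  cal <- calibration(x)
  state <- NULL
  for (i in seq_len(nframes(x))) {
    fi <- i - 1L
    det <- if (is.function(detector)) {
      detector(x[[i]], fi, cal)
    } else {
      detector[detector$frame == fi, , drop = FALSE]
    }
    state <- trackStep(state, det, fi, params)
  }
  tracks <- state$tracks %||% list()
  tracks <- Filter(function(t) t$hits >= params$minHits, tracks)
  tab <- do.call(rbind, lapply(tracks, function(t)
    data.frame(track_id = t$id, frame = t$frames, row = t$rows,
               col = t$cols, area = t$areas)))
  if (is.null(tab))
    tab <- data.frame(track_id = integer(), frame = integer(),
                      row = numeric(), col = numeric(), area = numeric())
  new("TrackSet", tracks = tracks, table = tab, params = params,
      calibration = cal)
}

#' Tracking rate of one identity
#'
#' Rt = 100 * Ft / Fw (%), where Ft is the number of frames the identity was
#' tracked and Fw the number of frames the object is present. Reported with
#' two decimals (half-up).
#'
#' @param Ft frames tracked (0 <= Ft <= Fw).
#' @param Fw frames present (> 0).
#' @return tracking rate in percent.
#' @export
#' @examples
#' trackingRate(55, 90)  # 61.11
trackingRate <- function(Ft, Fw) {
  if (any(Fw <= 0)) stop("Fw must be positive")
  if (any(Ft < 0 | Ft > Fw)) stop("Ft must satisfy 0 <= Ft <= Fw")
  roundHalfUp(100 * Ft / Fw, 2)
}

#' Summarize a set of tracking rates
#'
#' @param rt numeric vector of tracking rates in percent.
#' @return list: `meanRate` (arithmetic mean, %), `frac100` (% of scores
#'   equal to 100), `fracBelow50` (% of scores below 50).
#' @export
summarizeTracking <- function(rt) {
  if (length(rt) == 0) stop("empty list of tracking scores")
  list(meanRate = roundHalfUp(mean(rt), 2),
       frac100 = roundHalfUp(100 * mean(rt == 100), 2),
       fracBelow50 = roundHalfUp(100 * mean(rt < 50), 2))
}

#' Score tracks against ground truth
#'
#' For each true object, Ft is the largest number of presence frames in
#' which a single track reports a centroid within `tol` px of the true
#' position; Fw is the number of presence frames. Identity switches
#' therefore cap Ft at the longest correctly-identified segment.
#'
#' @param trackset a [TrackSet-class].
#' @param truth a `GroundTruth` from [simulateVideo()].
#' @param tol matching radius in px.
#' @return data.frame: `object`, `class`, `Ft`, `Fw`, `Rt`, `n_tracks`
#'   (tracks that ever matched the object).
#' @export
scoreTracks <- function(trackset, truth, tol = 5) {
  tab <- trackTable(trackset)
  out <- lapply(seq_along(truth$objects$id), function(k) {
    pos <- truth$positions[[k]]          # frame, row, col (px), present
    pos <- pos[pos$present, , drop = FALSE]
    Fw <- nrow(pos)
    perTrack <- integer(0)
    if (Fw > 0 && nrow(tab) > 0) {
      m <- merge(pos, tab, by = "frame", suffixes = c("_true", ""))
      if (nrow(m)) {
        d <- sqrt((m$row_true - m$row)^2 + (m$col_true - m$col)^2)
        hit <- m[d <= tol, , drop = FALSE]
        if (nrow(hit)) {
          # count each frame once per track
          perTrack <- tapply(hit$frame, hit$track_id,
                             function(f) length(unique(f)))
        }
      }
    }
    Ft <- if (length(perTrack)) max(perTrack) else 0L
    data.frame(object = truth$objects$id[k], class = truth$objects$class[k],
               Ft = as.integer(Ft), Fw = Fw,
               Rt = if (Fw > 0) trackingRate(Ft, Fw) else NA_real_,
               n_tracks = length(perTrack))
  })
  do.call(rbind, out)
}
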