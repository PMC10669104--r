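#' Synthetic scene configuration
#'
#' Describes a seeded brightfield-like synthetic video: bright sperm-shaped
#' ellipses over a noisy dark background, in three motility classes plus
#' sub-threshold debris. Progressive objects follow a straight mean path
#' with a sinusoidal lateral oscillation (the forward zigzag seen in real
#' trajectories); non-progressive objects jitter around a fixed anchor;
#' immotile objects are static; debris is rendered as single bright pixels
#' below the impurity-area threshold.
#'
#' Desk-scale defaults: 512 x 512 px at 0.5 um/px, 30 fps, 90 frames (3 s),
#' 16 sperm + 5 debris. Head size 8 x 4 um. Object placement is random but
#' rejection-sampled so that same-frame path separations stay above
#' `minSeparation` where possible; `placement = "lanes"` instead lays
#' objects on parallel lanes with a common travel direction, guaranteeing
#' separation for identity-tracking benchmarks.
#'
#' @param width,height frame size in px.
#' @param umPerPx,fpsVal calibration (0.5 um/px, 30 fps defaults).
#' @param frames number of frames.
#' @param nProgressive,nNonprogressive,nImmotile,nDebris object counts.
#' @param progressiveSpeed range of progressive mean-path speeds, um/s.
#' @param nonprogressiveSpeed range of jitter speeds, um/s.
#' @param zigzagAmplitude lateral oscillation amplitude, um.
#' @param zigzagPeriod oscillation period, frames.
#' @param headLength,headWidth ellipse axes (full lengths), um.
#' @param bgIntensity,objIntensity background / object gray levels (0-255).
#' @param noiseSd additive Gaussian noise sd in gray levels (default 3).
#' @param minSeparation target minimum same-frame separation, um.
#' @param placement `"random"` or `"lanes"`.
#' @param seed RNG seed; fixes all randomness of the scene.
#' @return a list of class `SceneConfig`.
#' @export
sceneConfig <- function(width = 512, height = 512, umPerPx = 0.5,
                        fpsVal = 30, frames = 90,
                        nProgressive = 8, nNonprogressive = 4,
                        nImmotile = 4, nDebris = 5,
                        progressiveSpeed = c(20, 45),
                        nonprogressiveSpeed = c(2, 5),
                        zigzagAmplitude = 1.5, zigzagPeriod = 8,
                        headLength = 8, headWidth = 4,
                        bgIntensity = 30, objIntensity = 200,
                        noiseSd = 3, minSeparation = 25,
                        placement = c("random", "lanes"), seed = 1) {
  placement <- match.arg(placement)
  stopifnot(width > 0, height > 0, frames >= 2,
            nProgressive >= 0, nNonprogressive >= 0, nImmotile >= 0,
            nDebris >= 0, all(progressiveSpeed >= 0),
            all(nonprogressiveSpeed >= 0), zigzagAmplitude >= 0,
            zigzagPeriod >= 2, headLength > 0, headWidth > 0, noiseSd >= 0)
  cfg <- list(width = width, height = height, umPerPx = umPerPx,
              fps = fpsVal, frames = frames,
              nProgressive = nProgressive,
              nNonprogressive = nNonprogressive,
              nImmotile = nImmotile, nDebris = nDebris,
              progressiveSpeed = progressiveSpeed,
              nonprogressiveSpeed = nonprogressiveSpeed,
              zigzagAmplitude = zigzagAmplitude,
              zigzagPeriod = zigzagPeriod,
              headLength = headLength, headWidth = headWidth,
              bgIntensity = bgIntensity, objIntensity = objIntensity,
              noiseSd = noiseSd, minSeparation = minSeparation,
              placement = placement, seed = seed)
  class(cfg) <- "SceneConfig"
  cfg
}

#' Well-separated benchmark scene
#'
#' Lane placement with moderate speeds: objects travel on parallel lanes
#' that stay far apart for the whole clip, so every identity is trackable
#' end to end.
#'
#' @param seed RNG seed.
#' @param ... overrides passed to [sceneConfig()].
#' @return a `SceneConfig`.
#' @export
wellSeparatedScene <- function(seed = 1, ...) {
  sceneConfig(nProgressive = 6, nNonprogressive = 2, nImmotile = 2,
              nDebris = 3, progressiveSpeed = c(10, 22),
              placement = "lanes", seed = seed, ...)
}

#' Crowded, noisier benchmark scene
#'
#' Random placement with a small separation target and doubled image noise:
#' paths cross, objects merge transiently, and identity switches occur.
#'
#' @param seed RNG seed.
#' @param ... overrides passed to [sceneConfig()].
#' @return a `SceneConfig`.
#' @export
crowdedScene <- function(seed = 1, ...) {
  sceneConfig(nProgressive = 12, nNonprogressive = 4, nImmotile = 2,
              nDebris = 5, noiseSd = 6, minSeparation = 10,
              placement = "random", seed = seed, ...)
}

# positions of one object for all frames, in px (0-based); returns a
# frames x 2 matrix (row, col)
objectPath <- function(class, start, angle, speedUmS, cfg) {
  t <- seq_len(cfg$frames) - 1
  u <- c(sin(angle), cos(angle))          # unit direction in (row, col)
  nrm <- c(cos(angle), -sin(angle))       # lateral unit
  if (class == "progressive") {
    stepPx <- speedUmS / cfg$fps / cfg$umPerPx
    aPx <- cfg$zigzagAmplitude / cfg$umPerPx
    lat <- aPx * sin(2 * pi * t / cfg$zigzagPeriod)
    cbind(start[1] + stepPx * t * u[1] + lat * nrm[1],
          start[2] + stepPx * t * u[2] + lat * nrm[2])
  } else if (class == "nonprogressive") {
    stepPx <- speedUmS / cfg$fps / cfg$umPerPx
    ang <- stats::runif(cfg$frames - 1, 0, 2 * pi)
    dr <- c(0, cumsum(stepPx * sin(ang)))
    dc <- c(0, cumsum(stepPx * cos(ang)))
    # soft-tether the walk so it stays near its anchor
    cbind(start[1] + dr - seq_along(dr) / length(dr) * dr[length(dr)],
          start[2] + dc - seq_along(dc) / length(dc) * dc[length(dc)])
  } else {
    cbind(rep(start[1], cfg$frames), rep(start[2], cfg$frames))
  }
}

# minimum same-frame distance between two path matrices
pathSeparation <- function(p1, p2) {
  min(sqrt((p1[, 1] - p2[, 1])^2 + (p1[, 2] - p2[, 2])^2))
}

#' Simulate a synthetic sperm video with ground truth
#'
#' Renders anti-aliased bright ellipses (oriented along the instantaneous
#' motion direction) over a uniform background, adds seeded Gaussian noise,
#' and records the exact object state: per-frame true centroids (px and um),
#' presence flags (fully inside the frame), per-frame object counts and
#' per-object kinematics derived from the true centroids with the motility
#' module itself. The same seed always produces bit-identical frames and
#' truth.
#'
#' @param cfg a `SceneConfig` from [sceneConfig()].
#' @return list with `frames` (a [FrameSequence-class]) and `truth`: a list
#'   of class `GroundTruth` with `objects` (data.frame id/class/speed),
#'   `positions` (list of per-frame data.frames: frame, row, col, row_um,
#'   col_um, present), `perFrameCount`, `debris` (data.frame), and
#'   `kinematics` (from [truthKinematics()]).
#' @export
simulateVideo <- function(cfg) {
  stopifnot(inherits(cfg, "SceneConfig"))
  aPx <- cfg$headLength / 2 / cfg$umPerPx     # semi-major, px
  bPx <- cfg$headWidth / 2 / cfg$umPerPx      # semi-minor, px
  if (2 * aPx >= min(cfg$width, cfg$height))
    stop("objects requested larger than frame")
  withSeed(cfg$seed, {
    classes <- c(rep("progressive", cfg$nProgressive),
                 rep("nonprogressive", cfg$nNonprogressive),
                 rep("immotile", cfg$nImmotile))
    nObj <- length(classes)
    speeds <- numeric(nObj)
    paths <- vector("list", nObj)
    margin <- aPx + 2
    minSepPx <- cfg$minSeparation / cfg$umPerPx

    if (cfg$placement == "lanes" && nObj > 0) {
      laneRows <- (seq_len(nObj)) * cfg$height / (nObj + 1)
      order <- sample(nObj)               # shuffle classes across lanes
      classes <- classes[order]
      for (k in seq_len(nObj)) {
        cls <- classes[k]
        speeds[k] <- switch(cls,
          progressive = stats::runif(1, cfg$progressiveSpeed[1],
                                     cfg$progressiveSpeed[2]),
          nonprogressive = stats::runif(1, cfg$nonprogressiveSpeed[1],
                                        cfg$nonprogressiveSpeed[2]),
          immotile = 0)
        travelPx <- speeds[k] / cfg$fps * (cfg$frames - 1) / cfg$umPerPx
        start <- c(laneRows[k], margin + 5)
        paths[[k]] <- objectPath(cls, start, 0, speeds[k], cfg)
        if (travelPx + start[2] > cfg$width - margin) {
          # lane too short at this speed: slow the object down to fit
          speeds[k] <- (cfg$width - margin - start[2]) * cfg$umPerPx *
            cfg$fps / (cfg$frames - 1)
          paths[[k]] <- objectPath(cls, start, 0, speeds[k], cfg)
        }
      }
    } else if (nObj > 0) {
      for (k in seq_len(nObj)) {
        cls <- classes[k]
        speeds[k] <- switch(cls,
          progressive = stats::runif(1, cfg$progressiveSpeed[1],
                                     cfg$progressiveSpeed[2]),
          nonprogressive = stats::runif(1, cfg$nonprogressiveSpeed[1],
                                        cfg$nonprogressiveSpeed[2]),
          immotile = 0)
        best <- NULL
        bestSep <- -Inf
        for (try in 1:60) {
          start <- c(stats::runif(1, margin, cfg$height - margin),
                     stats::runif(1, margin, cfg$width - margin))
          angle <- stats::runif(1, 0, 2 * pi)
          p <- objectPath(cls, start, angle, speeds[k], cfg)
          inside <- all(p[, 1] >= margin & p[, 1] <= cfg$height - margin &
                        p[, 2] >= margin & p[, 2] <= cfg$width - margin)
          sep <- if (k == 1) 1e8 else
            min(vapply(paths[seq_len(k - 1)], pathSeparation, 0, p1 = p),
                1e8)
          score <- sep + if (inside) 0 else -1e9
          if (score > bestSep) { bestSep <- score; best <- p }
          if (inside && sep >= minSepPx) break
        }
        paths[[k]] <- best
      }
    }

    debris <- if (cfg$nDebris > 0) {
      data.frame(row = round(stats::runif(cfg$nDebris, 2, cfg$height - 3)),
                 col = round(stats::runif(cfg$nDebris, 2, cfg$width - 3)))
    } else data.frame(row = numeric(), col = numeric())

    # presence: the whole ellipse inside the frame
    positions <- vector("list", max(nObj, 0))
    for (k in seq_len(nObj)) {
      p <- paths[[k]]
      present <- p[, 1] >= aPx & p[, 1] <= cfg$height - 1 - aPx &
                 p[, 2] >= aPx & p[, 2] <= cfg$width - 1 - aPx
      positions[[k]] <- data.frame(
        frame = seq_len(cfg$frames) - 1L,
        row = p[, 1], col = p[, 2],
        row_um = p[, 1] * cfg$umPerPx, col_um = p[, 2] * cfg$umPerPx,
        present = present)
    }
    perFrameCount <- if (nObj > 0) {
      rowSums(vapply(positions, function(p) p$present,
                     logical(cfg$frames)))
    } else rep(0L, cfg$frames)

    # orientations along instantaneous velocity (static: fixed random)
    orient <- vector("list", max(nObj, 0))
    for (k in seq_len(nObj)) {
      p <- paths[[k]]
      d <- rbind(diff(p), p[nrow(p), ] - p[nrow(p) - 1, ])
      ang <- atan2(d[, 1], d[, 2])
      still <- sqrt(rowSums(d^2)) < 1e-9
      fixedAng <- stats::runif(1, 0, pi)
      ang[still] <- fixedAng
      orient[[k]] <- ang
    }

    frameList <- vector("list", cfg$frames)
    for (t in seq_len(cfg$frames)) {
      img <- matrix(cfg$bgIntensity, cfg$height, cfg$width)
      for (k in seq_len(nObj)) {
        img <- drawEllipse(img, paths[[k]][t, 1], paths[[k]][t, 2],
                           aPx, bPx, orient[[k]][t],
                           cfg$bgIntensity, cfg$objIntensity)
      }
      if (nrow(debris)) {
        img[cbind(debris$row + 1, debris$col + 1)] <- cfg$objIntensity
      }
      if (cfg$noiseSd > 0) {
        img <- img + matrix(stats::rnorm(length(img), 0, cfg$noiseSd),
                            nrow(img), ncol(img))
      }
      frameList[[t]] <- clamp(round(img), 0, 255)
    }

    cal <- Calibration(cfg$umPerPx, cfg$fps)
    truth <- structure(list(
      objects = if (nObj > 0) {
        data.frame(id = seq_len(nObj), class = classes,
                   speed_um_s = speeds)
      } else data.frame(id = integer(), class = character(),
                        speed_um_s = numeric()),
      positions = positions,
      perFrameCount = as.integer(perFrameCount),
      debris = debris,
      calibration = cal), class = "GroundTruth")
    truth$kinematics <- truthKinematics(truth, cal)
    list(frames = FrameSequence(frameList, cal), truth = truth)
  })
}

# anti-aliased oriented ellipse, max-composited over the image
drawEllipse <- function(img, r0, c0, a, b, angle, bg, fg) {
  rad <- ceiling(a) + 1
  rlo <- max(1, floor(r0 + 1 - rad)); rhi <- min(nrow(img), ceiling(r0 + 1 + rad))
  clo <- max(1, floor(c0 + 1 - rad)); chi <- min(ncol(img), ceiling(c0 + 1 + rad))
  if (rlo > rhi || clo > chi) return(img)
  rr <- rlo:rhi; cc <- clo:chi
  dr <- outer(rr - 1 - r0, rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - 1 - c0)
  along <- dr * sin(angle) + dc * cos(angle)
  perp <- dr * cos(angle) - dc * sin(angle)
  q <- sqrt((along / a)^2 + (perp / b)^2)
  cov <- clamp((1 - q) * b + 0.5, 0, 1)   # ~1 px soft edge
  patch <- bg + (fg - bg) * cov
  img[rr, cc] <- pmax(img[rr, cc], patch)
  img
}

#' Kinematics of the true trajectories
#'
#' Applies the motility module's own operations ([computeKinematics()],
#' [gradeMotility()]) to the exact centroids recorded by the generator, so
#' pipeline recovery can be compared like for like.
#'
#' @param truth a `GroundTruth` from [simulateVideo()].
#' @param calibration a [Calibration-class] (default: the truth's own).
#' @param window VAP smoothing window.
#' @return data.frame: `id`, `class`, `VCL`, `VSL`, `VAP`, `LIN`, `STR`,
#'   `WOB`, `GRADE`.
#' @export
truthKinematics <- function(truth, calibration = truth$calibration,
                            window = 5) {
  if (nrow(truth$objects) == 0) {
    return(data.frame(id = integer(), class = character(), VCL = numeric(),
                      VSL = numeric(), VAP = numeric(), LIN = numeric(),
                      STR = numeric(), WOB = numeric(), GRADE = character()))
  }
  rows <- lapply(seq_len(nrow(truth$objects)), function(k) {
    pos <- truth$positions[[k]]
    xy <- cbind(pos$row_um, pos$col_um)
    kin <- computeKinematics(xy, fps(calibration), window)
    data.frame(id = truth$objects$id[k], class = truth$objects$class[k],
               kin, GRADE = gradeMotility(kin$VCL))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
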