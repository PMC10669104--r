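#' Full-pipeline run configuration
#'
#' Flat, YAML-serializable bundle of every stage parameter: a saved
#' configuration re-applied to the same input reproduces a run exactly.
#'
#' @param umPerPx,fpsVal calibration.
#' @param detector `"gmm"` (motion-based, moving sperm only) or
#'   `"threshold"` (static intensity detection from frame 0).
#' @param level fixed binarization level, or `NA` for per-frame Otsu.
#' @param openRadius,minArea counting-stage morphology parameters
#'   (`minArea = NA`: scale the 70 px reference by calibration).
#' @param K,alpha,lambda,xi,var0,varMin background-mixture parameters, see
#'   [gmmParams()].
#' @param minBlobArea foreground blob floor (`NA`: scale 40 px reference).
#' @param gate,maxAge,minHits tracking parameters, see [trackParams()]
#'   (`gate = NA`: scale the 50 px reference).
#' @param window,minFrames motility parameters, see [analyzeTracks()].
#' @param gradeA,gradeB,gradeC VCL grade cut-offs, um/s.
#' @param seed RNG seed recorded with the run (the pipeline itself is
#'   deterministic; the seed matters when the input is simulated).
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(umPerPx = 0.074, fpsVal = 29.80,
                           detector = c("gmm", "threshold"),
                           level = NA, openRadius = 1, minArea = NA,
                           K = 3, alpha = 0.01, lambda = 2.5, xi = 0.7,
                           var0 = 225, varMin = 16, minBlobArea = NA,
                           gate = NA, maxAge = 5, minHits = 1,
                           window = 5, minFrames = 15,
                           gradeA = 50, gradeB = 25, gradeC = 6,
                           seed = 1) {
  detector <- match.arg(detector)
  cfg <- as.list(environment())
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Save / load a run configuration (YAML)
#'
#' @param config a `PipelineConfig`.
#' @param path YAML file path.
#' @return `loadRunConfig` returns the `PipelineConfig`.
#' @export
saveRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname saveRunConfig
#' @export
loadRunConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  vals <- lapply(vals, function(v) if (is.null(v)) NA else v)
  do.call(pipelineConfig, vals)
}

naNull <- function(x) if (length(x) == 0 || is.na(x)) NULL else x

#' Run the whole analysis pipeline and write a report bundle
#'
#' Orchestrates counting, detection, tracking, motility analysis and
#' sharpness scoring over one recording and writes machine-readable outputs
#' to `outputDir`:
#' \itemize{
#'   \item `counts.csv` — per-frame total sperm count (static chain);
#'   \item `tracks.csv` — every tracked centroid (track_id, frame, row, col);
#'   \item `track_scores.csv` — per-track appear/disappear frames, frames
#'     tracked (Ft), observation window (Fw = disappear - appear + 1) and
#'     tracking rate Rt;
#'   \item `motility.csv` — per-track VCL/VSL/VAP/LIN/STR/WOB and grade;
#'   \item `sharpness.csv` — per-frame SDF/TDF focus scores;
#'   \item `cohort.json` — grade counts and percentages, parameter
#'     statistics, tracking summary, run status, and the full configuration
#'     echoed for provenance;
#'   \item `run.log` — stage log with timings (the only output that is not
#'     byte-reproducible across runs).
#' }
#'
#' @param input a [FrameSequence-class] or a frame-directory path for
#'   [loadFrames()].
#' @param outputDir output directory (created if needed).
#' @param config a `PipelineConfig` from [pipelineConfig()].
#' @return invisibly, a list with the in-memory results (`counts`,
#'   `tracks`, `scores`, `motility`, `cohort`, `sharpness`, `status`).
#' @export
runFullPipeline <- function(input, outputDir,
                            config = pipelineConfig()) {
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outputDir, "run.log")
  logCon <- file(logPath, open = "wt")
  on.exit(close(logCon), add = TRUE)
  stamp <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%OS2"),
                    stage, msg)
    writeLines(line, logCon)
    message(line)
  }
  stageFail <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stamp(stage, paste("ERROR:", conditionMessage(e)))
      stop(sprintf("[stage %s] %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  cal <- Calibration(config$umPerPx, config$fpsVal)
  x <- stageFail("load", {
    if (is(input, "FrameSequence")) input else loadFrames(input, cal)
  })
  stamp("load", sprintf("%d frames of %d x %d px", nframes(x),
                        dim(x)[1], dim(x)[2]))
  cal <- calibration(x)

  counts <- stageFail("count", {
    tryCatch(countFrames(x, level = naNull(config$level),
                         openRadius = config$openRadius,
                         minArea = naNull(config$minArea)),
             error = function(e) {
               if (grepl("degenerate histogram", conditionMessage(e)))
                 data.frame(frame = seq_len(nframes(x)) - 1L, count = 0L)
               else stop(e)
             })
  })
  utils::write.csv(counts, file.path(outputDir, "counts.csv"),
                   row.names = FALSE)
  stamp("count", sprintf("median per-frame count %d",
                         as.integer(stats::median(counts$count))))

  det <- stageFail("detect", {
    if (config$detector == "gmm") {
      gmmDetector(gmmParams(config$K, config$alpha, config$lambda,
                            config$xi, config$var0, config$varMin),
                  minBlobArea = naNull(config$minBlobArea))
    } else {
      thresholdDetector(level = naNull(config$level),
                        openRadius = config$openRadius,
                        minArea = naNull(config$minArea))
    }
  })
  tp <- trackParams(gate = naNull(config$gate), maxAge = config$maxAge,
                    minHits = config$minHits, calibration = cal)
  tracks <- stageFail("track", trackVideo(x, det, tp))
  utils::write.csv(trackTable(tracks), file.path(outputDir, "tracks.csv"),
                   row.names = FALSE)
  stamp("track", sprintf("%d track(s)", length(tracks)))

  scores <- stageFail("track", {
    if (length(tracks) == 0) {
      data.frame(id = integer(), appear = integer(), disappear = integer(),
                 ft = integer(), fw = integer(), rt = numeric())
    } else {
      do.call(rbind, lapply(tracks@tracks, function(t) {
        fw <- t$lastSeen - t$appear + 1L
        data.frame(id = t$id, appear = t$appear, disappear = t$lastSeen,
                   ft = t$hits, fw = fw, rt = trackingRate(t$hits, fw))
      }))
    }
  })
  utils::write.csv(scores, file.path(outputDir, "track_scores.csv"),
                   row.names = FALSE)

  thresholds <- c(A = config$gradeA, B = config$gradeB, C = config$gradeC)
  motility <- stageFail("analyze",
    analyzeTracks(tracks, window = config$window,
                  minFrames = config$minFrames, thresholds = thresholds))
  utils::write.csv(motility, file.path(outputDir, "motility.csv"),
                   row.names = FALSE)
  stamp("analyze", sprintf("%d track(s) with kinematics",
                           sum(motility$status == "ok")))

  sharp <- stageFail("sharpness", scoreSharpness(x))
  utils::write.csv(sharp, file.path(outputDir, "sharpness.csv"),
                   row.names = FALSE)

  graded <- motility[!is.na(motility$GRADE), , drop = FALSE]
  status <- if (nrow(graded) == 0) "no sperm detected" else "ok"
  cohort <- if (nrow(graded) > 0) summarizeCohort(graded) else NULL
  trackSummary <- if (nrow(scores) > 0) summarizeTracking(scores$rt)
                  else NULL
  report <- list(
    status = status,
    n_frames = nframes(x),
    calibration = list(um_per_px = umPerPx(cal), fps = fps(cal)),
    config = unclass(config),
    counts = list(median = stats::median(counts$count),
                  mean = roundHalfUp(mean(counts$count), 2)),
    tracking = trackSummary,
    cohort = cohort)
  jsonlite::write_json(report, file.path(outputDir, "cohort.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  stamp("report", status)

  invisible(list(counts = counts, tracks = tracks, scores = scores,
                 motility = motility, cohort = cohort, sharpness = sharp,
                 status = status))
}
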