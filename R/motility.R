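#' Curvilinear length of a trajectory
#'
#' Sum of consecutive Euclidean segment lengths of the sampled polyline.
#'
#' @param xy two-column matrix of positions (same unit for both axes).
#' @return total path length, in the unit of `xy`.
#' @export
curvilinearLength <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 2) return(0)
  d <- diff(xy)
  sum(sqrt(rowSums(d^2)))
}

#' Average path of a trajectory (centered moving average)
#'
#' The "average path" underlying VAP: each position is replaced by the mean
#' of a centered window of `window` frames; endpoints use the largest
#' centered window that fits (shrinking windows), so the smoothed path keeps
#' the same number of points and the same endpoints' neighbourhood.
#' `window = 1` is the identity.
#'
#' @param xy two-column matrix of positions.
#' @param window odd window length in frames (>= 1).
#' @return smoothed two-column matrix.
#' @export
averagePath <- function(xy, window = 5) {
  stopifnot(window >= 1, window %% 2 == 1)
  xy <- as.matrix(xy)
  if (window == 1 || nrow(xy) < 3) return(xy)
  n <- nrow(xy)
  half <- (window - 1) / 2
  out <- xy
  for (i in seq_len(n)) {
    h <- min(half, i - 1, n - i)        # shrink at the ends, keep centered
    out[i, ] <- colMeans(xy[(i - h):(i + h), , drop = FALSE])
  }
  out
}

#' Kinematic parameters of one trajectory
#'
#' Standard CASA kinematics on a sampled trajectory in micrometers:
#' VCL = L / T (curvilinear), VSL = |x(T) - x(0)| / T (straight-line),
#' VAP = S / T with S the curvilinear length of the average path; ratio
#' descriptors LIN = 100 VSL/VCL, STR = 100 VSL/VAP, WOB = 100 VAP/VCL,
#' reported as percentages rounded half-up to 2 decimals. T is the elapsed
#' time (n - 1) / fps.
#'
#' @param xyUm two-column matrix of positions in micrometers (>= 2 rows).
#' @param fps frames per second.
#' @param window VAP smoothing window (odd frames; 1 disables smoothing).
#' @return one-row data.frame: `VCL`, `VSL`, `VAP` (um/s), `LIN`, `STR`,
#'   `WOB` (%). Ratios are `NA` when their denominator is 0.
#' @export
computeKinematics <- function(xyUm, fps, window = 5) {
  xyUm <- as.matrix(xyUm)
  n <- nrow(xyUm)
  if (n < 2) stop("trajectory needs at least 2 points")
  T <- (n - 1) / fps
  if (T <= 0) stop("duration must be positive")
  L <- curvilinearLength(xyUm)
  VCL <- L / T
  VSL <- sqrt(sum((xyUm[n, ] - xyUm[1, ])^2)) / T
  S <- curvilinearLength(averagePath(xyUm, window))
  VAP <- S / T
  ratio <- function(num, den) if (den > 0) roundHalfUp(100 * num / den, 2)
                              else NA_real_
  data.frame(VCL = VCL, VSL = VSL, VAP = VAP,
             LIN = ratio(VSL, VCL), STR = ratio(VSL, VAP),
             WOB = ratio(VAP, VCL))
}

#' WHO-style motility grade from curvilinear velocity
#'
#' Four-class grading: A (fast progressive), B (slow progressive), C
#' (non-progressive), D (immotile). The default velocity rule grades on VCL
#' in um/s: A >= 50, 25 <= B < 50, 6 <= C < 25, D < 6. All cut-offs are
#' configurable.
#'
#' @param vcl curvilinear velocity, um/s (vectorized).
#' @param thresholds named numeric: `A`, `B`, `C` lower cut-offs (um/s).
#' @return character vector of grades.
#' @export
#' @examples
#' gradeMotility(c(27.42, 5.86, 0))  # "B" "D" "D"
gradeMotility <- function(vcl, thresholds = c(A = 50, B = 25, C = 6)) {
  stopifnot(all(c("A", "B", "C") %in% names(thresholds)),
            thresholds["A"] >= thresholds["B"],
            thresholds["B"] >= thresholds["C"])
  th <- unname(thresholds[c("A", "B", "C")])
  ifelse(vcl >= th[1], "A",
    ifelse(vcl >= th[2], "B",
      ifelse(vcl >= th[3], "C", "D")))
}

#' Per-track motility analysis
#'
#' Converts each track's pixel centroids to micrometers via the
#' calibration, computes kinematics and grade. Tracks with fewer than
#' `minFrames` observations give unstable velocity estimates and are
#' flagged `"insufficient"` with `NA` kinematics.
#'
#' @param x a [TrackSet-class] or a centroid data.frame (`track_id`,
#'   `frame`, `row`, `col` in px).
#' @param calibration a [Calibration-class] (taken from the TrackSet when
#'   available).
#' @param window VAP smoothing window (odd frames).
#' @param minFrames minimum track length in frames (default 15, about half a
#'   second at ~30 fps).
#' @param thresholds grade cut-offs, see [gradeMotility()].
#' @return data.frame: `track_id`, `n_frames`, `VCL`, `VSL`, `VAP`, `LIN`,
#'   `STR`, `WOB`, `GRADE`, `status` ("ok" or "insufficient").
#' @export
analyzeTracks <- function(x, calibration = NULL, window = 5, minFrames = 15,
                          thresholds = c(A = 50, B = 25, C = 6)) {
  if (is(x, "TrackSet")) {
    if (is.null(calibration)) calibration <- x@calibration
    tab <- trackTable(x)
  } else {
    tab <- x
    if (is.null(calibration)) calibration <- Calibration()
  }
  upp <- umPerPx(calibration)
  f <- fps(calibration)
  ids <- unique(tab$track_id)
  rows <- lapply(ids, function(id) {
    tr <- tab[tab$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    n <- nrow(tr)
    if (n < minFrames) {
      return(data.frame(track_id = id, n_frames = n, VCL = NA_real_,
                        VSL = NA_real_, VAP = NA_real_, LIN = NA_real_,
                        STR = NA_real_, WOB = NA_real_,
                        GRADE = NA_character_, status = "insufficient"))
    }
    xy <- cbind(tr$row, tr$col) * upp
    k <- computeKinematics(xy, f, window)
    data.frame(track_id = id, n_frames = n, k,
               GRADE = gradeMotility(k$VCL, thresholds), status = "ok")
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(track_id = integer(), n_frames = integer(),
                      VCL = numeric(), VSL = numeric(), VAP = numeric(),
                      LIN = numeric(), STR = numeric(), WOB = numeric(),
                      GRADE = character(), status = character())
  rownames(out) <- NULL
  out
}

#' Cohort summary of motility records
#'
#' Grade counts and percentages plus mean/median of each kinematic
#' parameter over graded records.
#'
#' @param records data.frame with columns `VCL`..`WOB` and `GRADE` (rows
#'   with `NA` grade are excluded).
#' @return list: `n`, `counts` (named A-D), `percentages` (named, sum 100),
#'   `parameters` (data.frame of mean/median per parameter).
#' @export
summarizeCohort <- function(records) {
  rec <- records[!is.na(records$GRADE), , drop = FALSE]
  if (nrow(rec) == 0) stop("empty cohort")
  grades <- factor(rec$GRADE, levels = c("A", "B", "C", "D"))
  counts <- table(grades)
  pct <- roundHalfUp(100 * as.numeric(counts) / nrow(rec), 2)
  names(pct) <- names(counts)
  pars <- c("VCL", "VSL", "VAP", "LIN", "STR", "WOB")
  pars <- intersect(pars, names(rec))
  stats <- data.frame(
    parameter = pars,
    mean = vapply(pars, function(p) roundHalfUp(mean(rec[[p]]), 2), 0),
    median = vapply(pars, function(p) roundHalfUp(stats::median(rec[[p]]), 2), 0))
  rownames(stats) <- NULL
  list(n = nrow(rec),
       counts = stats::setNames(as.integer(counts), names(counts)),
       percentages = pct,
       parameters = stats)
}

#' Ratio descriptors from velocities
#'
#' LIN/STR/WOB percentages from already-measured VCL, VSL, VAP (e.g. when
#' re-deriving the ratio columns of a published parameter table).
#'
#' @param vcl,vsl,vap velocities in um/s (vectorized).
#' @return data.frame with `LIN`, `STR`, `WOB` in percent (2 decimals,
#'   half-up).
#' @export
kinematicRatios <- function(vcl, vsl, vap) {
  data.frame(LIN = roundHalfUp(100 * vsl / vcl, 2),
             STR = roundHalfUp(100 * vsl / vap, 2),
             WOB = roundHalfUp(100 * vap / vcl, 2))
}
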