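#' Extract blob detections from a binary mask
#'
#' 8-connected components with area >= `minBlobArea` become detections with
#' intensity-unweighted centroids (mean of member pixel coordinates), ordered
#' by (row, col).
#'
#' @param mask binary 0/1 matrix.
#' @param frameIndex 0-based frame index stored with each detection.
#' @param minBlobArea minimum component area in px.
#' @return data.frame with columns `frame`, `row`, `col` (0-based,
#'   real-valued centroid), `area`, and bounding box `rmin`, `rmax`, `cmin`,
#'   `cmax` (0-based, inclusive).
#' @export
#' @examples
#' m <- matrix(0, 30, 40); m[11:15, 21:25] <- 1
#' extractDetections(m, 0, 1)  # centroid (12, 22)
extractDetections <- function(mask, frameIndex = 0L, minBlobArea = 1) {
  empty <- data.frame(frame = integer(), row = numeric(), col = numeric(),
                      area = integer(), rmin = integer(), rmax = integer(),
                      cmin = integer(), cmax = integer())
  if (!any(mask > 0)) return(empty)
  L <- labelComponents(mask)
  on <- which(L > 0)
  lab <- L[on]
  r <- (on - 1) %% nrow(mask)          # 0-based row
  cc <- (on - 1) %/% nrow(mask)        # 0-based col
  area <- tabulate(lab)
  det <- data.frame(
    frame = frameIndex,
    row  = tapply(r, lab, mean),
    col  = tapply(cc, lab, mean),
    area = area,
    rmin = tapply(r, lab, min), rmax = tapply(r, lab, max),
    cmin = tapply(cc, lab, min), cmax = tapply(cc, lab, max))
  det <- det[det$area >= minBlobArea, , drop = FALSE]
  det <- det[order(det$row, det$col), , drop = FALSE]
  rownames(det) <- NULL
  det
}
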