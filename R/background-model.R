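#' Per-pixel Gaussian-mixture background model
#'
#' Adaptive background subtraction in the Stauffer–Grimson style: each pixel
#' is modelled by K Gaussians with weights, means and (scalar, grayscale)
#' variances updated online. At each frame a pixel's current intensity is
#' matched to the first component, in weight/sigma-sorted order, within
#' `lambda` standard deviations; the background set is the smallest prefix of
#' that ordering whose cumulative weight exceeds `xi`. A pixel is foreground
#' when it matches no component or a component outside the background set.
#'
#' @slot w,mu,v numeric matrices (pixels x K): component weights, means,
#'   variances.
#' @slot nrow,ncol frame dimensions.
#' @slot params list: `K`, `alpha` (learning rate), `lambda` (match
#'   threshold, sigma units), `xi` (background proportion), `var0` (initial
#'   variance), `varMin` (variance floor).
#' @name BackgroundModel-class
#' @aliases BackgroundModel-class
#' @exportClass BackgroundModel
setClass("BackgroundModel",
         representation(w = "matrix", mu = "matrix", v = "matrix",
                        nrow = "integer", ncol = "integer", params = "list"))

setValidity("BackgroundModel", function(object) {
  if (any(object@w < 0)) return("negative component weight")
  if (any(object@v < object@params$varMin - 1e-9))
    return("variance below configured minimum")
  TRUE
})

setMethod("show", "BackgroundModel", function(object) {
  p <- object@params
  cat(sprintf(
    "BackgroundModel: %d x %d px, K=%d, alpha=%g, lambda=%g, xi=%g\n",
    object@nrow, object@ncol, p$K, p$alpha, p$lambda, p$xi))
})

#' Default Gaussian-mixture parameters
#'
#' Standard adaptive-mixture operating points: K = 3 components, learning
#' rate 0.01, match threshold 2.5 sigma, background proportion 0.7, initial
#' sigma 15 gray levels, sigma floor 4 gray levels.
#'
#' @param K number of Gaussian components per pixel (>= 1).
#' @param alpha learning rate in (0, 1).
#' @param lambda match threshold in sigma units.
#' @param xi background proportion in (0, 1).
#' @param var0 variance assigned to newly created components.
#' @param varMin numerical variance floor.
#' @return parameter list.
#' @export
gmmParams <- function(K = 3, alpha = 0.01, lambda = 2.5, xi = 0.7,
                      var0 = 15^2, varMin = 4^2) {
  stopifnot(K >= 1, alpha > 0, alpha < 1, lambda > 0, xi > 0, xi < 1,
            var0 >= varMin, varMin > 0)
  list(K = as.integer(K), alpha = alpha, lambda = lambda, xi = xi,
       var0 = var0, varMin = varMin)
}

#' Initialize a background model from the first frame
#'
#' Component 1 of every pixel takes the pixel value as mean with weight 1 and
#' variance `var0`; the remaining K - 1 components have weight 0.
#'
#' @param frame numeric matrix in [0, 255].
#' @param params list from [gmmParams()].
#' @return a [BackgroundModel-class].
#' @export
initBackground <- function(frame, params = gmmParams()) {
  if (is.null(params$K) || params$K < 1) stop("K must be >= 1")
  npx <- length(frame)
  K <- params$K
  w <- matrix(0, npx, K); w[, 1] <- 1
  mu <- matrix(0, npx, K); mu[, 1] <- as.vector(frame)
  v <- matrix(params$var0, npx, K)
  new("BackgroundModel", w = w, mu = mu, v = v,
      nrow = nrow(frame), ncol = ncol(frame), params = params)
}

#' Update the background model with a frame and classify pixels
#'
#' One online step: per pixel, the matched component (first in
#' weight/sigma-descending order with |X - mu| <= lambda * sigma) is pulled
#' toward the new value with learning rate alpha and its weight reinforced;
#' unmatched weights decay by (1 - alpha); if nothing matches, the weakest
#' component is replaced by a new one centred on the pixel value. Weights are
#' renormalized to sum to 1. The pixel is foreground iff no component
#' matched or the matched component lies outside the background prefix.
#'
#' @param model a [BackgroundModel-class].
#' @param frame numeric matrix with the model's dimensions.
#' @return list with elements `model` (updated [BackgroundModel-class]) and
#'   `mask` (binary foreground matrix).
#' @export
updateBackground <- function(model, frame) {
  if (nrow(frame) != model@nrow || ncol(frame) != model@ncol)
    stop("shape mismatch between frame and background model")
  p <- model@params
  K <- p$K; a <- p$alpha
  X <- as.vector(frame)
  w <- model@w; mu <- model@mu; v <- model@v
  npx <- length(X)

  fit <- w / sqrt(v)                       # ordering criterion omega/sigma
  # rank of each component per pixel (1 = best), ties broken by index
  rk <- matrix(1L, npx, K)
  for (k in seq_len(K)) for (j in seq_len(K)) {
    if (j == k) next
    rk[, k] <- rk[, k] +
      ((fit[, j] > fit[, k]) | (fit[, j] == fit[, k] & j < k))
  }
  # matched component: lowest rank among components within lambda sigma
  bestRank <- rep(Inf, npx)
  bestIdx <- integer(npx)                  # 0 = no match
  for (k in seq_len(K)) {
    ok <- abs(X - mu[, k]) <= p$lambda * sqrt(v[, k])
    better <- ok & rk[, k] < bestRank
    bestRank[better] <- rk[better, k]
    bestIdx[better] <- k
  }
  matched <- bestIdx > 0

  for (k in seq_len(K)) {
    isM <- bestIdx == k
    w[, k] <- (1 - a) * w[, k] + a * isM
    if (any(isM)) {
      d <- X[isM] - mu[isM, k]
      mu[isM, k] <- mu[isM, k] + a * d
      d2 <- X[isM] - mu[isM, k]
      v[isM, k] <- (1 - a) * v[isM, k] + a * d2 * d2
    }
  }
  if (any(!matched)) {
    nm <- which(!matched)
    for (k in seq_len(K)) {
      repl <- nm[rk[nm, k] == K]           # weakest component of those pixels
      if (length(repl)) {
        w[repl, k] <- 0.05
        mu[repl, k] <- X[repl]
        v[repl, k] <- p$var0
      }
    }
  }
  v <- pmax(v, p$varMin)
  w <- w / rowSums(w)

  # background set: smallest prefix (in the pre-update ordering) whose
  # cumulative weight exceeds xi; component at rank r is background iff the
  # weight ranked strictly before it totals <= xi
  cumBefore <- matrix(0, npx, K)
  for (k in seq_len(K)) for (j in seq_len(K)) {
    if (j == k) next
    cumBefore[, k] <- cumBefore[, k] + w[, j] * (rk[, j] < rk[, k])
  }
  isBg <- cumBefore <= p$xi
  fgMatched <- rep(TRUE, npx)
  for (k in seq_len(K)) {
    sel <- bestIdx == k
    fgMatched[sel] <- !isBg[sel, k]
  }
  fg <- !matched | fgMatched

  model@w <- w; model@mu <- mu; model@v <- v
  list(model = model,
       mask = matrix(as.numeric(fg), model@nrow, model@ncol))
}

#' Foreground detections over a whole sequence
#'
#' Initializes the model on the first frame, then updates and classifies
#' every subsequent frame. Foreground masks get one pass of
#' [removeSmall()] with `minBlobArea` before centroid extraction.
#'
#' @param x a [FrameSequence-class].
#' @param params list from [gmmParams()].
#' @param minBlobArea minimum foreground blob area in px; default 40 px at
#'   the 0.074 um/px reference pitch, rescaled by calibration.
#' @return list with `detections` (data.frame over all frames) and `masks`
#'   (list of binary matrices, one per frame; frame 0's mask is all zero
#'   since the model is initialized on it).
#' @export
detectMotion <- function(x, params = gmmParams(), minBlobArea = NULL) {
  if (is.null(minBlobArea))
    minBlobArea <- scaleArea(40, umPerPx(calibration(x)))
  model <- initBackground(x[[1]], params)
  masks <- vector("list", nframes(x))
  masks[[1]] <- matrix(0, nrow(x[[1]]), ncol(x[[1]]))
  dets <- vector("list", nframes(x))
  dets[[1]] <- extractDetections(masks[[1]], 0L, minBlobArea)
  for (i in seq_len(nframes(x))[-1]) {
    up <- updateBackground(model, x[[i]])
    model <- up$model
    m <- removeSmall(up$mask, minBlobArea)
    masks[[i]] <- m
    dets[[i]] <- extractDetections(m, i - 1L, minBlobArea)
  }
  list(detections = do.call(rbind, dets), masks = masks, model = model)
}
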