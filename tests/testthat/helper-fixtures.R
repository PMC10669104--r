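# small seeded scenes shared across test files

smallScene <- function(seed = 7, ...) {
  args <- list(width = 160, height = 160, frames = 30,
               nProgressive = 2, nNonprogressive = 1, nImmotile = 1,
               nDebris = 2, seed = seed)
  do.call(sceneConfig, utils::modifyList(args, list(...)))
}

# a single straight swimmer at a known speed
swimmerScene <- function(speed = 25, noiseSd = 0, seed = 11, ...) {
  sceneConfig(nProgressive = 1, nNonprogressive = 0, nImmotile = 0,
              nDebris = 0, progressiveSpeed = c(speed, speed),
              zigzagAmplitude = 0, noiseSd = noiseSd, seed = seed, ...)
}

# detection level from the generator's radiometry (midpoint of background
# and object intensity)
sceneLevel <- function(cfg) (cfg$bgIntensity + cfg$objIntensity) / 2 / 255

# brute-force Otsu oracle: exhaustive search over all 256 thresholds,
# maximizing between-class variance computed from first principles
otsuOracle <- function(img) {
  v <- pmin(pmax(floor(as.vector(img)), 0), 255)
  best <- -1
  bestT <- integer(0)
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    sb <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (sb > best + 1e-12 * max(best, 1)) { best <- sb; bestT <- t }
    else if (abs(sb - best) <= 1e-10 * max(best, 1)) bestT <- c(bestT, t)
  }
  (min(bestT) + max(bestT)) / 2 / 255
}

# all permutations of 1..n (for the assignment oracle)
allPerms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in allPerms(n - 1)) {
    for (i in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = i)
    }
  }
  out
}

bruteAssignmentCost <- function(C) {
  n <- nrow(C)
  min(vapply(allPerms(n), function(p) sum(C[cbind(seq_len(n), p)]), 0))
}
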