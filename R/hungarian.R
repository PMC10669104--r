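#' Minimum-cost one-to-one assignment (Hungarian algorithm)
#'
#' O(n^3) shortest-augmenting-path implementation with dual potentials.
#' Rectangular matrices are padded to square with zeros; every row of an
#' n x m matrix with n <= m is assigned, and the total over real entries is
#' the global minimum.
#'
#' @param cost numeric cost matrix (finite values).
#' @return list with `assignment` (integer vector: column index assigned to
#'   each row, `NA` for rows matched only to padding) and `cost` (total over
#'   assigned real entries).
#' @export
#' @examples
#' solveAssignment(matrix(c(4, 2, 8, 4, 3, 7, 3, 1, 6), 3, 3, byrow = TRUE))
solveAssignment <- function(cost) {
  if (length(cost) == 0 || nrow(cost) == 0 || ncol(cost) == 0)
    return(list(assignment = rep(NA_integer_, nrow(cost)), cost = 0))
  stopifnot(all(is.finite(cost)))
  nr <- nrow(cost); nc <- ncol(cost)
  n <- max(nr, nc)
  a <- matrix(0, n, n)
  a[seq_len(nr), seq_len(nc)] <- cost

  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)        # p[j+1]: row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- INF
      j1 <- 0
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- a[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assign <- rep(NA_integer_, nr)
  for (j in seq_len(n)) {
    i <- p[j + 1]
    if (i >= 1 && i <= nr && j <= nc) assign[i] <- j
  }
  total <- sum(cost[cbind(which(!is.na(assign)), assign[!is.na(assign)])])
  list(assignment = assign, cost = total)
}
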