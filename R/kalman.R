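#' Constant-velocity Kalman state for one track
#'
#' Linear-Gaussian state estimator with state x = (row, col, v_row, v_col)
#' in px and px/frame and measurement z = (row, col). The system is
#'
#'   x_k = A x_{k-1} + w_{k-1},   z_k = H x_k + v_k
#'
#' with constant-velocity transition A (dt = 1 frame), position observation
#' H, process noise covariance Q and measurement noise covariance R. There
#' is no control input. The functions are written for general (A, H, Q, R),
#' so scalar analogues can be evaluated directly.
#'
#' @param pos numeric (row, col) initial position.
#' @param P0 initial state covariance (default diag(1, 1, 10, 10): position
#'   observed, velocity unknown).
#' @param Q process noise covariance (default 0.01 * I).
#' @param R measurement noise covariance (default I).
#' @return a list of class `KalmanState` with elements `x`, `P`, `A`, `H`,
#'   `Q`, `R`.
#' @export
kalmanInit <- function(pos, P0 = diag(c(1, 1, 10, 10)),
                       Q = 0.01 * diag(4), R = diag(2)) {
  A <- matrix(c(1, 0, 0, 0,
                0, 1, 0, 0,
                1, 0, 1, 0,
                0, 1, 0, 1), 4, 4)       # column-major: x' = x + v
  H <- matrix(c(1, 0,
                0, 1,
                0, 0,
                0, 0), 2, 4)
  structure(list(x = c(pos[1], pos[2], 0, 0), P = P0,
                 A = A, H = H, Q = Q, R = R),
            class = "KalmanState")
}

#' Kalman prediction step
#'
#' Propagates the state one step: x- = A x, P- = A P A' + Q.
#'
#' @param state a `KalmanState` (any consistent A/H/Q/R dimensions).
#' @return the predicted `KalmanState`.
#' @export
kalmanPredict <- function(state) {
  state$x <- as.vector(state$A %*% state$x)
  P <- state$A %*% state$P %*% t(state$A) + state$Q
  state$P <- (P + t(P)) / 2
  state
}

#' Kalman measurement update
#'
#' Gain, state and covariance correction:
#' K = P- H' (H P- H' + R)^-1;  x = x- + K (z - H x-);  P = (I - K H) P-.
#'
#' @param state a predicted `KalmanState`.
#' @param z measurement vector (length = rows of H).
#' @return the corrected `KalmanState`.
#' @export
kalmanUpdate <- function(state, z) {
  H <- state$H
  S <- H %*% state$P %*% t(H) + state$R
  Sinv <- tryCatch(solve(S),
                   error = function(e) stop("singular innovation covariance"))
  K <- state$P %*% t(H) %*% Sinv
  state$x <- as.vector(state$x + K %*% (z - H %*% state$x))
  P <- (diag(nrow(state$P)) - K %*% H) %*% state$P
  state$P <- (P + t(P)) / 2
  state
}

#' Predicted measurement position of a state
#' @param state a `KalmanState`.
#' @return numeric (row, col).
#' @export
kalmanPosition <- function(state) as.vector(state$H %*% state$x)
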