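# Constant-velocity Kalman filter over the box state
# (cx, cy, a, h, vcx, vcy, va, vh), a = width/height.
# Measurements are (cx, cy, a, h). Time step is one frame. Noise scales are
# tied to the box height h, the convention of reference tracking-by-detection
# implementations: position/size std h/20, velocity std h/160, with fixed
# small constants for the (dimensionless) aspect ratio.

.kf <- local({
  F <- diag(8); F[cbind(1:4, 5:8)] <- 1
  H <- cbind(diag(4), matrix(0, 4, 4))
  list(F = F, H = H, w_pos = 1 / 20, w_vel = 1 / 160)
})

#' Convert a box to measurement space
#'
#' @param b A box ([box()]).
#' @return Numeric 4-vector `(cx, cy, a, h)` with `a = width/height`.
#' @export
box_to_measurement <- function(b) {
  c(b[[1]] + b[[3]] / 2, b[[2]] + b[[4]] / 2, b[[3]] / b[[4]], b[[4]])
}

#' Convert a measurement-space vector back to a box
#'
#' @param z Numeric 4-vector `(cx, cy, a, h)`.
#' @return A box ([box()]).
#' @export
measurement_to_box <- function(z) {
  w <- z[3] * z[4]
  box(z[1] - w / 2, z[2] - z[4] / 2, w, z[4])
}

#' Initiate a Kalman track state from a first measurement
#'
#' The mean holds the measured box with zero velocities; the covariance is
#' diagonal with inflated uncertainty (2x the per-step position std, 10x the
#' per-step velocity std), reflecting an unobserved velocity.
#'
#' @param b A box ([box()]).
#' @return A `kalman_state`: list with `mean` (8-vector) and `cov` (8x8).
#' @examples
#' s <- kf_initiate(box(0, 0, 10, 20))
#' s$mean # (5, 10, 0.5, 20, 0, 0, 0, 0)
#' @export
kf_initiate <- function(b) {
  z <- box_to_measurement(b)
  h <- z[4]
  std <- c(2 * .kf$w_pos * h, 2 * .kf$w_pos * h, 1e-2, 2 * .kf$w_pos * h,
           10 * .kf$w_vel * h, 10 * .kf$w_vel * h, 1e-5, 10 * .kf$w_vel * h)
  structure(list(mean = c(z, 0, 0, 0, 0), cov = diag(std^2)),
            class = "kalman_state")
}

#' Predict the state one frame ahead
#'
#' Applies the constant-velocity transition and inflates the covariance with
#' process noise scaled by the current height.
#'
#' @param s A `kalman_state`.
#' @return The predicted `kalman_state`.
#' @export
kf_predict <- function(s) {
  h <- s$mean[4]
  std <- c(.kf$w_pos * h, .kf$w_pos * h, 1e-2, .kf$w_pos * h,
           .kf$w_vel * h, .kf$w_vel * h, 1e-5, .kf$w_vel * h)
  mean <- drop(.kf$F %*% s$mean)
  cov <- .kf$F %*% s$cov %*% t(.kf$F) + diag(std^2)
  structure(list(mean = mean, cov = (cov + t(cov)) / 2),
            class = "kalman_state")
}

# project state into measurement space: list(mean 4-vector, S 4x4 innovation cov)
kf_project <- function(s) {
  h <- s$mean[4]
  std <- c(.kf$w_pos * h, .kf$w_pos * h, 1e-1, .kf$w_pos * h)
  S <- .kf$H %*% s$cov %*% t(.kf$H) + diag(std^2)
  list(mean = s$mean[1:4], S = (S + t(S)) / 2)
}

#' Kalman measurement update
#'
#' Standard correction in `(cx, cy, a, h)` measurement space. The posterior
#' mean lies between prediction and measurement; the posterior covariance
#' never exceeds the prior in the measured subspace.
#'
#' @param s A `kalman_state` (typically after [kf_predict()]).
#' @param b The measured box ([box()]).
#' @return The updated `kalman_state`.
#' @export
kf_update <- function(s, b) {
  z <- box_to_measurement(b)
  if (!all(is.finite(z))) stop("non-finite measurement")
  pr <- kf_project(s)
  PHt <- s$cov %*% t(.kf$H)
  K <- t(solve(pr$S, t(PHt)))          # Kalman gain, 8 x 4
  mean <- s$mean + drop(K %*% (z - pr$mean))
  cov <- s$cov - K %*% pr$S %*% t(K)
  structure(list(mean = mean, cov = (cov + t(cov)) / 2),
            class = "kalman_state")
}

#' Squared Mahalanobis gating distance to candidate boxes
#'
#' Distance of each candidate's `(cx, cy, a, h)` measurement to the predicted
#' measurement distribution, used to gate track-detection pairs before
#' appearance matching.
#'
#' @param s A `kalman_state`.
#' @param boxes An n x 4 matrix (or data frame) of candidate boxes with
#'   columns `left`, `top`, `width`, `height`.
#' @return Numeric vector of squared Mahalanobis distances, one per candidate.
#' @export
kf_gating_distance <- function(s, boxes) {
  boxes <- as_box_matrix(boxes)
  if (nrow(boxes) == 0) return(numeric(0))
  pr <- kf_project(s)
  Z <- cbind(boxes[, 1] + boxes[, 3] / 2,
             boxes[, 2] + boxes[, 4] / 2,
             boxes[, 3] / boxes[, 4],
             boxes[, 4])
  D <- t(Z) - pr$mean                  # 4 x n residuals
  M <- solve(pr$S, D)
  colSums(D * M)
}

#' Chi-square gate for the 4-D measurement space
#'
#' The 0.95 quantile of the chi-square distribution with 4 degrees of
#' freedom (about 9.4877): squared Mahalanobis distances above this value
#' are treated as infeasible associations.
#'
#' @return A single number.
#' @export
chi2_gate <- function() stats::qchisq(0.95, df = 4)
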