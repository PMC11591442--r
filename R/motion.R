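# Constant-velocity Kalman filter over bounding boxes.
#
# State is the 8-vector (cx, cy, a, h, vcx, vcy, va, vh): box center, aspect
# ratio (width / height), height, and their per-frame velocities. The
# measurement is (cx, cy, a, h). Process and measurement noise scale with the
# box height, the convention of the SORT/BYTE tracker family.

#' Kalman filter noise parameters
#'
#' Standard deviations of position-like and velocity-like noise, as fractions
#' of box height per frame.
#'
#' @param std_weight_position Position noise weight (default 1/20).
#' @param std_weight_velocity Velocity noise weight (default 1/160).
#' @return A list of class `kf_pars`.
#' @export
kf_pars <- function(std_weight_position = 1 / 20,
                    std_weight_velocity = 1 / 160) {
  stopifnot(std_weight_position > 0, std_weight_velocity > 0)
  structure(list(std_weight_position = std_weight_position,
                 std_weight_velocity = std_weight_velocity),
            class = "kf_pars")
}

# box <-> measurement conversions; box is c(left, top, right, bottom)
box_to_z <- function(box) {
  w <- box[3] - box[1]; h <- box[4] - box[2]
  if (!all(is.finite(box)) || w <= 0 || h <= 0) {
    stop("degenerate box: width and height must be positive")
  }
  c(cx = box[1] + w / 2, cy = box[2] + h / 2, a = w / h, h = h)
}

z_to_box <- function(z) {
  w <- z[3] * z[4]; h <- z[4]
  c(left = z[1] - w / 2, top = z[2] - h / 2,
    right = z[1] + w / 2, bottom = z[2] + h / 2)
}

kf_F <- function() {
  F <- diag(8)
  F[cbind(1:4, 5:8)] <- 1
  F
}

#' Initialize a track's motion state from a box
#'
#' Mean position is the box's (center, aspect, height) with zero velocities;
#' the covariance is diagonal with scales proportional to box height.
#'
#' @param box Numeric `c(left, top, right, bottom)`.
#' @param pars A [kf_pars()] object.
#' @return A list of class `kf_state` with elements `mean` (8-vector) and
#'   `cov` (8x8 matrix).
#' @export
kf_init <- function(box, pars = kf_pars()) {
  z <- box_to_z(box)
  mean <- c(z, rep(0, 4))
  wp <- pars$std_weight_position; wv <- pars$std_weight_velocity
  h <- z[4]
  std <- c(2 * wp * h, 2 * wp * h, 1e-2, 2 * wp * h,
           10 * wv * h, 10 * wv * h, 1e-5, 10 * wv * h)
  structure(list(mean = unname(mean), cov = diag(std^2)), class = "kf_state")
}

#' Advance a motion state by one frame
#'
#' Constant-velocity propagation plus additive process noise, so the
#' covariance trace never decreases across a predict.
#'
#' @param state A `kf_state`.
#' @param pars A [kf_pars()] object.
#' @return The predicted `kf_state`.
#' @export
kf_predict <- function(state, pars = kf_pars()) {
  F <- kf_F()
  wp <- pars$std_weight_position; wv <- pars$std_weight_velocity
  h <- state$mean[4]
  std <- c(wp * h, wp * h, 1e-2, wp * h, wv * h, wv * h, 1e-5, wv * h)
  Q <- diag(std^2)
  mean <- as.numeric(F %*% state$mean)
  cov <- F %*% state$cov %*% t(F) + Q
  structure(list(mean = mean, cov = symmetrize(cov)), class = "kf_state")
}

#' Correct a motion state with a measured box
#'
#' Standard Kalman update with measurement noise proportional to box height.
#' The posterior mean of each measured coordinate lies between the prior mean
#' and the measurement, and the covariance trace does not increase.
#'
#' @param state A `kf_state` (normally just predicted).
#' @param box Numeric `c(left, top, right, bottom)`.
#' @param pars A [kf_pars()] object.
#' @return The updated `kf_state`.
#' @export
kf_update <- function(state, box, pars = kf_pars()) {
  z <- unname(box_to_z(box))
  wp <- pars$std_weight_position
  h <- state$mean[4]
  std <- c(wp * h, wp * h, 1e-1, wp * h)
  R <- diag(std^2)
  H <- cbind(diag(4), matrix(0, 4, 4))
  S <- H %*% state$cov %*% t(H) + R
  K <- state$cov %*% t(H) %*% solve(S)
  innov <- z - as.numeric(H %*% state$mean)
  mean <- state$mean + as.numeric(K %*% innov)
  IKH <- diag(8) - K %*% H
  # Joseph form keeps the covariance symmetric PSD under roundoff
  cov <- IKH %*% state$cov %*% t(IKH) + K %*% R %*% t(K)
  structure(list(mean = mean, cov = symmetrize(cov)), class = "kf_state")
}

#' Current box of a motion state
#'
#' @param state A `kf_state`.
#' @return Numeric `c(left, top, right, bottom)`.
#' @export
kf_box <- function(state) {
  unname(z_to_box(state$mean[1:4]))
}

symmetrize <- function(m) (m + t(m)) / 2
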