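#' Tilt angles from a single accelerometer sample
#'
#' Gravity-referenced roll and pitch observations: `roll = atan2(ay, az)`,
#' `pitch = atan2(-ax, sqrt(ay^2 + az^2))`, in degrees (aerospace convention:
#' roll about the X axis, pitch about Y). These are the measurement inputs of
#' the attitude Kalman filter.
#'
#' @param ax,ay,az acceleration components in g (vectorized).
#' @return List with numeric vectors `roll_deg`, `pitch_deg`.
#' @export
accel_tilt <- function(ax, ay, az) {
  mag <- sqrt(ax^2 + ay^2 + az^2)
  if (any(mag == 0)) stop("undefined tilt observation: zero-magnitude acceleration vector")
  list(roll_deg = atan2(ay, az) * 180 / pi,
       pitch_deg = atan2(-ax, sqrt(ay^2 + az^2)) * 180 / pi)
}

#' Configuration of a linear-Gaussian Kalman filter
#'
#' The discrete filter alternates a time update — prior mean `A x + B u` and
#' covariance `A P A' + Q` — with a measurement update through gain
#' `K = P H' (H P H' + R)^-1`. Defaults describe the standard per-axis
#' two-state tilt filter with state `[angle, gyro bias]`, gyro rate as the
#' control input and the accelerometer tilt angle as the observation.
#'
#' @param dt sample period in seconds.
#' @param A state-transition matrix (default `[[1, -dt], [0, 1]]`).
#' @param B input-to-state matrix (default `[dt, 0]'`).
#' @param H state-to-observation matrix (default `[1, 0]`).
#' @param Q process-noise covariance (default `diag(0.001, 0.003) * dt`,
#'   angle^2 / bias^2 units).
#' @param R measurement-noise covariance (default `0.03` deg^2).
#' @param x0 initial state (default zero; [estimate_attitude()] replaces the
#'   angle component with the first accelerometer tilt observation).
#' @param P0 initial covariance (default identity).
#' @return A `kalman_config` list.
#' @export
kalman_config <- function(dt, A = matrix(c(1, 0, -dt, 1), 2, 2),
                          B = matrix(c(dt, 0), 2, 1),
                          H = matrix(c(1, 0), 1, 2),
                          Q = diag(c(0.001, 0.003)) * dt,
                          R = matrix(0.03, 1, 1),
                          x0 = numeric(nrow(A)), P0 = diag(nrow(A))) {
  A <- as.matrix(A); B <- as.matrix(B); H <- as.matrix(H)
  Q <- as.matrix(Q); R <- as.matrix(R); P0 <- as.matrix(P0)
  n <- nrow(A)
  stopifnot(ncol(A) == n, nrow(B) == n, ncol(H) == n, nrow(Q) == n,
            nrow(R) == nrow(H), length(x0) == n, nrow(P0) == n)
  check_psd <- function(M, nm) {
    if (max(abs(M - t(M))) > 1e-10) stop(nm, " must be symmetric")
    if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
      stop(nm, " must be positive semi-definite")
  }
  check_psd(Q, "Q"); check_psd(R, "R"); check_psd(P0, "P0")
  structure(list(A = A, B = B, H = H, Q = Q, R = R,
                 x0 = as.numeric(x0), P0 = P0, dt = dt),
            class = "kalman_config")
}

#' One predict-update cycle of the Kalman filter
#'
#' Computes the prior `x_bar = A x + B u`, `P_bar = A P A' + Q`; the gain
#' `K = P_bar H' (H P_bar H' + R)^-1`; the posterior
#' `x = x_bar + K (z - H x_bar)` and `P = (I - K H) P_bar`. The returned
#' covariance is re-symmetrized for numerical robustness.
#'
#' @param state list with `x_hat` (state vector) and `P` (covariance).
#' @param u control input vector (gyro rate for the tilt filter).
#' @param z observation vector.
#' @param cfg a [kalman_config()].
#' @return Updated state: list `x_hat`, `P`, plus the intermediate gain `K`
#'   and prior `x_bar`, `P_bar`.
#' @export
kalman_step <- function(state, u, z, cfg) {
  x_bar <- cfg$A %*% state$x_hat + cfg$B %*% u
  P_bar <- cfg$A %*% state$P %*% t(cfg$A) + cfg$Q
  S <- cfg$H %*% P_bar %*% t(cfg$H) + cfg$R
  if (rcond(S) < 1e-14) stop("singular innovation covariance (H P H' + R)")
  K <- P_bar %*% t(cfg$H) %*% solve(S)
  x_hat <- x_bar + K %*% (z - cfg$H %*% x_bar)
  P <- (diag(nrow(P_bar)) - K %*% cfg$H) %*% P_bar
  P <- (P + t(P)) / 2
  list(x_hat = as.numeric(x_hat), P = P, K = K,
       x_bar = as.numeric(x_bar), P_bar = P_bar)
}

new_attitude_series <- function(t, roll, pitch, yaw = NULL,
                                P_roll = NA_real_, P_pitch = NA_real_,
                                method = "kalman") {
  structure(list(t = t, roll_deg = roll, pitch_deg = pitch, yaw_deg = yaw,
                 P_trace = data.frame(roll = P_roll, pitch = P_pitch),
                 method = method),
            class = "attitude_series")
}

#' @export
print.attitude_series <- function(x, ...) {
  cat(sprintf("<attitude_series> %d steps (%s), roll range [%.2f, %.2f] deg\n",
              length(x$t), x$method, min(x$roll_deg), max(x$roll_deg)))
  invisible(x)
}

#' @export
as.data.frame.attitude_series <- function(x, ...) {
  d <- data.frame(t = x$t, roll_deg = x$roll_deg, pitch_deg = x$pitch_deg)
  if (!is.null(x$yaw_deg)) d$yaw_deg <- x$yaw_deg
  d$P_trace_roll <- x$P_trace$roll
  d$P_trace_pitch <- x$P_trace$pitch
  d
}

#' Kalman-filtered roll/pitch attitude of a recording
#'
#' Runs two independent two-state filters (state = `[angle, gyro bias]`):
#' roll driven by `gx` and observed by the accelerometer roll angle, pitch
#' driven by `gy` and observed by the accelerometer pitch angle. The initial
#' angle is taken from the first tilt observation. Yaw, if requested, is
#' pure gyro integration of `gz` and drifts without an absolute reference.
#'
#' @param rec an [imu_recording] (cleaned, non-empty).
#' @param q_angle,q_bias process-noise spectral densities (per second) for
#'   the angle and bias states; the per-step covariance is
#'   `diag(q_angle, q_bias) * dt`.
#' @param r_angle measurement-noise variance of the tilt observation (deg^2).
#' @param yaw include gyro-integrated yaw (default `FALSE`; drift-prone and
#'   excluded from downstream features).
#' @return An `attitude_series`: `t`, `roll_deg`, `pitch_deg`, optional
#'   `yaw_deg`, and `P_trace` (per-step posterior covariance trace per axis).
#' @export
estimate_attitude <- function(rec, q_angle = 0.001, q_bias = 0.003,
                              r_angle = 0.03, yaw = FALSE) {
  stopifnot(inherits(rec, "imu_recording"))
  d <- rec$data
  if (nrow(d) == 0L) stop("empty recording")
  dt <- 1 / rec$sample_rate_hz
  obs <- accel_tilt(d$ax, d$ay, d$az)
  roll <- kalman_scan_2state(d$gx, obs$roll_deg, dt, q_angle, q_bias, r_angle,
                             obs$roll_deg[1])
  pitch <- kalman_scan_2state(d$gy, obs$pitch_deg, dt, q_angle, q_bias, r_angle,
                              obs$pitch_deg[1])
  yaw_deg <- if (yaw) cumtrapz_scalar(d$gz, dt) else NULL
  new_attitude_series(d$t, roll$angle, pitch$angle, yaw_deg,
                      P_roll = roll$P_trace, P_pitch = pitch$P_trace,
                      method = "kalman")
}

# trapezoidal cumulative integral starting at x0 = 0
cumtrapz_scalar <- function(rate, dt, x0 = 0) {
  n <- length(rate)
  x0 + c(0, cumsum((rate[-n] + rate[-1]) / 2 * dt))
}

#' Gyro-integration attitude baseline
#'
#' Trapezoidal integration of the gyroscope rates from an initial attitude;
#' unbiased over short spans but drifts without bound under gyro bias.
#'
#' @param rec an [imu_recording].
#' @param x0 initial `(roll, pitch)` in degrees (default: first tilt
#'   observation).
#' @return An `attitude_series` with `method = "gyro"`.
#' @export
gyro_integrate <- function(rec, x0 = NULL) {
  stopifnot(inherits(rec, "imu_recording"))
  d <- rec$data
  if (nrow(d) == 0L) stop("empty recording")
  dt <- 1 / rec$sample_rate_hz
  if (is.null(x0)) {
    o <- accel_tilt(d$ax[1], d$ay[1], d$az[1])
    x0 <- c(o$roll_deg, o$pitch_deg)
  }
  new_attitude_series(d$t, cumtrapz_scalar(d$gx, dt, x0[1]),
                      cumtrapz_scalar(d$gy, dt, x0[2]), method = "gyro")
}

#' Accelerometer-only attitude baseline
#'
#' Per-sample tilt angles from [accel_tilt()]; unbiased in a static scene
#' but with the full accelerometer noise variance at every step.
#'
#' @param rec an [imu_recording].
#' @return An `attitude_series` with `method = "accel"`.
#' @export
accel_only <- function(rec) {
  stopifnot(inherits(rec, "imu_recording"))
  d <- rec$data
  if (nrow(d) == 0L) stop("empty recording")
  o <- accel_tilt(d$ax, d$ay, d$az)
  new_attitude_series(d$t, o$roll_deg, o$pitch_deg, method = "accel")
}

#' Root-mean-square attitude error against ground truth
#'
#' @param est an `attitude_series`.
#' @param truth a `ground_truth` from [spiral_attitude()].
#' @return Named numeric vector `c(roll, pitch)` RMSE in degrees.
#' @export
attitude_rmse <- function(est, truth) {
  stopifnot(length(est$roll_deg) == length(truth$true_roll_deg))
  c(roll = sqrt(mean((est$roll_deg - truth$true_roll_deg)^2)),
    pitch = sqrt(mean((est$pitch_deg - truth$true_pitch_deg)^2)))
}
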