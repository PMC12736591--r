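# independent oracle: one Kalman cycle as joint-Gaussian conditioning.
# Prior x ~ N(m, P); observation z = H x + v, v ~ N(0, R). Condition the
# stacked Gaussian [x; z] on z.
conditioning_oracle <- function(x_hat, P, u, z, cfg) {
  m <- cfg$A %*% x_hat + cfg$B %*% u
  Pb <- cfg$A %*% P %*% t(cfg$A) + cfg$Q
  S <- cfg$H %*% Pb %*% t(cfg$H) + cfg$R
  cross <- Pb %*% t(cfg$H)
  post_mean <- m + cross %*% solve(S, z - cfg$H %*% m)
  post_cov <- Pb - cross %*% solve(S, t(cross))
  list(x_hat = as.numeric(post_mean), P = (post_cov + t(post_cov)) / 2)
}

random_psd <- function(n) {
  M <- matrix(rnorm(n * n), n)
  M %*% t(M) + diag(n) * 0.1
}

test_that("kalman_step matches joint-Gaussian conditioning on random instances", {
  set.seed(100)
  for (i in 1:100) {
    n <- sample(1:3, 1)
    m_obs <- sample(1:2, 1)
    cfg <- kalman_config(dt = 0.01,
                         A = matrix(rnorm(n * n), n), B = matrix(rnorm(n), n, 1),
                         H = matrix(rnorm(m_obs * n), m_obs, n),
                         Q = random_psd(n), R = random_psd(m_obs),
                         x0 = rnorm(n), P0 = random_psd(n))
    st <- list(x_hat = rnorm(n), P = random_psd(n))
    u <- rnorm(1); z <- rnorm(m_obs)
    got <- kalman_step(st, u, z, cfg)
    want <- conditioning_oracle(st$x_hat, st$P, u, z, cfg)
    expect_lt(max(abs(got$x_hat - want$x_hat)), 1e-10)
    expect_lt(max(abs(got$P - want$P)), 1e-10)
    # covariance contraction: posterior trace never exceeds prior trace
    expect_lte(sum(diag(got$P)), sum(diag(got$P_bar)) + 1e-12)
  }
})

test_that("scalar worked case gives K = 0.5, P = 0.5, and large R freezes the prior", {
  cfg <- kalman_config(dt = 1, A = matrix(1), B = matrix(0), H = matrix(1),
                       Q = matrix(0), R = matrix(1), x0 = 0, P0 = matrix(1))
  st <- kalman_step(list(x_hat = 0, P = matrix(1)), u = 0, z = 1, cfg)
  expect_equal(as.numeric(st$K), 0.5)
  expect_equal(as.numeric(st$P), 0.5)
  expect_equal(st$x_hat, 0.5)

  cfg_inf <- kalman_config(dt = 1, A = matrix(1), B = matrix(0), H = matrix(1),
                           Q = matrix(0), R = matrix(1e12), x0 = 0, P0 = matrix(1))
  st2 <- kalman_step(list(x_hat = 2, P = matrix(1)), u = 0, z = 100, cfg_inf)
  expect_lt(abs(as.numeric(st2$K)), 1e-11)
  expect_equal(st2$x_hat, 2, tolerance = 1e-8)
})

test_that("accel_tilt closed form: gravity-aligned, quarter-turn, 30-degree pitch", {
  expect_equal(unlist(accel_tilt(0, 0, 1)), c(roll_deg = 0, pitch_deg = 0))
  expect_equal(unlist(accel_tilt(0, 1, 0)), c(roll_deg = 90, pitch_deg = 0))
  got <- accel_tilt(-sin(pi / 6), 0, cos(pi / 6))
  expect_equal(got$roll_deg, 0)
  expect_equal(got$pitch_deg, 30)
  expect_error(accel_tilt(0, 0, 0), "zero-magnitude")
})

test_that("the compiled per-axis scan reproduces step-wise kalman_step iteration", {
  set.seed(21)
  n <- 200; dt <- 1 / 330
  u <- rnorm(n, 0, 20)
  z <- rnorm(n, 5, 0.5)
  scan <- airspiral:::kalman_scan_2state(u, z, dt, 0.001, 0.003, 0.03, z[1])
  cfg <- kalman_config(dt)
  st <- list(x_hat = c(z[1], 0), P = diag(2))
  angle_r <- numeric(n); ptr <- numeric(n)
  angle_r[1] <- z[1]; ptr[1] <- 2
  for (k in 2:n) {
    st <- kalman_step(st, u[k], z[k], cfg)
    angle_r[k] <- st$x_hat[1]
    ptr[k] <- sum(diag(st$P))
  }
  expect_equal(scan$angle, angle_r, tolerance = 1e-12)
  expect_equal(scan$P_trace, ptr, tolerance = 1e-12)
})

test_that("noiseless static recording is a fixed point of the filter", {
  s <- static_recording(2, accel_noise_g = 0, gyro_noise_dps = 0,
                        gyro_bias_walk = 0, roll0 = 3, pitch0 = -2)
  att <- estimate_attitude(s$rec)
  expect_lt(max(abs(att$roll_deg - 3)), 1e-9)
  expect_lt(max(abs(att$pitch_deg + 2)), 1e-9)
})

test_that("Kalman filter beats gyro-integration and accel-only baselines", {
  for (seed in 1:3) {
    s <- static_recording(10, accel_noise_g = 0.05, gyro_noise_dps = 0.5,
                          gyro_bias_walk = 0.05, seed = seed)
    k <- attitude_rmse(estimate_attitude(s$rec), s$truth)
    g <- attitude_rmse(gyro_integrate(s$rec), s$truth)
    a <- attitude_rmse(accel_only(s$rec), s$truth)
    expect_lt(k["roll"], g["roll"])
    expect_lt(k["roll"], a["roll"])
    expect_lt(k["pitch"], g["pitch"])
    expect_lt(k["pitch"], a["pitch"])
  }
  # dynamic tasks too
  set.seed(31)
  for (task in c("line", "spiral")) {
    prof <- subject_profile("healthy", jitter_amp_deg = 0.2)
    truth <- spiral_attitude(8, prof, task = task)
    rec <- imu_from_attitude(truth)
    k <- attitude_rmse(estimate_attitude(rec), truth)
    g <- attitude_rmse(gyro_integrate(rec), truth)
    a <- attitude_rmse(accel_only(rec), truth)
    expect_lt(mean(k), mean(g))
    expect_lt(mean(k), mean(a))
  }
})

test_that("filtering retains the 5 Hz tremor spectral peak", {
  set.seed(41)
  prof <- subject_profile("pd", tremor_freq_hz = 5, tremor_amp_deg = 4,
                          burst_duty = 1, jitter_amp_deg = 0)
  truth <- spiral_attitude(10, prof, task = "spiral")
  rec <- imu_from_attitude(truth)
  att <- estimate_attitude(rec)
  expect_lt(abs(dominant_freq(att$roll_deg, 330) - 5), 0.3)
})

test_that("biased gyro produces roughly linear integration error growth", {
  set.seed(51)
  s <- static_recording(20, accel_noise_g = 0, gyro_noise_dps = 0,
                        gyro_bias_walk = 0)
  rec <- s$rec
  rec$data$gx <- rec$data$gx + 1          # constant 1 deg/s bias
  gy <- gyro_integrate(rec)
  err <- gy$roll_deg - s$truth$true_roll_deg
  fit <- suppressWarnings(stats::lm(err ~ rec$data$t))
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.05)
  expect_gt(suppressWarnings(summary(fit)$r.squared), 0.99)
})

test_that("accel-only estimate on a noisy static scene is unbiased", {
  s <- static_recording(10, accel_noise_g = 0.05, gyro_noise_dps = 0.5,
                        seed = 6, roll0 = 5, pitch0 = 0)
  a <- accel_only(s$rec)
  expect_lt(abs(mean(a$roll_deg) - 5), 0.2)
  expect_gt(stats::sd(a$roll_deg), 0.5)
})

test_that("negating ay negates the estimated roll on a symmetric input", {
  s <- static_recording(3, accel_noise_g = 0, gyro_noise_dps = 0,
                        gyro_bias_walk = 0, roll0 = 10)
  rec2 <- s$rec
  rec2$data$ay <- -rec2$data$ay
  att1 <- estimate_attitude(s$rec)
  att2 <- estimate_attitude(rec2)
  expect_equal(att2$roll_deg, -att1$roll_deg, tolerance = 1e-9)
})

test_that("yaw output is gyro-integrated and empty recordings error", {
  s <- static_recording(1, accel_noise_g = 0, gyro_noise_dps = 0,
                        gyro_bias_walk = 0)
  att <- estimate_attitude(s$rec, yaw = TRUE)
  expect_equal(att$yaw_deg, rep(0, length(att$t)))
  rec <- s$rec
  rec$data <- rec$data[0, ]
  expect_error(estimate_attitude(rec), "empty")
})
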