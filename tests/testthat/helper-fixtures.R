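# Shared fixtures: small seeded recordings and cohorts built in code.

# static scene with configurable noise; returns list(rec, truth)
static_recording <- function(duration_s = 5, accel_noise_g = 0.05,
                             gyro_noise_dps = 0.5, gyro_bias_walk = 0.05,
                             seed = 1, roll0 = 0, pitch0 = 0) {
  set.seed(seed)
  prof <- subject_profile("healthy", jitter_amp_deg = 0,
                          gyro_bias_walk = gyro_bias_walk,
                          accel_noise_g = accel_noise_g,
                          gyro_noise_dps = gyro_noise_dps)
  truth <- spiral_attitude(duration_s, prof, task = "rest")
  truth$true_roll_deg[] <- roll0
  truth$true_pitch_deg[] <- pitch0
  rec <- imu_from_attitude(truth, subject_id = "static")
  list(rec = rec, truth = truth)
}

noiseless_profile <- function(group = "healthy", ...) {
  subject_profile(group, jitter_amp_deg = 0, gyro_bias_walk = 0,
                  accel_noise_g = 0, gyro_noise_dps = 0, ...)
}

# tiny, well-separated cohort for fast training tests
toy_dataset <- function(n_per_group = 5, duration_s = 6, seed = 3,
                        tremor_amp = c(6, 8), duty = c(0.9, 1)) {
  ranges <- cohort_parameter_ranges()
  ranges$pd$tremor_amp_deg <- tremor_amp
  ranges$pd$burst_duty <- duty
  cohort <- generate_cohort(n_per_group, n_per_group, duration_s,
                            seed = seed, ranges = ranges)
  feats <- cohort_features(cohort)
  make_dataset(feats, fractions = c(0.6, 0.2, 0.2), seed = seed)
}

# dominant frequency of the detrended trace via periodogram (oracle)
dominant_freq <- function(x, rate, detrend_span = 33) {
  sm <- stats::filter(x, rep(1 / detrend_span, detrend_span), sides = 2)
  resid <- x - sm
  resid <- resid[!is.na(resid)]
  sp <- stats::spec.pgram(stats::ts(resid, frequency = rate), plot = FALSE,
                          taper = 0, detrend = TRUE)
  sp$freq[which.max(sp$spec)]
}

# mean periodogram power in [f_lo, f_hi] Hz (oracle)
band_power <- function(x, rate, f_lo, f_hi) {
  sp <- stats::spec.pgram(stats::ts(x - mean(x), frequency = rate),
                          plot = FALSE, taper = 0, detrend = TRUE)
  sel <- sp$freq >= f_lo & sp$freq <= f_hi
  mean(sp$spec[sel])
}
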