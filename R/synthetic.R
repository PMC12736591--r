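#' Subject simulation profile
#'
#' Parameter set controlling one simulated subject's mid-air drawing
#' kinematics and sensor imperfections. Parkinsonian subjects superimpose
#' 4-6 Hz tremor bursts on the drawing sweep and trace it more slowly
#' (bradykinesia); healthy subjects carry only low-amplitude 8-12 Hz
#' physiological jitter. All angles in degrees, rates in Hz.
#'
#' @param group `"healthy"` or `"pd"`.
#' @param tremor_freq_hz tremor oscillation frequency (PD classically 4-6 Hz;
#'   0 disables tremor).
#' @param tremor_amp_deg peak tremor angle amplitude.
#' @param burst_duty fraction of time tremor bursts are active, in `[0, 1]`.
#' @param jitter_amp_deg amplitude of always-on physiological jitter.
#' @param jitter_freq_hz jitter frequency (default band 8-12 Hz).
#' @param slow_factor bradykinetic slowing multiplier on trace speed
#'   (1 = normal speed; > 1 traces the same figure more slowly).
#' @param gyro_bias_walk random-walk standard deviation of the gyroscope
#'   bias, deg/s per sqrt(s).
#' @param accel_noise_g accelerometer white-noise standard deviation, g.
#' @param gyro_noise_dps gyroscope white-noise standard deviation, deg/s.
#' @return A `subject_profile` list.
#' @export
subject_profile <- function(group = c("healthy", "pd"),
                            tremor_freq_hz = 0, tremor_amp_deg = 0,
                            burst_duty = 0, jitter_amp_deg = 0.2,
                            jitter_freq_hz = 10, slow_factor = 1,
                            gyro_bias_walk = 0.05, accel_noise_g = 0.02,
                            gyro_noise_dps = 0.3) {
  group <- match.arg(group)
  stopifnot(tremor_freq_hz >= 0, tremor_amp_deg >= 0,
            burst_duty >= 0, burst_duty <= 1,
            jitter_amp_deg >= 0, slow_factor > 0,
            gyro_bias_walk >= 0, accel_noise_g >= 0, gyro_noise_dps >= 0)
  if (group == "pd" && tremor_freq_hz > 0 &&
      (tremor_freq_hz < 3 || tremor_freq_hz > 7)) {
    stop("PD tremor_freq_hz must lie in [3, 7] Hz")
  }
  structure(list(group = group, tremor_freq_hz = tremor_freq_hz,
                 tremor_amp_deg = tremor_amp_deg, burst_duty = burst_duty,
                 jitter_amp_deg = jitter_amp_deg, jitter_freq_hz = jitter_freq_hz,
                 slow_factor = slow_factor, gyro_bias_walk = gyro_bias_walk,
                 accel_noise_g = accel_noise_g, gyro_noise_dps = gyro_noise_dps),
            class = "subject_profile")
}

#' Group-level simulator parameter ranges
#'
#' Ranges from which per-subject profiles are drawn. Defaults encode the
#' classical parkinsonian phenomenology: 4-6 Hz tremor at 2-5 degrees peak
#' amplitude active 40-80% of the time, 1.3-2x bradykinetic slowing; healthy
#' subjects have no tremor bursts, only 8-12 Hz jitter under 0.3 degrees.
#' These are simulator knobs, not claims about any clinical cohort.
#'
#' @return Nested list of `c(lo, hi)` ranges per group.
#' @export
cohort_parameter_ranges <- function() {
  list(
    healthy = list(tremor_freq_hz = c(0, 0), tremor_amp_deg = c(0, 0),
                   burst_duty = c(0, 0), jitter_amp_deg = c(0.1, 0.3),
                   jitter_freq_hz = c(8, 12), slow_factor = c(1, 1)),
    pd = list(tremor_freq_hz = c(4, 6), tremor_amp_deg = c(2, 5),
              burst_duty = c(0.4, 0.8), jitter_amp_deg = c(0.1, 0.3),
              jitter_freq_hz = c(8, 12), slow_factor = c(1.3, 2.0))
  )
}

#' Draw a random subject profile for a group
#'
#' Samples each kinematic parameter uniformly from the group's range in
#' [cohort_parameter_ranges()]; uses the current RNG state.
#'
#' @param group `"healthy"` or `"pd"`.
#' @param ranges parameter ranges (default [cohort_parameter_ranges()]).
#' @param ... fixed overrides passed to [subject_profile()].
#' @return A `subject_profile`.
#' @export
draw_profile <- function(group, ranges = cohort_parameter_ranges(), ...) {
  r <- ranges[[group]]
  u <- function(b) runif(1, b[1], b[2])
  args <- list(group = group, tremor_freq_hz = u(r$tremor_freq_hz),
               tremor_amp_deg = u(r$tremor_amp_deg), burst_duty = u(r$burst_duty),
               jitter_amp_deg = u(r$jitter_amp_deg),
               jitter_freq_hz = u(r$jitter_freq_hz), slow_factor = u(r$slow_factor))
  over <- list(...)
  args[names(over)] <- over
  do.call(subject_profile, args)
}

# Draw disjoint tremor-burst [start, end] intervals covering roughly
# `duty` of [0, duration]. Alternates off/on segments with mean burst
# length 1 s; returns a 2-column matrix (possibly 0 rows).
draw_burst_intervals <- function(duration_s, duty, mean_burst_s = 1) {
  if (duty <= 0) return(matrix(numeric(0), ncol = 2,
                               dimnames = list(NULL, c("start", "end"))))
  if (duty >= 1) return(matrix(c(0, duration_s), ncol = 2,
                               dimnames = list(NULL, c("start", "end"))))
  mean_gap_s <- mean_burst_s * (1 - duty) / duty
  t <- runif(1, 0, 2 * mean_gap_s)  # random initial gap
  out <- NULL
  while (t < duration_s) {
    len <- runif(1, 0.5, 1.5) * mean_burst_s
    end <- min(t + len, duration_s)
    if (end > t) out <- rbind(out, c(t, end))
    t <- end + runif(1, 0.5, 1.5) * mean_gap_s
  }
  if (is.null(out)) out <- matrix(numeric(0), ncol = 2)
  colnames(out) <- c("start", "end")
  out
}

# Raised-cosine-edged burst envelope evaluated on time grid t for the
# given intervals; 50 ms ramps avoid discontinuous angular velocity.
burst_envelope <- function(t, intervals, ramp_s = 0.05) {
  w <- numeric(length(t))
  if (nrow(intervals) == 0) return(w)
  for (i in seq_len(nrow(intervals))) {
    s <- intervals[i, 1]; e <- intervals[i, 2]
    ramp <- min(ramp_s, (e - s) / 2)
    inside <- t >= s & t <= e
    wi <- rep(1, sum(inside))
    ti <- t[inside]
    if (ramp > 0) {
      up <- ti < s + ramp
      dn <- ti > e - ramp
      wi[up] <- 0.5 - 0.5 * cos(pi * (ti[up] - s) / ramp)
      wi[dn] <- 0.5 - 0.5 * cos(pi * (e - ti[dn]) / ramp)
    }
    w[inside] <- pmax(w[inside], wi)
  }
  w
}

#' Simulate ground-truth wrist attitude for a drawing task
#'
#' Generates noiseless roll/pitch angle traces for a subject tracing one of
#' three tasks in mid-air. For `task = "spiral"` the wrist orientation sweeps
#' an Archimedean spiral r = a + b*theta mapped to bounded angle excursions
#' (pitch tracks the horizontal spiral coordinate, roll the vertical);
#' `"line"` is a monotone pitch sweep; `"rest"` holds a constant base
#' attitude. The sweep is time-scaled by the profile's `slow_factor`
#' (bradykinesia). Tremor bursts — a sinusoid at `tremor_freq_hz` gated by
#' burst intervals drawn to match `burst_duty` — and always-on physiological
#' jitter are superimposed on both angles.
#'
#' @param duration_s recording length in seconds (> 0).
#' @param profile a [subject_profile()].
#' @param task `"rest"`, `"line"` or `"spiral"`.
#' @param sample_rate_hz sampling rate (default 330 Hz).
#' @param sweep_amp_deg peak base-attitude excursion of the drawing sweep
#'   (default 15 degrees).
#' @param n_turns spiral revolutions a healthy subject completes in
#'   `duration_s` (default 3).
#' @return A `ground_truth` list: `t`, `true_roll_deg`, `true_pitch_deg`,
#'   `burst_intervals` (2-column matrix, seconds), `profile`, `task`,
#'   `sample_rate_hz`.
#' @export
spiral_attitude <- function(duration_s, profile, task = c("spiral", "line", "rest"),
                            sample_rate_hz = 330, sweep_amp_deg = 15, n_turns = 3) {
  task <- match.arg(task)
  if (duration_s <= 0) stop("duration_s must be positive")
  stopifnot(inherits(profile, "subject_profile"))
  n <- round(sample_rate_hz * duration_s)
  t <- (seq_len(n) - 1) / sample_rate_hz
  # progress through the figure, slowed by bradykinesia and capped at done
  prog <- pmin(t / (profile$slow_factor * duration_s), 1)
  if (task == "spiral") {
    theta <- 2 * pi * n_turns * prog
    r <- theta / (2 * pi * n_turns)          # a = 0, b chosen so r(theta_max) = 1
    base_pitch <- sweep_amp_deg * r * cos(theta)
    base_roll <- sweep_amp_deg * r * sin(theta)
  } else if (task == "line") {
    base_pitch <- sweep_amp_deg * (2 * prog - 1)
    base_roll <- rep(0, n)
  } else {
    base_pitch <- rep(2, n)
    base_roll <- rep(-1, n)
  }
  intervals <- draw_burst_intervals(duration_s, profile$burst_duty)
  env <- burst_envelope(t, intervals)
  tremor_phase <- runif(1, 0, 2 * pi)
  trem <- profile$tremor_amp_deg * env * sin(2 * pi * profile$tremor_freq_hz * t + tremor_phase)
  jit_phase <- runif(2, 0, 2 * pi)
  jit_r <- profile$jitter_amp_deg * sin(2 * pi * profile$jitter_freq_hz * t + jit_phase[1])
  jit_p <- profile$jitter_amp_deg * sin(2 * pi * profile$jitter_freq_hz * t + jit_phase[2])
  # tremor loads both axes; quadrature phase on pitch mimics rotational tremor
  trem_p <- profile$tremor_amp_deg * env * cos(2 * pi * profile$tremor_freq_hz * t + tremor_phase)
  structure(list(t = t,
                 true_roll_deg = base_roll + trem + jit_r,
                 true_pitch_deg = base_pitch + trem_p + jit_p,
                 burst_intervals = intervals, profile = profile, task = task,
                 sample_rate_hz = sample_rate_hz),
            class = "ground_truth")
}

#' Synthesize a six-axis IMU recording from ground-truth attitude
#'
#' Inverts the attitude-estimation observation model: gyroscope channels are
#' the time derivatives of roll/pitch plus a bias random walk and white
#' noise; accelerometer channels are the gravity unit vector rotated by
#' (roll, pitch) plus white noise. With zero noise and zero bias walk,
#' [accel_tilt()] recovers the true roll/pitch exactly and integrating the
#' gyro rates recovers the angles up to discretization error.
#'
#' @param truth a `ground_truth` from [spiral_attitude()].
#' @param profile subject profile supplying the noise parameters
#'   (default: the profile stored in `truth`).
#' @param sample_rate_hz must match the truth's rate.
#' @return An [imu_recording] labelled with the profile's group.
#' @param subject_id identifier stored on the recording.
#' @export
imu_from_attitude <- function(truth, profile = truth$profile,
                              sample_rate_hz = truth$sample_rate_hz,
                              subject_id = "sim") {
  stopifnot(inherits(truth, "ground_truth"))
  if (!isTRUE(all.equal(sample_rate_hz, truth$sample_rate_hz))) {
    stop("sample_rate_hz does not match the ground truth's rate")
  }
  n <- length(truth$t)
  if (n < 2) stop("ground truth must contain at least two samples")
  dt <- 1 / sample_rate_hz
  roll <- truth$true_roll_deg
  pitch <- truth$true_pitch_deg
  # central-difference angular rates (one-sided at the ends), deg/s
  ddt <- function(x) {
    d <- numeric(n)
    d[1] <- (x[2] - x[1]) / dt
    d[n] <- (x[n] - x[n - 1]) / dt
    d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
    d
  }
  bias_walk <- function() cumsum(rnorm(n, 0, profile$gyro_bias_walk * sqrt(dt)))
  gx <- ddt(roll) + bias_walk() + rnorm(n, 0, profile$gyro_noise_dps)
  gy <- ddt(pitch) + bias_walk() + rnorm(n, 0, profile$gyro_noise_dps)
  gz <- bias_walk() + rnorm(n, 0, profile$gyro_noise_dps)
  # gravity direction in body frame (aerospace ZYX convention), units of g
  phi <- roll * pi / 180
  th <- pitch * pi / 180
  ax <- -sin(th) + rnorm(n, 0, profile$accel_noise_g)
  ay <- sin(phi) * cos(th) + rnorm(n, 0, profile$accel_noise_g)
  az <- cos(phi) * cos(th) + rnorm(n, 0, profile$accel_noise_g)
  imu_recording(data.frame(ax = ax, ay = ay, az = az, gx = gx, gy = gy, gz = gz),
                sample_rate_hz = sample_rate_hz,
                label = if (profile$group == "pd") "pd" else "healthy",
                subject_id = subject_id, task = truth$task)
}

#' Generate a labelled healthy/PD cohort of simulated recordings
#'
#' Draws per-subject profiles from the group parameter ranges with a seeded
#' RNG, simulates ground-truth attitude for the requested task and converts
#' each to a six-axis recording. Deterministic given `seed`.
#'
#' @param n_healthy,n_pd subject counts per group (>= 0).
#' @param duration_s recording length (default 60 s).
#' @param sample_rate_hz sampling rate (default 330 Hz).
#' @param task drawing task (default `"spiral"`).
#' @param seed integer RNG seed.
#' @param ranges group parameter ranges (default [cohort_parameter_ranges()]).
#' @return A `cohort`: list of elements each holding `recording`
#'   ([imu_recording]) and `truth` (`ground_truth`).
#' @export
generate_cohort <- function(n_healthy, n_pd, duration_s = 60,
                            sample_rate_hz = 330, task = "spiral", seed = 1,
                            ranges = cohort_parameter_ranges()) {
  stopifnot(n_healthy >= 0, n_pd >= 0)
  set.seed(seed)
  groups <- c(rep("healthy", n_healthy), rep("pd", n_pd))
  out <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    prof <- draw_profile(groups[i], ranges)
    truth <- spiral_attitude(duration_s, prof, task = task,
                             sample_rate_hz = sample_rate_hz)
    rec <- imu_from_attitude(truth, subject_id = sprintf("S%03d_%s", i, groups[i]))
    out[[i]] <- list(recording = rec, truth = truth)
  }
  structure(out, class = "cohort")
}

#' Write a simulated cohort to disk
#'
#' Writes one packet text file and one JSON ground-truth sidecar (profile,
#' burst intervals) per subject, plus a cohort manifest CSV
#' (`subject_id, group, file, profile parameters`).
#'
#' @param cohort a cohort from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return Path to the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(s) {
    rec <- s$recording
    f <- file.path(dir, paste0(rec$subject_id, ".txt"))
    write_recording(rec, f)
    side <- file.path(dir, paste0(rec$subject_id, "_truth.json"))
    jsonlite::write_json(
      list(profile = unclass(s$truth$profile),
           burst_intervals = s$truth$burst_intervals,
           task = s$truth$task, sample_rate_hz = s$truth$sample_rate_hz),
      side, auto_unbox = TRUE, digits = NA)
    data.frame(subject_id = rec$subject_id, group = rec$label, file = basename(f),
               as.data.frame(unclass(s$truth$profile)[-1]))
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}
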