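test_that("attention normalization contracts: unit mass, scale invariance, fallback", {
  expect_equal(normalize_attention(c(0.2, 0.3, 0.5)), c(0.2, 0.3, 0.5))
  expect_equal(normalize_attention(c(2, 3, 5)), c(0.2, 0.3, 0.5))
  expect_equal(normalize_attention(rep(1, 32)), rep(1 / 32, 32))
  expect_equal(sum(normalize_attention(runif(32))), 1)
  # sign-mixed weights fall back to absolute-value normalization with a warning
  expect_warning(v <- normalize_attention(c(-1, 1, 2)), "absolute value")
  expect_equal(v, c(0.25, 0.25, 0.5))
  expect_equal(sum(v), 1)
  expect_error(suppressWarnings(normalize_attention(c(0, 0))), "all-zero")
  # matrix input normalizes each window independently
  m <- matrix(c(1, 1, 2, 2, 3, 5), 2)
  expect_equal(rowSums(normalize_attention(m)), c(1, 1))
})

test_that("upsample + Savitzky-Golay reproduces polynomials and preserves mass", {
  # constant profile stays constant
  out <- upsample_smooth(rep(0.05, 20), 200)
  expect_equal(out, rep(0.05, 200), tolerance = 1e-10)
  # linear ramp preserved (linear interpolation + cubic-exact filter)
  ramp <- seq(0.01, 0.09, length.out = 32)
  up <- upsample_smooth(ramp, 330)
  expect_equal(up, seq(0.01, 0.09, length.out = 330), tolerance = 1e-8)
  # the window-51 order-3 filter reproduces a cubic exactly
  x <- seq(-1, 1, length.out = 301)
  cubic <- 2 + x - 3 * x^2 + 0.5 * x^3
  sm <- as.numeric(signal::sgolayfilt(cubic, p = 3, n = 51))
  expect_equal(sm, cubic, tolerance = 1e-10)
  # total mass approximately preserved on smooth long inputs
  set.seed(140)
  a <- normalize_attention(runif(32, 0.5, 1.5))
  up2 <- upsample_smooth(a, 330)
  expect_equal(mean(up2), mean(a), tolerance = 0.02)
  # too-short traces skip smoothing with a message
  expect_message(short <- upsample_smooth(c(0.4, 0.6), 40), "skipped")
  expect_length(short, 40)
})

test_that("channel importance percentages sum to 100 and track attention mass", {
  # uniform apportioned weights over 6 channels
  ac <- matrix(1 / (32 * 6), 32, 6)
  imp <- channel_importance(ac)
  expect_equal(unname(imp), rep(100 / 6, 6), tolerance = 1e-10)
  # all mass on one channel
  one <- matrix(0, 32, 3)
  one[, 2] <- 1 / 32
  expect_equal(unname(channel_importance(one)), c(0, 100, 0))
  # apportionment from scalar attention: sums to 100, favors larger-magnitude axes
  set.seed(141)
  alpha <- normalize_attention(runif(32))
  x <- cbind(big = rnorm(32, sd = 10), small = rnorm(32, sd = 0.1))
  imp2 <- channel_importance(alpha, x)
  expect_equal(sum(imp2), 100)
  expect_gt(imp2["big"], imp2["small"])
  # apportioned per-channel weights sum over channels back to the temporal weights
  mag <- abs(x) / rowSums(abs(x))
  expect_equal(rowSums(alpha * mag), alpha)
})

test_that("attention_report returns per-window contracts on a trained toy model", {
  ds <- toy_dataset(n_per_group = 3, duration_s = 3, seed = 143)
  fit <- train_model(variant_spec("LAFNet", hidden_dim = 8), ds,
                     train_config(epochs = 5, seed = 143))
  te <- dataset_split(ds, "test")
  rep <- attention_report(fit, te$x, channel_names = c("roll", "pitch"))
  n <- dim(te$x)[1]
  expect_equal(dim(rep$alpha_norm), c(n, 32L))
  expect_equal(rowSums(rep$alpha_norm), rep(1, n), tolerance = 1e-10)
  expect_equal(unname(rowSums(rep$channel_importance)), rep(100, n),
               tolerance = 1e-10)
  expect_equal(colnames(rep$channel_importance), c("roll", "pitch"))
  expect_equal(ncol(rep$alpha_smooth), 32L)
  # no-attention variants cannot be interpreted
  m0 <- build_model(variant_spec("LDLFNet", hidden_dim = 4), 2, seed = 1)
  expect_error(attention_report(m0, te$x), "no attention")
})

test_that("attention overlay aligns tables and validates lengths", {
  ds <- toy_dataset(n_per_group = 3, duration_s = 3, seed = 149)
  fit <- train_model(variant_spec("LAFNet", hidden_dim = 8), ds,
                     train_config(epochs = 3, seed = 149))
  te <- dataset_split(ds, "test")
  rep <- attention_report(fit, te$x)
  L <- ncol(rep$alpha_smooth)
  ov <- attention_overlay(rep, 1, roll = te$x[1, , 1], pitch = te$x[1, , 2])
  expect_equal(nrow(ov$table), L)
  expect_named(ov$table, c("t", "roll_deg", "pitch_deg", "attention"))
  expect_equal(nrow(ov$step_summary), 32L)
  expect_error(attention_overlay(rep, 1, roll = rnorm(5), pitch = rnorm(5)),
               "length")
})

test_that("burst_attention splits window steps by ground-truth intervals", {
  alpha <- matrix(1 / 10, 2, 10)
  alpha[1, 6:10] <- 3 / 10   # window 1: high attention late
  alpha <- normalize_attention(alpha)
  iv <- matrix(c(0.5, 2.0), 1, 2)   # burst from 0.5 s
  rate <- 10                         # 10 Hz -> steps at 0.0..0.9 s
  ba <- burst_attention(alpha, window_start_s = c(0, 5), rep(list(iv), 2),
                        sample_rate_hz = rate)
  # window 1 spans 0–0.9 s: steps >= 0.5 s are inside
  expect_equal(ba$n_inside[1], 5L)
  expect_gt(ba$mean_inside[1], ba$mean_outside[1])
  # window 2 spans 5–5.9 s: entirely outside the burst
  expect_equal(ba$n_inside[2], 0L)
  expect_true(is.na(ba$mean_inside[2]))
})

test_that("recording-level co-location detects attention mass on burst windows", {
  # 4 windows of 10 steps at 10 Hz starting at 0,1,2,3 s; burst covers [0, 2)
  alpha <- matrix(0.1, 4, 10)
  alpha[1:2, ] <- 0.4          # mass concentrated on the burst-covered windows
  iv <- matrix(c(0, 1.95), 1, 2)
  bc <- burst_colocation(alpha, window_start_s = 0:3, iv, sample_rate_hz = 10)
  expect_gt(bc$ratio, 1)
  expect_equal(bc$n_inside, 20L)
  expect_equal(bc$n_outside, 20L)
  # uniform mass gives ratio 1
  flat <- burst_colocation(matrix(1, 4, 10), 0:3, iv, sample_rate_hz = 10)
  expect_equal(flat$ratio, 1)
  # total normalized mass is 1
  expect_equal(bc$mean_inside * bc$n_inside + bc$mean_outside * bc$n_outside, 1)
})
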