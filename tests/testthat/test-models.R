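test_that("the five canonical variants map to the documented architecture table", {
  v <- all_variants()
  expect_equal(v$LAFNet$attention, "linear")
  expect_false(v$LAFNet$dropout_after_lstm)
  expect_true(v$LAFNet$dropout_after_attention)
  expect_equal(v$TAFNet$attention, "tanh")
  expect_true(v$TAFNet$dropout_after_attention)
  expect_equal(v$LDLFNet$attention, "none")
  expect_true(v$LDLFNet$dropout_after_lstm)
  expect_equal(v$LDLAFNet$attention, "linear")
  expect_true(v$LDLAFNet$dropout_after_lstm)
  expect_equal(v$LDTAFNet$attention, "tanh")
  expect_true(v$LDTAFNet$dropout_after_lstm)
  # five distinct fingerprints
  fp <- vapply(v, function(s) paste(s$attention, s$dropout_after_lstm,
                                    s$dropout_after_attention), character(1))
  expect_length(unique(fp), 5L)
  expect_error(variant_spec("NOPE"), "arg")
})

test_that("compiled batched forward equals the plain-R reference pipeline", {
  set.seed(70)
  for (attn in c("linear", "tanh", "none")) {
    spec <- variant_spec("custom", attention = attn, hidden_dim = 7,
                         n_lstm_layers = 2, dropout_rate = 0)
    m <- build_model(spec, 3, seed = 71)
    x <- array(rnorm(5 * 11 * 3), dim = c(5, 11, 3))
    fw <- model_forward(m, x)
    for (i in 1:5) {
      H <- lstm_encode(matrix(x[i, , ], 11, 3), m$params, 2)
      ref <- switch(attn,
        linear = attend_linear(H, m$params$wa, m$params$ba),
        tanh = attend_tanh(H, m$params$wa, m$params$ba),
        none = list(a = NULL, context = H[nrow(H), ]))
      p_ref <- classify(ref$context, m$params$Wc, m$params$bc)
      expect_equal(as.numeric(fw$probs[i, ]), as.numeric(p_ref), tolerance = 1e-12)
      if (attn != "none") {
        expect_equal(as.numeric(fw$alpha[i, ]), as.numeric(ref$a), tolerance = 1e-12)
      }
    }
  }
})

test_that("LSTM encoding contracts: shapes, zero fixed point, batch independence", {
  spec <- variant_spec("custom", attention = "linear", hidden_dim = 4,
                       n_lstm_layers = 1, dropout_rate = 0)
  m <- build_model(spec, 2, seed = 5)
  expect_equal(dim(lstm_encode(matrix(0, 1, 2), m$params, 1)), c(1L, 4L))
  # all-zero input with all-zero parameters stays at zero
  zp <- lapply(m$params, function(p) p * 0)
  H0 <- lstm_encode(matrix(0, 6, 2), zp, 1)
  expect_equal(max(abs(H0)), 0)
  expect_error(lstm_encode(matrix(0, 0, 2), m$params, 1), "empty")
  # per-sequence independence: batch order does not change outputs
  x <- array(rnorm(4 * 5 * 2), dim = c(4, 5, 2))
  p1 <- model_forward(m, x)$probs
  p2 <- model_forward(m, x[4:1, , ])$probs
  expect_equal(p2, p1[4:1, ], tolerance = 1e-12)
})

test_that("linear attention identities: annihilation, uniform weights, single step", {
  H <- matrix(rnorm(12), 4, 3)
  z <- attend_linear(H, rep(0, 3), 0)
  expect_equal(z$a, rep(0, 4))
  expect_equal(z$context, rep(0, 3))
  u <- attend_linear(H, rep(0, 3), 1)
  expect_equal(u$a, rep(1, 4))
  expect_equal(u$context, colSums(H))
  one <- attend_linear(H[1, , drop = FALSE], c(1, 2, 3), 0.5)
  expect_equal(one$context, as.numeric(one$a) * H[1, ])
  # linearity in H: a scales by alpha, context by alpha^2 (zero bias)
  wa <- rnorm(3)
  s1 <- attend_linear(H, wa, 0)
  s2 <- attend_linear(2 * H, wa, 0)
  expect_equal(s2$a, 2 * s1$a)
  expect_equal(s2$context, 4 * s1$context)
})

test_that("tanh attention is bounded and saturates", {
  H <- matrix(rnorm(15), 5, 3)
  z <- attend_tanh(H, rep(0, 3), 0)
  expect_equal(z$a, rep(0, 5))
  expect_equal(z$context, rep(0, 3))
  big <- attend_tanh(H, rep(0, 3), 50)
  expect_equal(big$a, rep(1, 5), tolerance = 1e-12)
  expect_equal(big$context, colSums(H), tolerance = 1e-10)
  r <- attend_tanh(H, rnorm(3, sd = 3), rnorm(1))
  expect_true(all(abs(r$a) <= 1))
})

test_that("softmax head outputs probability vectors; dropout off at inference", {
  expect_equal(classify(c(0, 0), diag(2), c(0, 0)), c(0.5, 0.5))
  set.seed(80)
  for (i in 1:20) {
    p <- classify(rnorm(4), matrix(rnorm(8), 4, 2), rnorm(2))
    expect_equal(sum(p), 1)
    expect_true(all(p > 0 & p < 1))
  }
  m <- build_model(variant_spec("LAFNet", hidden_dim = 8), 2, seed = 81)
  x <- array(rnorm(3 * 32 * 2), dim = c(3, 32, 2))
  expect_identical(predict(m, x), predict(m, x))
})

test_that("backpropagation matches numerical differentiation for every variant", {
  set.seed(90)
  x <- array(rnorm(4 * 6 * 2), dim = c(4, 6, 2))
  y <- c(0L, 1L, 1L, 0L)
  eps <- 1e-6
  for (nm in c("LAFNet", "TAFNet", "LDLFNet")) {
    spec <- variant_spec(nm, hidden_dim = 5, n_lstm_layers = 2, dropout_rate = 0)
    m <- build_model(spec, 2, seed = 91)
    fw <- model_forward(m, x, y = y, training = TRUE, grads = TRUE)
    for (pn in names(m$params)) {
      idx <- sample(length(m$params[[pn]]), min(3, length(m$params[[pn]])))
      for (i in idx) {
        mp <- m
        mp$params[[pn]][i] <- m$params[[pn]][i] + eps
        lp <- model_forward(mp, x, y = y)$loss
        mp$params[[pn]][i] <- m$params[[pn]][i] - eps
        lm_ <- model_forward(mp, x, y = y)$loss
        num <- (lp - lm_) / (2 * eps)
        ana <- fw$grads[[pn]][i]
        expect_lt(abs(num - ana), 1e-4 * max(1, abs(num)))
        # smoke: gradient exists and is finite
        expect_true(is.finite(ana))
      }
    }
  }
})

test_that("all parameters receive nonzero gradient on a random batch", {
  set.seed(95)
  m <- build_model(variant_spec("LAFNet", hidden_dim = 6, dropout_rate = 0), 2, seed = 96)
  x <- array(rnorm(8 * 10 * 2), dim = c(8, 10, 2))
  fw <- model_forward(m, x, y = rep(0:1, 4), training = TRUE, grads = TRUE)
  for (pn in names(m$params)) {
    expect_gt(max(abs(fw$grads[[pn]])), 0)
  }
})

test_that("model shape contracts and input validation", {
  m <- build_model(variant_spec("LAFNet"), 2, seed = 1)
  x <- matrix(rnorm(32 * 2), 32, 2)        # single window promoted to batch
  p <- predict(m, x)
  expect_equal(dim(p), c(1L, 2L))
  expect_equal(sum(p), 1)
  expect_gt(m$n_parameters, 0)
  expect_error(model_forward(m, array(0, c(1, 32, 3))), "channel count")
  # no-attention variant pools the final hidden state: alpha is empty
  m0 <- build_model(variant_spec("LDLFNet", hidden_dim = 4), 2, seed = 2)
  fw <- model_forward(m0, x)
  expect_equal(length(fw$alpha), 0L)
})

test_that("model checkpoints round-trip with embedded normalization stats", {
  m <- build_model(variant_spec("LAFNet", hidden_dim = 6), 2, seed = 7)
  stats <- fit_minmax(matrix(rnorm(20), ncol = 2))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path, stats = stats)
  back <- load_model(path)
  expect_equal(back$params, m$params)
  expect_equal(attr(back, "stats"), stats)
  x <- array(rnorm(2 * 8 * 2), dim = c(2, 8, 2))
  expect_equal(predict(back, x), predict(m, x))
  # conversion helpers are exact inverses
  v <- rnorm(5)
  expect_equal(ms2_to_g(g_to_ms2(v)), v)
  expect_equal(radps_to_dps(dps_to_radps(v)), v)
  expect_equal(g_to_ms2(1), 9.80665)
})
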