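#' Architecture specification of a LAFNet-family variant
#'
#' The five named variants share a stacked-LSTM encoder and a dense softmax
#' head and differ in attention kind and dropout placement:
#' \describe{
#'   \item{LAFNet}{linear attention, dropout after the attention module.}
#'   \item{TAFNet}{tanh-gated attention, dropout after attention.}
#'   \item{LDLFNet}{no attention (final-hidden-state pooling), dropout after
#'     the LSTM stack.}
#'   \item{LDLAFNet}{linear attention, dropout after the LSTM stack.}
#'   \item{LDTAFNet}{tanh-gated attention, dropout after the LSTM stack.}
#' }
#'
#' @param name one of the five variant names above, or `"custom"`.
#' @param attention `"linear"`, `"tanh"` or `"none"` (ignored unless
#'   `name = "custom"`).
#' @param dropout_after_lstm,dropout_after_attention dropout placement flags
#'   (ignored unless `name = "custom"`).
#' @param n_lstm_layers encoder depth (default 2).
#' @param hidden_dim hidden-state width Hd (default 32, a desk-scale choice
#'   that trains in minutes on one CPU; wider encoders are configurable).
#' @param dropout_rate dropout probability (default 0.3).
#' @param n_classes output classes (default 2).
#' @return A `variant_spec` list.
#' @export
variant_spec <- function(name = c("LAFNet", "TAFNet", "LDLFNet", "LDLAFNet",
                                  "LDTAFNet", "custom"),
                         attention = c("linear", "tanh", "none"),
                         dropout_after_lstm = FALSE,
                         dropout_after_attention = FALSE,
                         n_lstm_layers = 2, hidden_dim = 32,
                         dropout_rate = 0.3, n_classes = 2) {
  name <- match.arg(name)
  table <- list(
    LAFNet   = list(attention = "linear", after_lstm = FALSE, after_attn = TRUE),
    TAFNet   = list(attention = "tanh",   after_lstm = FALSE, after_attn = TRUE),
    LDLFNet  = list(attention = "none",   after_lstm = TRUE,  after_attn = FALSE),
    LDLAFNet = list(attention = "linear", after_lstm = TRUE,  after_attn = FALSE),
    LDTAFNet = list(attention = "tanh",   after_lstm = TRUE,  after_attn = FALSE)
  )
  if (name != "custom") {
    row <- table[[name]]
    attention <- row$attention
    dropout_after_lstm <- row$after_lstm
    dropout_after_attention <- row$after_attn
  } else {
    attention <- match.arg(attention)
  }
  stopifnot(hidden_dim >= 1, n_lstm_layers >= 1,
            dropout_rate >= 0, dropout_rate < 1, n_classes >= 2)
  structure(list(name = name, attention = attention,
                 dropout_after_lstm = dropout_after_lstm,
                 dropout_after_attention = dropout_after_attention,
                 n_lstm_layers = as.integer(n_lstm_layers),
                 hidden_dim = as.integer(hidden_dim),
                 dropout_rate = dropout_rate, n_classes = as.integer(n_classes)),
            class = "variant_spec")
}

#' The five canonical variant specifications
#'
#' @param ... shared overrides passed to [variant_spec()] (e.g. `hidden_dim`).
#' @return Named list of `variant_spec`s.
#' @export
all_variants <- function(...) {
  nm <- c("LAFNet", "TAFNet", "LDLFNet", "LDLAFNet", "LDTAFNet")
  setNames(lapply(nm, function(n) variant_spec(n, ...)), nm)
}

attention_code <- function(spec) {
  switch(spec$attention, none = 0L, linear = 1L, tanh = 2L)
}

#' Assemble a LAFNet-family model with initialized parameters
#'
#' Wires input -> stacked LSTM -> optional dropout -> attention (or
#' final-hidden-state pooling) -> optional dropout -> dense softmax head.
#' LSTM and dense weights use uniform Glorot-style initialization scaled by
#' fan-in; forget-gate biases start at 1 (standard practice, helps gradient
#' flow early in training).
#'
#' @param spec a [variant_spec()].
#' @param input_channels feature dimension of each time step (2 for
#'   roll/pitch, 6 for raw sensor channels).
#' @param seed RNG seed for the initialization.
#' @return A `lafnet_model`: list `spec`, `input_channels`, `params`
#'   (named list of weight arrays), `n_parameters`.
#' @export
build_model <- function(spec, input_channels, seed = NULL) {
  stopifnot(inherits(spec, "variant_spec"), input_channels >= 1)
  if (!is.null(seed)) set.seed(seed)
  H <- spec$hidden_dim
  init <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  params <- list()
  in_dim <- input_channels
  for (l in seq_len(spec$n_lstm_layers)) {
    params[[paste0("Wx", l)]] <- init(in_dim, 4 * H)
    params[[paste0("Wh", l)]] <- init(H, 4 * H)
    b <- numeric(4 * H)
    b[(H + 1):(2 * H)] <- 1  # forget gate bias
    params[[paste0("b", l)]] <- b
    in_dim <- H
  }
  params$wa <- as.numeric(init(H, 1))
  params$ba <- 0
  params$Wc <- init(H, spec$n_classes)
  params$bc <- numeric(spec$n_classes)
  n_par <- sum(vapply(params, length, numeric(1)))
  structure(list(spec = spec, input_channels = as.integer(input_channels),
                 params = params, n_parameters = n_par),
            class = "lafnet_model")
}

#' @export
print.lafnet_model <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<lafnet_model> %s: %d-layer LSTM (Hd=%d), attention=%s, %s%d params\n",
              s$name, s$n_lstm_layers, s$hidden_dim, s$attention,
              if (s$dropout_after_lstm) "dropout after LSTM, "
              else if (s$dropout_after_attention) "dropout after attention, " else "",
              x$n_parameters))
  invisible(x)
}

# windows array (n, T, C) -> cube layout (n, C, T) expected by the C++ pass
windows_to_cube <- function(x) {
  if (length(dim(x)) == 2L) x <- array(x, dim = c(1L, dim(x)))
  aperm(x, c(1, 3, 2))
}

# inverted-dropout masks; NULL when inactive
make_dropout_masks <- function(model, n, T) {
  spec <- model$spec
  H <- spec$hidden_dim
  p <- spec$dropout_rate
  mask_h <- NULL
  mask_c <- NULL
  if (p > 0 && spec$dropout_after_lstm) {
    mask_h <- array(rbinom(n * H * T, 1, 1 - p) / (1 - p), dim = c(n, H, T))
  }
  if (p > 0 && spec$dropout_after_attention) {
    mask_c <- matrix(rbinom(n * H, 1, 1 - p) / (1 - p), n, H)
  }
  list(h = mask_h, c = mask_c)
}

#' Forward pass of a LAFNet-family model on a batch of windows
#'
#' Inference is deterministic (dropout disabled); in training mode inverted
#' dropout is applied at the variant's placement and, when `y` is supplied,
#' the mean cross-entropy loss and parameter gradients are returned.
#'
#' @param model a `lafnet_model` from [build_model()].
#' @param x window array `(n, num_steps, input_channels)` (a single
#'   `(num_steps, input_channels)` matrix is promoted to a batch of one).
#' @param y optional integer class labels (0-based) of length n.
#' @param training apply dropout (default `FALSE`).
#' @param grads also compute gradients (requires `y`).
#' @return List: `probs` (n x n_classes), `alpha` (n x num_steps raw
#'   attention weights; empty matrix when the variant has no attention),
#'   `context`, `loss` (NA without labels), and `grads` when requested.
#' @export
model_forward <- function(model, x, y = NULL, training = FALSE, grads = FALSE) {
  stopifnot(inherits(model, "lafnet_model"))
  cube <- windows_to_cube(x)
  n <- dim(cube)[1]; T <- dim(cube)[3]
  if (dim(cube)[2] != model$input_channels) {
    stop("window channel count (", dim(cube)[2], ") does not match model input_channels (",
         model$input_channels, ")")
  }
  masks <- if (training) make_dropout_masks(model, n, T) else list(h = NULL, c = NULL)
  yv <- if (is.null(y)) integer(0) else as.integer(y)
  if (length(yv) && length(yv) != n) stop("labels must match the batch size")
  lafnet_batch(cube, model$params, model$spec$n_lstm_layers,
               attention_code(model$spec), yv, isTRUE(grads),
               masks$h, masks$c)
}

#' Predicted class probabilities for a window array
#'
#' @param object a `lafnet_model`.
#' @param x window array `(n, num_steps, input_channels)`.
#' @param ... unused.
#' @return Matrix (n x n_classes) of class probabilities.
#' @export
predict.lafnet_model <- function(object, x, ...) {
  model_forward(object, x)$probs
}

# ---- Reference (plain-R) building blocks -------------------------------
# Single-sequence implementations of the network's stages. They define the
# operations' semantics independently of the batched compiled pass and are
# cross-checked against it in the test suite.

#' Stacked-LSTM hidden sequence for a single window (reference)
#'
#' Standard LSTM recursion (gates input/forget/cell/output, zero initial
#' state), layers stacked so layer l consumes layer l-1's hidden sequence;
#' returns the top layer's full hidden sequence.
#'
#' @param x `num_steps x input_channels` feature matrix.
#' @param params named parameter list as in [build_model()] (`Wx1`, `Wh1`,
#'   `b1`, ...).
#' @param n_lstm_layers encoder depth.
#' @return `num_steps x hidden_dim` matrix of top-layer hidden states.
#' @export
lstm_encode <- function(x, params, n_lstm_layers = 2) {
  x <- as.matrix(x)
  if (nrow(x) < 1) stop("empty sequence")
  sigm <- function(v) 1 / (1 + exp(-v))
  input <- x
  H <- length(params$wa)
  for (l in seq_len(n_lstm_layers)) {
    Wx <- params[[paste0("Wx", l)]]
    Wh <- params[[paste0("Wh", l)]]
    b <- params[[paste0("b", l)]]
    h <- numeric(H); c <- numeric(H)
    out <- matrix(0, nrow(input), H)
    for (t in seq_len(nrow(input))) {
      pre <- drop(input[t, ] %*% Wx + h %*% Wh) + b
      i <- sigm(pre[1:H]); f <- sigm(pre[(H + 1):(2 * H)])
      g <- tanh(pre[(2 * H + 1):(3 * H)]); o <- sigm(pre[(3 * H + 1):(4 * H)])
      c <- f * c + i * g
      h <- o * tanh(c)
      out[t, ] <- h
    }
    input <- out
  }
  input
}

#' Linear attention over a hidden sequence (reference)
#'
#' Raw per-step weights `a_t = wa . h_t + ba` (no normalization in the
#' forward pass) and context vector `sum_t a_t h_t`.
#'
#' @param H `num_steps x hidden_dim` hidden sequence.
#' @param wa length-`hidden_dim` attention weight vector.
#' @param ba scalar attention bias.
#' @return List `a` (per-step weights) and `context` (hidden_dim vector).
#' @export
attend_linear <- function(H, wa, ba) {
  H <- as.matrix(H)
  if (nrow(H) < 1) stop("empty hidden sequence")
  a <- drop(H %*% wa) + ba
  list(a = a, context = drop(crossprod(H, a)))
}

#' Tanh-gated attention over a hidden sequence (reference)
#'
#' As [attend_linear()] with the weights passed through a tanh gate:
#' `a_t = tanh(wa . h_t + ba)`, so every weight lies in `[-1, 1]`.
#'
#' @inheritParams attend_linear
#' @return List `a` and `context`.
#' @export
attend_tanh <- function(H, wa, ba) {
  H <- as.matrix(H)
  if (nrow(H) < 1) stop("empty hidden sequence")
  a <- tanh(drop(H %*% wa) + ba)
  list(a = a, context = drop(crossprod(H, a)))
}

#' Dense softmax classification head (reference)
#'
#' `z = softmax(W'x + b)`; always a probability vector.
#'
#' @param x context/feature vector (length `hidden_dim`).
#' @param Wc `hidden_dim x n_classes` weight matrix.
#' @param bc length-`n_classes` bias.
#' @return Probability vector summing to 1.
#' @export
classify <- function(x, Wc, bc) {
  logits <- drop(x %*% Wc) + bc
  e <- exp(logits - max(logits))
  e / sum(e)
}

#' Save / load a model checkpoint
#'
#' Checkpoints carry the variant specification, the input channel count, the
#' trained parameters and (optionally) the preprocessing statistics, so a
#' saved model can be applied to new recordings without the training data.
#'
#' @param model a `lafnet_model`.
#' @param path destination file.
#' @param stats optional `minmax_stats` to embed (e.g. `dataset$stats`).
#' @return `path` invisibly; `load_model()` returns the `lafnet_model` with
#'   attribute `"stats"` if one was embedded.
#' @export
save_model <- function(model, path, stats = NULL) {
  stopifnot(inherits(model, "lafnet_model"))
  saveRDS(list(model = model, stats = stats,
               version = as.character(utils::packageVersion("airspiral"))),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$model) || !inherits(obj$model, "lafnet_model")) {
    stop("not an airspiral model checkpoint: ", path)
  }
  m <- obj$model
  attr(m, "stats") <- obj$stats
  m
}
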