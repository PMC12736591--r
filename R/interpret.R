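#' Normalize per-step attention weights to unit mass
#'
#' Divides each window's raw attention weights by their sum so that they
#' form a distribution over time steps. Linear attention can emit negative
#' or sign-mixed weights, for which sum-normalization is ill-posed; such
#' windows are normalized by absolute value instead, with a warning (once
#' per call).
#'
#' @param alpha numeric vector of one window's raw weights, or an
#'   `n x num_steps` matrix of per-window weights.
#' @return Object of the same shape; every row sums to 1.
#' @export
normalize_attention <- function(alpha) {
  one <- function(a) {
    s <- sum(a)
    if (s <= 0 || any(a < 0)) {
      a <- abs(a)
      s <- sum(a)
      if (s == 0) stop("cannot normalize all-zero attention weights")
      attr(a, "rectified") <- TRUE
    }
    a / s
  }
  if (is.matrix(alpha)) {
    rect <- FALSE
    out <- t(apply(alpha, 1L, function(r) {
      v <- one(r)
      if (isTRUE(attr(v, "rectified"))) rect <<- TRUE
      as.numeric(v)
    }))
    if (rect) warning("sign-mixed attention weights normalized by absolute value")
    return(out)
  }
  v <- one(alpha)
  if (isTRUE(attr(v, "rectified"))) {
    warning("sign-mixed attention weights normalized by absolute value")
    attr(v, "rectified") <- NULL
  }
  as.numeric(v)
}

#' Upsample normalized attention to the raw sampling rate and smooth
#'
#' Linear interpolation of the per-step weights to the raw-rate length of
#' the window, followed by light Savitzky-Golay smoothing (window 51,
#' polynomial order 3). When the upsampled trace is not longer than the
#' smoothing window the smoothing is skipped with a message.
#'
#' @param alpha_norm normalized per-step weights of one window (length
#'   `num_steps`).
#' @param window_span_samples window span at the raw rate (e.g. `num_steps`
#'   windows of raw samples map 1:1; an attention window summarizing a span
#'   of raw samples upsamples to that span).
#' @param sg_window,sg_order Savitzky-Golay filter length (odd, default 51)
#'   and polynomial order (default 3).
#' @return Numeric vector of length `window_span_samples`.
#' @export
upsample_smooth <- function(alpha_norm, window_span_samples,
                            sg_window = 51, sg_order = 3) {
  stopifnot(length(alpha_norm) >= 2, window_span_samples >= length(alpha_norm))
  up <- approx(x = seq_along(alpha_norm), y = alpha_norm,
               xout = seq(1, length(alpha_norm), length.out = window_span_samples))$y
  if (length(up) <= sg_window) {
    message("upsampled length <= smoothing window; smoothing skipped")
    return(up)
  }
  as.numeric(signal::sgolayfilt(up, p = sg_order, n = sg_window))
}

#' Channel-wise importance percentages from attention
#'
#' The model's attention weight is a per-step scalar; per-channel weights
#' are constructed by apportioning each step's normalized attention across
#' input axes by their normalized magnitudes,
#' `alpha[t, c] = alpha_norm[t] * |x[t, c]| / sum_c |x[t, c]|` (summing over
#' channels recovers the temporal weights). Importance is the time average
#' `I_c = mean_t alpha[t, c]`, normalized to percentages per sequence.
#'
#' @param alpha_norm normalized per-step attention weights (length
#'   `num_steps`), or an already-apportioned `num_steps x n_channels` weight
#'   matrix (then used as is).
#' @param x the window's `num_steps x n_channels` input features (required
#'   when `alpha_norm` is a vector).
#' @return Named numeric vector of per-channel percentages summing to 100.
#' @export
channel_importance <- function(alpha_norm, x = NULL) {
  if (is.matrix(alpha_norm)) {
    ac <- alpha_norm
  } else {
    if (is.null(x)) stop("x is required to apportion scalar attention across channels")
    x <- as.matrix(x)
    stopifnot(nrow(x) == length(alpha_norm))
    mag <- abs(x)
    rs <- rowSums(mag)
    share <- ifelse(rs > 0, 1, 0) * mag / ifelse(rs > 0, rs, 1)
    share[rs == 0, ] <- 1 / ncol(x)  # no signal: spread evenly
    ac <- alpha_norm * share
  }
  imp <- colMeans(ac)
  if (sum(imp) == 0) stop("zero total attention mass")
  pct <- 100 * imp / sum(imp)
  if (!is.null(colnames(ac))) names(pct) <- colnames(ac)
  pct
}

#' Attention report for a trained model on a set of windows
#'
#' Runs the model, extracts raw per-step attention weights, normalizes them
#' per window, upsamples/smooths each to the raw sampling rate and computes
#' per-window channel importances plus group summary statistics (mean and
#' spread of the per-step attention profile per predicted class).
#'
#' @param model a trained `lafnet_model` with an attention variant.
#' @param x window array `(n, num_steps, n_channels)`.
#' @param raw_span_samples raw-rate span each window covers (default:
#'   `num_steps`, i.e. windows taken directly at the raw rate are smoothed
#'   at their own length).
#' @param channel_names optional channel labels.
#' @return An `attention_report`: `alpha` (raw), `alpha_norm`,
#'   `alpha_smooth` (n x raw_span matrix), `channel_importance`
#'   (n x n_channels, rows sum to 100), `pred` (predicted class per window),
#'   `group_stats` (per-class mean/sd/min/max attention per step).
#' @export
attention_report <- function(model, x, raw_span_samples = NULL,
                             channel_names = NULL) {
  stopifnot(inherits(model, "lafnet_model"))
  if (model$spec$attention == "none") {
    stop("variant '", model$spec$name, "' has no attention module")
  }
  if (length(dim(x)) == 2L) x <- array(x, dim = c(1L, dim(x)))
  fw <- model_forward(model, x)
  alpha <- fw$alpha
  T <- ncol(alpha)
  if (is.null(raw_span_samples)) raw_span_samples <- T
  alpha_norm <- suppressWarnings(normalize_attention(alpha))
  alpha_smooth <- t(apply(alpha_norm, 1L, function(a)
    suppressMessages(upsample_smooth(a, raw_span_samples))))
  n_ch <- dim(x)[3]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(n_ch))
  imp <- t(vapply(seq_len(dim(x)[1]), function(i) {
    xi <- matrix(x[i, , ], nrow = T, ncol = n_ch)
    channel_importance(alpha_norm[i, ], xi)
  }, numeric(n_ch)))
  colnames(imp) <- channel_names
  pred <- max.col(fw$probs) - 1L
  group_stats <- lapply(split(seq_len(nrow(alpha_norm)), pred), function(idx) {
    a <- alpha_norm[idx, , drop = FALSE]
    data.frame(step = seq_len(T), mean = colMeans(a),
               sd = apply(a, 2, sd), min = apply(a, 2, min),
               max = apply(a, 2, max))
  })
  structure(list(alpha = alpha, alpha_norm = alpha_norm,
                 alpha_smooth = alpha_smooth, channel_importance = imp,
                 pred = pred, group_stats = group_stats),
            class = "attention_report")
}

#' @export
print.attention_report <- function(x, ...) {
  cat(sprintf("<attention_report> %d windows x %d steps; mean channel importance:\n",
              nrow(x$alpha_norm), ncol(x$alpha_norm)))
  print(round(colMeans(x$channel_importance), 2))
  invisible(x)
}

#' Overlay table of attention intensity on an attitude trace
#'
#' Aligns a window's smoothed attention trace with the corresponding raw
#' roll/pitch samples, producing the per-sample table used for
#' color-intensity overlays, plus histogram and per-step box summaries.
#'
#' @param report an `attention_report`.
#' @param window_index which window of the report to overlay.
#' @param roll,pitch raw-rate angle samples spanning the window (lengths
#'   equal to `ncol(report$alpha_smooth)`).
#' @param t optional time stamps (seconds), same length.
#' @return List: `table` (data frame `t, roll_deg, pitch_deg, attention`),
#'   `histogram` (of the window's normalized weights), `step_summary`
#'   (five-number summary per step over all report windows).
#' @export
attention_overlay <- function(report, window_index, roll, pitch, t = NULL) {
  stopifnot(inherits(report, "attention_report"))
  att <- report$alpha_smooth[window_index, ]
  if (length(roll) != length(att) || length(pitch) != length(att)) {
    stop("roll/pitch length (", length(roll), ") must equal the smoothed attention length (",
         length(att), ")")
  }
  if (is.null(t)) t <- seq_along(att)
  tab <- data.frame(t = t, roll_deg = roll, pitch_deg = pitch, attention = att)
  h <- graphics::hist(report$alpha_norm[window_index, ], plot = FALSE)
  steps <- apply(report$alpha_norm, 2L, quantile,
                 probs = c(0, 0.25, 0.5, 0.75, 1))
  list(table = tab, histogram = h,
       step_summary = data.frame(step = seq_len(ncol(report$alpha_norm)),
                                 t(steps)))
}

#' Recording-level attention co-location with tremor bursts
#'
#' Pools one recording's windows: the raw attention weights are normalized
#' by absolute value over the whole set (total mass 1 across the recording),
#' every (window, step) pair is mapped to its time stamp, and the mean
#' normalized weight inside ground-truth burst intervals is compared with
#' the mean outside. Tremor bursts (~1 s) are much longer than one window
#' (97 ms at 330 Hz with 32 steps), so attention mass concentrates on
#' burst-covered windows; this recording-level statistic captures that,
#' whereas the within-window contrast of [burst_attention()] is dominated by
#' positional effects at sub-burst window scales.
#'
#' @param alpha `n_windows x num_steps` raw attention weights of one
#'   recording's windows.
#' @param window_start_s window start times in seconds.
#' @param intervals `[start, end]` burst matrix for the recording, seconds.
#' @param sample_rate_hz raw sampling rate (default 330).
#' @return List: `mean_inside`, `mean_outside`, `ratio`
#'   (`mean_inside / mean_outside`), `n_inside`, `n_outside` step counts.
#' @export
burst_colocation <- function(alpha, window_start_s, intervals,
                             sample_rate_hz = 330) {
  stopifnot(is.matrix(alpha), nrow(alpha) == length(window_start_s))
  w <- abs(alpha)
  total <- sum(w)
  if (total == 0) stop("zero total attention mass")
  w <- w / total
  T <- ncol(alpha)
  inside <- matrix(FALSE, nrow(alpha), T)
  for (i in seq_len(nrow(alpha))) {
    tt <- window_start_s[i] + (seq_len(T) - 1) / sample_rate_hz
    if (!is.null(intervals) && nrow(intervals) > 0) {
      for (k in seq_len(nrow(intervals))) {
        inside[i, ] <- inside[i, ] | (tt >= intervals[k, 1] & tt <= intervals[k, 2])
      }
    }
  }
  n_in <- sum(inside); n_out <- sum(!inside)
  mi <- if (n_in > 0) sum(w[inside]) / n_in else NA_real_
  mo <- if (n_out > 0) sum(w[!inside]) / n_out else NA_real_
  list(mean_inside = mi, mean_outside = mo, ratio = mi / mo,
       n_inside = n_in, n_outside = n_out)
}

#' Mean attention inside versus outside tremor-burst intervals
#'
#' Co-location statistic for simulated data with ground-truth annotations:
#' for each window overlapping at least one burst boundary, compares the
#' mean normalized attention over steps falling inside burst intervals with
#' the mean over outside steps.
#'
#' @param alpha_norm `n x num_steps` normalized attention weights.
#' @param window_start_s window start times in seconds.
#' @param burst_intervals_list list (per window) of `[start, end]` burst
#'   matrices in seconds, or a single matrix shared by all windows.
#' @param sample_rate_hz raw sampling rate.
#' @param stride_samples raw samples per attention step (default 1:
#'   window steps are raw samples).
#' @return Data frame per window: `mean_inside`, `mean_outside`,
#'   `n_inside`, `n_outside` (NA means the window lies entirely on one
#'   side).
#' @export
burst_attention <- function(alpha_norm, window_start_s, burst_intervals_list,
                            sample_rate_hz = 330, stride_samples = 1) {
  n <- nrow(alpha_norm)
  T <- ncol(alpha_norm)
  if (is.matrix(burst_intervals_list)) {
    burst_intervals_list <- rep(list(burst_intervals_list), n)
  }
  stopifnot(length(window_start_s) == n, length(burst_intervals_list) == n)
  out <- data.frame(mean_inside = rep(NA_real_, n), mean_outside = NA_real_,
                    n_inside = 0L, n_outside = 0L)
  for (i in seq_len(n)) {
    tt <- window_start_s[i] + (seq_len(T) - 1) * stride_samples / sample_rate_hz
    iv <- burst_intervals_list[[i]]
    inside <- rep(FALSE, T)
    if (!is.null(iv) && nrow(iv) > 0) {
      for (k in seq_len(nrow(iv))) inside <- inside | (tt >= iv[k, 1] & tt <= iv[k, 2])
    }
    out$n_inside[i] <- sum(inside)
    out$n_outside[i] <- sum(!inside)
    if (any(inside)) out$mean_inside[i] <- mean(alpha_norm[i, inside])
    if (any(!inside)) out$mean_outside[i] <- mean(alpha_norm[i, !inside])
  }
  out
}
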