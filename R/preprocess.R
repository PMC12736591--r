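#' Fit per-feature min-max normalization statistics
#'
#' Learns each feature's minimum and maximum over the fitting partition
#' (by default the training windows only, so no information from validation
#' or test data enters the scaling).
#'
#' @param x numeric matrix (rows = samples, columns = features) or a 3-d
#'   window array `(n_windows, num_steps, n_channels)`.
#' @return A `minmax_stats` list with vectors `x_min`, `x_max`.
#' @export
fit_minmax <- function(x) {
  if (length(dim(x)) == 3L) {
    d <- dim(x)
    x <- matrix(aperm(x, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
  }
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("fitting partition is empty")
  structure(list(x_min = apply(x, 2L, min), x_max = apply(x, 2L, max)),
            class = "minmax_stats")
}

#' Apply min-max normalization
#'
#' Affine map `x' = (x - x_min) / (x_max - x_min)` per feature, preserving
#' proportional relationships within each feature. Zero-range (constant)
#' features map to 0 with a warning. Values outside the fitted range (e.g.
#' test data scaled with train statistics) legitimately fall outside
#' `[0, 1]`.
#'
#' @param x numeric matrix or 3-d window array; trailing dimension indexes
#'   features.
#' @param stats a `minmax_stats` from [fit_minmax()].
#' @return Normalized object with the same shape as `x`.
#' @export
apply_minmax <- function(x, stats) {
  stopifnot(inherits(stats, "minmax_stats"))
  rng <- stats$x_max - stats$x_min
  degenerate <- rng == 0
  if (any(degenerate)) {
    warning("zero-range feature(s) ", paste(which(degenerate), collapse = ", "),
            " mapped to 0")
    rng[degenerate] <- 1
  }
  scale_feature <- function(v, j) {
    out <- (v - stats$x_min[j]) / rng[j]
    if (degenerate[j]) out[] <- 0
    out
  }
  if (length(dim(x)) == 3L) {
    for (j in seq_len(dim(x)[3])) x[, , j] <- scale_feature(x[, , j], j)
    return(x)
  }
  x <- as.matrix(x)
  for (j in seq_len(ncol(x))) x[, j] <- scale_feature(x[, j], j)
  x
}

#' Literal sliding-window subsequence count
#'
#' The segmentation formula `num_subseqs = floor((data_len - 1) / num_steps)`
#' (non-overlapping stride equal to the window length, with one sample
#' reserved). This differs by one from the number of complete windows that
#' fit in `data_len` exactly when `num_steps` divides `data_len`; both counts
#' are reported by [segment_windows()].
#'
#' @param data_len series length in samples.
#' @param num_steps window length in samples.
#' @return Integer count.
#' @export
eq_subseq_count <- function(data_len, num_steps) {
  as.integer(floor((data_len - 1) / num_steps))
}

#' Segment a multichannel series into fixed-length windows
#'
#' Emits complete windows starting at offsets `0, stride, 2*stride, ...`
#' (no padding; any tail remainder is dropped). With `stride = num_steps`
#' the emitted count is `floor(data_len / num_steps)`; the literal
#' subsequence-count formula [eq_subseq_count()] is attached as attribute
#' `"formula_count"` — the two agree unless `num_steps` divides `data_len`.
#'
#' @param series numeric matrix (rows = time steps, columns = channels) or
#'   vector.
#' @param num_steps window length in samples (default 32).
#' @param stride hop between window starts, `1 <= stride <= num_steps`
#'   (default `num_steps`, i.e. non-overlapping).
#' @return Array `(n_windows, num_steps, n_channels)` with attribute
#'   `"formula_count"`.
#' @export
segment_windows <- function(series, num_steps = 32, stride = num_steps) {
  if (is.vector(series)) series <- matrix(series, ncol = 1)
  series <- as.matrix(series)
  data_len <- nrow(series)
  stopifnot(num_steps >= 1, stride >= 1, stride <= num_steps)
  if (data_len < num_steps) {
    stop("series length (", data_len, ") shorter than window length (", num_steps, ")")
  }
  starts <- seq(1L, data_len - num_steps + 1L, by = stride)
  out <- array(NA_real_, dim = c(length(starts), num_steps, ncol(series)))
  for (i in seq_along(starts)) {
    out[i, , ] <- series[starts[i]:(starts[i] + num_steps - 1L), , drop = FALSE]
  }
  attr(out, "formula_count") <- eq_subseq_count(data_len, num_steps)
  out
}

#' Subject-level train/validation/test assignment
#'
#' Assigns every subject — hence all of its windows — to exactly one split.
#' Split sizes are the rounded global fractions (10 subjects at 8:1:1 give
#' an 8/1/1 assignment). Subjects are shuffled with a seeded RNG within each
#' class and the classes interleaved before cutting, so each split's class
#' composition stays close to the cohort's. Errors if the resulting training
#' split contains a single class (no classifier can be fitted).
#'
#' @param labels per-subject class labels (0/1 or factor/character).
#' @param fractions length-3 numeric `c(train, val, test)` summing to 1
#'   (default `c(0.8, 0.1, 0.1)`).
#' @param seed RNG seed.
#' @return Character vector (`"train"`, `"val"`, `"test"`) per subject.
#' @export
split_subjects <- function(labels, fractions = c(0.8, 0.1, 0.1), seed = 1) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8,
            all(fractions >= 0))
  n <- length(labels)
  set.seed(seed)
  # shuffle within class, then interleave classes round-robin
  classes <- sample(unique(labels))
  pools <- lapply(classes, function(cl) {
    idx <- which(labels == cl)
    idx[sample.int(length(idx))]
  })
  order_idx <- integer(0)
  while (any(lengths(pools) > 0)) {
    for (k in seq_along(pools)) {
      if (length(pools[[k]]) > 0) {
        order_idx <- c(order_idx, pools[[k]][1])
        pools[[k]] <- pools[[k]][-1]
      }
    }
  }
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  if (n_train + n_val > n) n_val <- n - n_train
  n_test <- n - n_train - n_val
  split <- character(n)
  split[order_idx] <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
  if (length(unique(labels[split == "train"])) < length(unique(labels))) {
    stop("training split is missing a class at the requested fractions; ",
         "increase the training fraction or the number of subjects per class")
  }
  split
}

#' Roll/pitch (or raw six-axis) feature matrices for a cohort
#'
#' For `channels = "roll_pitch"` each recording is passed through the
#' attitude Kalman filter ([estimate_attitude()]) and the two filtered angle
#' traces become the feature columns; `"raw_six"` uses the six sensor
#' channels directly.
#'
#' @param cohort a cohort from [generate_cohort()], or a list of
#'   [imu_recording]s.
#' @param channels `"roll_pitch"` (default) or `"raw_six"`.
#' @return List of numeric feature matrices, one per subject, with
#'   attributes `"label"` and `"subject_id"` on each.
#' @export
cohort_features <- function(cohort, channels = c("roll_pitch", "raw_six")) {
  channels <- match.arg(channels)
  lapply(cohort, function(s) {
    rec <- if (inherits(s, "imu_recording")) s else s$recording
    f <- if (channels == "roll_pitch") {
      att <- estimate_attitude(rec)
      cbind(roll = att$roll_deg, pitch = att$pitch_deg)
    } else {
      as.matrix(rec$data[, c("ax", "ay", "az", "gx", "gy", "gz")])
    }
    attr(f, "label") <- rec$label
    attr(f, "subject_id") <- rec$subject_id
    f
  })
}

#' Build a windowed, normalized, split classification dataset
#'
#' Segments each subject's feature matrix into fixed-length windows, labels
#' every window with its source recording's class (healthy = 0, pd = 1),
#' assigns splits at the subject level (seeded, stratified; no subject
#' appears in two splits), fits min-max statistics on the training windows
#' only and applies them to all windows.
#'
#' @param features list of per-subject feature matrices from
#'   [cohort_features()] (each carrying `"label"` and `"subject_id"`
#'   attributes).
#' @param num_steps window length in samples (default 32).
#' @param stride hop between windows (default `num_steps`).
#' @param fractions train/val/test fractions (default `c(0.8, 0.1, 0.1)`).
#' @param seed RNG seed for the subject shuffle.
#' @param normalize fit-and-apply min-max scaling (default `TRUE`).
#' @param sample_rate_hz raw sampling rate, used only to attach window start
#'   times in seconds (default 330).
#' @return A `windowed_dataset`: list with `windows` (array
#'   `(n, num_steps, n_channels)`), `labels` (integer 0/1), `subject_id`,
#'   `split` (per window), `stats` (`minmax_stats` or `NULL`),
#'   `window_start_s` (window start time, seconds) and `config`.
#' @export
make_dataset <- function(features, num_steps = 32, stride = num_steps,
                         fractions = c(0.8, 0.1, 0.1), seed = 1,
                         normalize = TRUE, sample_rate_hz = 330) {
  stopifnot(length(features) > 0)
  subj_labels <- vapply(features, function(f) attr(f, "label"), character(1))
  if (length(unique(subj_labels)) < 2) stop("both classes must be present in the cohort")
  subj_ids <- vapply(features, function(f) attr(f, "subject_id"), character(1))
  split_by_subj <- split_subjects(subj_labels, fractions, seed)

  wins <- vector("list", length(features))
  meta <- vector("list", length(features))
  for (i in seq_along(features)) {
    w <- segment_windows(features[[i]], num_steps, stride)
    wins[[i]] <- w
    nw <- dim(w)[1]
    meta[[i]] <- data.frame(
      label = ifelse(subj_labels[i] == "pd", 1L, 0L),
      subject_id = rep(subj_ids[i], nw),
      split = rep(split_by_subj[i], nw),
      window_start_s = (seq_len(nw) - 1) * stride / sample_rate_hz)
  }
  n_tot <- sum(vapply(wins, function(w) dim(w)[1], integer(1)))
  n_ch <- dim(wins[[1]])[3]
  windows <- array(NA_real_, dim = c(n_tot, num_steps, n_ch))
  at <- 1L
  for (w in wins) {
    nw <- dim(w)[1]
    windows[at:(at + nw - 1L), , ] <- w
    at <- at + nw
  }
  meta <- do.call(rbind, meta)

  stats <- NULL
  if (normalize) {
    train_idx <- meta$split == "train"
    if (!any(train_idx)) stop("training split is empty")
    stats <- fit_minmax(windows[train_idx, , , drop = FALSE])
    windows <- apply_minmax(windows, stats)
  }
  structure(list(windows = windows, labels = meta$label,
                 subject_id = meta$subject_id, split = meta$split,
                 window_start_s = meta$window_start_s, stats = stats,
                 config = list(num_steps = num_steps, stride = stride,
                               fractions = fractions, seed = seed,
                               sample_rate_hz = sample_rate_hz)),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf("<windowed_dataset> %d windows of %d x %d, splits: %s\n",
              dim(x$windows)[1], dim(x$windows)[2], dim(x$windows)[3],
              paste(names(table(x$split)), table(x$split), sep = "=", collapse = " ")))
  invisible(x)
}

#' Subset a windowed dataset by split
#'
#' @param dataset a `windowed_dataset`.
#' @param split `"train"`, `"val"` or `"test"`.
#' @return List `x` (window array), `y` (labels), `subject_id`,
#'   `window_start_s`.
#' @export
dataset_split <- function(dataset, split) {
  idx <- which(dataset$split == split)
  if (length(idx) == 0L) stop("split '", split, "' is empty")
  list(x = dataset$windows[idx, , , drop = FALSE], y = dataset$labels[idx],
       subject_id = dataset$subject_id[idx],
       window_start_s = dataset$window_start_s[idx])
}
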