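#' Construct a six-axis IMU recording
#'
#' An `imu_recording` holds an ordered stream of six-axis packets from a
#' wrist-worn inertial measurement unit: triaxial linear acceleration
#' (`ax`, `ay`, `az`, in g) and triaxial angular velocity (`gx`, `gy`, `gz`,
#' in deg/s). Timestamps are reconstructed from the nominal sample rate
#' (the packet format stores no clock): sample `i` has `t = (i-1)/rate`.
#'
#' @param data data frame or matrix with columns `ax, ay, az, gx, gy, gz`
#'   (extra columns ignored; a bare 6-column matrix is accepted in that order).
#' @param sample_rate_hz nominal sampling rate in Hz (default 330).
#' @param label subject class: `"healthy"`, `"pd"` or `"unknown"`.
#' @param subject_id opaque subject identifier.
#' @param task drawing task: `"rest"`, `"line"` or `"spiral"`.
#' @return An object of class `imu_recording`: a list with elements `data`
#'   (data frame `t, ax, ay, az, gx, gy, gz`), `sample_rate_hz`, `label`,
#'   `subject_id`, `task`.
#' @export
imu_recording <- function(data, sample_rate_hz = 330, label = "unknown",
                          subject_id = "anon", task = "spiral") {
  chans <- c("ax", "ay", "az", "gx", "gy", "gz")
  if (is.matrix(data)) {
    if (ncol(data) != 6L) stop("matrix input must have exactly 6 columns (ax ay az gx gy gz)")
    data <- as.data.frame(data)
    names(data) <- chans
  }
  if (!all(chans %in% names(data))) {
    stop("data must contain columns ", paste(chans, collapse = ", "))
  }
  if (nrow(data) == 0L) stop("recording must contain at least one sample")
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0) stop("sample_rate_hz must be positive")
  label <- match.arg(label, c("healthy", "pd", "unknown"))
  task <- match.arg(task, c("rest", "line", "spiral"))
  n <- nrow(data)
  out <- data.frame(t = (seq_len(n) - 1) / sample_rate_hz, data[, chans, drop = FALSE])
  rownames(out) <- NULL
  structure(
    list(data = out, sample_rate_hz = sample_rate_hz, label = label,
         subject_id = subject_id, task = task),
    class = "imu_recording"
  )
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %d samples @ %g Hz (%.2f s)\n",
              nrow(x$data), x$sample_rate_hz, nrow(x$data) / x$sample_rate_hz))
  cat(sprintf("  subject: %s  label: %s  task: %s\n", x$subject_id, x$label, x$task))
  invisible(x)
}

#' @export
length.imu_recording <- function(x) nrow(x$data)

#' @export
as.data.frame.imu_recording <- function(x, ...) x$data

#' Read a six-axis packet text file
#'
#' Parses the plain-text packet stream format: one packet per line, six
#' numeric fields in the order `ax ay az gx gy gz`, separated by whitespace
#' or commas (dialect auto-detected). Timestamps are reconstructed from the
#' nominal sample rate.
#'
#' @param path path to the text file.
#' @param sample_rate_hz nominal sampling rate (default 330 Hz).
#' @inheritParams imu_recording
#' @return An [imu_recording].
#' @export
read_recording <- function(path, sample_rate_hz = 330, label = "unknown",
                           subject_id = NULL, task = "spiral") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty packet file: ", path)
  mat <- matrix(NA_real_, nrow = length(lines), ncol = 6L)
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
    tok <- tok[nzchar(tok)]
    if (length(tok) != 6L) {
      stop(sprintf("parse error at line %d of %s: expected 6 fields, found %d",
                   line_no[i], path, length(tok)))
    }
    v <- suppressWarnings(as.numeric(tok))
    if (anyNA(v)) {
      stop(sprintf("parse error at line %d of %s: non-numeric token '%s'",
                   line_no[i], path, tok[which(is.na(v))[1]]))
    }
    mat[i, ] <- v
  }
  if (is.null(subject_id)) subject_id <- tools::file_path_sans_ext(basename(path))
  imu_recording(mat, sample_rate_hz = sample_rate_hz, label = label,
                subject_id = subject_id, task = task)
}

#' Write a recording in the six-column packet text dialect
#'
#' Emits the same format [read_recording()] accepts (one packet per line,
#' `ax ay az gx gy gz`, space-separated); reading the file back recovers the
#' channel values up to text formatting precision.
#'
#' @param rec an [imu_recording].
#' @param path destination file path.
#' @param digits significant digits to keep (default 10).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, digits = 10) {
  stopifnot(inherits(rec, "imu_recording"))
  if (nrow(rec$data) == 0L) stop("cannot write an empty recording")
  m <- as.matrix(rec$data[, c("ax", "ay", "az", "gx", "gy", "gz")])
  lines <- apply(m, 1L, function(r) paste(sprintf("%.*g", digits, r),
                                          collapse = " "))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) stop("cannot write to ", path, ": ", conditionMessage(e)))
  invisible(path)
}

#' Default per-channel plausibility bounds
#'
#' Closed intervals matching common IMU full-scale ranges: |acceleration|
#' <= 16 g, |angular rate| <= 2000 deg/s.
#' @return Named list of `c(lo, hi)` per channel.
#' @export
default_channel_limits <- function() {
  list(ax = c(-16, 16), ay = c(-16, 16), az = c(-16, 16),
       gx = c(-2000, 2000), gy = c(-2000, 2000), gz = c(-2000, 2000))
}

#' Remove abnormal or invalid samples from a recording
#'
#' Drops packets containing non-finite values or values outside the
#' per-channel plausibility bounds; surviving order is preserved and
#' timestamps are rebuilt from the nominal rate. Cleaning is idempotent.
#'
#' @param rec an [imu_recording].
#' @param limits named list of closed intervals per channel
#'   (default [default_channel_limits()]).
#' @return The cleaned recording, with attribute `"removal_report"`: a list
#'   with counts `n_input`, `n_kept`, `n_removed`, `n_nonfinite`,
#'   `n_out_of_range`.
#' @export
clean_recording <- function(rec, limits = default_channel_limits()) {
  stopifnot(inherits(rec, "imu_recording"))
  chans <- c("ax", "ay", "az", "gx", "gy", "gz")
  m <- as.matrix(rec$data[, chans])
  nonfinite <- !apply(m, 1L, function(r) all(is.finite(r)))
  out_of_range <- rep(FALSE, nrow(m))
  for (ch in chans) {
    lim <- limits[[ch]]
    v <- m[, ch]
    bad <- is.finite(v) & (v < lim[1] | v > lim[2])
    out_of_range <- out_of_range | bad
  }
  out_of_range <- out_of_range & !nonfinite  # count each sample once, by reason
  drop <- nonfinite | out_of_range
  if (all(drop)) stop("all samples removed during cleaning")
  kept <- imu_recording(rec$data[!drop, chans, drop = FALSE],
                        sample_rate_hz = rec$sample_rate_hz, label = rec$label,
                        subject_id = rec$subject_id, task = rec$task)
  attr(kept, "removal_report") <- list(
    n_input = nrow(m), n_kept = sum(!drop), n_removed = sum(drop),
    n_nonfinite = sum(nonfinite), n_out_of_range = sum(out_of_range)
  )
  kept
}

#' Write a cleaning removal report as JSON
#'
#' @param rec a recording returned by [clean_recording()].
#' @param path destination JSON path.
#' @return `path`, invisibly.
#' @export
write_removal_report <- function(rec, path) {
  rep <- attr(rec, "removal_report")
  if (is.null(rep)) rep <- list(n_input = nrow(rec$data), n_kept = nrow(rec$data),
                                n_removed = 0L, n_nonfinite = 0L, n_out_of_range = 0L)
  jsonlite::write_json(rep, path, auto_unbox = TRUE)
  invisible(path)
}

#' Unit conversion helpers
#'
#' The pipeline is unit-consistent internally (acceleration in g, angular
#' rate in deg/s — the sensor's native conventions); these helpers convert
#' to SI for interoperability.
#'
#' @param x numeric vector.
#' @return Converted vector.
#' @name unit-conversions
NULL

#' @rdname unit-conversions
#' @export
g_to_ms2 <- function(x) x * 9.80665

#' @rdname unit-conversions
#' @export
ms2_to_g <- function(x) x / 9.80665

#' @rdname unit-conversions
#' @export
dps_to_radps <- function(x) x * pi / 180

#' @rdname unit-conversions
#' @export
radps_to_dps <- function(x) x * 180 / pi
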