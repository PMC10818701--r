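#' Signal-vector-magnitude features
#'
#' `svma()` is the signal vector magnitude of acceleration: the Euclidean
#' norm of the three body-axis accelerations, approximately 1 g at rest,
#' dipping toward 0 in free fall and spiking at ground impact.
#' `delta_svma()` is the first difference of an SVMa series between
#' consecutive time points, large for abrupt movements.  `svmo()` is the
#' signal vector magnitude of the rotation angles (pitch, roll), which
#' tracks posture change; the Euclidean norm of the two angles is the
#' implemented reading, since no closed form is standard.
#'
#' @param ax,ay,az acceleration per axis in g (vectorised; finite).
#' @return `svma()` and `svmo()` return non-negative numeric vectors;
#'   `delta_svma()` returns a vector one element shorter than its input.
#' @examples
#' svma(0.6, 0.8, 0)      # 1: 3-4-5 identity
#' delta_svma(c(1, 1.5, 0.9))
#' svmo(30, 40)           # 50
#' @export
svma <- function(ax, ay, az) {
  if (!all(is.finite(ax), is.finite(ay), is.finite(az))) {
    stop_imufall("svma requires finite acceleration values",
                 "imufall_argument_error")
  }
  sqrt(ax^2 + ay^2 + az^2)
}

#' @rdname svma
#' @param series numeric SVMa series of length >= 1.
#' @export
delta_svma <- function(series) {
  if (length(series) < 1L) {
    stop_imufall("delta_svma requires a series of length >= 1",
                 "imufall_argument_error")
  }
  if (!all(is.finite(series))) {
    stop_imufall("delta_svma requires finite values", "imufall_argument_error")
  }
  diff(series)
}

#' @rdname svma
#' @param pitch,roll orientation angles in degrees (finite).
#' @export
svmo <- function(pitch, roll) {
  if (!all(is.finite(pitch), is.finite(roll))) {
    stop_imufall("svmo requires finite angles", "imufall_argument_error")
  }
  sqrt(pitch^2 + roll^2)
}

#' Per-sample feature channels of a recording
#'
#' Appends the SVM feature family to a recording's raw channels: `svma`,
#' `delta_svma` (difference to the previous raw sample; 0 for the first
#' sample of the recording) and `svmo`.
#'
#' @param recording an [imu_recording()].
#' @return the recording with three extra numeric columns.
#' @export
add_features <- function(recording) {
  validate_recording(recording)
  s <- svma(recording$ax, recording$ay, recording$az)
  recording$svma <- s
  recording$delta_svma <- if (nrow(recording)) c(0, diff(s)) else numeric(0)
  recording$svmo <- svmo(recording$pitch, recording$roll)
  recording
}

#' Default channel set fed to sequence classifiers
#' @export
default_channels <- function() {
  c("ax", "ay", "az", "pitch", "roll", "svma", "delta_svma", "svmo")
}

#' Sliding-window segmentation
#'
#' Cuts a recording (or every recording of a dataset) into fixed-length
#' sliding windows.  With the defaults — 20 samples (2 s at 0.1 s), stride
#' 1 — each window is labelled by the status of its 10th sample (1-based,
#' i.e. the first window spans samples 1–20 and takes the label of sample
#' 10; the second spans 2–21 and takes the label of sample 11).  Windows
#' are never formed across recording boundaries.
#'
#' @param x an [imu_recording()] or [imu_dataset()].
#' @param window_len window length in samples (>= 1).
#' @param stride step between window starts, in samples.
#' @param label_pos 1-based position within the window whose status labels
#'   the window.
#' @param channels character vector of per-sample channels to extract;
#'   defaults to [default_channels()].
#' @return an object of class `imu_windows`: list with `x` (array
#'   `n_windows x window_len x n_channels`), `label` (integer codes),
#'   `t_label` (time of each window's label sample, seconds),
#'   `participant` and `start` (1-based start sample index), plus the
#'   windowing parameters.
#' @examples
#' r <- simulate_scenario("rest", duration = 2.1, seed = 1)
#' w <- make_windows(r)
#' dim(w$x)       # 2 windows x 20 samples x 8 channels
#' @export
make_windows <- function(x, window_len = 20L, stride = 1L, label_pos = 10L,
                         channels = default_channels()) {
  window_len <- as.integer(window_len)
  stride <- as.integer(stride)
  label_pos <- as.integer(label_pos)
  if (window_len < 1L) {
    stop_imufall("window_len must be >= 1", "imufall_argument_error")
  }
  if (stride < 1L) {
    stop_imufall("stride must be >= 1", "imufall_argument_error")
  }
  if (label_pos < 1L || label_pos > window_len) {
    stop_imufall(sprintf("label_pos (%d) must lie in [1, window_len = %d]",
                         label_pos, window_len),
                 "imufall_argument_error")
  }
  recs <- if (inherits(x, "imu_dataset")) x$recordings else list(x)
  parts <- lapply(recs, windows_one, window_len = window_len, stride = stride,
                  label_pos = label_pos, channels = channels)
  n_tot <- sum(vapply(parts, function(p) length(p$label), integer(1)))
  out <- list(
    x = array(NA_real_, dim = c(n_tot, window_len, length(channels)),
              dimnames = list(NULL, NULL, channels)),
    label = integer(n_tot), t_label = numeric(n_tot),
    participant = character(n_tot), start = integer(n_tot),
    window_len = window_len, stride = stride, label_pos = label_pos,
    channels = channels)
  at <- 0L
  for (p in parts) {
    k <- length(p$label)
    if (k == 0L) next
    out$x[at + seq_len(k), , ] <- p$x
    out$label[at + seq_len(k)] <- p$label
    out$t_label[at + seq_len(k)] <- p$t_label
    out$participant[at + seq_len(k)] <- p$participant
    out$start[at + seq_len(k)] <- p$start
    at <- at + k
  }
  class(out) <- "imu_windows"
  out
}

windows_one <- function(recording, window_len, stride, label_pos, channels) {
  rec <- add_features(recording)
  n <- nrow(rec)
  n_win <- if (n >= window_len) (n - window_len) %/% stride + 1L else 0L
  if (n_win == 0L) {
    return(list(x = array(0, c(0L, window_len, length(channels))),
                label = integer(0), t_label = numeric(0),
                participant = character(0), start = integer(0)))
  }
  starts <- 1L + (seq_len(n_win) - 1L) * stride
  mat <- as.matrix(as.data.frame(rec)[, channels, drop = FALSE])
  x <- array(NA_real_, dim = c(n_win, window_len, length(channels)))
  for (j in seq_len(window_len)) {
    x[, j, ] <- mat[starts + j - 1L, , drop = FALSE]
  }
  lab_idx <- starts + label_pos - 1L
  list(x = x, label = rec$label[lab_idx], t_label = rec$t[lab_idx],
       participant = rep(participant_id(recording), n_win), start = starts)
}

#' @export
print.imu_windows <- function(x, ...) {
  cat(sprintf("<imu_windows> %d windows of %d samples x %d channels (stride %d, label at sample %d)\n",
              dim(x$x)[1L], x$window_len, length(x$channels), x$stride,
              x$label_pos))
  tab <- table(status_factor(x$label))
  cat("labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Subset windows by index
#' @param i integer or logical index over windows.
#' @param x an `imu_windows` object.
#' @param ... unused.
#' @export
`[.imu_windows` <- function(x, i, ...) {
  out <- x
  out$x <- x$x[i, , , drop = FALSE]
  out$label <- x$label[i]
  out$t_label <- x$t_label[i]
  out$participant <- x$participant[i]
  out$start <- x$start[i]
  out
}
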