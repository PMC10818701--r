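#' IMU recordings and datasets
#'
#' An `imu_recording` is a data frame with one row per 0.1 s sensor sample and
#' columns `t` (seconds since recording start, on the sampling grid), `ax`,
#' `ay`, `az` (acceleration per body axis, in g), `pitch`, `roll` (degrees)
#' and `label` (integer status code, see [status_levels()]).  Attributes carry
#' the participant id, the sampling interval, optional free-text annotations
#' (index -> text; never used by any computation) and, for simulated data,
#' the phase plan emitted by the simulator.
#'
#' An `imu_dataset` is a list of recordings with unique participant ids.
#'
#' @param t numeric seconds since start; consecutive samples must differ by
#'   exactly one sampling interval.
#' @param ax,ay,az numeric acceleration in g.
#' @param pitch,roll numeric orientation angles in degrees; pitch must lie in
#'   \eqn{[-90, 90]} and roll in \eqn{[-180, 180]}.
#' @param label integer status codes in `0:3`, same length as `t`.
#' @param participant_id single string identifying the wearer.
#' @param sampling_interval sampling period in seconds (default 0.1).
#' @param annotations optional named character vector mapping sample index to
#'   a human-readable note.
#' @param phase_plan optional phase-plan data frame (simulator ground truth).
#' @return `imu_recording()` returns a validated `imu_recording` object.
#' @examples
#' r <- imu_recording(t = c(0, 0.1, 0.2), ax = 0, ay = 0, az = 1,
#'                    pitch = 0, roll = 0, label = 0L)
#' nrow(r)
#' @export
imu_recording <- function(t, ax, ay, az, pitch, roll, label,
                          participant_id = "P01", sampling_interval = 0.1,
                          annotations = NULL, phase_plan = NULL) {
  n <- length(t)
  df <- data.frame(t = as.numeric(t),
                   ax = rep_len(as.numeric(ax), n),
                   ay = rep_len(as.numeric(ay), n),
                   az = rep_len(as.numeric(az), n),
                   pitch = rep_len(as.numeric(pitch), n),
                   roll = rep_len(as.numeric(roll), n),
                   label = rep_len(as.integer(label), n))
  attr(df, "participant_id") <- as.character(participant_id)
  attr(df, "sampling_interval") <- sampling_interval
  attr(df, "annotations") <- annotations
  attr(df, "phase_plan") <- phase_plan
  class(df) <- c("imu_recording", "data.frame")
  validate_recording(df)
}

#' @rdname imu_recording
#' @param x object to validate or test.
#' @export
validate_recording <- function(x) {
  if (!is.data.frame(x)) {
    stop_imufall("a recording must be a data frame", "imufall_validation_error")
  }
  needed <- c("t", "ax", "ay", "az", "pitch", "roll", "label")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    stop_imufall(sprintf("recording is missing column(s): %s",
                         paste(missing_cols, collapse = ", ")),
                 "imufall_validation_error")
  }
  dt <- attr(x, "sampling_interval") %||% 0.1
  n <- nrow(x)
  if (n > 1L) {
    dts <- diff(x$t)
    if (any(dts <= 0)) {
      stop_imufall(sprintf("timestamps are not strictly increasing at sample %d",
                           which(dts <= 0)[1L] + 1L),
                   "imufall_validation_error")
    }
    if (any(abs(dts - dt) > 1e-6)) {
      stop_imufall(
        sprintf("timestamps deviate from the %.3g s sampling grid at sample %d",
                dt, which(abs(dts - dt) > 1e-6)[1L] + 1L),
        "imufall_validation_error")
    }
  }
  if (n > 0L) {
    if (any(x$pitch < -90 - 1e-9 | x$pitch > 90 + 1e-9)) {
      stop_imufall("pitch outside [-90, 90] degrees", "imufall_validation_error")
    }
    if (any(x$roll < -180 - 1e-9 | x$roll > 180 + 1e-9)) {
      stop_imufall("roll outside [-180, 180] degrees", "imufall_validation_error")
    }
    validate_labels(x$label)
  }
  invisible(x)
}

#' @rdname imu_recording
#' @export
is_imu_recording <- function(x) inherits(x, "imu_recording")

#' @rdname imu_recording
#' @param recordings list of `imu_recording` objects with distinct
#'   participant ids.
#' @export
imu_dataset <- function(recordings, sampling_interval = 0.1) {
  if (is_imu_recording(recordings)) recordings <- list(recordings)
  ids <- vapply(recordings, participant_id, character(1))
  if (anyDuplicated(ids)) {
    stop_imufall(sprintf("duplicate participant id(s): %s",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")),
                 "imufall_validation_error")
  }
  structure(list(recordings = recordings,
                 sampling_interval = sampling_interval),
            class = "imu_dataset")
}

#' @rdname imu_recording
#' @export
participant_id <- function(x) {
  attr(x, "participant_id") %||% "unknown"
}

#' @rdname imu_recording
#' @export
phase_plan <- function(x) attr(x, "phase_plan")

#' @export
print.imu_recording <- function(x, ...) {
  dt <- attr(x, "sampling_interval") %||% 0.1
  cat(sprintf("<imu_recording> participant %s: %d samples (%.1f s at %g s)\n",
              participant_id(x), nrow(x), nrow(x) * dt, dt))
  tab <- table(status_factor(x$label))
  cat("labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 4L))
  invisible(x)
}

#' @export
print.imu_dataset <- function(x, ...) {
  ns <- vapply(x$recordings, nrow, integer(1))
  cat(sprintf("<imu_dataset> %d participants, %d samples total\n",
              length(x$recordings), sum(ns)))
  invisible(x)
}

#' @export
length.imu_dataset <- function(x) length(x$recordings)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `code` with a fixed RNG seed, restoring the caller's RNG state on exit.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
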