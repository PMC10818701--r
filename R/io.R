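#' Read and write CSV sensor logs
#'
#' The on-disk interchange format is a UTF-8 CSV with header
#' `date,time,ax,ay,az,pitch,roll,label[,annotation]`: ISO date, wall-clock
#' time with 0.1 s resolution, three acceleration axes in g, pitch and roll
#' in degrees, the integer status label, and an optional free-text
#' annotation column (human-readable only; ignored by all computation).
#' Internally the date/time pair is merged into seconds since the first
#' sample.
#'
#' @param path file path.
#' @param participant_id participant id to attach to the recording (defaults
#'   to the file base name).
#' @param fill_label if `TRUE`, admit unlabelled field logs (no `label`
#'   column) by filling safe (0).  Default `FALSE`: the label column is
#'   mandatory.
#' @param sampling_interval expected sampling period in seconds.
#' @return `read_sensor_log()` returns an [imu_recording()];
#'   `write_sensor_log()` invisibly returns `path`.
#' @examples
#' r <- simulate_scenario("rest", duration = 2, seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_sensor_log(r, f)
#' r2 <- read_sensor_log(f)
#' all.equal(r$ax, r2$ax, tolerance = 1e-4)
#' @export
read_sensor_log <- function(path, participant_id = NULL, fill_label = FALSE,
                            sampling_interval = 0.1) {
  if (!file.exists(path)) {
    stop_imufall(sprintf("sensor log not found: %s", path), "imufall_io_error")
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  needed <- c("date", "time", "ax", "ay", "az", "pitch", "roll")
  if (!all(needed %in% names(raw))) {
    stop_imufall(sprintf("header must contain columns %s; found %s",
                         paste(needed, collapse = ","),
                         paste(names(raw), collapse = ",")),
                 "imufall_parse_error")
  }
  has_label <- "label" %in% names(raw)
  if (!has_label && !fill_label) {
    stop_imufall("sensor log has no 'label' column (use fill_label = TRUE for unlabelled field logs)",
                 "imufall_parse_error")
  }
  n <- nrow(raw)
  num_col <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) | is.na(raw[[col]]))
    if (length(bad)) {
      stop_imufall(sprintf("malformed value '%s' in column '%s' on line %d",
                           raw[[col]][bad[1L]], col, bad[1L] + 1L),
                   "imufall_parse_error")
    }
    v
  }
  if (n == 0L) {
    return(imu_recording(t = numeric(0), ax = numeric(0), ay = numeric(0),
                         az = numeric(0), pitch = numeric(0), roll = numeric(0),
                         label = integer(0),
                         participant_id = participant_id %||%
                           tools::file_path_sans_ext(basename(path)),
                         sampling_interval = sampling_interval))
  }
  secs <- parse_clock(raw$date, raw$time)
  t <- secs - secs[1L]
  if (n > 1L && any(diff(t) <= 0)) {
    stop_imufall(sprintf("non-monotone timestamp on line %d",
                         which(diff(t) <= 0)[1L] + 2L),
                 "imufall_validation_error")
  }
  label <- if (has_label) {
    codes <- suppressWarnings(as.integer(raw$label))
    bad <- which(is.na(codes) | !(codes %in% 0:3))
    if (length(bad)) {
      stop_imufall(sprintf("unknown status label '%s' on line %d",
                           raw$label[bad[1L]], bad[1L] + 1L),
                   "imufall_validation_error")
    }
    codes
  } else rep(0L, n)
  ann <- NULL
  if ("annotation" %in% names(raw)) {
    keep <- !is.na(raw$annotation) & nzchar(raw$annotation)
    if (any(keep)) ann <- stats::setNames(raw$annotation[keep],
                                          as.character(which(keep)))
  }
  imu_recording(t = round(t, 6), ax = num_col("ax"), ay = num_col("ay"),
                az = num_col("az"), pitch = num_col("pitch"),
                roll = num_col("roll"), label = label,
                participant_id = participant_id %||%
                  tools::file_path_sans_ext(basename(path)),
                sampling_interval = sampling_interval, annotations = ann)
}

# "YYYY-MM-DD" + "HH:MM:SS.s" -> seconds since epoch day origin.
parse_clock <- function(date, time) {
  d <- as.Date(date, format = "%Y-%m-%d")
  if (anyNA(d)) {
    stop_imufall(sprintf("malformed date '%s' on line %d",
                         date[which(is.na(d))[1L]], which(is.na(d))[1L] + 1L),
                 "imufall_parse_error")
  }
  parts <- regmatches(time, regexec("^([0-9]{2}):([0-9]{2}):([0-9]{2}(?:\\.[0-9]+)?)$", time))
  bad <- which(vapply(parts, length, integer(1)) != 4L)
  if (length(bad)) {
    stop_imufall(sprintf("malformed time '%s' on line %d", time[bad[1L]], bad[1L] + 1L),
                 "imufall_parse_error")
  }
  hms <- vapply(parts, function(p) {
    as.numeric(p[2L]) * 3600 + as.numeric(p[3L]) * 60 + as.numeric(p[4L])
  }, numeric(1))
  as.numeric(d - d[1L]) * 86400 + hms
}

#' @rdname read_sensor_log
#' @param recording an [imu_recording()].
#' @param start_datetime POSIXct-parseable string giving the wall-clock time
#'   of the first sample (the internal representation is seconds since
#'   start; an absolute clock is only needed on disk).
#' @param digits decimal places for numeric columns (at least 4, so that
#'   acceleration round-trips to better than 1e-4 g).
#' @export
write_sensor_log <- function(recording, path,
                             start_datetime = "2024-01-02 09:00:00",
                             digits = 5) {
  validate_recording(recording)
  if (digits < 4) {
    stop_imufall("digits must be >= 4 to preserve acceleration precision",
                 "imufall_argument_error")
  }
  origin <- as.POSIXct(start_datetime, tz = "UTC")
  # work on an integer decisecond grid so clock fields never hit 60.0 s
  ds <- round((as.numeric(origin) + recording$t) * 10)
  day <- ds %/% 864000
  rem <- ds - day * 864000
  hh <- rem %/% 36000
  mm <- (rem %% 36000) %/% 600
  ss <- (rem %% 600) / 10
  fmt <- function(v) formatC(v, format = "f", digits = digits)
  df <- data.frame(
    date = format(as.Date(day, origin = "1970-01-01"), "%Y-%m-%d"),
    time = sprintf("%02d:%02d:%04.1f", hh, mm, round(ss, 1)),
    ax = fmt(recording$ax), ay = fmt(recording$ay), az = fmt(recording$az),
    pitch = fmt(recording$pitch), roll = fmt(recording$roll),
    label = recording$label,
    stringsAsFactors = FALSE)
  ann <- attr(recording, "annotations")
  if (!is.null(ann)) {
    df$annotation <- ""
    df$annotation[as.integer(names(ann))] <- unname(ann)
  }
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop_imufall(sprintf("cannot write sensor log to '%s': %s",
                         path, conditionMessage(ok)), "imufall_io_error")
  }
  invisible(path)
}

#' Split a dataset by participant
#'
#' Partitions the recordings of a dataset into disjoint training and test
#' sets by drawing `n_train` participants at random, reproducibly for a
#' fixed seed.  The split is at recording level, so no analysis window can
#' ever straddle it.
#'
#' @param dataset an [imu_dataset()].
#' @param n_train number of training participants; must be smaller than the
#'   number of participants.
#' @param seed integer RNG seed.
#' @return list with elements `train` and `test`, both [imu_dataset()]s.
#' @examples
#' ds <- simulate_cohort(4, seed = 1,
#'                       plan = data.frame(kind = "rest", duration = 2))
#' sp <- split_by_participant(ds, n_train = 3, seed = 7)
#' length(sp$train); length(sp$test)
#' @export
split_by_participant <- function(dataset, n_train, seed = 1) {
  stopifnot(inherits(dataset, "imu_dataset"))
  n <- length(dataset$recordings)
  if (n_train >= n || n_train < 1) {
    stop_imufall(sprintf("n_train (%d) must be in [1, %d)", n_train, n),
                 "imufall_argument_error")
  }
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = imu_dataset(dataset$recordings[sort(idx)],
                           dataset$sampling_interval),
       test = imu_dataset(dataset$recordings[sort(setdiff(seq_len(n), idx))],
                          dataset$sampling_interval))
}
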