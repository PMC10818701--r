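#' Hierarchical-threshold detector configuration
#'
#' Thresholds for the hierarchical baseline detector, which combines
#' signal-vector-magnitude and vertical-axis acceleration rules in a fixed
#' decision order (fall, then stumble, then coma, else safe).  All values
#' are calibrated from data via [her_s()] rather than hard-coded, since no
#' published threshold set applies to this signal model.
#'
#' @param theta_freefall SVMa dip ceiling in g: values below it count as
#'   free-fall evidence.  Must be < 1.
#' @param theta_impact SVMa spike floor in g: values above it count as
#'   impact evidence.  Must be > 1.
#' @param theta_delta ΔSVMa spike floor in g for abrupt-movement evidence.
#' @param theta_vert vertical-axis |acceleration| floor in g; an alternative
#'   impact evidence channel.
#' @param stillness_sd rolling-SVMa standard-deviation ceiling in g below
#'   which a sample counts as still.
#' @param stillness_duration minimum stillness run, seconds, before the coma
#'   rule may fire.
#' @param posture_change SVMo change floor in degrees distinguishing
#'   fall-like posture disruption from steps.
#' @param lying_angle smoothed SVMo floor in degrees gating the coma rule to
#'   non-upright postures (a worker resting upright is not in a coma).
#' @param vertical_axis body-frame axis closest to gravity at rest.
#' @param horizon seconds within which a free-fall dip must precede impact
#'   evidence for the fall rule.
#' @param rolling_window seconds for rolling statistics (matches the 2 s
#'   decision granularity).
#' @return an object of class `threshold_config`.
#' @export
threshold_config <- function(theta_freefall = 0.35, theta_impact = 2.0,
                             theta_delta = 1.2, theta_vert = 3.5,
                             stillness_sd = 0.03, stillness_duration = 10,
                             posture_change = 25, lying_angle = 40,
                             vertical_axis = "az", horizon = 1.5,
                             rolling_window = 2) {
  cfg <- list(theta_freefall = theta_freefall, theta_impact = theta_impact,
              theta_delta = theta_delta, theta_vert = theta_vert,
              stillness_sd = stillness_sd,
              stillness_duration = stillness_duration,
              posture_change = posture_change, lying_angle = lying_angle,
              vertical_axis = vertical_axis, horizon = horizon,
              rolling_window = rolling_window)
  if (!(cfg$theta_freefall < 1 && cfg$theta_impact > 1)) {
    stop_imufall("need theta_freefall < 1 < theta_impact",
                 "imufall_argument_error")
  }
  if (cfg$stillness_duration <= 0 || cfg$horizon <= 0 ||
      cfg$rolling_window <= 0) {
    stop_imufall("durations must be > 0", "imufall_argument_error")
  }
  structure(cfg, class = "threshold_config")
}

# trailing "any TRUE within the last k samples (inclusive)"
run_any <- function(flag, k) {
  cs <- cumsum(as.integer(flag))
  lag <- c(rep(0L, min(k, length(cs))), cs[seq_len(max(0L, length(cs) - k))])
  (cs - lag) > 0L
}

# trailing rolling mean / sd over k samples, partial windows at the start
roll_mean <- function(x, k) {
  n <- length(x)
  cs <- cumsum(x)
  lag <- c(rep(0, min(k, n)), cs[seq_len(max(0L, n - k))])
  w <- pmin(seq_len(n), k)
  (cs - lag) / w
}

roll_sd <- function(x, k) {
  n <- length(x)
  m <- roll_mean(x, k)
  m2 <- roll_mean(x^2, k)
  w <- pmin(seq_len(n), k)
  v <- pmax(0, (m2 - m^2) * w / pmax(1, w - 1))
  sqrt(v)
}

# leading (centered-forward) rolling mean over the next k samples
roll_mean_lead <- function(x, k) {
  rev(roll_mean(rev(x), k))
}

#' Hierarchical threshold detection
#'
#' Applies the fixed decision hierarchy per sample: (1) *fall* — impact
#' evidence (SVMa above `theta_impact` or vertical-axis |acceleration|
#' above `theta_vert`) preceded within `horizon` seconds by a free-fall dip
#' below `theta_freefall`, together with a posture change larger than
#' `posture_change`; (2) *stumble* — impact or ΔSVMa evidence without the
#' full fall signature; (3) *coma* — rolling SVMa standard deviation below
#' `stillness_sd` sustained for at least `stillness_duration` seconds while
#' the smoothed posture is non-upright (SVMo above `lying_angle`);
#' (4) *safe* otherwise.  Earlier rules shadow later ones.
#'
#' @param recording an [imu_recording()].
#' @param cfg a [threshold_config()].
#' @return integer vector of status codes, one per sample.
#' @examples
#' r <- simulate_fall(seed = 1)
#' table(status_factor(detect_hierarchical(r, threshold_config())))
#' @export
detect_hierarchical <- function(recording, cfg = threshold_config()) {
  stopifnot(inherits(cfg, "threshold_config"))
  validate_recording(recording)
  n <- nrow(recording)
  if (n == 0L) return(integer(0))
  dt <- attr(recording, "sampling_interval") %||% 0.1
  s <- svma(recording$ax, recording$ay, recording$az)
  ds <- c(0, diff(s))
  o <- svmo(recording$pitch, recording$roll)
  av <- recording[[cfg$vertical_axis]]
  k_h <- max(1L, round(cfg$horizon / dt))
  k_w <- max(2L, round(cfg$rolling_window / dt))
  impact <- s > cfg$theta_impact | abs(av) > cfg$theta_vert
  recent_dip <- run_any(s < cfg$theta_freefall, k_h)
  post_delta <- abs(roll_mean_lead(o, k_h) - roll_mean(o, k_h))
  fall <- impact & recent_dip & (post_delta > cfg$posture_change)
  stumble <- (impact | ds > cfg$theta_delta) & !fall
  still <- roll_sd(s, k_w) < cfg$stillness_sd
  min_run <- max(1L, round(cfg$stillness_duration / dt))
  runs <- rle(still)
  qualifying <- rep(runs$values & runs$lengths >= min_run, runs$lengths)
  coma <- qualifying & (roll_mean(o, k_w) > cfg$lying_angle) &
    !fall & !stumble
  out <- integer(n)
  out[coma] <- 3L
  out[stumble] <- 2L
  out[fall] <- 1L
  out
}

#' Fit the hierarchical-threshold baseline by grid calibration
#'
#' Exhaustive grid search over candidate threshold values, selecting the
#' configuration that maximises macro-averaged per-sample F1 of
#' [detect_hierarchical()] over the training recordings.  Ties break
#' deterministically in favour of the first configuration in grid order.
#' The training data must contain all four status classes.
#'
#' @param train an [imu_dataset()] (or single recording) with all four
#'   classes present.
#' @param grid named list of candidate value vectors for any subset of
#'   [threshold_config()] fields; unlisted fields keep their defaults.
#' @param defaults base [threshold_config()] supplying non-searched fields.
#' @return object of class `her_s`: list with the selected `config`, its
#'   `macro_f1`, and the full `grid_scores` data frame.
#' @seealso [predict.her_s()]
#' @export
her_s <- function(train, grid = default_threshold_grid(),
                  defaults = threshold_config()) {
  if (is_imu_recording(train)) train <- imu_dataset(train)
  stopifnot(inherits(train, "imu_dataset"))
  truth <- unlist(lapply(train$recordings, `[[`, "label"), use.names = FALSE)
  present <- sort(unique(truth))
  if (!all(0:3 %in% present)) {
    stop_imufall(sprintf("training data must contain all four classes; missing: %s",
                         paste(status_name(setdiff(0:3, present)),
                               collapse = ", ")),
                 "imufall_validation_error")
  }
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  if (nrow(combos) == 0L) {
    stop_imufall("empty calibration grid", "imufall_argument_error")
  }
  scores <- numeric(nrow(combos))
  best <- -Inf
  best_cfg <- NULL
  for (g in seq_len(nrow(combos))) {
    cfg <- do.call(threshold_config,
                   utils::modifyList(unclass(defaults),
                                     as.list(combos[g, , drop = FALSE])))
    pred <- unlist(lapply(train$recordings, detect_hierarchical, cfg = cfg),
                   use.names = FALSE)
    cm <- confusion_matrix(truth, pred)
    f1s <- vapply(0:3, function(cl) class_metrics(cm, cl)$f1, numeric(1))
    scores[g] <- mean(f1s)
    if (scores[g] > best) {      # strict: first-in-grid wins ties
      best <- scores[g]
      best_cfg <- cfg
    }
  }
  structure(list(config = best_cfg, macro_f1 = best,
                 grid_scores = cbind(combos, macro_f1 = scores)),
            class = "her_s")
}

#' Default calibration grid for [her_s()]
#' @export
default_threshold_grid <- function() {
  list(theta_freefall = c(0.2, 0.35, 0.5),
       theta_impact = c(1.5, 2.0, 2.5, 3.0, 3.5),
       theta_delta = c(0.8, 1.2, 1.8))
}

#' @export
print.her_s <- function(x, ...) {
  cat("Hierarchical-threshold detector (calibrated)\n")
  cat(sprintf("  training macro-F1: %.3f over %d grid points\n",
              x$macro_f1, nrow(x$grid_scores)))
  cfg <- x$config
  cat(sprintf("  thresholds: freefall < %.2f g, impact > %.2f g, dSVMa > %.2f g, vert > %.2f g\n",
              cfg$theta_freefall, cfg$theta_impact, cfg$theta_delta,
              cfg$theta_vert))
  cat(sprintf("  coma: rolling sd < %.3f g for >= %.0f s, posture > %.0f deg\n",
              cfg$stillness_sd, cfg$stillness_duration, cfg$lying_angle))
  invisible(x)
}

#' @export
summary.her_s <- function(object, ...) {
  print(object)
  top <- object$grid_scores[order(-object$grid_scores$macro_f1), , drop = FALSE]
  cat("top grid points:\n")
  print(utils::head(top, 5L), row.names = FALSE)
  invisible(object)
}

#' Predict per-sample status with a calibrated hierarchical detector
#'
#' @param object a fitted [her_s()] model.
#' @param newdata an [imu_recording()] or [imu_dataset()].
#' @param ... unused.
#' @return for a recording, an integer label vector; for a dataset, a list
#'   of label vectors named by participant.
#' @export
predict.her_s <- function(object, newdata, ...) {
  if (is_imu_recording(newdata)) {
    return(detect_hierarchical(newdata, object$config))
  }
  stopifnot(inherits(newdata, "imu_dataset"))
  stats::setNames(lapply(newdata$recordings, detect_hierarchical,
                         cfg = object$config),
                  vapply(newdata$recordings, participant_id, character(1)))
}
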