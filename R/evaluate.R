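#' Confusion matrix over status labels
#'
#' Tallies a 4x4 confusion matrix with rows = true class and columns =
#' predicted class, in status-code order (safe, fall, stumble, coma).
#'
#' @param truth,pred equal-length integer label vectors (codes 0-3).
#' @return integer matrix of class `confusion_matrix`.
#' @examples
#' confusion_matrix(c(0, 1, 1), c(0, 1, 2))
#' @export
confusion_matrix <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    stop_imufall(sprintf("truth (%d) and pred (%d) differ in length",
                         length(truth), length(pred)),
                 "imufall_argument_error")
  }
  truth <- validate_labels(truth)
  pred <- validate_labels(pred)
  lv <- names(status_levels())
  cm <- table(factor(lv[truth + 1L], levels = lv),
              factor(lv[pred + 1L], levels = lv))
  m <- matrix(as.integer(cm), 4L, 4L, dimnames = list(truth = lv, pred = lv))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = truth, cols = predicted):\n")
  print(unclass(x))
  invisible(x)
}

#' One-vs-rest classification metrics for a class
#'
#' Derives TP/FP/FN/TN for the given class from a confusion matrix and
#' computes accuracy \eqn{(TP+TN)/(TP+TN+FP+FN)}, precision
#' \eqn{TP/(TP+FP)}, recall \eqn{TP/(TP+FN)}, specificity
#' \eqn{TN/(TN+FP)} and the F1 score (harmonic mean of precision and
#' recall).  A metric whose denominator is zero is reported as 0.
#'
#' @param cm a [confusion_matrix()].
#' @param cls class code (0-3) or name.
#' @return list with `tp`, `fp`, `fn`, `tn`, `accuracy`, `precision`,
#'   `recall`, `specificity`, `f1`.
#' @export
class_metrics <- function(cm, cls) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (sum(cm) == 0L) {
    stop_imufall("metrics are undefined for an empty confusion matrix",
                 "imufall_undefined_metric")
  }
  i <- if (is.character(cls)) status_code(cls) + 1L else as.integer(cls) + 1L
  stopifnot(i >= 1L, i <= 4L)
  tp <- cm[i, i]
  fp <- sum(cm[-i, i])
  fn <- sum(cm[i, -i])
  tn <- sum(cm[-i, -i])
  safe_div <- function(num, den) if (den > 0) num / den else 0
  p <- safe_div(tp, tp + fp)
  r <- safe_div(tp, tp + fn)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       accuracy = safe_div(tp + tn, tp + tn + fp + fn),
       precision = p, recall = r,
       specificity = safe_div(tn, tn + fp),
       f1 = f1_score(p, r))
}

#' Metric table for all four classes
#'
#' @param cm a [confusion_matrix()].
#' @return data frame with one row per class, percentages at 2 d.p. and F1
#'   at 3 d.p. (matching the reporting convention of the metric tables this
#'   layout mirrors), plus unrounded columns.
#' @export
metric_table <- function(cm) {
  rows <- lapply(0:3, function(cl) {
    m <- class_metrics(cm, cl)
    data.frame(label = status_name(cl),
               accuracy_pct = round(100 * m$accuracy, 2),
               precision_pct = round(100 * m$precision, 2),
               recall_pct = round(100 * m$recall, 2),
               specificity_pct = round(100 * m$specificity, 2),
               f1 = round(m$f1, 3))
  })
  do.call(rbind, rows)
}

#' F1 score
#'
#' Harmonic mean of precision and recall, \eqn{2pr/(p+r)}; defined as 0
#' when both are 0.
#'
#' @param precision,recall fractions in \eqn{[0,1]}.
#' @return fraction in \eqn{[0,1]}.
#' @examples
#' f1_score(0.9518, 0.9443)
#' @export
f1_score <- function(precision, recall) {
  stopifnot(all(precision >= 0 & precision <= 1),
            all(recall >= 0 & recall <= 1))
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Alarm-centric accuracy and false-detection rates
#'
#' Of all alarms a detector generated, the fraction that were correct
#' (accuracy rate) and incorrect (false detection rate).  These rates
#' ignore the dominant safe class entirely, so they are not diluted by the
#' large number of uneventful samples.  They sum to 1 whenever any alarm
#' exists; with zero alarms they are undefined and a typed error is raised
#' (distinct from reporting 0).
#'
#' @param n_correct number of correct detections (<= `n_alarms`).
#' @param n_alarms number of alarms generated.
#' @return list with `accuracy_rate` and `false_detection_rate`.
#' @examples
#' alarm_rates(177, 200)
#' @export
alarm_rates <- function(n_correct, n_alarms) {
  if (n_correct > n_alarms || n_correct < 0 || n_alarms < 0) {
    stop_imufall("need 0 <= n_correct <= n_alarms", "imufall_argument_error")
  }
  if (n_alarms == 0) {
    stop_imufall("rates are undefined when no alarms were generated",
                 "imufall_undefined_rate")
  }
  list(accuracy_rate = n_correct / n_alarms,
       false_detection_rate = (n_alarms - n_correct) / n_alarms)
}

#' Collapse per-window labels into alarm events
#'
#' Maximal runs of identical non-safe labels become one alarm event; runs
#' of the same type separated only by safe labels spanning at most
#' `merge_gap` seconds are merged (an event interrupted by a brief safe
#' flicker is still one alarm).
#'
#' @param labels integer label codes, one per time point.
#' @param times increasing numeric times (seconds) of the label points.
#' @param merge_gap merge window in seconds.
#' @return data frame of class `alarm_events` with columns `type`, `start`,
#'   `end` (seconds).
#' @examples
#' windows_to_alarms(c(0, 1, 1, 0), c(0, 0.1, 0.2, 0.3))
#' @export
windows_to_alarms <- function(labels, times, merge_gap = 2) {
  if (length(labels) != length(times)) {
    stop_imufall("labels and times differ in length", "imufall_argument_error")
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop_imufall("times must be strictly increasing", "imufall_argument_error")
  }
  labels <- validate_labels(labels)
  ev <- list()
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] == 0L) next
    ev[[length(ev) + 1L]] <- list(type = r$values[k],
                                  start = times[starts[k]],
                                  end = times[ends[k]])
  }
  out <- data.frame(type = integer(0), start = numeric(0), end = numeric(0))
  for (e in ev) {
    m <- nrow(out)
    # events are emitted in time order, so adjacency in `out` plus the gap
    # test guarantees no other-type event intervenes
    if (m > 0L && out$type[m] == e$type && e$start - out$end[m] <= merge_gap) {
      out$end[m] <- e$end
    } else {
      out <- rbind(out, data.frame(type = e$type, start = e$start,
                                   end = e$end))
    }
  }
  class(out) <- c("alarm_events", "data.frame")
  out
}

#' Ground-truth events of a recording
#'
#' Derives the true accident events (fall, stumble, coma spans) from a
#' recording's per-sample labels.
#'
#' @param recording an [imu_recording()].
#' @param merge_gap seconds; same-type spans closer than this merge.
#' @return an `alarm_events` data frame.
#' @export
truth_events <- function(recording, merge_gap = 2) {
  windows_to_alarms(recording$label, recording$t, merge_gap = merge_gap)
}

#' Event-level detection report
#'
#' Matches alarm events against ground-truth events and tallies, per event
#' type, the number of targets, the number accurately detected, the
#' sensitivity (percentage of targets matched by at least one same-type
#' alarm) and the number of false alarms (alarms matching no target of
#' their type).  Matching is greedy in time order and one-to-one: a truth
#' event is detected iff at least one unused same-type alarm overlaps it
#' within `tolerance` seconds; each alarm can match at most one truth
#' event.  A truth event covered only by an alarm of a different type
#' counts as a miss, and that alarm as a false alarm of its own type; such
#' cross-type pairs are additionally tallied in the `cross_type` table.
#'
#' @param truth an `alarm_events` data frame of ground-truth events (e.g.
#'   from [truth_events()]).
#' @param alarms an `alarm_events` data frame of detected events.
#' @param tolerance match tolerance in seconds (truth intervals are widened
#'   by this much on both sides before testing overlap).
#' @return object of class `event_report`: data frame `by_type` with one
#'   row per non-safe type, a `cross_type` 3x3 matrix (rows = truth type,
#'   cols = alarm type of unmatched overlapping alarms), the time-sorted
#'   `alarms` with a `matched` flag, and `tolerance`.
#' @examples
#' tr <- data.frame(type = 1L, start = 10, end = 11)
#' al <- data.frame(type = 1L, start = 10.5, end = 11.5)
#' event_report(tr, al)
#' @export
event_report <- function(truth, alarms, tolerance = 2) {
  truth <- as.data.frame(truth)
  alarms <- as.data.frame(alarms)
  if (nrow(truth) > 1L && is.unsorted(truth$start)) {
    truth <- truth[order(truth$start), , drop = FALSE]
  }
  if (nrow(alarms) > 1L && is.unsorted(alarms$start)) {
    alarms <- alarms[order(alarms$start), , drop = FALSE]
  }
  used <- rep(FALSE, nrow(alarms))
  matched <- rep(FALSE, nrow(truth))
  overlaps <- function(ti, ai) {
    alarms$start[ai] <= truth$end[ti] + tolerance &&
      alarms$end[ai] >= truth$start[ti] - tolerance
  }
  for (ti in seq_len(nrow(truth))) {
    for (ai in seq_len(nrow(alarms))) {
      if (used[ai] || alarms$type[ai] != truth$type[ti]) next
      if (overlaps(ti, ai)) {
        used[ai] <- TRUE
        matched[ti] <- TRUE
        break
      }
    }
  }
  # cross-type tally: unmatched truth events overlapped by unused alarms of
  # another type (the alarm stays a false alarm of its own type)
  cross <- matrix(0L, 3L, 3L,
                  dimnames = list(truth = names(status_levels())[2:4],
                                  alarm = names(status_levels())[2:4]))
  for (ti in which(!matched)) {
    for (ai in which(!used)) {
      if (alarms$type[ai] != truth$type[ti] && overlaps(ti, ai)) {
        cross[truth$type[ti], alarms$type[ai]] <-
          cross[truth$type[ti], alarms$type[ai]] + 1L
        break
      }
    }
  }
  by_type <- do.call(rbind, lapply(1:3, function(tp) {
    n_t <- sum(truth$type == tp)
    n_a <- sum(matched & truth$type == tp)
    n_fa <- sum(!used & alarms$type == tp)
    data.frame(type = status_name(tp), n_targets = n_t, n_accurate = n_a,
               sensitivity = if (n_t > 0) 100 * n_a / n_t else NA_real_,
               n_false_alarms = n_fa)
  }))
  alarms$matched <- used
  structure(list(by_type = by_type, cross_type = cross, alarms = alarms,
                 tolerance = tolerance),
            class = "event_report")
}

#' @export
print.event_report <- function(x, ...) {
  b <- x$by_type
  cat("Event-level detection report\n")
  cat(sprintf("%-28s %8s %8s %8s\n", "Performance index", "fall", "stumble",
              "coma"))
  cat(sprintf("%-28s %8d %8d %8d\n", "number of target events",
              b$n_targets[1], b$n_targets[2], b$n_targets[3]))
  cat(sprintf("%-28s %8d %8d %8d\n", "number of accurate detection",
              b$n_accurate[1], b$n_accurate[2], b$n_accurate[3]))
  cat(sprintf("%-28s %7.0f%% %7.0f%% %7.0f%%\n", "Sensitivity (%)",
              b$sensitivity[1], b$sensitivity[2], b$sensitivity[3]))
  cat(sprintf("%-28s %8d %8d %8d\n", "number of false alarms",
              b$n_false_alarms[1], b$n_false_alarms[2], b$n_false_alarms[3]))
  invisible(x)
}

#' Long-horizon coma persistence filter
#'
#' A genuine coma produces a steady run of coma decisions, whereas a
#' resting worker produces occasional safe flickers among them.  This
#' higher-level filter confirms a coma label only when at least
#' `min_fraction` of the trailing `horizon` labels (the label itself
#' included) are coma; otherwise it is demoted to safe.  Labels earlier
#' than a full horizon are treated conservatively: the missing history
#' counts as non-coma.
#'
#' @param labels integer per-window label codes.
#' @param horizon number of trailing labels considered (default 30, i.e.
#'   one minute of 2 s decisions).
#' @param min_fraction minimum coma fraction in the trailing window.
#' @return integer label vector with unconfirmed comas demoted to safe.
#' @examples
#' coma_persistence_filter(rep(3L, 30))[30]  # confirmed
#' @export
coma_persistence_filter <- function(labels, horizon = 30, min_fraction = 1.0) {
  if (horizon < 1) {
    stop_imufall("horizon must be >= 1", "imufall_argument_error")
  }
  labels <- validate_labels(labels)
  n <- length(labels)
  if (n == 0L) return(labels)
  is_coma <- as.integer(labels == 3L)
  cs <- cumsum(is_coma)
  lag <- c(rep(0L, min(horizon, n)), cs[seq_len(max(0L, n - horizon))])
  frac <- (cs - lag) / horizon     # missing history counts as non-coma
  out <- labels
  out[labels == 3L & frac < min_fraction - 1e-12] <- 0L
  out
}
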