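#' Evaluate a detector on test recordings
#'
#' Runs a per-recording labelling function over every test recording,
#' collapses its output into alarm events, matches them against the
#' ground-truth events of the recording labels, and aggregates event-level
#' counts, the per-time-unit confusion matrix, and — when phase plans are
#' available — false-alarm counts per scenario kind.
#'
#' @param test an [imu_dataset()].
#' @param label_fun function(recording) returning a list with `labels`
#'   (integer codes) and `times` (seconds, aligned with `labels`).
#' @param tolerance event-matching tolerance in seconds.
#' @param merge_gap alarm merge window in seconds.
#' @return list with `events` (aggregated per-type data frame), `cm`
#'   (confusion matrix on the prediction time grid) and
#'   `false_alarms_by_scenario` (named integer vector over scenario kinds,
#'   fall+stumble false alarms only).
#' @export
evaluate_detector <- function(test, label_fun, tolerance = 2, merge_gap = 2) {
  stopifnot(inherits(test, "imu_dataset"))
  acc <- matrix(0L, 3L, 3L,
                dimnames = list(c("fall", "stumble", "coma"),
                                c("n_targets", "n_accurate",
                                  "n_false_alarms")))
  truth_all <- integer(0)
  pred_all <- integer(0)
  fa_scen <- integer(0)
  for (rec in test$recordings) {
    out <- label_fun(rec)
    # truth labels on the detector's own time grid
    idx <- match(round(out$times, 6), round(rec$t, 6))
    truth_here <- rec$label[idx]
    truth_all <- c(truth_all, truth_here)
    pred_all <- c(pred_all, out$labels)
    tr_ev <- windows_to_alarms(rec$label, rec$t, merge_gap = merge_gap)
    al_ev <- windows_to_alarms(out$labels, out$times, merge_gap = merge_gap)
    rep <- event_report(tr_ev, al_ev, tolerance = tolerance)
    acc <- acc + as.matrix(rep$by_type[, colnames(acc)])
    plan <- phase_plan(rec)
    if (!is.null(plan) && !is.null(rep$alarms) && nrow(rep$alarms)) {
      fa <- rep$alarms[!rep$alarms$matched & rep$alarms$type %in% c(1L, 2L), ,
                       drop = FALSE]
      if (nrow(fa)) {
        scen <- vapply(fa$start, function(s) {
          hit <- which(plan$start <= s & plan$end > s)
          if (length(hit)) plan$scenario[hit[1L]] else "unknown"
        }, character(1))
        for (k in scen) {
          if (!k %in% names(fa_scen)) fa_scen[k] <- 0L
          fa_scen[k] <- fa_scen[k] + 1L
        }
      }
    }
  }
  agg <- data.frame(type = rownames(acc), n_targets = acc[, "n_targets"],
                    n_accurate = acc[, "n_accurate"],
                    sensitivity = ifelse(acc[, "n_targets"] > 0,
                                         100 * acc[, "n_accurate"] /
                                           acc[, "n_targets"], NA_real_),
                    n_false_alarms = acc[, "n_false_alarms"],
                    row.names = NULL)
  list(events = agg, cm = confusion_matrix(truth_all, pred_all),
       false_alarms_by_scenario = fa_scen)
}

#' Train and compare the GRU classifier against the hierarchical baseline
#'
#' The full study pipeline on one dataset: split by participant, train the
#' GRU classifier on the training windows, calibrate the
#' hierarchical-threshold baseline on the training recordings, and evaluate
#' both on the held-out participants at the event level (sensitivity and
#' false alarms per accident type) and per time unit (confusion metrics).
#'
#' @param dataset an [imu_dataset()] (e.g. from [simulate_cohort()]).
#' @param n_train training participants; defaults to all but one sixth of
#'   the cohort (25 of 30).
#' @param seed integer seed driving the split and GRU training.
#' @param gru a [gru_config()]; defaults to `gru_config(seed = seed)`.
#' @param grid calibration grid for [her_s()].
#' @param train_stride window stride used for the GRU *training* set (the
#'   evaluation always uses stride 1); thinning the heavily overlapping
#'   training windows keeps training time moderate without changing the
#'   evaluation protocol.
#' @param tolerance,merge_gap event-matching parameters, seconds.
#' @return object of class `model_comparison`: list with `gru`, `her`
#'   (each as returned by [evaluate_detector()], plus the fitted model) and
#'   the split.
#' @export
compare_models <- function(dataset, n_train = NULL, seed = 1, gru = NULL,
                           grid = default_threshold_grid(),
                           train_stride = 4L, tolerance = 2, merge_gap = 2) {
  n <- length(dataset)
  n_train <- n_train %||% max(1L, n - max(1L, round(n / 6)))
  sp <- split_by_participant(dataset, n_train, seed = seed)
  wtr <- make_windows(sp$train, stride = train_stride)
  gcfg <- gru %||% gru_config(seed = seed)
  gcfg$n_channels <- dim(wtr$x)[3L]
  gfit <- gru_train(build_gru(gcfg), wtr)
  hfit <- her_s(sp$train, grid = grid)
  gru_eval <- evaluate_detector(sp$test, function(rec) {
    w <- make_windows(rec)
    list(labels = predict(gfit, w), times = w$t_label)
  }, tolerance = tolerance, merge_gap = merge_gap)
  her_eval <- evaluate_detector(sp$test, function(rec) {
    list(labels = detect_hierarchical(rec, hfit$config), times = rec$t)
  }, tolerance = tolerance, merge_gap = merge_gap)
  structure(list(gru = c(gru_eval, list(fit = gfit)),
                 her = c(her_eval, list(fit = hfit)),
                 n_train = n_train, n_test = n - n_train, seed = seed),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison on %d held-out participants (%d trained)\n\n",
              x$n_test, x$n_train))
  fmt <- function(ev, name) {
    cat(sprintf("%s:\n", name))
    cat(sprintf("  %-28s %8s %8s %8s\n", "", "fall", "stumble", "coma"))
    cat(sprintf("  %-28s %8d %8d %8d\n", "number of target events",
                ev$n_targets[1], ev$n_targets[2], ev$n_targets[3]))
    cat(sprintf("  %-28s %8d %8d %8d\n", "number of accurate detection",
                ev$n_accurate[1], ev$n_accurate[2], ev$n_accurate[3]))
    cat(sprintf("  %-28s %7.0f%% %7.0f%% %7.0f%%\n", "Sensitivity (%)",
                ev$sensitivity[1], ev$sensitivity[2], ev$sensitivity[3]))
    cat(sprintf("  %-28s %8d %8d %8d\n\n", "number of false alarms",
                ev$n_false_alarms[1], ev$n_false_alarms[2],
                ev$n_false_alarms[3]))
  }
  fmt(x$gru$events, "GRU-S")
  fmt(x$her$events, "hierarchical baseline")
  invisible(x)
}
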