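test_that("confusion matrix matches a brute-force tally", {
  expect_error(confusion_matrix(0:1, 0L), class = "imufall_argument_error")
  cm <- confusion_matrix(c(0, 1, 1), c(0, 1, 2))
  expect_equal(unname(cm["fall", "stumble"]), 1L)
  expect_equal(sum(cm), 3L)
  d <- confusion_matrix(0:3, 0:3)
  expect_equal(unname(diag(unclass(d))), rep(1L, 4))
  expect_equal(sum(d) - sum(diag(unclass(d))), 0L)
  set.seed(21)
  truth <- sample(0:3, 1000, replace = TRUE, prob = c(0.8, 0.05, 0.1, 0.05))
  pred <- sample(0:3, 1000, replace = TRUE)
  cm <- confusion_matrix(truth, pred)
  oracle <- matrix(0L, 4, 4)
  for (i in seq_along(truth)) {
    oracle[truth[i] + 1L, pred[i] + 1L] <- oracle[truth[i] + 1L, pred[i] + 1L] + 1L
  }
  expect_equal(unclass(unname(cm)), oracle, ignore_attr = TRUE)
})

test_that("class metrics agree with a per-pair one-vs-rest oracle", {
  set.seed(22)
  truth <- sample(0:3, 500, replace = TRUE)
  pred <- sample(0:3, 500, replace = TRUE)
  cm <- confusion_matrix(truth, pred)
  for (cl in 0:3) {
    m <- class_metrics(cm, cl)
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    tn <- sum(truth != cl & pred != cl)
    expect_equal(m$tp, tp)
    expect_equal(m$accuracy, (tp + tn) / 500)
    expect_equal(m$precision, tp / (tp + fp))
    expect_equal(m$recall, tp / (tp + fn))
    expect_equal(m$specificity, tn / (tn + fp))
    expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
  }
  perfect <- confusion_matrix(rep(0:3, 5), rep(0:3, 5))
  for (cl in 0:3) {
    m <- class_metrics(perfect, cl)
    expect_equal(unlist(m[c("accuracy", "precision", "recall",
                            "specificity", "f1")]),
                 c(accuracy = 1, precision = 1, recall = 1,
                   specificity = 1, f1 = 1))
  }
  empty <- confusion_matrix(integer(0), integer(0))
  expect_error(class_metrics(empty, 0), class = "imufall_undefined_metric")
})

test_that("f1 is the harmonic mean with the 0/0 convention", {
  expect_equal(f1_score(0.5, 0.5), 0.5)
  for (p in c(0, 0.3, 1)) expect_equal(f1_score(p, p), p)
  expect_equal(f1_score(0, 0), 0)
  expect_equal(f1_score(1, 0), 0)
})

test_that("alarm rates split correct and incorrect detections", {
  r <- alarm_rates(177, 200)
  expect_equal(r$accuracy_rate, 0.885)
  expect_equal(r$false_detection_rate, 0.115)
  expect_equal(alarm_rates(10, 10),
               list(accuracy_rate = 1, false_detection_rate = 0))
  expect_equal(alarm_rates(0, 10),
               list(accuracy_rate = 0, false_detection_rate = 1))
  set.seed(23)
  for (i in 1:20) {
    n_a <- sample(1:500, 1)
    n_c <- sample(0:n_a, 1)
    rr <- alarm_rates(n_c, n_a)
    expect_equal(rr$accuracy_rate + rr$false_detection_rate, 1)
  }
  expect_error(alarm_rates(0, 0), class = "imufall_undefined_rate")
  expect_error(alarm_rates(5, 3), class = "imufall_argument_error")
})

test_that("label runs collapse to alarms as a run-length oracle predicts", {
  expect_equal(nrow(windows_to_alarms(rep(0L, 5), (0:4) / 10)), 0L)
  a <- windows_to_alarms(c(0, 1, 1, 0), c(0, 0.1, 0.2, 0.3))
  expect_equal(nrow(a), 1L)
  expect_equal(a$type, 1L)
  expect_equal(a$start, 0.1)
  expect_equal(a$end, 0.2)
  # same-type runs separated by <= merge_gap merge; > merge_gap do not
  lab <- c(1, 1, rep(0, 10), 1)
  tt <- (seq_along(lab) - 1) * 0.1
  expect_equal(nrow(windows_to_alarms(lab, tt, merge_gap = 2)), 1L)
  expect_equal(nrow(windows_to_alarms(lab, tt, merge_gap = 0.5)), 2L)
  # an interposed other-type event blocks the merge
  lab2 <- c(1, 0, 2, 0, 1)
  expect_equal(nrow(windows_to_alarms(lab2, (0:4) / 10, merge_gap = 2)), 3L)
  # run-length-encoding oracle on random sequences, merge_gap 0
  set.seed(24)
  for (i in 1:10) {
    lab <- sample(0:3, 60, replace = TRUE, prob = c(0.7, 0.1, 0.1, 0.1))
    tt <- (seq_along(lab) - 1) * 0.1
    got <- windows_to_alarms(lab, tt, merge_gap = 0)
    r <- rle(lab)
    expect_equal(nrow(got), sum(r$values != 0))
  }
})

test_that("event reports match targets greedily and tally false alarms", {
  mk <- function(type, starts, dur = 1) {
    data.frame(type = type, start = starts, end = starts + dur)
  }
  truth <- mk(1L, seq(0, by = 60, length.out = 10))
  alarms <- rbind(mk(1L, seq(0, by = 60, length.out = 10) + 0.5),
                  mk(1L, c(700, 800, 900)))
  rep <- event_report(truth, alarms)
  fall <- rep$by_type[rep$by_type$type == "fall", ]
  expect_equal(fall$n_accurate, 10)
  expect_equal(fall$sensitivity, 100)
  expect_equal(fall$n_false_alarms, 3)
  none <- event_report(truth, alarms[0, ])
  expect_equal(none$by_type$sensitivity[1], 0)
  expect_equal(sum(none$by_type$n_false_alarms), 0)
  # permutation invariance and the one-extra-alarm property
  perm <- event_report(truth, alarms[sample(nrow(alarms)), ])
  expect_equal(perm$by_type, rep$by_type)
  plus <- event_report(truth, rbind(alarms, mk(2L, 1000)))
  expect_equal(plus$by_type$n_false_alarms - rep$by_type$n_false_alarms,
               c(0, 1, 0))
})

test_that("greedy matching attains the exhaustive-matching optimum", {
  # brute force over all injective alarm->truth assignments (<= 8 events)
  oracle_max <- function(truth, alarms, tol = 2) {
    ok <- function(ti, ai) {
      alarms$type[ai] == truth$type[ti] &&
        alarms$start[ai] <= truth$end[ti] + tol &&
        alarms$end[ai] >= truth$start[ti] - tol
    }
    best <- 0L
    rec <- function(ti, used) {
      if (ti > nrow(truth)) {
        best <<- max(best, sum(used))
        return()
      }
      rec(ti + 1L, used)
      for (ai in seq_len(nrow(alarms))) {
        if (!used[ai] && ok(ti, ai)) {
          used[ai] <- TRUE
          rec(ti + 1L, used)
          used[ai] <- FALSE
        }
      }
    }
    rec(1L, rep(FALSE, nrow(alarms)))
    best
  }
  set.seed(25)
  for (i in 1:15) {
    n_t <- sample(1:4, 1)
    n_a <- sample(0:4, 1)
    truth <- data.frame(type = sample(1:3, n_t, replace = TRUE),
                        start = sort(stats::runif(n_t, 0, 100)))
    truth$end <- truth$start + stats::runif(n_t, 0.5, 3)
    alarms <- data.frame(type = sample(1:3, max(n_a, 1), replace = TRUE),
                         start = sort(stats::runif(max(n_a, 1), 0, 100)))
    alarms$end <- alarms$start + stats::runif(max(n_a, 1), 0.2, 2)
    alarms <- alarms[seq_len(n_a), , drop = FALSE]
    rep <- event_report(truth, alarms)
    expect_equal(sum(rep$by_type$n_accurate), oracle_max(truth, alarms),
                 info = sprintf("case %d", i))
  }
})

test_that("the coma persistence filter demotes flickering comas only", {
  steady <- rep(3L, 30)
  out <- coma_persistence_filter(steady, horizon = 30, min_fraction = 1)
  expect_equal(out[30], 3L)
  expect_true(all(out[1:29] == 0L))   # insufficient trailing history
  flick <- steady
  flick[15] <- 0L
  out2 <- coma_persistence_filter(flick, horizon = 30, min_fraction = 1)
  expect_true(all(out2[16:30] == 0L))
  expect_equal(coma_persistence_filter(rep(0L, 40)), rep(0L, 40))
  # relaxed fraction tolerates the flicker
  out3 <- coma_persistence_filter(flick, horizon = 30, min_fraction = 0.9)
  expect_equal(out3[30], 3L)
  # monotonicity: filtering never adds coma labels
  set.seed(26)
  for (i in 1:10) {
    lab <- sample(c(0L, 3L), 100, replace = TRUE)
    filt <- coma_persistence_filter(lab, horizon = 10, min_fraction = 0.8)
    expect_true(all(which(filt == 3L) %in% which(lab == 3L)))
  }
  expect_error(coma_persistence_filter(steady, horizon = 0),
               class = "imufall_argument_error")
})

test_that("metric tables round as reported: percentages 2 d.p., F1 3 d.p.", {
  set.seed(27)
  cm <- confusion_matrix(sample(0:3, 200, TRUE), sample(0:3, 200, TRUE))
  tab <- metric_table(cm)
  expect_equal(tab$label, c("safe", "fall", "stumble", "coma"))
  expect_equal(tab$recall_pct, round(tab$recall_pct, 2))
  expect_equal(tab$f1, round(tab$f1, 3))
})
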