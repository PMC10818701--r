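small_cfg <- function(...) {
  defaults <- list(recurrent_units = 16L,
                   dense_layers = c(32L, 16L, 8L, 8L, 4L),
                   epochs = 30L, batch_size = 32L, learning_rate = 3e-3,
                   validation_split = 0.1, seed = 1L)
  do.call(gru_config, utils::modifyList(defaults, list(...)))
}

test_that("the parameter count matches the closed-form oracle", {
  for (cfg in list(gru_config(),
                   small_cfg(),
                   gru_config(n_channels = 3, recurrent_units = 5,
                              dense_layers = c(7L, 6L, 5L, 4L, 3L)))) {
    u <- cfg$recurrent_units
    ch <- cfg$n_channels
    widths <- c(u, cfg$dense_layers, 4L)
    oracle <- 3 * (u * (u + ch) + u) +
      sum(vapply(seq_len(length(widths) - 1), function(i) {
        widths[i] * widths[i + 1] + widths[i + 1]
      }, numeric(1)))
    expect_equal(gru_parameter_count(cfg), oracle)
    m <- build_gru(cfg)
    expect_equal(sum(vapply(m$weights, length, numeric(1))), oracle)
  }
})

test_that("configuration constraints are enforced", {
  expect_equal(length(gru_config()$dense_layers), 5L)
  expect_equal(length(gru_config()$dropout_positions), 2L)
  expect_error(gru_config(dropout_rate = 1), class = "imufall_argument_error")
  expect_error(gru_config(dense_layers = c(8L, 0L)),
               class = "imufall_argument_error")
  expect_error(gru_config(dropout_positions = c(1L, 9L)),
               class = "imufall_argument_error")
})

test_that("untrained models emit normalized probabilities, seeded identically", {
  cfg <- small_cfg()
  m1 <- build_gru(cfg)
  m2 <- build_gru(cfg)
  expect_identical(m1$weights, m2$weights)
  m3 <- build_gru(small_cfg(seed = 2L))
  expect_false(identical(m1$weights, m3$weights))
  w <- archetype_windows(n_per_class = 2)
  p <- predict(m1, w, type = "prob")
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-9)
  expect_true(all(predict(m1, w) %in% 0:3))
})

test_that("training with zero epochs returns the built model unchanged", {
  m <- build_gru(small_cfg())
  w <- archetype_windows(n_per_class = 3)
  m0 <- gru_train(m, w, epochs = 0)
  expect_identical(m0, m)
})

test_that("training refuses windows missing a class or channels", {
  w <- archetype_windows(n_per_class = 3)
  w_no_fall <- w[w$label != 1L]
  m <- build_gru(small_cfg())
  expect_error(gru_train(m, w_no_fall), class = "imufall_validation_error")
  expect_error(gru_train(build_gru(small_cfg(n_channels = 3L)), w),
               class = "imufall_argument_error")
  fit <- gru_train(m, w, epochs = 1)
  w_bad <- w
  w_bad$x <- w$x[, , 1:3, drop = FALSE]
  expect_error(predict(fit, w_bad), class = "imufall_argument_error")
})

test_that("a separable archetype set is learned almost perfectly", {
  train <- archetype_windows(n_per_class = 50, noise = 0, seed = 1)
  fit <- gru_s(train, small_cfg())
  h <- fit$history
  expect_equal(nrow(h), 30L)
  expect_true(all(is.finite(h$train_loss)))
  expect_gt(h$train_acc[nrow(h)], 0.95)
  # held-out jittered archetypes classify correctly
  test <- archetype_windows(n_per_class = 10, noise = 0.02, seed = 99)
  pred <- predict(fit, test)
  expect_gte(mean(pred == test$label), 0.9)
  p <- predict(fit, test, type = "prob")
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-6)
})

test_that("training is reproducible and prediction is stateless", {
  train <- archetype_windows(n_per_class = 10, noise = 0.05, seed = 3)
  cfg <- small_cfg(epochs = 3L)
  f1 <- gru_s(train, cfg)
  f2 <- gru_s(train, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$weights, f2$weights)
  test <- archetype_windows(n_per_class = 5, noise = 0.05, seed = 4)
  p <- predict(f1, test)
  idx <- rev(seq_along(p))
  expect_identical(predict(f1, test[idx]), p[idx])
})
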