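#' GRU sequence-classifier configuration
#'
#' Architecture and training settings for the gated-recurrent-unit status
#' classifier: one GRU recurrent layer reads each feature window time step
#' by time step, its final hidden state feeds a stack of five dense hidden
#' layers with ReLU activations and two dropout layers, and a softmax
#' output layer produces probabilities over the four status classes.
#' Training minimises cross-entropy with the Adam optimiser via
#' backpropagation through time.
#'
#' @param n_channels number of per-time-step input channels (default: the
#'   eight channels of [default_channels()]).
#' @param recurrent_units width of the GRU layer.
#' @param dense_layers integer widths of the dense hidden stack (five by
#'   default).
#' @param dropout_rate dropout fraction in \eqn{[0,1)} applied after the
#'   dense layers named in `dropout_positions`.
#' @param dropout_positions indices into `dense_layers` after which dropout
#'   is applied (two by default).
#' @param n_classes number of output classes (4).
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param validation_split fraction of training windows held out for the
#'   per-epoch validation history.
#' @param class_weights if `TRUE`, weight the loss by inverse class
#'   frequency to counter the dominance of the safe class; off by default.
#' @param seed integer seed fixing weight initialisation, shuffling and
#'   dropout, making training reproducible on one platform.
#' @return list of class `gru_config`.
#' @export
gru_config <- function(n_channels = length(default_channels()),
                       recurrent_units = 64L,
                       dense_layers = c(128L, 64L, 32L, 16L, 8L),
                       dropout_rate = 0.2, dropout_positions = c(1L, 3L),
                       n_classes = 4L, epochs = 15L, batch_size = 64L,
                       learning_rate = 1e-3, validation_split = 0.1,
                       class_weights = FALSE, seed = 1L) {
  cfg <- list(n_channels = as.integer(n_channels),
              recurrent_units = as.integer(recurrent_units),
              dense_layers = as.integer(dense_layers),
              dropout_rate = dropout_rate,
              dropout_positions = as.integer(dropout_positions),
              n_classes = as.integer(n_classes), epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              learning_rate = learning_rate,
              validation_split = validation_split,
              class_weights = isTRUE(class_weights), seed = as.integer(seed))
  if (any(cfg$dense_layers < 1L) || cfg$recurrent_units < 1L ||
      cfg$n_channels < 1L) {
    stop_imufall("layer widths must be positive integers",
                 "imufall_argument_error")
  }
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1) {
    stop_imufall("dropout_rate must lie in [0, 1)", "imufall_argument_error")
  }
  if (length(cfg$dropout_positions) &&
      !all(cfg$dropout_positions %in% seq_along(cfg$dense_layers))) {
    stop_imufall("dropout_positions must index the dense stack",
                 "imufall_argument_error")
  }
  structure(cfg, class = "gru_config")
}

#' Trainable parameter count of a GRU configuration
#'
#' Closed form: the GRU layer has \eqn{3(U(U+C)+U)} parameters for
#' `U` recurrent units and `C` input channels (three gates, each with an
#' input map, a recurrent map and a bias), plus
#' \eqn{\sum_l (d_{l-1} d_l + d_l)} over the dense stack and the output
#' layer.
#'
#' @param cfg a [gru_config()] or fitted `gru_s` model.
#' @return integer parameter count.
#' @export
gru_parameter_count <- function(cfg) {
  if (inherits(cfg, "gru_s")) cfg <- cfg$config
  u <- cfg$recurrent_units; c <- cfg$n_channels
  widths <- c(u, cfg$dense_layers, cfg$n_classes)
  3L * (u * (u + c) + u) +
    sum(widths[-length(widths)] * widths[-1L] + widths[-1L])
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Build an untrained GRU model
#'
#' Initialises weights (Glorot-uniform, zero biases) reproducibly from the
#' configuration seed.  The returned object already supports [predict()];
#' before training it outputs near-uniform class probabilities.
#'
#' @param cfg a [gru_config()].
#' @return object of class `gru_s` with `trained = FALSE`.
#' @export
build_gru <- function(cfg = gru_config()) {
  stopifnot(inherits(cfg, "gru_config"))
  C <- cfg$n_channels; U <- cfg$recurrent_units
  w <- with_seed(cfg$seed, {
    w <- list(Wz = glorot(C, U), Wr = glorot(C, U), Wh = glorot(C, U),
              Uz = glorot(U, U), Ur = glorot(U, U), Uh = glorot(U, U),
              bz = numeric(U), br = numeric(U), bh = numeric(U))
    prev <- U
    for (l in seq_along(cfg$dense_layers)) {
      d <- cfg$dense_layers[l]
      w[[paste0("W", l)]] <- glorot(prev, d)
      w[[paste0("b", l)]] <- numeric(d)
      prev <- d
    }
    w$Wout <- glorot(prev, cfg$n_classes)
    w$bout <- numeric(cfg$n_classes)
    w
  })
  structure(list(config = cfg, weights = w,
                 scaling = NULL, history = NULL, trained = FALSE,
                 channels = NULL),
            class = "gru_s")
}

sigmoid <- function(x) 1 / (1 + exp(-x))
addb <- function(M, b) sweep(M, 2L, b, "+")

# Forward pass over a standardized batch X (B x T x C).  Returns class
# probabilities and, when `cache = TRUE`, everything the backward pass
# needs.  Dropout masks are drawn from the current RNG stream when
# `training = TRUE` (inverted dropout).
gru_forward <- function(w, X, cfg, training = FALSE, cache = FALSE) {
  B <- dim(X)[1L]; Tn <- dim(X)[2L]; C <- dim(X)[3L]
  U <- cfg$recurrent_units
  h <- matrix(0, B, U)
  cz <- cr <- chc <- chp <- if (cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    xt <- matrix(X[, t, ], B, C)
    z <- sigmoid(addb(xt %*% w$Wz + h %*% w$Uz, w$bz))
    r <- sigmoid(addb(xt %*% w$Wr + h %*% w$Ur, w$br))
    hc <- tanh(addb(xt %*% w$Wh + (r * h) %*% w$Uh, w$bh))
    hnew <- (1 - z) * h + z * hc
    if (cache) {
      cz[[t]] <- z; cr[[t]] <- r; chc[[t]] <- hc; chp[[t]] <- h
    }
    h <- hnew
  }
  a <- h
  acts <- if (cache) vector("list", length(cfg$dense_layers)) else NULL
  pres <- if (cache) vector("list", length(cfg$dense_layers)) else NULL
  masks <- if (cache) vector("list", length(cfg$dense_layers)) else NULL
  ins <- if (cache) vector("list", length(cfg$dense_layers)) else NULL
  keep <- 1 - cfg$dropout_rate
  for (l in seq_along(cfg$dense_layers)) {
    if (cache) ins[[l]] <- a
    pre <- addb(a %*% w[[paste0("W", l)]], w[[paste0("b", l)]])
    a <- pmax(pre, 0)
    if (training && cfg$dropout_rate > 0 && l %in% cfg$dropout_positions) {
      mask <- matrix(stats::runif(length(a)) < keep, nrow(a), ncol(a)) / keep
      a <- a * mask
      if (cache) masks[[l]] <- mask
    }
    if (cache) { pres[[l]] <- pre; acts[[l]] <- a }
  }
  logits <- addb(a %*% w$Wout, w$bout)
  mx <- apply(logits, 1L, max)
  e <- exp(logits - mx)
  p <- e / rowSums(e)
  list(p = p, h_final = h, a_final = a,
       z = cz, r = cr, hc = chc, hp = chp,
       ins = ins, pres = pres, masks = masks, X = X)
}

# Backward pass; returns gradients named like the weights.
gru_backward <- function(w, cfg, fw, dlogits) {
  g <- list()
  g$Wout <- t(fw$a_final) %*% dlogits
  g$bout <- colSums(dlogits)
  da <- dlogits %*% t(w$Wout)
  for (l in rev(seq_along(cfg$dense_layers))) {
    if (!is.null(fw$masks[[l]])) da <- da * fw$masks[[l]]
    dpre <- da * (fw$pres[[l]] > 0)
    g[[paste0("W", l)]] <- t(fw$ins[[l]]) %*% dpre
    g[[paste0("b", l)]] <- colSums(dpre)
    da <- dpre %*% t(w[[paste0("W", l)]])
  }
  U <- cfg$recurrent_units
  Tn <- length(fw$z)
  B <- nrow(dlogits)
  C <- dim(fw$X)[3L]
  for (nm in c("Wz", "Wr", "Wh")) g[[nm]] <- matrix(0, C, U)
  for (nm in c("Uz", "Ur", "Uh")) g[[nm]] <- matrix(0, U, U)
  for (nm in c("bz", "br", "bh")) g[[nm]] <- numeric(U)
  dh <- da
  for (t in rev(seq_len(Tn))) {
    z <- fw$z[[t]]; r <- fw$r[[t]]; hc <- fw$hc[[t]]; hp <- fw$hp[[t]]
    xt <- matrix(fw$X[, t, ], B, C)
    dz <- dh * (hc - hp)
    dhc <- dh * z
    dhp <- dh * (1 - z)
    dah <- dhc * (1 - hc^2)
    g$Wh <- g$Wh + t(xt) %*% dah
    g$Uh <- g$Uh + t(r * hp) %*% dah
    g$bh <- g$bh + colSums(dah)
    drh <- dah %*% t(w$Uh)
    dr <- drh * hp
    dhp <- dhp + drh * r
    daz <- dz * z * (1 - z)
    dar <- dr * r * (1 - r)
    g$Wz <- g$Wz + t(xt) %*% daz
    g$Uz <- g$Uz + t(hp) %*% daz
    g$bz <- g$bz + colSums(daz)
    g$Wr <- g$Wr + t(xt) %*% dar
    g$Ur <- g$Ur + t(hp) %*% dar
    g$br <- g$br + colSums(dar)
    dh <- dhp + daz %*% t(w$Uz) + dar %*% t(w$Ur)
  }
  g
}

standardize_windows <- function(x, scaling) {
  d <- dim(x)
  for (ch in seq_len(d[3L])) {
    x[, , ch] <- (x[, , ch] - scaling$center[ch]) / scaling$scale[ch]
  }
  x
}

#' Train a GRU status classifier
#'
#' Trains (or continues from) a built model on labelled feature windows.
#' Channels are standardized to zero mean and unit variance using training
#' statistics stored with the model.  Every source of randomness — weight
#' initialisation, epoch shuffling, dropout, the validation split — is
#' driven by the configuration seed, so training is reproducible on one
#' platform.  With `epochs = 0` the model is returned unchanged.
#'
#' @param model a `gru_s` object from [build_gru()].
#' @param windows an `imu_windows` object from [make_windows()]; all four
#'   status classes must be present.
#' @param epochs optional override of the configured epoch count.
#' @return the model with updated weights, a `history` data frame
#'   (per-epoch train/validation loss and accuracy) and `trained = TRUE`.
#' @seealso [gru_s()] for the one-call build-and-train interface.
#' @export
gru_train <- function(model, windows, epochs = NULL) {
  stopifnot(inherits(model, "gru_s"), inherits(windows, "imu_windows"))
  cfg <- model$config
  n_epochs <- as.integer(epochs %||% cfg$epochs)
  if (n_epochs == 0L) return(model)
  y <- windows$label
  present <- sort(unique(y))
  if (!all(0:(cfg$n_classes - 1L) %in% present)) {
    stop_imufall(sprintf("training windows must contain every class; missing: %s",
                         paste(status_name(setdiff(0:(cfg$n_classes - 1L),
                                                   present)), collapse = ", ")),
                 "imufall_validation_error")
  }
  if (dim(windows$x)[3L] != cfg$n_channels) {
    stop_imufall(sprintf("windows have %d channels but the model expects %d",
                         dim(windows$x)[3L], cfg$n_channels),
                 "imufall_argument_error")
  }
  n <- dim(windows$x)[1L]
  center <- apply(windows$x, 3L, mean)
  scale <- apply(windows$x, 3L, stats::sd)
  scale[!is.finite(scale) | scale < 1e-8] <- 1
  model$scaling <- list(center = center, scale = scale)
  model$channels <- windows$channels
  X <- standardize_windows(windows$x, model$scaling)
  w <- model$weights
  cw <- if (cfg$class_weights) {
    tab <- tabulate(y + 1L, nbins = cfg$n_classes)
    n / (cfg$n_classes * pmax(1L, tab))
  } else rep(1, cfg$n_classes)
  hist <- data.frame(epoch = seq_len(n_epochs), train_loss = NA_real_,
                     train_acc = NA_real_, val_loss = NA_real_,
                     val_acc = NA_real_)
  adam <- list(m = lapply(w, function(p) p * 0),
               v = lapply(w, function(p) p * 0), t = 0L)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  with_seed(cfg$seed + 1L, {
    n_val <- floor(cfg$validation_split * n)
    perm <- sample.int(n)
    val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
    tr_idx <- setdiff(perm, val_idx)
    Y <- diag(cfg$n_classes)[y + 1L, , drop = FALSE]
    for (ep in seq_len(n_epochs)) {
      ord <- tr_idx[sample.int(length(tr_idx))]
      ep_loss <- 0; ep_hits <- 0; ep_n <- 0
      for (b0 in seq(1L, length(ord), by = cfg$batch_size)) {
        bi <- ord[b0:min(b0 + cfg$batch_size - 1L, length(ord))]
        Xb <- X[bi, , , drop = FALSE]
        Yb <- Y[bi, , drop = FALSE]
        fw <- gru_forward(w, Xb, cfg, training = TRUE, cache = TRUE)
        wt <- cw[y[bi] + 1L]
        pi_true <- rowSums(fw$p * Yb)
        ep_loss <- ep_loss - sum(wt * log(pmax(pi_true, 1e-12)))
        ep_hits <- ep_hits + sum(max.col(fw$p) == y[bi] + 1L)
        ep_n <- ep_n + length(bi)
        dlogits <- (fw$p - Yb) * wt / sum(wt)
        g <- gru_backward(w, cfg, fw, dlogits)
        adam$t <- adam$t + 1L
        corr1 <- 1 - b1^adam$t
        corr2 <- 1 - b2^adam$t
        for (nm in names(w)) {
          adam$m[[nm]] <- b1 * adam$m[[nm]] + (1 - b1) * g[[nm]]
          adam$v[[nm]] <- b2 * adam$v[[nm]] + (1 - b2) * g[[nm]]^2
          w[[nm]] <- w[[nm]] - cfg$learning_rate *
            (adam$m[[nm]] / corr1) / (sqrt(adam$v[[nm]] / corr2) + eps)
        }
      }
      hist$train_loss[ep] <- ep_loss / ep_n
      hist$train_acc[ep] <- ep_hits / ep_n
      if (length(val_idx)) {
        vm <- eval_batches(w, X[val_idx, , , drop = FALSE], y[val_idx], cfg)
        hist$val_loss[ep] <- vm$loss
        hist$val_acc[ep] <- vm$acc
      }
    }
  })
  model$weights <- w
  model$history <- if (is.null(model$history)) hist else
    rbind(model$history, hist)
  model$trained <- TRUE
  model
}

eval_batches <- function(w, X, y, cfg, batch = 512L) {
  n <- dim(X)[1L]
  loss <- 0; hits <- 0
  for (b0 in seq(1L, n, by = batch)) {
    bi <- b0:min(b0 + batch - 1L, n)
    p <- gru_forward(w, X[bi, , , drop = FALSE], cfg)$p
    loss <- loss - sum(log(pmax(p[cbind(seq_along(bi), y[bi] + 1L)], 1e-12)))
    hits <- hits + sum(max.col(p) == y[bi] + 1L)
  }
  list(loss = loss / n, acc = hits / n)
}

#' Fit a GRU status classifier to labelled windows
#'
#' One-call interface: builds an untrained model from the configuration and
#' trains it on the windows.
#'
#' @param windows an `imu_windows` object from [make_windows()].
#' @param config a [gru_config()]; its `n_channels` is aligned to the
#'   windows automatically.
#' @return a fitted `gru_s` model.
#' @examples
#' \donttest{
#' ds <- simulate_cohort(2, seed = 1)
#' w <- make_windows(ds, stride = 10)
#' fit <- gru_s(w, gru_config(epochs = 2))
#' print(fit)
#' }
#' @export
gru_s <- function(windows, config = gru_config()) {
  stopifnot(inherits(windows, "imu_windows"))
  if (config$n_channels != dim(windows$x)[3L]) {
    config$n_channels <- dim(windows$x)[3L]
  }
  gru_train(build_gru(config), windows)
}

#' Predict status labels for feature windows
#'
#' Deterministic for a fixed model: dropout is inactive at prediction time
#' and each window is scored independently, so permuting a batch permutes
#' the predictions identically.
#'
#' @param object a `gru_s` model.
#' @param windows an `imu_windows` object with the same window length and
#'   channel set the model was trained on.
#' @param type `"class"` for integer status codes, `"prob"` for the n x 4
#'   matrix of class probabilities, `"both"` for a list of the two.
#' @param ... unused.
#' @return see `type`.
#' @export
predict.gru_s <- function(object, windows, type = c("class", "prob", "both"),
                          ...) {
  type <- match.arg(type)
  stopifnot(inherits(windows, "imu_windows"))
  cfg <- object$config
  if (dim(windows$x)[3L] != cfg$n_channels) {
    stop_imufall(sprintf("windows have %d channels but the model expects %d",
                         dim(windows$x)[3L], cfg$n_channels),
                 "imufall_argument_error")
  }
  X <- if (is.null(object$scaling)) windows$x else
    standardize_windows(windows$x, object$scaling)
  n <- dim(X)[1L]
  probs <- matrix(NA_real_, n, cfg$n_classes,
                  dimnames = list(NULL, names(status_levels())))
  for (b0 in seq(1L, n, by = 512L)) {
    bi <- b0:min(b0 + 511L, n)
    probs[bi, ] <- gru_forward(object$weights, X[bi, , , drop = FALSE], cfg)$p
  }
  cls <- max.col(probs, ties.method = "first") - 1L
  switch(type, class = cls, prob = probs, both = list(class = cls,
                                                      prob = probs))
}

#' @export
print.gru_s <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("GRU status classifier (%s)\n",
              if (x$trained) "trained" else "untrained"))
  cat(sprintf("  GRU(%d) -> dense(%s) + dropout %.2f after layers %s -> softmax(%d)\n",
              cfg$recurrent_units, paste(cfg$dense_layers, collapse = ","),
              cfg$dropout_rate, paste(cfg$dropout_positions, collapse = ","),
              cfg$n_classes))
  cat(sprintf("  %d channels x window, %d trainable parameters\n",
              cfg$n_channels, gru_parameter_count(cfg)))
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  after %d epochs: train acc %.3f, val acc %.3f\n",
                nrow(x$history), last$train_acc, last$val_acc))
  }
  invisible(x)
}

#' @export
summary.gru_s <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    cat("training history (last 5 epochs):\n")
    print(utils::tail(object$history, 5L), row.names = FALSE)
  }
  invisible(object)
}

#' Plot the training history of a GRU model
#'
#' @param x a trained `gru_s` model.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.gru_s <- function(x, ...) {
  h <- x$history
  if (is.null(h)) {
    stop_imufall("model has no training history to plot",
                 "imufall_argument_error")
  }
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::matplot(h$epoch, cbind(h$train_acc, h$val_acc), type = "l",
                    lty = 1, col = c("black", "red"), xlab = "epoch",
                    ylab = "accuracy", main = "Accuracy", ...)
  graphics::legend("bottomright", c("train", "validation"), lty = 1,
                   col = c("black", "red"), bty = "n")
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red"), xlab = "epoch",
                    ylab = "loss", main = "Loss", ...)
  invisible(x)
}
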