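#' Training configuration
#'
#' Defaults follow the reference full-scale protocol: cross-entropy loss, Adam,
#' learning rate 1e-5, 100 epochs, no early stopping, no schedule or weight
#' decay. Batch size is left open by that protocol; 32 is the package
#' default. `stability_fraction` parameterizes the convergence metric (first
#' epoch reaching at least that fraction of the run's top validation
#' accuracy).
#'
#' @param learning_rate Adam step size.
#' @param n_epochs number of epochs (the loop always runs all of them).
#' @param batch_size minibatch size.
#' @param seed RNG seed controlling initialization-independent training
#'   randomness (shuffling, dropout).
#' @param stability_fraction fraction in (0, 1] for [stability_metrics()].
#' @param beta1,beta2,epsilon Adam moment decay rates and stabilizer
#'   (conventional defaults).
#' @return An object of class `"training_config"`.
#' @export
training_config <- function(learning_rate = 1e-5, n_epochs = 100L,
                            batch_size = 32L, seed = 1L,
                            stability_fraction = 0.95,
                            beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8) {
  if (learning_rate <= 0) stop("'learning_rate' must be > 0")
  if (stability_fraction <= 0 || stability_fraction > 1)
    stop("'stability_fraction' must be in (0, 1]")
  if (batch_size < 1L) stop("'batch_size' must be >= 1")
  if (n_epochs < 0L) stop("'n_epochs' must be >= 0")
  structure(list(learning_rate = learning_rate, n_epochs = as.integer(n_epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 stability_fraction = stability_fraction,
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon),
            class = "training_config")
}

adam_init <- function(layers) {
  lapply(layers, function(ly) {
    if (is.null(ly$w)) NULL
    else list(mw = array(0, dim(ly$w) %||% length(ly$w)), vw = array(0, dim(ly$w) %||% length(ly$w)),
              mb = numeric(length(ly$b)), vb = numeric(length(ly$b)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(model, grads, state, t, cfg) {
  b1 <- cfg$beta1; b2 <- cfg$beta2; eps <- cfg$epsilon; lr <- cfg$learning_rate
  c1 <- 1 - b1^t; c2 <- 1 - b2^t
  for (li in seq_along(model$layers)) {
    gr <- grads[[li]]
    if (is.null(gr)) next
    st <- state[[li]]
    st$mw <- b1 * st$mw + (1 - b1) * gr$gw
    st$vw <- b2 * st$vw + (1 - b2) * gr$gw^2
    st$mb <- b1 * st$mb + (1 - b1) * gr$gb
    st$vb <- b2 * st$vb + (1 - b2) * gr$gb^2
    model$layers[[li]]$w <- model$layers[[li]]$w - lr * (st$mw / c1) / (sqrt(st$vw / c2) + eps)
    model$layers[[li]]$b <- model$layers[[li]]$b - lr * (st$mb / c1) / (sqrt(st$vb / c2) + eps)
    state[[li]] <- st
  }
  list(model = model, state = state)
}

#' Train a classifier and record its learning curve
#'
#' Minibatch Adam on cross-entropy, running exactly `n_epochs` epochs (no
#' early stopping). Per epoch it records the mean training loss, the
#' validation accuracy, and cumulative wall-clock seconds. Shuffling and
#' dropout are driven by `config$seed`, so with single-threaded BLAS a rerun
#' with the same seed reproduces the loss sequence.
#'
#' @param model a [build_classifier()] result.
#' @param x,y training images (array `(H, W, N)` or `(H, W, C, N)`) and
#'   integer labels in `1..n_classes`.
#' @param val_x,val_y validation images and labels.
#' @param config a [training_config()].
#' @param verbose print per-epoch progress?
#' @return An object of class `"training_run"`: list with `model` (final
#'   weights) and `curve` (data frame `epoch`, `train_loss`, `val_accuracy`,
#'   `cum_seconds`).
#' @export
train_classifier <- function(model, x, y, val_x, val_y, config = training_config(),
                             verbose = FALSE) {
  x <- as_batch(x); val_x <- as_batch(val_x)
  N <- dim(x)[4]
  if (N == 0L || length(y) != N) stop("training set empty or labels mismatched")
  if (dim(val_x)[4] != length(val_y)) stop("validation labels mismatched")
  y <- as.integer(y); val_y <- as.integer(val_y)
  if (any(y < 1L | y > model$config$n_classes)) stop("labels out of range")

  curve <- data.frame(epoch = integer(), train_loss = numeric(),
                      val_accuracy = numeric(), cum_seconds = numeric())
  if (config$n_epochs == 0L)
    return(structure(list(model = model, curve = curve, config = config),
                     class = "training_run"))

  set.seed(config$seed)
  state <- adam_init(model$layers)
  t0 <- proc.time()[["elapsed"]]
  step <- 0L
  for (epoch in seq_len(config$n_epochs)) {
    ord <- sample.int(N)
    losses <- numeric(0)
    for (start in seq(1L, N, by = config$batch_size)) {
      idx <- ord[start:min(N, start + config$batch_size - 1L)]
      fw <- nn_forward(model, x[, , , idx, drop = FALSE], train = TRUE)
      ce <- softmax_ce(fw$logits, y[idx])
      if (!is.finite(ce$loss))
        stop(sprintf("non-finite loss at epoch %d, batch starting at %d", epoch, start))
      losses <- c(losses, ce$loss)
      grads <- nn_backward(model, fw$caches, ce$grad)
      step <- step + 1L
      up <- adam_step(model, grads, state, step, config)
      model <- up$model; state <- up$state
    }
    acc <- classification_accuracy(model, val_x, val_y)
    curve <- rbind(curve, data.frame(epoch = epoch, train_loss = mean(losses),
                                     val_accuracy = acc,
                                     cum_seconds = proc.time()[["elapsed"]] - t0))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val acc %.4f", epoch, mean(losses), acc))
  }
  structure(list(model = model, curve = curve, config = config),
            class = "training_run")
}

#' @export
print.training_run <- function(x, ...) {
  n <- nrow(x$curve)
  cat(sprintf("<training run: %d epoch(s)>\n", n))
  if (n > 0) {
    sm <- stability_metrics(x$curve, x$config$stability_fraction)
    cat(sprintf("top val accuracy %.4f; stable at epoch %d (%.4f)\n",
                sm$top_accuracy, sm$stable_epoch, sm$stable_accuracy))
  }
  invisible(x)
}

#' Convergence summary of a learning curve
#'
#' The convergence metric: `top_accuracy` is the maximum validation
#' accuracy over the run; `stable_epoch` is the first epoch whose accuracy
#' reaches at least `fraction` times that maximum; `stable_accuracy` is the
#' accuracy at that epoch and `time_until_stability` the cumulative
#' wall-clock seconds there (reported, hardware-dependent).
#'
#' @param curve a learning-curve data frame with columns `epoch`,
#'   `val_accuracy` and (optionally) `cum_seconds`, or a `"training_run"`.
#' @param fraction threshold fraction of the top accuracy (default 0.95).
#' @return An object of class `"stability_metrics"`: list with
#'   `top_accuracy`, `stable_epoch`, `stable_accuracy`,
#'   `time_until_stability`.
#' @export
stability_metrics <- function(curve, fraction = 0.95) {
  if (inherits(curve, "training_run")) curve <- curve$curve
  if (!is.data.frame(curve) || nrow(curve) == 0L)
    stop("'curve' must be a nonempty learning curve")
  if (fraction <= 0 || fraction > 1) stop("'fraction' must be in (0, 1]")
  acc <- curve$val_accuracy
  top <- max(acc)
  stable <- which(acc >= fraction * top)[1L]
  structure(list(top_accuracy = top,
                 stable_epoch = curve$epoch[stable],
                 stable_accuracy = acc[stable],
                 time_until_stability = if (!is.null(curve$cum_seconds))
                   curve$cum_seconds[stable] else NA_real_),
            class = "stability_metrics")
}

#' @export
print.stability_metrics <- function(x, ...) {
  cat(sprintf("top accuracy %.4f; stable epoch %d (accuracy %.4f)",
              x$top_accuracy, x$stable_epoch, x$stable_accuracy))
  if (is.finite(x$time_until_stability))
    cat(sprintf("; time until stability %.1f s", x$time_until_stability))
  cat("\n")
  invisible(x)
}

#' Write a learning curve to CSV
#'
#' @param run a `"training_run"` or learning-curve data frame.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_learning_curve <- function(run, path) {
  curve <- if (inherits(run, "training_run")) run$curve else run
  utils::write.csv(curve, path, row.names = FALSE)
  invisible(path)
}
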