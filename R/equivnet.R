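#' Fit a (group-equivariant) convolutional image classifier
#'
#' The package's main modelling interface: builds a baseline or
#' p4/p4m-equivariant VGG-style classifier from an architecture
#' description, trains it with minibatch Adam on cross-entropy, and returns
#' a fitted-model object with the usual methods ([predict.equivnet()],
#' [print.equivnet()], [summary.equivnet()], [plot.equivnet()],
#' [coef.equivnet()]).
#'
#' @param x grayscale images: array `(H, W, N)` (or `(H, W, C, N)`).
#' @param y integer class labels in `1..n_classes`.
#' @param architecture an [arch_config()]; defaults to a desk-scale preset
#'   matching the input size and label range.
#' @param training a [training_config()].
#' @param validation optional list `(x, y)` used for the learning curve; if
#'   omitted, a stratified fraction `val_split` of the training data is
#'   held out.
#' @param val_split held-out fraction when `validation` is missing.
#' @param seed seed for weight initialization and the validation split.
#' @param verbose print per-epoch progress?
#' @return An object of class `"equivnet"`.
#' @examples
#' \donttest{
#' ds <- generate_dataset(synth_spec(n_classes = 2, per_class_counts = 8,
#'                                   image_size = 32, seed = 1))
#' arr <- samples_to_arrays(ds$samples)
#' fit <- equivnet(arr$x, arr$y,
#'                 architecture = desk_arch(input_size = 32, n_classes = 2,
#'                                          equivariant = TRUE),
#'                 training = training_config(n_epochs = 2, learning_rate = 1e-3,
#'                                            batch_size = 8))
#' predict(fit, arr$x)
#' }
#' @export
equivnet <- function(x, y, architecture = NULL, training = training_config(),
                     validation = NULL, val_split = 0.2, seed = 1L,
                     verbose = FALSE) {
  x <- as_batch(x)
  y <- as.integer(y)
  if (dim(x)[4] != length(y)) stop("'x' and 'y' disagree on the number of samples")
  if (is.null(architecture))
    architecture <- desk_arch(input_size = dim(x)[1], n_classes = max(y))
  if (is.null(validation)) {
    set.seed(as.integer(seed))
    hold <- unlist(lapply(split(seq_along(y), y), function(idx) {
      n <- max(1L, round(length(idx) * val_split))
      sample(idx, n)
    }), use.names = FALSE)
    validation <- list(x = x[, , , hold, drop = FALSE], y = y[hold])
    x <- x[, , , -hold, drop = FALSE]
    y <- y[-hold]
  }
  model <- build_classifier(architecture, seed = seed)
  run <- train_classifier(model, x, y, as_batch(validation$x), validation$y,
                          training, verbose = verbose)
  structure(list(model = run$model, curve = run$curve,
                 architecture = architecture, training = training,
                 seed = as.integer(seed), call = match.call()),
            class = "equivnet")
}

#' @export
print.equivnet <- function(x, ...) {
  cat("Call:\n"); print(x$call)
  kind <- if (x$architecture$equivariant)
    sprintf("group-equivariant (%s)", x$architecture$group_name) else "baseline CNN"
  cat(sprintf("\n%s classifier, %d classes, input %dx%d\n", kind,
              x$architecture$n_classes, x$architecture$input_size,
              x$architecture$input_size))
  if (nrow(x$curve)) {
    sm <- stability_metrics(x$curve, x$training$stability_fraction)
    cat(sprintf("trained %d epoch(s); top validation accuracy %.4f\n",
                nrow(x$curve), sm$top_accuracy))
  }
  invisible(x)
}

#' @describeIn equivnet summary: parameter counts and convergence metrics.
#' @param object,... method arguments.
#' @export
summary.equivnet <- function(object, ...) {
  pc <- count_parameters(object$model)
  sm <- if (nrow(object$curve))
    stability_metrics(object$curve, object$training$stability_fraction) else NULL
  out <- list(architecture = object$architecture, parameters = pc,
              stability = sm, curve = object$curve)
  class(out) <- "summary.equivnet"
  out
}

#' @export
print.summary.equivnet <- function(x, ...) {
  kind <- if (x$architecture$equivariant)
    sprintf("group-equivariant (%s)", x$architecture$group_name) else "baseline CNN"
  cat(sprintf("%s, %s parameters\n", kind, format(x$parameters$total, big.mark = ",")))
  print(x$parameters$table, row.names = FALSE)
  if (!is.null(x$stability)) { cat("\nConvergence: "); print(x$stability) }
  invisible(x)
}

#' Predict from a fitted equivnet classifier
#'
#' @param object an [equivnet()] fit.
#' @param newdata image array `(H, W, N)` or `(H, W, C, N)`.
#' @param type `"class"` for labels, `"prob"` for softmax probabilities,
#'   `"logit"` for raw scores.
#' @param ... unused.
#' @return Integer labels, or an `N x n_classes` matrix.
#' @export
predict.equivnet <- function(object, newdata, type = c("class", "prob", "logit"), ...) {
  type <- match.arg(type)
  if (type == "class") return(predict_classes(object$model, newdata))
  lg <- forward(object$model, newdata)
  if (type == "logit") return(lg)
  e <- exp(lg - apply(lg, 1L, max))
  e / rowSums(e)
}

#' @describeIn equivnet plot: validation-accuracy learning curve.
#' @export
plot.equivnet <- function(x, ...) {
  if (!nrow(x$curve)) stop("no learning curve recorded")
  graphics::plot(x$curve$epoch, x$curve$val_accuracy, type = "b",
                 xlab = "epoch", ylab = "validation accuracy", ylim = c(0, 1), ...)
  sm <- stability_metrics(x$curve, x$training$stability_fraction)
  graphics::abline(v = sm$stable_epoch, lty = 2)
  invisible(x)
}

#' @describeIn equivnet coef: the list of layer weight arrays.
#' @export
coef.equivnet <- function(object, ...) {
  ws <- Filter(Negate(is.null), lapply(object$model$layers, function(ly)
    if (is.null(ly$w)) NULL else list(kind = ly$kind, w = ly$w, b = ly$b)))
  ws
}
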