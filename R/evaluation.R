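#' Multi-class confusion matrix
#'
#' Rows are actual classes, columns predicted classes.
#'
#' @param actual,predicted integer class labels in `1..n_classes`.
#' @param n_classes number of classes.
#' @return Integer matrix of class `"confusion_matrix"` with
#'   `counts[i, j]` = number of samples of actual class `i` predicted as `j`.
#' @export
confusion_matrix <- function(actual, predicted, n_classes) {
  if (length(actual) != length(predicted))
    stop("'actual' and 'predicted' must have equal length")
  actual <- as.integer(actual); predicted <- as.integer(predicted)
  n_classes <- as.integer(n_classes)
  if (any(actual < 1L | actual > n_classes | predicted < 1L | predicted > n_classes))
    stop("class labels out of range 1..n_classes")
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(actual)) cm[actual[i], predicted[i]] <- cm[actual[i], predicted[i]] + 1L
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion matrix: %d classes, %d samples (rows = actual)>\n",
              nrow(x), sum(x)))
  print(unclass(x))
  invisible(x)
}

ovr_counts <- function(cm, cls) {
  tp <- cm[cls, cls]
  fn <- sum(cm[cls, ]) - tp
  fp <- sum(cm[, cls]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(tp = tp, fn = fn, fp = fp, tn = tn)
}

#' Macro-averaged sensitivity (recall)
#'
#' Unweighted mean over classes of `TP / (TP + FN)`, one-vs-rest.
#'
#' @param cm a [confusion_matrix()].
#' @return A single number in `[0, 1]`.
#' @export
macro_sensitivity <- function(cm) {
  per <- vapply(seq_len(nrow(cm)), function(cls) {
    v <- ovr_counts(cm, cls)
    if (v["tp"] + v["fn"] == 0)
      stop(sprintf("class %d has no actual samples; sensitivity undefined", cls))
    v[["tp"]] / (v[["tp"]] + v[["fn"]])
  }, numeric(1))
  mean(per)
}

#' Macro-averaged specificity
#'
#' Unweighted mean over classes of `TN / (TN + FP)`, one-vs-rest.
#'
#' @param cm a [confusion_matrix()].
#' @return A single number in `[0, 1]`.
#' @export
macro_specificity <- function(cm) {
  per <- vapply(seq_len(nrow(cm)), function(cls) {
    v <- ovr_counts(cm, cls)
    if (v["tn"] + v["fp"] == 0)
      stop(sprintf("class %d has no negative samples; specificity undefined", cls))
    v[["tn"]] / (v[["tn"]] + v[["fp"]])
  }, numeric(1))
  mean(per)
}

#' Micro-averaged sensitivity
#'
#' Pooled `sum(TP) / sum(TP + FN)` over one-vs-rest classes (equals overall
#' accuracy for single-label classification).
#'
#' @param cm a [confusion_matrix()].
#' @return A single number in `[0, 1]`.
#' @export
micro_sensitivity <- function(cm) sum(diag(unclass(cm))) / sum(cm)

#' Micro-averaged specificity
#'
#' Pooled `sum(TN) / sum(TN + FP)` over one-vs-rest classes.
#'
#' @param cm a [confusion_matrix()].
#' @return A single number in `[0, 1]`.
#' @export
micro_specificity <- function(cm) {
  v <- rowSums(vapply(seq_len(nrow(cm)), function(cls) ovr_counts(cm, cls), numeric(4)))
  v[["tn"]] / (v[["tn"]] + v[["fp"]])
}

#' Relative improvement in percent
#'
#' `100 * (new - baseline) / baseline`.
#'
#' @param new,baseline values to compare; `baseline` must be positive.
#' @return Percent change.
#' @examples
#' relative_improvement(82.43, 76.59)  # ~7.6
#' @export
relative_improvement <- function(new, baseline) {
  if (any(baseline <= 0)) stop("'baseline' must be > 0")
  100 * (new - baseline) / baseline
}

#' Fit a power law y = a * x^k by log-log linear regression
#'
#' Ordinary least squares of `log(y)` on `log(x)` (natural logs; the slope
#' is base-invariant): the slope estimates the exponent `k` and the
#' exponentiated intercept the amplitude `a`.
#'
#' @param x,y positive numeric vectors (at least two distinct `x`).
#' @return An object of class `"power_law_fit"`: list with `amplitude`,
#'   `exponent`, `log_a`, `rss` (residual sum of squares in log space),
#'   `n_points`, and the underlying `lm` fit.
#' @examples
#' fit_power_law(c(1, 10, 100), c(1, 0.1, 0.01))  # exponent -1
#' @export
fit_power_law <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("'x' and 'y' must be equal-length vectors with n >= 2")
  if (any(x <= 0) || any(y <= 0)) stop("power-law fitting requires positive x and y")
  if (length(unique(x)) < 2L) stop("'x' values must not all be equal")
  lx <- log(x); ly <- log(y)
  fit <- stats::lm(ly ~ lx)
  co <- stats::coef(fit)
  structure(list(amplitude = exp(unname(co[1])), exponent = unname(co[2]),
                 log_a = unname(co[1]), rss = sum(stats::residuals(fit)^2),
                 n_points = length(x), lm = fit),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power law fit: y = %.4g * x^%.4f  (n = %d, rss = %.4g)>\n",
              x$amplitude, x$exponent, x$n_points, x$rss))
  invisible(x)
}

#' @export
predict.power_law_fit <- function(object, newdata, ...) {
  object$amplitude * newdata^object$exponent
}

#' @export
plot.power_law_fit <- function(x, data_x = NULL, data_y = NULL, ...) {
  if (is.null(data_x)) {
    data_x <- exp(x$lm$model$lx); data_y <- exp(x$lm$model$ly)
  }
  graphics::plot(data_x, data_y, log = "xy", xlab = "training samples",
                 ylab = "end error", ...)
  xs <- exp(seq(log(min(data_x)), log(max(data_x)), length.out = 50))
  graphics::lines(xs, predict(x, xs))
  invisible(x)
}

#' Data-efficiency scaling experiment
#'
#' For each model condition, training-set size and seed: draw a nested
#' class-balanced subsample, build and train a classifier, and record the
#' end error (one minus the evaluation accuracy) on a fixed held-out set.
#' One power law is fitted per condition to the per-size mean errors.
#' Per-cell results can be cached to disk, making reruns resumable.
#'
#' @param train_samples,eval_samples sample lists (see [generate_dataset()]).
#' @param archs named list of [arch_config()]s, one per condition.
#' @param sizes increasing vector of training-set sizes.
#' @param seeds integer vector of replicate seeds.
#' @param training a [training_config()].
#' @param error_from `"final"` uses the final-epoch accuracy; `"best"` the
#'   best epoch.
#' @param cache_dir optional directory for per-cell caching.
#' @param verbose print progress?
#' @return An object of class `"scaling_result"`: `results` data frame
#'   (`condition`, `size`, `seed`, `end_error`, `failed`) and `fits`, a
#'   named list of [fit_power_law()] objects.
#' @export
run_scaling_experiment <- function(train_samples, eval_samples, archs, sizes,
                                   seeds, training = training_config(),
                                   error_from = c("final", "best"),
                                   cache_dir = NULL, verbose = FALSE) {
  error_from <- match.arg(error_from)
  if (is.null(names(archs)) || any(names(archs) == ""))
    stop("'archs' must be a named list of arch_config objects")
  if (is.unsorted(sizes, strictly = TRUE)) stop("'sizes' must be strictly increasing")
  ev <- samples_to_arrays(eval_samples)
  if (!is.null(cache_dir)) dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (cond in names(archs)) {
    for (size in sizes) {
      for (seed in seeds) {
        key <- sprintf("%s_n%d_s%d", cond, size, seed)
        cache <- if (!is.null(cache_dir)) file.path(cache_dir, paste0(key, ".rds")) else NULL
        if (!is.null(cache) && file.exists(cache)) {
          err <- readRDS(cache)
        } else {
          err <- tryCatch({
            sub <- subsample_training(train_samples, size, seed = seed)
            tr <- samples_to_arrays(sub)
            cfg <- training; cfg$seed <- as.integer(seed)
            model <- build_classifier(archs[[cond]], seed = seed)
            run <- train_classifier(model, tr$x, tr$y, ev$x, ev$y, cfg)
            acc <- if (error_from == "final")
              run$curve$val_accuracy[nrow(run$curve)] else max(run$curve$val_accuracy)
            1 - acc
          }, error = function(e) {
            warning(sprintf("cell %s failed: %s", key, conditionMessage(e)))
            NA_real_
          })
          if (!is.null(cache) && !is.na(err)) saveRDS(err, cache)
        }
        if (verbose) message(sprintf("%s: end error %.4f", key, err))
        rows[[length(rows) + 1L]] <-
          data.frame(condition = cond, size = size, seed = seed,
                     end_error = err, failed = is.na(err))
      }
    }
  }
  results <- do.call(rbind, rows)
  fits <- lapply(names(archs), function(cond) {
    sub <- results[results$condition == cond & !results$failed, ]
    means <- tapply(sub$end_error, sub$size, mean)
    xs <- as.numeric(names(means)); ys <- pmax(as.numeric(means), 1e-12)
    if (length(xs) >= 2L) fit_power_law(xs, ys) else NULL
  })
  names(fits) <- names(archs)
  structure(list(results = results, fits = fits, error_from = error_from),
            class = "scaling_result")
}

#' @export
print.scaling_result <- function(x, ...) {
  cat("<scaling experiment>\n")
  for (cond in names(x$fits)) {
    f <- x$fits[[cond]]
    if (is.null(f)) cat(sprintf("  %s: no fit\n", cond))
    else cat(sprintf("  %s: error = %.3g * n^%.3f\n", cond, f$amplitude, f$exponent))
  }
  nf <- sum(x$results$failed)
  if (nf) cat(sprintf("  %d failed cell(s)\n", nf))
  invisible(x)
}

#' Four-condition comparison experiment
#'
#' Runs the 2 x 2 protocol (baseline CNN / equivariant GCNN, with and
#' without p4m orbit augmentation of the training set) over a list of
#' seeds, and summarizes three planned comparisons: augmentation helping
#' the CNN (control 1), the unaugmented GCNN against the augmented CNN
#' (main hypothesis), and augmentation helping the GCNN (control 2). Before
#' any training, the GCNN is checked for end-to-end logit invariance and
#' the run aborts if the check fails.
#'
#' @param train_samples,val_samples sample lists.
#' @param arch_cnn,arch_gcnn [arch_config()]s for the two families.
#' @param training a [training_config()].
#' @param seeds integer vector of replicate seeds.
#' @param invariance_tol maximum allowed GCNN logit deviation under group
#'   transformations of the input.
#' @param verbose print progress?
#' @return An object of class `"main_experiment"`: `runs` (per
#'   condition/seed stability metrics), `summary` (per-condition mean and
#'   sd), `comparisons` (the three planned contrasts with relative
#'   improvements in percent).
#' @export
run_main_experiment <- function(train_samples, val_samples, arch_cnn, arch_gcnn,
                                training = training_config(), seeds = 1:3,
                                invariance_tol = 1e-4, verbose = FALSE) {
  val <- samples_to_arrays(val_samples)
  probe <- val$x[, , seq_len(min(2, dim(val$x)[3])), drop = FALSE]
  dev <- logit_invariance_deviation(build_classifier(arch_gcnn, seed = seeds[1]), probe)
  if (dev > invariance_tol)
    stop(sprintf("GCNN failed the equivariance self-check (logit deviation %.3g)", dev))

  aug_train <- augment_p4m(train_samples)
  conditions <- list(
    cnn_noaug  = list(arch = arch_cnn,  samples = train_samples),
    cnn_aug    = list(arch = arch_cnn,  samples = aug_train),
    gcnn_noaug = list(arch = arch_gcnn, samples = train_samples),
    gcnn_aug   = list(arch = arch_gcnn, samples = aug_train))

  rows <- list()
  for (cond in names(conditions)) {
    tr <- samples_to_arrays(conditions[[cond]]$samples)
    for (seed in seeds) {
      cfg <- training; cfg$seed <- as.integer(seed)
      model <- build_classifier(conditions[[cond]]$arch, seed = seed)
      run <- train_classifier(model, tr$x, tr$y, val$x, val$y, cfg)
      sm <- stability_metrics(run$curve, cfg$stability_fraction)
      if (verbose)
        message(sprintf("%s seed %d: top %.4f stable epoch %d",
                        cond, seed, sm$top_accuracy, sm$stable_epoch))
      rows[[length(rows) + 1L]] <-
        data.frame(condition = cond, seed = seed,
                   top_accuracy = sm$top_accuracy,
                   stable_epoch = sm$stable_epoch,
                   stable_accuracy = sm$stable_accuracy,
                   time_until_stability = sm$time_until_stability)
    }
  }
  runs <- do.call(rbind, rows)
  agg <- function(v) c(mean = mean(v), sd = stats::sd(v))
  summary_df <- do.call(rbind, lapply(split(runs, runs$condition), function(d)
    data.frame(condition = d$condition[1],
               mean_top_accuracy = mean(d$top_accuracy),
               sd_top_accuracy = stats::sd(d$top_accuracy),
               mean_stable_epoch = mean(d$stable_epoch),
               mean_time_until_stability = mean(d$time_until_stability))))
  rownames(summary_df) <- NULL
  m <- function(cond) summary_df$mean_top_accuracy[summary_df$condition == cond]
  comparisons <- data.frame(
    comparison = c("control1_cnn_aug_vs_cnn_noaug",
                   "main_gcnn_noaug_vs_cnn_aug",
                   "control2_gcnn_aug_vs_gcnn_noaug"),
    new = c(m("cnn_aug"), m("gcnn_noaug"), m("gcnn_aug")),
    baseline = c(m("cnn_noaug"), m("cnn_aug"), m("gcnn_noaug")))
  comparisons$relative_improvement_pct <-
    relative_improvement(comparisons$new, comparisons$baseline)
  structure(list(runs = runs, summary = summary_df, comparisons = comparisons,
                 invariance_deviation = dev),
            class = "main_experiment")
}

#' @export
print.main_experiment <- function(x, ...) {
  cat("<main 2x2 experiment>\n")
  print(x$summary, digits = 4)
  cat("comparisons (percent change of mean top accuracy):\n")
  print(x$comparisons, digits = 3)
  invisible(x)
}

#' Stratified k-fold cross-validation of a classifier
#'
#' Builds folds with [make_cv_folds()], optionally expands each training
#' fold to its p4m orbit, trains one classifier per fold and reports the
#' per-fold test accuracies with their mean and standard deviation.
#'
#' @param samples sample list (the merged pool to fold).
#' @param k number of folds.
#' @param arch an [arch_config()].
#' @param training a [training_config()].
#' @param augment expand training folds with [augment_p4m()]?
#' @param mode,test_size fold stratification, see [make_cv_folds()].
#' @param seed fold-construction seed.
#' @param verbose print progress?
#' @return An object of class `"crossval_result"`: `fold_accuracy`
#'   (numeric vector), `mean`, `sd`.
#' @export
run_crossval <- function(samples, k, arch, training = training_config(),
                         augment = FALSE, mode = "even", test_size = NULL,
                         seed = 1L, verbose = FALSE) {
  folds <- make_cv_folds(samples, k, seed = seed, mode = mode, test_size = test_size)
  accs <- numeric(k)
  for (f in seq_len(k)) {
    tr_samples <- folds[[f]]$train
    if (augment) tr_samples <- augment_p4m(tr_samples)
    stopifnot(length(intersect(
      vapply(tr_samples, `[[`, character(1), "id"),
      vapply(folds[[f]]$test, `[[`, character(1), "id"))) == 0L)
    tr <- samples_to_arrays(tr_samples)
    te <- samples_to_arrays(folds[[f]]$test)
    cfg <- training; cfg$seed <- as.integer(seed + f)
    model <- build_classifier(arch, seed = seed + f)
    run <- train_classifier(model, tr$x, tr$y, te$x, te$y, cfg)
    accs[f] <- max(run$curve$val_accuracy)
    if (verbose) message(sprintf("fold %d: accuracy %.4f", f, accs[f]))
  }
  structure(list(fold_accuracy = accs, mean = mean(accs), sd = stats::sd(accs)),
            class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf("<%d-fold cross-validation: mean accuracy %.4f (sd %.4f)>\n",
              length(x$fold_accuracy), x$mean, x$sd))
  invisible(x)
}
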