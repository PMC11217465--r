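test_that("confusion matrices match examples and the tally oracle", {
  perfect <- confusion_matrix(c(1, 2, 3, 1), c(1, 2, 3, 1), 3)
  expect_equal(unclass(perfect), diag(c(2L, 1L, 1L)), ignore_attr = TRUE)
  all_one <- confusion_matrix(c(1, 2, 3), c(1, 1, 1), 3)
  expect_equal(colSums(all_one), c(3, 0, 0))
  set.seed(31)
  a <- sample(1:4, 50, TRUE); p <- sample(1:4, 50, TRUE)
  cm <- confusion_matrix(a, p, 4)
  expect_equal(unclass(cm), oracle_confusion(a, p, 4), ignore_attr = TRUE)
  expect_equal(sum(cm), 50)
  expect_error(confusion_matrix(c(1, 5), c(1, 1), 4), "out of range")
  expect_error(confusion_matrix(1:3, 1:2, 3), "equal length")
})

test_that("macro metrics are exact on identity and match per-class brute force", {
  idm <- confusion_matrix(1:4, 1:4, 4)
  expect_equal(macro_sensitivity(idm), 1.0)
  expect_equal(macro_specificity(idm), 1.0)
  set.seed(32)
  a <- sample(1:4, 80, TRUE); p <- sample(1:4, 80, TRUE)
  cm <- confusion_matrix(a, p, 4)
  sens <- mean(sapply(1:4, function(k) sum(a == k & p == k) / sum(a == k)))
  spec <- mean(sapply(1:4, function(k) sum(a != k & p != k) / sum(a != k)))
  expect_equal(macro_sensitivity(cm), sens)
  expect_equal(macro_specificity(cm), spec)
  # micro sensitivity is overall accuracy
  expect_equal(micro_sensitivity(cm), mean(a == p))
})

test_that("macro metrics are invariant under simultaneous class relabeling", {
  set.seed(33)
  a <- sample(1:5, 60, TRUE); p <- sample(1:5, 60, TRUE)
  cm <- confusion_matrix(a, p, 5)
  perm <- sample(1:5)
  cm2 <- confusion_matrix(perm[a], perm[p], 5)
  expect_equal(macro_sensitivity(cm), macro_sensitivity(cm2))
  expect_equal(macro_specificity(cm), macro_specificity(cm2))
})

test_that("undefined per-class metrics raise errors naming the class", {
  cm <- confusion_matrix(c(1, 1, 2), c(1, 2, 2), 3)  # class 3 never occurs
  expect_error(macro_sensitivity(cm), "class 3")
})

test_that("relative improvement reproduces the reference arithmetic", {
  expect_equal(round(relative_improvement(82.43, 76.59), 1), 7.6)
  expect_equal(relative_improvement(5, 5), 0)
  expect_equal(round(relative_improvement(76.59, 82.43), 1), -7.1)
  expect_error(relative_improvement(1, 0), "baseline")
})

test_that("power-law fitting is exact on noiseless data", {
  f <- fit_power_law(c(1, 10, 100), c(1, 0.1, 0.01))
  expect_equal(f$exponent, -1, tolerance = 1e-10)
  expect_equal(f$amplitude, 1, tolerance = 1e-10)
  expect_equal(f$amplitude, exp(f$log_a))
  flat <- fit_power_law(c(2, 4, 8), c(3, 3, 3))
  expect_equal(flat$exponent, 0, tolerance = 1e-12)
  expect_equal(flat$amplitude, 3, tolerance = 1e-12)
  expect_error(fit_power_law(c(1, 2), c(-1, 1)), "positive")
  expect_error(fit_power_law(c(2, 2), c(1, 1)), "equal")
})

test_that("power-law fits are scale-equivariant in y", {
  set.seed(34)
  x <- sort(runif(20, 10, 1000))
  y <- 2 * x^-0.4 * exp(rnorm(20, 0, 0.1))
  f1 <- fit_power_law(x, y)
  f2 <- fit_power_law(x, 5 * y)
  expect_equal(f2$exponent, f1$exponent)
  expect_equal(f2$amplitude, 5 * f1$amplitude)
  expect_equal(predict(f1, 100), f1$amplitude * 100^f1$exponent)
})

test_that("the exponent is recovered from noisy synthetic power laws", {
  set.seed(35)
  ks <- replicate(100, {
    x <- exp(seq(log(126), log(1302), length.out = 50))
    y <- 2 * x^-0.43 * exp(rnorm(50, 0, 0.05))
    fit_power_law(x, y)$exponent
  })
  expect_lt(abs(mean(ks) - (-0.43)), 0.03)
})

test_that("the scaling experiment produces one fit per condition and caches", {
  ds <- generate_dataset(synth_spec(n_classes = 2, per_class_counts = 12,
                                    image_size = 32, noise_sd = 0.05,
                                    translation_jitter = 0, seed = 41))
  ev <- generate_dataset(synth_spec(n_classes = 2, per_class_counts = 4,
                                    image_size = 32, noise_sd = 0.05,
                                    translation_jitter = 0, split = "test",
                                    seed = 42))
  archs <- list(cnn = desk_arch(32, 2, conv_channels = c(2L, 2L, 4L, 4L, 8L),
                                linear_sizes = 8L),
                gcnn = desk_arch(32, 2, conv_channels = c(2L, 2L, 4L, 4L, 8L),
                                 linear_sizes = 8L, equivariant = TRUE))
  cache <- tempfile()
  cfg <- training_config(learning_rate = 3e-3, n_epochs = 2, batch_size = 8)
  res <- run_scaling_experiment(ds$samples, ev$samples, archs,
                                sizes = c(8L, 16L), seeds = 1L,
                                training = cfg, cache_dir = cache)
  expect_equal(nrow(res$results), 4L)  # 2 sizes x 1 seed x 2 conditions
  expect_length(res$fits, 2L)
  expect_false(any(res$results$failed))
  expect_true(all(res$results$end_error >= 0 & res$results$end_error <= 1))
  # cached rerun does no training: identical results, much faster
  t0 <- proc.time()[["elapsed"]]
  res2 <- run_scaling_experiment(ds$samples, ev$samples, archs,
                                 sizes = c(8L, 16L), seeds = 1L,
                                 training = cfg, cache_dir = cache)
  expect_lt(proc.time()[["elapsed"]] - t0, 2)
  expect_equal(res2$results$end_error, res$results$end_error)
})

test_that("scaling rejects unsorted sizes and unnamed conditions", {
  expect_error(run_scaling_experiment(list(), list(), list(desk_arch(32, 2)),
                                      c(8, 16), 1), "named")
})
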