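small_spec <- function(...) {
  synth_spec(n_classes = 4, per_class_counts = 10, image_size = 32,
             noise_sd = 0.05, translation_jitter = 1, seed = 1, ...)
}

test_that("generation honours counts, ranges and determinism", {
  ds <- generate_dataset(small_spec())
  expect_length(ds$samples, 40L)
  expect_equal(as.vector(table(sample_labels(ds$samples))), rep(10L, 4))
  rng <- range(vapply(ds$samples, function(s) range(s$image), numeric(2)))
  expect_true(rng[1] >= 0 && rng[2] <= 1)
  ds2 <- generate_dataset(small_spec())
  expect_identical(ds$samples, ds2$samples)
  expect_equal(nrow(ds$manifest), 40L)
})

test_that("p4-mode samples are group transforms of their class template", {
  spec <- synth_spec(n_classes = 3, per_class_counts = 6, image_size = 32,
                     noise_sd = 0, translation_jitter = 0, seed = 5)
  ds <- generate_dataset(spec)
  p4 <- symmetry_group("p4")
  templates <- lapply(spec$morphologies, render_template, image_size = 32)
  for (s in ds$samples) {
    matches <- vapply(p4$elements, function(g)
      isTRUE(all.equal(g_act(g, templates[[s$label]]), s$image)), logical(1))
    # radially symmetric classes can match under several rotations
    expect_gte(sum(matches), 1L)
  }
})

test_that("distinct classes render distinct templates", {
  morphs <- default_morphologies(14, 64)
  imgs <- lapply(morphs, render_template, image_size = 64)
  for (i in 1:13) for (j in (i + 1):14)
    expect_false(isTRUE(all.equal(imgs[[i]], imgs[[j]])))
})

test_that("oversized geometry is rejected", {
  m <- class_morphology(1, ring_radius = 30, ring_thickness = 2)
  expect_error(render_template(m, 32), "exceeds image bounds")
})

test_that("p4m augmentation yields exactly the 8-element orbit", {
  ds <- generate_dataset(small_spec())
  aug <- augment_p4m(ds$samples[1:3])
  expect_length(aug, 24L)
  expect_length(augment_p4m(ds$samples[1]), 8L)
  flags <- vapply(aug[1:8], `[[`, logical(1), "is_augmented")
  expect_equal(sum(!flags), 1L)  # only the identity copy keeps its flag
  # an asymmetric image has eight pairwise distinct transforms
  img <- matrix(0, 6, 6); img[2, 3] <- 1
  s <- list(list(image = img, label = 1L, is_augmented = FALSE,
                 provenance = "probe", id = "probe", split = "train"))
  orbit <- augment_p4m(s)
  for (i in 1:7) for (j in (i + 1):8)
    expect_false(identical(orbit[[i]]$image, orbit[[j]]$image))
})

test_that("rebalancing removes augmented samples first, then originals", {
  mk <- function(id, label, aug) list(image = matrix(0, 2, 2), label = label,
                                      is_augmented = aug, provenance = id,
                                      id = id, split = "train")
  # class 1: 5 originals + 10 augmented; class 2: 6 originals (the minimum)
  samples <- c(lapply(1:5, function(i) mk(paste0("o", i), 1L, FALSE)),
               lapply(1:10, function(i) mk(paste0("a", i), 1L, TRUE)),
               lapply(1:6, function(i) mk(paste0("m", i), 2L, FALSE)))
  out <- rebalance(samples, seed = 3, target = 6)
  labs <- sample_labels(out)
  expect_equal(as.vector(table(labs)), c(6L, 6L))
  kept1 <- out[labs == 1L]
  augkept <- vapply(kept1, `[[`, logical(1), "is_augmented")
  expect_equal(sum(!augkept), 5L)  # all originals retained
  expect_equal(sum(augkept), 1L)   # exactly one augmented survivor
  # simple numeric case {3, 5} -> {3, 3}
  s2 <- c(lapply(1:3, function(i) mk(paste0("x", i), 1L, FALSE)),
          lapply(1:5, function(i) mk(paste0("y", i), 2L, FALSE)))
  expect_equal(as.vector(table(sample_labels(rebalance(s2, 1)))), c(3L, 3L))
})

test_that("augment-then-rebalance on a balanced set strips the augmentation", {
  ds <- generate_dataset(small_spec())
  aug <- augment_p4m(ds$samples)
  back <- rebalance(aug, seed = 2)
  expect_length(back, length(ds$samples))
  expect_false(any(vapply(back, `[[`, logical(1), "is_augmented")))
})

test_that("subsampling is balanced, seeded and nested", {
  ds <- generate_dataset(synth_spec(n_classes = 4, per_class_counts = 30,
                                    image_size = 32, seed = 7))
  sub <- subsample_training(ds$samples, 48, seed = 9)
  expect_equal(as.vector(table(sample_labels(sub))), rep(12L, 4))
  # uneven total: counts differ by at most one
  sub2 <- subsample_training(ds$samples, 50, seed = 9)
  counts <- table(sample_labels(sub2))
  expect_lte(diff(range(counts)), 1)
  expect_equal(sum(counts), 50L)
  # nesting for a fixed seed
  ids <- function(s) vapply(s, `[[`, character(1), "id")
  expect_true(all(ids(sub) %in% ids(sub2)))
  small <- subsample_training(ds$samples, 20, seed = 9)
  expect_true(all(ids(small) %in% ids(sub)))
  # identity and error branches
  expect_length(subsample_training(ds$samples, 120, seed = 1), 120L)
  expect_error(subsample_training(ds$samples, 121, seed = 1), "available")
})

test_that("the 126-of-1302 subsample takes nine per class over 14 classes", {
  mk <- function(cls, i) list(image = matrix(0, 2, 2), label = cls,
                              is_augmented = FALSE, provenance = "x",
                              id = sprintf("c%d_%d", cls, i), split = "train")
  pool <- unlist(lapply(1:14, function(cls) lapply(1:93, function(i) mk(cls, i))),
                 recursive = FALSE)
  expect_length(pool, 1302L)
  sub <- subsample_training(pool, 126, seed = 1)
  expect_equal(as.vector(table(sample_labels(sub))), rep(9L, 14))
})

test_that("cross-validation folds are disjoint, exhaustive and stratified", {
  ds <- generate_dataset(synth_spec(n_classes = 3, per_class_counts = 13,
                                    image_size = 32, seed = 8))
  folds <- make_cv_folds(ds$samples, 5, seed = 2)
  ids <- function(s) sort(vapply(s, `[[`, character(1), "id"))
  all_test <- unlist(lapply(folds, function(f) ids(f$test)))
  expect_equal(sort(all_test), ids(ds$samples))   # union = everything, disjoint
  expect_equal(anyDuplicated(all_test), 0L)
  for (f in folds) {
    expect_length(intersect(ids(f$train), ids(f$test)), 0L)
    counts <- table(sample_labels(f$test))
    expect_lte(diff(range(counts)), 1)
  }
})

test_that("fixed-size folds reproduce the 100/23 split on 123 per class", {
  mk <- function(cls, i) list(image = matrix(0, 2, 2), label = cls,
                              is_augmented = FALSE, provenance = "x",
                              id = sprintf("c%d_%d", cls, i), split = "train")
  pool <- unlist(lapply(1:2, function(cls) lapply(1:123, function(i) mk(cls, i))),
                 recursive = FALSE)
  folds <- make_cv_folds(pool, 5, seed = 3, mode = "fixed", test_size = 23)
  for (f in folds) {
    expect_equal(as.vector(table(sample_labels(f$test))), rep(23L, 2))
    expect_equal(as.vector(table(sample_labels(f$train))), rep(100L, 2))
  }
  # even mode consumes everything: per-class fold sizes 24,24,25,25,25
  ev <- make_cv_folds(pool, 5, seed = 3, mode = "even")
  sizes <- sort(vapply(ev, function(f) length(f$test) / 2L, numeric(1)))
  expect_equal(sizes, c(24, 24, 25, 25, 25))
  expect_error(make_cv_folds(pool[1:4], 5, seed = 1), "fewer than")
})

test_that("labels are invariant under any p4m transform of the images", {
  ds <- generate_dataset(small_spec())
  aug <- augment_p4m(ds$samples)
  base <- sample_labels(ds$samples)
  expect_equal(sample_labels(aug), rep(base, each = 8L))
})

test_that("datasets round-trip through disk at both bit depths", {
  ds <- generate_dataset(synth_spec(n_classes = 2, per_class_counts = 3,
                                    image_size = 32, seed = 4))
  for (depth in c(8L, 16L)) {
    dir <- file.path(tempfile(), paste0("d", depth))
    manifest <- write_dataset(ds$samples, dir, bit_depth = depth)
    expect_equal(nrow(manifest), length(list.files(dir, pattern = "\\.(png|tif)$")))
    back <- read_dataset(dir)
    expect_equal(sample_labels(back$samples), sample_labels(ds$samples))
    expect_equal(as.vector(table(back$manifest$label)),
                 as.vector(table(ds$manifest$label)))
    tol <- if (depth == 8L) 1 / 255 else 1 / 65535
    for (i in seq_along(ds$samples))
      expect_lte(max(abs(back$samples[[i]]$image - ds$samples[[i]]$image)), tol)
  }
})

test_that("reading fails loudly when manifest rows lack files", {
  ds <- generate_dataset(synth_spec(n_classes = 2, per_class_counts = 2,
                                    image_size = 32, seed = 4))
  dir <- tempfile()
  manifest <- write_dataset(ds$samples, dir)
  unlink(file.path(dir, manifest$filename[2]))
  expect_error(read_dataset(dir), manifest$filename[2])
})

test_that("continuous orientation mode produces in-range rotated samples", {
  spec <- synth_spec(n_classes = 2, per_class_counts = 2, image_size = 32,
                     noise_sd = 0, translation_jitter = 0,
                     orientation_mode = "continuous", seed = 6)
  ds <- generate_dataset(spec)
  expect_length(ds$samples, 4L)
  for (s in ds$samples) {
    expect_true(all(s$image >= 0 & s$image <= 1))
    expect_true(grepl("angle=", s$provenance))
  }
})
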