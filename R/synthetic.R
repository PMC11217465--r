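#' Morphology of one synthetic particle class
#'
#' Parameterizes a rotation-invariant particle rendered at the image centre:
#' a bright ring (capsid envelope), an optional corona of `n_spikes`
#' radially arranged protrusions, and a radial internal texture. Classes are
#' told apart by morphology only, never by orientation.
#'
#' @param class_id integer class label.
#' @param ring_radius ring radius in pixels.
#' @param ring_thickness Gaussian thickness of the ring in pixels.
#' @param n_spikes number of corona protrusions (>= 0).
#' @param texture_frequency radial frequency (cycles/pixel) of the internal
#'   texture; 0 disables it.
#' @param intensity peak intensity in (0, 1].
#' @return An object of class `"class_morphology"`.
#' @export
class_morphology <- function(class_id, ring_radius, ring_thickness,
                             n_spikes = 0L, texture_frequency = 0,
                             intensity = 1) {
  if (ring_radius <= 0 || ring_thickness <= 0) stop("ring geometry must be positive")
  if (n_spikes < 0L) stop("'n_spikes' must be >= 0")
  if (intensity <= 0 || intensity > 1) stop("'intensity' must be in (0, 1]")
  structure(list(class_id = as.integer(class_id), ring_radius = ring_radius,
                 ring_thickness = ring_thickness, n_spikes = as.integer(n_spikes),
                 texture_frequency = texture_frequency, intensity = intensity),
            class = "class_morphology")
}

#' Default palette of distinct class morphologies
#'
#' All classes share the same ring radius, thickness and intensity, so no
#' purely radial (orientation-free) feature separates them; what
#' distinguishes classes is angular structure — the spike count of the
#' corona (non-multiples of four first, so that a particle's appearance
#' genuinely depends on its orientation even though its label does not) —
#' plus a mild radial texture. Geometry is scaled to the image size and
#' leaves margin for translation jitter.
#'
#' @param n_classes number of classes (<= 14).
#' @param image_size image side length in pixels.
#' @return List of [class_morphology()] objects.
#' @export
default_morphologies <- function(n_classes, image_size = 64L) {
  if (n_classes < 1L || n_classes > 14L) stop("'n_classes' must be in 1..14")
  spikes <- c(3L, 5L, 7L, 9L, 6L, 10L, 11L, 13L, 2L, 12L, 1L, 8L, 4L, 0L)
  lapply(seq_len(n_classes), function(i) {
    class_morphology(class_id = i,
                     ring_radius = image_size * 0.26,
                     ring_thickness = image_size * 0.035,
                     n_spikes = spikes[i],
                     texture_frequency = 0.15 * ((i - 1L) %% 3L),
                     intensity = 1)
  })
}

#' Render the noise-free, unrotated template of a class
#'
#' Deterministic; particle centred on the array centre (even sizes use the
#' half-pixel centre, matching the rotation convention of [g_act()]).
#'
#' @param morph a [class_morphology()].
#' @param image_size image side length.
#' @return Numeric matrix in `[0, 1]`.
#' @export
render_template <- function(morph, image_size) {
  s <- as.integer(image_size)
  ctr <- (s + 1) / 2
  spike_len <- if (morph$n_spikes > 0L) 2.2 * morph$ring_thickness + 2 else 0
  if (morph$ring_radius + spike_len + 2 > s / 2)
    stop(sprintf("class %d geometry (radius %.1f + spikes) exceeds image bounds",
                 morph$class_id, morph$ring_radius))
  dx <- matrix(rep(seq_len(s) - ctr, each = s), s, s)   # column offset
  dy <- matrix(rep(seq_len(s) - ctr, times = s), s, s)  # row offset
  r <- sqrt(dx^2 + dy^2)
  img <- morph$intensity * exp(-(r - morph$ring_radius)^2 /
                                 (2 * morph$ring_thickness^2))
  if (morph$n_spikes > 0L) {
    sr <- morph$ring_radius + spike_len
    ssd <- morph$ring_thickness * 0.8
    for (k in seq_len(morph$n_spikes)) {
      phi <- 2 * pi * (k - 1) / morph$n_spikes
      d2 <- (dx - sr * cos(phi))^2 + (dy - sr * sin(phi))^2
      img <- img + 0.9 * morph$intensity * exp(-d2 / (2 * ssd^2))
    }
  }
  if (morph$texture_frequency > 0) {
    inside <- r < morph$ring_radius - morph$ring_thickness
    img <- img + inside * 0.45 * morph$intensity *
      (0.5 + 0.5 * cos(2 * pi * morph$texture_frequency * r))
  }
  pmin(pmax(img, 0), 1)
}

shift_image <- function(img, drow, dcol) {
  s <- nrow(img)
  out <- matrix(0, s, s)
  rs <- seq_len(s) - drow
  cs <- seq_len(s) - dcol
  ok_r <- rs >= 1L & rs <= s
  ok_c <- cs >= 1L & cs <= s
  out[which(ok_r), which(ok_c)] <- img[rs[ok_r], cs[ok_c]]
  out
}

rotate_bilinear <- function(img, angle_deg) {
  s <- nrow(img)
  ctr <- (s + 1) / 2
  th <- angle_deg * pi / 180
  co <- cos(th); si <- sin(th)
  out <- matrix(0, s, s)
  for (j in seq_len(s)) {
    xo <- j - ctr
    for (i in seq_len(s)) {
      yo <- i - ctr
      # inverse map: sample source at rotation by -angle
      xs <- co * xo + si * yo + ctr
      ys <- -si * xo + co * yo + ctr
      x0 <- floor(xs); y0 <- floor(ys)
      if (x0 < 1 || y0 < 1 || x0 >= s || y0 >= s) next
      fx <- xs - x0; fy <- ys - y0
      out[i, j] <- (1 - fx) * ((1 - fy) * img[y0, x0] + fy * img[y0 + 1, x0]) +
        fx * ((1 - fy) * img[y0, x0 + 1] + fy * img[y0 + 1, x0 + 1])
    }
  }
  out
}

#' Specification of a synthetic rotation-invariant dataset
#'
#' @param n_classes number of particle classes.
#' @param per_class_counts integer vector of samples per class (recycled to
#'   `n_classes` if scalar).
#' @param image_size image side length (default 64; use 256 to mirror
#'   full-scale TEM crops).
#' @param noise_sd standard deviation of the additive Gaussian noise
#'   (clipped to `[0, 1]` after addition).
#' @param translation_jitter maximum absolute centre shift in pixels.
#' @param orientation_mode `"p4"` draws exact quarter-turn orientations
#'   (interpolation-free); `"continuous"` draws arbitrary angles with
#'   bilinear interpolation (excluded from exact-equivariance testing).
#' @param morphologies optional list of [class_morphology()]; defaults to
#'   [default_morphologies()].
#' @param split split tag recorded in the manifest (`"train"`,
#'   `"validation"` or `"test"`).
#' @param seed RNG seed; generation is a pure function of (spec, seed).
#' @return An object of class `"synth_spec"`.
#' @export
synth_spec <- function(n_classes = 4L, per_class_counts = 10L, image_size = 64L,
                       noise_sd = 0.1, translation_jitter = 2L,
                       orientation_mode = c("p4", "continuous"),
                       morphologies = NULL, split = "train", seed = 1L) {
  orientation_mode <- match.arg(orientation_mode)
  if (length(per_class_counts) == 1L)
    per_class_counts <- rep(as.integer(per_class_counts), n_classes)
  if (length(per_class_counts) != n_classes)
    stop("'per_class_counts' must have length n_classes")
  if (any(per_class_counts < 1L)) stop("all per-class counts must be >= 1")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (!split %in% c("train", "validation", "test")) stop("invalid 'split'")
  if (is.null(morphologies)) morphologies <- default_morphologies(n_classes, image_size)
  if (length(morphologies) != n_classes)
    stop("'morphologies' must have one entry per class")
  structure(list(n_classes = as.integer(n_classes),
                 per_class_counts = as.integer(per_class_counts),
                 image_size = as.integer(image_size), noise_sd = noise_sd,
                 translation_jitter = as.integer(translation_jitter),
                 orientation_mode = orientation_mode,
                 morphologies = morphologies, split = split,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a labelled synthetic dataset
#'
#' Each sample is its class template rendered at a random global orientation
#' (a p4 element, or an arbitrary angle in continuous mode), translated by
#' integer jitter, with additive clipped Gaussian noise. The label depends
#' only on the morphology, never on the orientation. Deterministic given the
#' spec's seed.
#'
#' @param spec a [synth_spec()].
#' @return List with `samples` (list of sample records: `image`, `label`,
#'   `is_augmented`, `provenance`, `id`, `split`) and `manifest` (data
#'   frame, see [dataset_manifest()]).
#' @export
generate_dataset <- function(spec) {
  if (!inherits(spec, "synth_spec")) stop("'spec' must be a synth_spec")
  set.seed(spec$seed)
  p4 <- symmetry_group("p4")
  templates <- lapply(spec$morphologies, render_template,
                      image_size = spec$image_size)
  samples <- list()
  for (cls in seq_len(spec$n_classes)) {
    for (i in seq_len(spec$per_class_counts[cls])) {
      if (spec$orientation_mode == "p4") {
        gi <- sample.int(p4$order, 1L)
        img <- g_act(p4$elements[[gi]], templates[[cls]])
        orient <- sprintf("g=%s", format(p4$elements[[gi]]))
      } else {
        ang <- stats::runif(1, 0, 360)
        img <- rotate_bilinear(templates[[cls]], ang)
        orient <- sprintf("angle=%.2f", ang)
      }
      j <- spec$translation_jitter
      dr <- if (j > 0) sample(-j:j, 1L) else 0L
      dc <- if (j > 0) sample(-j:j, 1L) else 0L
      if (dr != 0L || dc != 0L) img <- shift_image(img, dr, dc)
      if (spec$noise_sd > 0)
        img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sd), nrow(img))
      img <- pmin(pmax(img, 0), 1)
      id <- sprintf("c%02d_s%04d", cls, i)
      samples[[length(samples) + 1L]] <-
        list(image = img, label = cls, is_augmented = FALSE,
             provenance = sprintf("%s:%s:jitter=%d,%d", id, orient, dr, dc),
             id = id, split = spec$split)
    }
  }
  list(samples = samples, manifest = dataset_manifest(samples))
}

#' Manifest data frame for a list of samples
#'
#' @param samples list of sample records.
#' @param bit_depth bit depth recorded for on-disk storage (8 or 16).
#' @return Data frame with columns `filename`, `label`, `split`,
#'   `is_augmented`, `provenance`, `bit_depth`.
#' @export
dataset_manifest <- function(samples, bit_depth = 8L) {
  ext <- if (bit_depth == 16L) ".tif" else ".png"
  data.frame(filename = paste0(vapply(samples, `[[`, character(1), "id"), ext),
             label = vapply(samples, `[[`, integer(1), "label"),
             split = vapply(samples, `[[`, character(1), "split"),
             is_augmented = vapply(samples, `[[`, logical(1), "is_augmented"),
             provenance = vapply(samples, `[[`, character(1), "provenance"),
             bit_depth = as.integer(bit_depth),
             stringsAsFactors = FALSE)
}

#' Class labels of a sample list
#'
#' @param samples list of sample records.
#' @return Integer vector of labels.
#' @export
sample_labels <- function(samples) vapply(samples, `[[`, integer(1), "label")

#' Expand samples to their full p4m orbit
#'
#' Each input image yields its eight p4m transforms (identity included) in
#' canonical group order, i.e. the three further quarter-turn rotations and
#' the four reflected versions. The identity copy keeps the original
#' `is_augmented` flag; the other seven are marked augmented.
#'
#' @param samples list of sample records with square images.
#' @return List of `8 * length(samples)` sample records.
#' @export
augment_p4m <- function(samples) {
  p4m <- symmetry_group("p4m")
  out <- list()
  for (s in samples) {
    for (gi in seq_len(p4m$order)) {
      g <- p4m$elements[[gi]]
      is_id <- gi == p4m$identity_index
      rec <- s
      rec$image <- g_act(g, s$image)
      rec$is_augmented <- if (is_id) s$is_augmented else TRUE
      rec$provenance <- paste0(s$provenance, ":aug=", format(g))
      rec$id <- sprintf("%s_a%d", s$id, gi - 1L)
      out[[length(out) + 1L]] <- rec
    }
  }
  out
}

#' Rebalance classes down to the smallest original class count
#'
#' Every class is downsampled to `target`, which defaults to the lowest
#' per-class count of original (non-augmented) samples — the rule used to
#' equalize class sizes before training. Within a class, augmented samples
#' are removed first (in seeded random order), then originals uniformly at
#' random; classes already at or below the target are untouched.
#'
#' @param samples list of sample records.
#' @param seed RNG seed for the random removals.
#' @param target per-class count to downsample to; `NULL` for the default
#'   rule above.
#' @return The retained samples, original order preserved.
#' @export
rebalance <- function(samples, seed = 1L, target = NULL) {
  labels <- sample_labels(samples)
  counts <- table(labels)
  if (any(counts < 1L)) stop("every class must have at least one sample")
  if (is.null(target)) {
    aug <- vapply(samples, `[[`, logical(1), "is_augmented")
    target <- min(vapply(as.integer(names(counts)), function(cls) {
      n_orig <- sum(labels == cls & !aug)
      if (n_orig > 0L) n_orig else sum(labels == cls)
    }, integer(1)))
  }
  target <- as.integer(target)
  if (target < 1L) stop("'target' must be >= 1")
  set.seed(as.integer(seed))
  drop <- logical(length(samples))
  for (cls in as.integer(names(counts))) {
    idx <- which(labels == cls)
    n_rm <- length(idx) - target
    if (n_rm <= 0L) next
    aug <- idx[vapply(samples[idx], `[[`, logical(1), "is_augmented")]
    ori <- setdiff(idx, aug)
    rm_aug <- if (length(aug)) sample(aug)[seq_len(min(n_rm, length(aug)))] else integer()
    rest <- n_rm - length(rm_aug)
    rm_ori <- if (rest > 0L) sample(ori)[seq_len(rest)] else integer()
    drop[c(rm_aug, rm_ori)] <- TRUE
  }
  samples[!drop]
}

#' Class-balanced nested subsample of a training set
#'
#' Draws `n_total` samples with per-class counts differing by at most one.
#' For a fixed seed the subsets are nested: the subset of a smaller
#' `n_total` is contained in that of a larger one, reducing variance across
#' training-set sizes in scaling experiments.
#'
#' @param samples list of sample records.
#' @param n_total total number of samples to keep.
#' @param seed RNG seed.
#' @return The selected samples, original order preserved.
#' @export
subsample_training <- function(samples, n_total, seed = 1L) {
  labels <- sample_labels(samples)
  classes <- sort(unique(labels))
  k <- length(classes)
  n_total <- as.integer(n_total)
  if (n_total > length(samples))
    stop(sprintf("requested %d samples but only %d available", n_total, length(samples)))
  if (n_total < 0L) stop("'n_total' must be >= 0")
  set.seed(as.integer(seed))
  prio <- sample(classes)                      # remainder priority, fixed per seed
  perms <- lapply(classes, function(cl) sample(which(labels == cl)))
  base <- n_total %/% k
  rem <- n_total %% k
  keep <- integer()
  for (ci in seq_len(k)) {
    m <- base + as.integer(match(classes[ci], prio) <= rem)
    if (m > length(perms[[ci]]))
      stop(sprintf("class %d has only %d sample(s) but %d requested",
                   classes[ci], length(perms[[ci]]), m))
    keep <- c(keep, perms[[ci]][seq_len(m)])
  }
  samples[sort(keep)]
}

#' Stratified k-fold cross-validation folds
#'
#' Partitions each class into `k` disjoint test folds (seeded); each pair's
#' training set is the complement. Two stratifications are available:
#' `"even"` splits each class as evenly as possible (fold sizes differing by
#' at most one); `"fixed"` puts exactly `test_size` samples per class in
#' each test fold and leaves any per-class remainder permanently in
#' training (with 123 samples per class, `k = 5` and `test_size = 23` this
#' reproduces test folds of 23 and training folds of 100 per class).
#'
#' @param samples list of sample records.
#' @param k number of folds.
#' @param seed RNG seed.
#' @param mode `"even"` or `"fixed"`.
#' @param test_size per-class test-fold size for `"fixed"` mode (default
#'   `floor(min class count / k)`).
#' @return List of `k` lists, each with `train` and `test` sample lists.
#' @export
make_cv_folds <- function(samples, k, seed = 1L, mode = c("even", "fixed"),
                          test_size = NULL) {
  mode <- match.arg(mode)
  labels <- sample_labels(samples)
  counts <- table(labels)
  k <- as.integer(k)
  if (any(counts < k))
    stop(sprintf("class %s has fewer than k = %d samples",
                 names(counts)[which.min(counts)], k))
  set.seed(as.integer(seed))
  fold_of <- integer(length(samples))  # 0 = never in a test fold
  for (cls in as.integer(names(counts))) {
    idx <- sample(which(labels == cls))
    n <- length(idx)
    if (mode == "even") {
      sizes <- rep(n %/% k, k) + as.integer(seq_len(k) <= n %% k)
    } else {
      ts <- if (is.null(test_size)) min(counts) %/% k else as.integer(test_size)
      if (k * ts > n)
        stop(sprintf("class %d: k * test_size = %d exceeds class count %d",
                     cls, k * ts, n))
      sizes <- rep(ts, k)
    }
    pos <- 1L
    for (f in seq_len(k)) {
      if (sizes[f] > 0L) {
        fold_of[idx[pos:(pos + sizes[f] - 1L)]] <- f
        pos <- pos + sizes[f]
      }
    }
  }
  lapply(seq_len(k), function(f)
    list(train = samples[fold_of != f], test = samples[fold_of == f]))
}

#' Write a dataset to disk (images + CSV manifest)
#'
#' Images are stored as 8-bit grayscale PNG or, for `bit_depth = 16`,
#' 16-bit grayscale TIFF (the PNG writer available to the package is
#' 8-bit-only for grayscale); the format is declared per row in the
#' manifest. The manifest is `manifest.csv` with header
#' `filename,label,split,is_augmented,provenance,bit_depth`.
#'
#' @param samples list of sample records.
#' @param dir output directory (created if missing).
#' @param bit_depth 8 or 16.
#' @return The manifest data frame, invisibly.
#' @export
write_dataset <- function(samples, dir, bit_depth = 8L) {
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("'bit_depth' must be 8 or 16")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- dataset_manifest(samples, bit_depth)
  for (i in seq_along(samples)) {
    path <- file.path(dir, manifest$filename[i])
    if (bit_depth == 8L) png::writePNG(samples[[i]]$image, path)
    else tiff::writeTIFF(samples[[i]]$image, path, bits.per.sample = 16L)
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @return List with `samples` and `manifest`. Missing image files raise an
#'   integrity error listing the offenders.
#' @export
read_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("no manifest.csv in ", dir)
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  paths <- file.path(dir, manifest$filename)
  missing <- manifest$filename[!file.exists(paths)]
  if (length(missing))
    stop("manifest lists missing image file(s): ", paste(missing, collapse = ", "))
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- if (grepl("\\.tif$", manifest$filename[i])) tiff::readTIFF(paths[i])
           else png::readPNG(paths[i])
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    list(image = img, label = as.integer(manifest$label[i]),
         is_augmented = as.logical(manifest$is_augmented[i]),
         provenance = manifest$provenance[i],
         id = sub("\\.(png|tif)$", "", manifest$filename[i]),
         split = manifest$split[i])
  })
  list(samples = samples, manifest = manifest)
}

#' Convert a list of samples to image/label arrays
#'
#' @param samples list of sample records.
#' @return List with `x` (array `(H, W, N)`) and `y` (integer labels).
#' @export
samples_to_arrays <- function(samples) {
  if (!length(samples)) stop("empty sample list")
  s <- nrow(samples[[1]]$image)
  x <- array(0, c(s, s, length(samples)))
  for (i in seq_along(samples)) x[, , i] <- samples[[i]]$image
  list(x = x, y = sample_labels(samples))
}
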