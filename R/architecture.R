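#' Layer geometry specification
#'
#' @param kernel window side length.
#' @param stride stride (>= 1).
#' @param pad symmetric zero padding (>= 0).
#' @return A one-row data frame with columns `kernel`, `stride`, `pad`.
#' @export
layer_spec <- function(kernel, stride = 1L, pad = 0L) {
  kernel <- as.integer(kernel); stride <- as.integer(stride); pad <- as.integer(pad)
  if (stride < 1L) stop("'stride' must be >= 1")
  if (pad < 0L) stop("'pad' must be >= 0")
  data.frame(kernel = kernel, stride = stride, pad = pad)
}

default_conv_specs <- function() {
  rbind(do.call(rbind, replicate(12, layer_spec(3, 1, 1), simplify = FALSE)),
        layer_spec(4, 1, 0))
}

default_pool_specs <- function() {
  rbind(do.call(rbind, replicate(4, layer_spec(2, 2, 0), simplify = FALSE)),
        layer_spec(13, 1, 0))
}

#' Declarative VGG16-style architecture description
#'
#' One description from which both the baseline CNN and its group-equivariant
#' counterpart are derived. The defaults encode the full-scale reference schedule:
#' thirteen convolutions with channel schedule
#' 32-32-64-64-128-128-128-256-256-256-256-256-256, layers 1-12 of spec
#' (3,1,1) and layer 13 of (4,1,0), max pools after layers 2, 4, 7, 10 and 13
#' (four (2,2,0) pools and one final (13,1,0) global pool), two 4096-wide
#' hidden linear layers with dropout 0.5 between them, and 14 output classes.
#' When `equivariant` is set, every convolution becomes a group convolution
#' (the first a lifting convolution) and the channel counts are divided by
#' `channel_divisor` so the weight count per group-to-group layer matches the
#' baseline on p4.
#'
#' @param input_size input image side length in pixels (square).
#' @param input_channels input channels (1 for grayscale).
#' @param conv_channels integer vector of conv output channels per layer.
#' @param conv_specs data frame of [layer_spec()] rows, one per conv layer.
#' @param pool_after conv-layer indices followed by a max pool.
#' @param pool_specs data frame of [layer_spec()] rows, one per pool.
#' @param linear_sizes widths of the hidden linear layers.
#' @param n_classes number of output classes (>= 2).
#' @param dropout_rate dropout probability between linear layers.
#' @param equivariant build the group-equivariant variant?
#' @param group_name `"p4"` or `"p4m"`.
#' @param channel_divisor divisor applied to conv/linear widths when
#'   `equivariant` (2 keeps p4 group-layer weight counts equal to baseline).
#' @return An object of class `"arch_config"`.
#' @export
arch_config <- function(input_size = 256L,
                        input_channels = 1L,
                        conv_channels = c(32L, 32L, 64L, 64L, 128L, 128L, 128L,
                                          256L, 256L, 256L, 256L, 256L, 256L),
                        conv_specs = default_conv_specs(),
                        pool_after = c(2L, 4L, 7L, 10L, 13L),
                        pool_specs = default_pool_specs(),
                        linear_sizes = c(4096L, 4096L),
                        n_classes = 14L,
                        dropout_rate = 0.5,
                        equivariant = FALSE,
                        group_name = c("p4", "p4m"),
                        channel_divisor = 2L) {
  group_name <- match.arg(group_name)
  n_conv <- length(conv_channels)
  if (nrow(conv_specs) != n_conv)
    stop("conv_specs must have one row per conv layer")
  if (length(pool_after) != nrow(pool_specs))
    stop("pool_specs must have one row per pooled layer")
  if (any(pool_after < 1L | pool_after > n_conv))
    stop("pool_after indices out of range")
  if (n_classes < 2L) stop("'n_classes' must be >= 2")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("'dropout_rate' must be in [0, 1)")
  cfg <- structure(list(input_size = as.integer(input_size),
                        input_channels = as.integer(input_channels),
                        conv_channels = as.integer(conv_channels),
                        conv_specs = conv_specs,
                        pool_after = as.integer(pool_after),
                        pool_specs = pool_specs,
                        linear_sizes = as.integer(linear_sizes),
                        n_classes = as.integer(n_classes),
                        dropout_rate = dropout_rate,
                        equivariant = isTRUE(equivariant),
                        group_name = group_name,
                        channel_divisor = as.integer(channel_divisor)),
                   class = "arch_config")
  spatial_trace(cfg)  # validates; errors name the offending layer
  cfg
}

#' Compact architecture preset for desk-scale experiments
#'
#' A reduced VGG-style schedule (five convolutions, two pool stages plus a
#' global pool) for small synthetic images, preserving the structure of the
#' full architecture: all-(3,1,1) convolutions except a final (4,1,0), and a
#' global max pool collapsing the last feature map to 1x1.
#'
#' @param input_size input side length (32 or 64 work out of the box).
#' @param n_classes number of classes.
#' @param conv_channels five conv widths (baseline scale; halved when
#'   `equivariant`).
#' @param linear_sizes hidden linear widths.
#' @param equivariant build the group-equivariant variant?
#' @param group_name `"p4"` or `"p4m"`.
#' @return An [arch_config()].
#' @export
desk_arch <- function(input_size = 64L, n_classes = 4L,
                      conv_channels = c(8L, 8L, 16L, 16L, 32L),
                      linear_sizes = 32L,
                      equivariant = FALSE, group_name = "p4") {
  specs <- rbind(do.call(rbind, replicate(4, layer_spec(3, 1, 1), simplify = FALSE)),
                 layer_spec(4, 1, 0))
  # spatial size reaching the last conv: two halvings, then kernel-4 valid conv
  before_last <- input_size %/% 4L
  final_pool <- before_last - 4L + 1L
  if (final_pool < 1L) stop("'input_size' too small for the desk preset")
  arch_config(input_size = input_size, input_channels = 1L,
              conv_channels = conv_channels, conv_specs = specs,
              pool_after = c(2L, 4L, 5L),
              pool_specs = rbind(layer_spec(2, 2, 0), layer_spec(2, 2, 0),
                                 layer_spec(final_pool, 1, 0)),
              linear_sizes = linear_sizes, n_classes = n_classes,
              dropout_rate = 0.5, equivariant = equivariant,
              group_name = group_name)
}

conv_out_size <- function(s, kernel, stride, pad) {
  (s + 2L * pad - kernel) %/% stride + 1L
}

#' Spatial size trace through an architecture
#'
#' @param config an [arch_config()].
#' @return Data frame with one row per conv/pool stage: `stage`, `layer`,
#'   `size_in`, `size_out`. Errors name the first layer whose window no
#'   longer fits.
#' @export
spatial_trace <- function(config) {
  s <- config$input_size
  rows <- list()
  pool_of <- match(seq_along(config$conv_channels), config$pool_after)
  for (i in seq_along(config$conv_channels)) {
    sp <- config$conv_specs[i, ]
    if (s + 2L * sp$pad < sp$kernel)
      stop(sprintf("conv layer %d: kernel %d larger than padded input %d",
                   i, sp$kernel, s + 2L * sp$pad))
    s2 <- conv_out_size(s, sp$kernel, sp$stride, sp$pad)
    if (s2 < 1L) stop(sprintf("conv layer %d: output size %d invalid", i, s2))
    rows[[length(rows) + 1L]] <- data.frame(stage = "conv", layer = i,
                                            size_in = s, size_out = s2)
    s <- s2
    if (!is.na(pool_of[i])) {
      pp <- config$pool_specs[pool_of[i], ]
      if (pp$kernel > s)
        stop(sprintf("max pool after conv layer %d: window %d larger than input %d",
                     i, pp$kernel, s))
      s2 <- conv_out_size(s, pp$kernel, pp$stride, 0L)
      rows[[length(rows) + 1L]] <- data.frame(stage = "pool", layer = i,
                                              size_in = s, size_out = s2)
      s <- s2
    }
  }
  do.call(rbind, rows)
}

#' Flattened feature count entering the first linear layer
#'
#' @param config an [arch_config()].
#' @return Integer: final spatial size squared times the final channel count
#'   (after group pooling and channel halving for the equivariant variant).
#' @export
flatten_width <- function(config) {
  tr <- spatial_trace(config)
  s <- tr$size_out[nrow(tr)]
  ch <- config$conv_channels[length(config$conv_channels)]
  if (config$equivariant) ch <- max(1L, ch %/% config$channel_divisor)
  s * s * ch
}

he_init <- function(n, fan_in) {
  stats::rnorm(n, mean = 0, sd = sqrt(2 / fan_in))
}

#' Build a classifier from an architecture description
#'
#' Baseline: thirteen planar convolutions with ReLU, max pools per schedule,
#' flatten, then the linear stack with dropout between linear layers.
#' Equivariant variant: the first convolution is a lifting convolution, the
#' rest group convolutions, conv/linear widths divided by the channel
#' divisor, and a group pooling layer inserted after the final spatial pool,
#' before the linear layers. Weights use He initialization (fan-in for group
#' layers includes the group axis); biases start at zero. Deterministic
#' given `seed`.
#'
#' @param config an [arch_config()].
#' @param seed integer RNG seed for the initialization.
#' @return An object of class `"classifier_model"`.
#' @export
build_classifier <- function(config, seed = 1L) {
  if (!inherits(config, "arch_config")) stop("'config' must be an arch_config")
  set.seed(as.integer(seed))
  eq <- config$equivariant
  group <- if (eq) symmetry_group(config$group_name) else NULL
  G <- if (eq) group$order else 1L
  div <- if (eq) config$channel_divisor else 1L
  channels <- pmax(1L, config$conv_channels %/% div)

  layers <- list()
  cin <- config$input_channels
  pool_of <- match(seq_along(channels), config$pool_after)
  for (i in seq_along(channels)) {
    sp <- config$conv_specs[i, ]
    k <- sp$kernel; cout <- channels[i]
    if (!eq) {
      w <- array(he_init(k * k * cin * cout, cin * k * k), c(k, k, cin, cout))
      layers[[length(layers) + 1L]] <-
        list(kind = "conv", w = w, b = numeric(cout),
             stride = sp$stride, pad = sp$pad)
    } else if (i == 1L) {
      w <- array(he_init(k * k * cin * cout, cin * k * k), c(k, k, cin, cout))
      layers[[length(layers) + 1L]] <-
        list(kind = "lift", w = w, b = numeric(cout),
             stride = sp$stride, pad = sp$pad,
             exp_idx = lift_expansion_index(k, cin, cout, group))
    } else {
      w <- array(he_init(k * k * G * cin * cout, cin * G * k * k),
                 c(k, k, G, cin, cout))
      layers[[length(layers) + 1L]] <-
        list(kind = "gconv", w = w, b = numeric(cout),
             stride = sp$stride, pad = sp$pad,
             exp_idx = group_expansion_index(k, cin, cout, group))
    }
    layers[[length(layers) + 1L]] <- list(kind = "relu")
    if (!is.na(pool_of[i])) {
      pp <- config$pool_specs[pool_of[i], ]
      layers[[length(layers) + 1L]] <-
        list(kind = "pool", size = pp$kernel, stride = pp$stride)
    }
    cin <- cout
  }
  if (eq) layers[[length(layers) + 1L]] <- list(kind = "gpool")
  layers[[length(layers) + 1L]] <- list(kind = "flatten")

  nfeat <- flatten_width(config)
  widths <- config$linear_sizes  # hidden widths are shared; only conv channels halve
  fin <- nfeat
  for (wdt in widths) {
    layers[[length(layers) + 1L]] <-
      list(kind = "linear", w = matrix(he_init(fin * wdt, fin), fin, wdt),
           b = numeric(wdt))
    layers[[length(layers) + 1L]] <- list(kind = "relu_vec")
    layers[[length(layers) + 1L]] <- list(kind = "dropout", rate = config$dropout_rate)
    fin <- wdt
  }
  layers[[length(layers) + 1L]] <-
    list(kind = "linear", w = matrix(he_init(fin * config$n_classes, fin),
                                     fin, config$n_classes),
         b = numeric(config$n_classes))

  structure(list(config = config, group = group, layers = layers),
            class = "classifier_model")
}

#' @export
print.classifier_model <- function(x, ...) {
  kind <- if (x$config$equivariant)
    sprintf("group-equivariant (%s)", x$config$group_name) else "baseline"
  cat(sprintf("<%s VGG-style classifier: input %dx%d, %d conv layer(s), %d class(es)>\n",
              kind, x$config$input_size, x$config$input_size,
              length(x$config$conv_channels), x$config$n_classes))
  pc <- count_parameters(x)
  cat(sprintf("parameters: %s\n", format(pc$total, big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters per layer
#'
#' Counts stored (base) weights and biases; expanded kernel copies produced
#' by the group action share these weights and are not counted.
#'
#' @param model a [build_classifier()] result.
#' @return List with `total` (integer) and `table` (data frame with columns
#'   `layer`, `kind`, `weights`, `biases`, `total`).
#' @export
count_parameters <- function(model) {
  rows <- list()
  i <- 0L
  for (ly in model$layers) {
    if (is.null(ly$w)) next
    i <- i + 1L
    rows[[i]] <- data.frame(layer = i, kind = ly$kind,
                            weights = length(ly$w), biases = length(ly$b),
                            total = length(ly$w) + length(ly$b))
  }
  tab <- do.call(rbind, rows)
  list(total = sum(tab$total), table = tab)
}
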