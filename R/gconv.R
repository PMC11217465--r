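#' Planar (translation-only) feature map
#'
#' A stack of 2-D feature channels indexed `(channel, row, column)`,
#' rows/columns counted from the top-left.
#'
#' @param values numeric array with dim `(channels, height, width)`; a plain
#'   matrix is promoted to a single channel.
#' @return An object of class `"planar_map"`.
#' @export
planar_map <- function(values) {
  if (is.matrix(values)) values <- array(values, c(1L, dim(values)))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a (channel, row, column) array")
  if (!all(is.finite(values))) stop("feature map values must be finite")
  structure(list(values = values), class = "planar_map")
}

#' Group-indexed feature map
#'
#' The output of a lifting or group convolution: a real array indexed
#' `(channel, group element, row, column)`, the group axis following the
#' group's canonical element order.
#'
#' @param values numeric array with dim `(channels, group order, height, width)`.
#' @param group the [symmetry_group()] the group axis refers to.
#' @return An object of class `"group_map"`.
#' @export
group_map <- function(values, group) {
  if (!is.array(values) || length(dim(values)) != 4L)
    stop("'values' must be a (channel, group, row, column) array")
  if (!inherits(group, "symmetry_group")) stop("'group' must be a symmetry_group")
  if (dim(values)[2] != group$order)
    stop(sprintf("group axis has length %d but group %s has order %d",
                 dim(values)[2], group$name, group$order))
  if (!all(is.finite(values))) stop("feature map values must be finite")
  structure(list(values = values, group = group), class = "group_map")
}

#' @export
print.planar_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<planar feature map: %d channel(s), %d x %d>\n", d[1], d[2], d[3]))
  invisible(x)
}

#' @export
print.group_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<group feature map on %s: %d channel(s) x %d element(s), %d x %d>\n",
              x$group$name, d[1], d[2], d[3], d[4]))
  invisible(x)
}

# permutation vector P for a k x k kernel slice: as.vector(g_act(g, X)) == X[P]
act_perm <- function(g, k) {
  as.vector(g_act(g, matrix(seq_len(k * k), k, k)))
}

# Index map from a lifting kernel (k,k,Cin,Cout) to its expanded planar form
# (k,k,Cin,Cout*G), expanded output channel (o-1)*G + g (group fastest):
# slice (o,g) is the base slice for o spatially transformed by element g.
lift_expansion_index <- function(k, cin, cout, group) {
  G <- group$order
  base <- array(seq_len(k * k * cin * cout), c(k, k, cin, cout))
  idx <- array(0L, c(k, k, cin, cout * G))
  perms <- lapply(group$elements, act_perm, k = k)
  for (o in seq_len(cout)) {
    bo <- base[, , , o, drop = FALSE]
    dim(bo) <- c(k * k, cin)
    for (g in seq_len(G)) {
      idx[, , , (o - 1L) * G + g] <- bo[perms[[g]], ]
    }
  }
  as.vector(idx)
}

# Index map from a group kernel (k,k,G,Cin,Cout) to its expanded planar form
# (k,k,Cin*G,Cout*G): the expanded slice for input (ci,h) and output (o,g) is
# the base slice at group index compose(inverse(g), h), transformed by g.
group_expansion_index <- function(k, cin, cout, group) {
  G <- group$order
  base <- array(seq_len(k * k * G * cin * cout), c(k, k, G, cin, cout))
  idx <- array(0L, c(k, k, cin * G, cout * G))
  perms <- lapply(group$elements, act_perm, k = k)
  tab <- group$composition_table
  inv <- group$inverses
  for (o in seq_len(cout)) for (g in seq_len(G)) {
    pg <- perms[[g]]
    for (ci in seq_len(cin)) for (h in seq_len(G)) {
      bslice <- as.vector(base[, , tab[inv[g], h], ci, o])
      idx[, , (ci - 1L) * G + h, (o - 1L) * G + g] <- bslice[pg]
    }
  }
  as.vector(idx)
}

# internal single-sample planar correlation on (H,W,C) arrays via the
# compiled primitive; w is (k,k,Cin,Cout), b length Cout
conv_planar_hw <- function(x_hwc, w, b, stride, pad) {
  dim(x_hwc) <- c(dim(x_hwc), 1L)
  y <- cpp_conv_fwd(x_hwc, w, b, as.integer(stride), as.integer(pad))
  d <- dim(y)
  dim(y) <- d[1:3]
  y
}

#' Lifting convolution: planar input to group feature stack
#'
#' The input-layer G-convolution: the kernel stack is swept over the input
#' once per group element, each sweep using the kernels spatially
#' transformed by that element, producing one feature-map slice per
#' element. Implemented by kernel expansion (all transformed copies
#' precomputed) dispatched to a planar correlation primitive; bias is
#' shared across the group axis.
#'
#' @param f a [planar_map()] (square spatial extent).
#' @param weights numeric array `(out_channel, in_channel, k, k)`.
#' @param group a [symmetry_group()].
#' @param stride,pad convolution stride and symmetric zero padding.
#' @param bias optional per-out-channel bias (default zeros).
#' @return A [group_map()] on `group`.
#' @export
lift_conv <- function(f, weights, group, stride = 1L, pad = 0L, bias = NULL) {
  if (!inherits(f, "planar_map")) stop("'f' must be a planar_map")
  dv <- dim(f$values)
  if (dv[2] != dv[3]) stop("input must be square")
  if (length(dim(weights)) != 4L) stop("'weights' must be (out, in, k, k)")
  dw <- dim(weights)
  if (dw[3] != dw[4]) stop("kernel must be square")
  if (dw[2] != dv[1])
    stop(sprintf("input has %d channel(s) but kernel expects %d", dv[1], dw[2]))
  cout <- dw[1]; cin <- dw[2]; k <- dw[3]; G <- group$order
  if (is.null(bias)) bias <- numeric(cout)

  wint <- aperm(weights, c(3, 4, 2, 1))           # (k,k,Cin,Cout)
  idx <- lift_expansion_index(k, cin, cout, group)
  wexp <- array(as.vector(wint)[idx], c(k, k, cin, cout * G))
  bexp <- rep(bias, each = G)
  x <- aperm(f$values, c(2, 3, 1))                # (H,W,C)
  y <- conv_planar_hw(x, wexp, bexp, stride, pad) # (Ho,Wo,Cout*G)
  dim(y) <- c(dim(y)[1:2], G, cout)
  group_map(aperm(y, c(4, 3, 1, 2)), group)
}

#' Group convolution: group feature stack to group feature stack
#'
#' The layer-to-layer G-convolution in the regular representation: the
#' output slice at element `g` sums, over input elements `h`, the spatial
#' correlation of the input's `h`-slice with the kernel slice indexed
#' `compose(inverse(g), h)`, spatially transformed by `g`. Bias is shared
#' across the group axis.
#'
#' @param f a [group_map()] on `group`.
#' @param weights numeric array `(out_channel, in_channel, group, k, k)`.
#' @param group a [symmetry_group()] matching `f$group`.
#' @param stride,pad convolution stride and symmetric zero padding.
#' @param bias optional per-out-channel bias (default zeros).
#' @return A [group_map()] on `group`.
#' @export
group_conv <- function(f, weights, group, stride = 1L, pad = 0L, bias = NULL) {
  if (!inherits(f, "group_map")) stop("'f' must be a group_map")
  if (!identical(f$group$name, group$name))
    stop(sprintf("feature map is on %s but group argument is %s",
                 f$group$name, group$name))
  if (length(dim(weights)) != 5L) stop("'weights' must be (out, in, group, k, k)")
  dw <- dim(weights)
  dv <- dim(f$values)
  if (dw[3] != group$order) stop("kernel group axis does not match group order")
  if (dw[2] != dv[1])
    stop(sprintf("input has %d channel(s) but kernel expects %d", dv[1], dw[2]))
  if (dw[4] != dw[5]) stop("kernel must be square")
  cout <- dw[1]; cin <- dw[2]; k <- dw[4]; G <- group$order
  if (is.null(bias)) bias <- numeric(cout)

  wint <- aperm(weights, c(4, 5, 3, 2, 1))        # (k,k,G,Cin,Cout)
  idx <- group_expansion_index(k, cin, cout, group)
  wexp <- array(as.vector(wint)[idx], c(k, k, cin * G, cout * G))
  bexp <- rep(bias, each = G)
  x <- aperm(f$values, c(3, 4, 2, 1))             # (H,W,G,C) -> combined (c-1)*G+g
  dim(x) <- c(dv[3], dv[4], G * dv[1])
  y <- conv_planar_hw(x, wexp, bexp, stride, pad) # (Ho,Wo,Cout*G)
  dim(y) <- c(dim(y)[1:2], G, cout)
  group_map(aperm(y, c(4, 3, 1, 2)), group)
}

#' Group pooling: reduce the group axis by a per-pixel maximum
#'
#' Converts equivariance into invariance: the per-channel, per-pixel max
#' over the group axis commutes a group transformation of its input into a
#' plain spatial transformation of its output.
#'
#' @param f a [group_map()].
#' @return A [planar_map()].
#' @export
group_pool <- function(f) {
  if (!inherits(f, "group_map")) stop("'f' must be a group_map")
  v <- f$values
  d <- dim(v)
  out <- array(v[, 1L, , ], c(d[1], d[3], d[4]))
  for (g in seq_len(d[2])[-1L]) out <- pmax(out, array(v[, g, , ], c(d[1], d[3], d[4])))
  planar_map(out)
}

#' Spatial max pooling
#'
#' Standard max pooling over the two spatial axes; the group axis (if any)
#' is untouched.
#'
#' @param f a [planar_map()] or [group_map()].
#' @param size pooling window side length.
#' @param stride pooling stride (defaults to `size`).
#' @return The same kind of map with reduced spatial extent.
#' @export
spatial_max_pool <- function(f, size, stride = size) {
  size <- as.integer(size); stride <- as.integer(stride)
  if (stride < 1L) stop("'stride' must be >= 1")
  if (inherits(f, "planar_map")) {
    x <- aperm(f$values, c(2, 3, 1))
    dim(x) <- c(dim(x), 1L)
    if (size > dim(x)[1] || size > dim(x)[2]) stop("pooling window larger than input")
    y <- cpp_maxpool_fwd(x, size, stride)$y
    d <- dim(y)
    dim(y) <- d[1:3]
    planar_map(aperm(y, c(3, 1, 2)))
  } else if (inherits(f, "group_map")) {
    d <- dim(f$values)
    x <- aperm(f$values, c(3, 4, 2, 1))           # (H,W,G,C)
    dim(x) <- c(d[3], d[4], d[2] * d[1], 1L)
    if (size > d[3] || size > d[4]) stop("pooling window larger than input")
    y <- cpp_maxpool_fwd(x, size, stride)$y
    dy <- dim(y)
    dim(y) <- c(dy[1], dy[2], d[2], d[1])
    group_map(aperm(y, c(4, 3, 1, 2)), f$group)
  } else stop("'f' must be a planar_map or group_map")
}

#' Apply a group element to a feature map
#'
#' For a [planar_map()], every channel is transformed with [g_act()]. For a
#' [group_map()], the regular-representation action is used: the spatial
#' axes are transformed and the group axis is permuted by
#' left-multiplication, i.e. the output slice at element `h` is the input
#' slice at `compose(inverse(g), h)` transformed spatially by `g`.
#'
#' @param g a [group_element()].
#' @param f a [planar_map()] or [group_map()].
#' @param group the [symmetry_group()] defining the action (required for
#'   planar maps when `g` is to be validated; defaults to the map's group
#'   for group maps).
#' @return A transformed map of the same class.
#' @export
g_act_map <- function(g, f, group = NULL) {
  if (inherits(f, "planar_map")) {
    v <- f$values
    out <- v
    for (c in seq_len(dim(v)[1])) out[c, , ] <- g_act(g, v[c, , ])
    planar_map(out)
  } else if (inherits(f, "group_map")) {
    grp <- f$group
    gi <- element_index(g, grp)
    v <- f$values
    out <- v
    for (h in seq_len(grp$order)) {
      src <- grp$composition_table[grp$inverses[gi], h]
      for (c in seq_len(dim(v)[1])) out[c, h, , ] <- g_act(g, v[c, src, , ])
    }
    group_map(out, grp)
  } else stop("'f' must be a planar_map or group_map")
}

#' Check a layer's equivariance empirically
#'
#' Draws random feature maps, and for every element `g` of the group
#' compares transform-then-apply with apply-then-transform; the layer is
#' equivariant when the two agree. With integer-valued inputs and weights
#' the comparison is exact in double precision.
#'
#' @param layer_fn a function mapping a feature map to a feature map.
#' @param group a [symmetry_group()].
#' @param trials number of random inputs.
#' @param seed RNG seed (the report is deterministic given the seed).
#' @param input_maker function `(trial_index) -> feature map` producing the
#'   random inputs; defaults to 1-channel integer-valued 8x8 planar maps.
#' @return A data frame with one row per group element: `element` and
#'   `max_deviation` (max absolute difference over trials and positions).
#' @export
check_equivariance <- function(layer_fn, group, trials = 5L, seed = 1L,
                               input_maker = NULL) {
  if (is.null(input_maker)) {
    input_maker <- function(i) {
      planar_map(array(sample(-9:9, 64, replace = TRUE), c(1L, 8L, 8L)))
    }
  }
  set.seed(seed)
  inputs <- lapply(seq_len(trials), input_maker)
  dev <- numeric(group$order)
  for (x in inputs) {
    yx <- layer_fn(x)
    for (gi in seq_len(group$order)) {
      g <- group$elements[[gi]]
      lhs <- g_act_map(g, yx)
      rhs <- layer_fn(g_act_map(g, x))
      vals_l <- if (inherits(lhs, "planar_map") || inherits(lhs, "group_map")) lhs$values else lhs
      vals_r <- if (inherits(rhs, "planar_map") || inherits(rhs, "group_map")) rhs$values else rhs
      dev[gi] <- max(dev[gi], max(abs(vals_l - vals_r)))
    }
  }
  data.frame(element = vapply(group$elements, format, character(1)),
             max_deviation = dev, stringsAsFactors = FALSE)
}
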