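# Independent brute-force oracles. These deliberately avoid the package's
# g_act / expansion machinery: kernel transforms and correlations are written
# as explicit index loops so they form a second, independent path.

rot_ccw_manual <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) out[i, j] <- m[j, n + 1 - i]
  out
}

mirror_manual <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) out[i, j] <- m[i, n + 1 - j]
  out
}

transform_manual <- function(m, mirror, rotation) {
  if (mirror) m <- mirror_manual(m)
  r <- rotation
  while (r > 0) { m <- rot_ccw_manual(m); r <- r - 1 }
  m
}

# plain zero-padded strided correlation by nested loops
corr_manual <- function(img, ker, stride, pad) {
  s <- nrow(img); k <- nrow(ker)
  sp <- s + 2 * pad
  padded <- matrix(0, sp, sp)
  padded[(pad + 1):(pad + s), (pad + 1):(pad + s)] <- img
  no <- (sp - k) %/% stride + 1
  out <- matrix(0, no, no)
  for (r in seq_len(no)) for (c in seq_len(no)) {
    acc <- 0
    for (i in seq_len(k)) for (j in seq_len(k))
      acc <- acc + ker[i, j] * padded[(r - 1) * stride + i, (c - 1) * stride + j]
    out[r, c] <- acc
  }
  out
}

# lifting convolution oracle: slice at element g is the correlation of the
# input with the kernel stack transformed by g, plus bias
oracle_lift <- function(fvals, w, group, stride = 1, pad = 0, bias = NULL) {
  cout <- dim(w)[1]; cin <- dim(w)[2]
  if (is.null(bias)) bias <- numeric(cout)
  G <- group$order
  s <- dim(fvals)[2]; k <- dim(w)[3]
  no <- (s + 2 * pad - k) %/% stride + 1
  out <- array(0, c(cout, G, no, no))
  for (o in seq_len(cout)) for (gi in seq_len(G)) {
    g <- group$elements[[gi]]
    acc <- matrix(bias[o], no, no)
    for (ci in seq_len(cin)) {
      kg <- transform_manual(w[o, ci, , ], g$mirror, g$rotation)
      acc <- acc + corr_manual(fvals[ci, , ], kg, stride, pad)
    }
    out[o, gi, , ] <- acc
  }
  out
}

# layer-to-layer group convolution oracle: slice at g sums over input
# elements h the correlation of the h-slice with the kernel slice indexed
# compose(inverse(g), h), spatially transformed by g
oracle_gconv <- function(fvals, w, group, stride = 1, pad = 0, bias = NULL) {
  cout <- dim(w)[1]; cin <- dim(w)[2]
  if (is.null(bias)) bias <- numeric(cout)
  G <- group$order
  s <- dim(fvals)[3]; k <- dim(w)[4]
  no <- (s + 2 * pad - k) %/% stride + 1
  out <- array(0, c(cout, G, no, no))
  for (o in seq_len(cout)) for (gi in seq_len(G)) {
    g <- group$elements[[gi]]
    acc <- matrix(bias[o], no, no)
    for (ci in seq_len(cin)) for (h in seq_len(G)) {
      hk <- group$composition_table[group$inverses[gi], h]
      kg <- transform_manual(w[o, ci, hk, , ], g$mirror, g$rotation)
      acc <- acc + corr_manual(fvals[ci, h, , ], kg, stride, pad)
    }
    out[o, gi, , ] <- acc
  }
  out
}

oracle_maxpool <- function(img, size, stride) {
  s <- nrow(img)
  no <- (s - size) %/% stride + 1
  out <- matrix(0, no, no)
  for (r in seq_len(no)) for (c in seq_len(no))
    out[r, c] <- max(img[(r - 1) * stride + seq_len(size),
                         (c - 1) * stride + seq_len(size)])
  out
}

oracle_stability <- function(acc, fraction) {
  top <- -Inf
  for (a in acc) if (a > top) top <- a
  for (e in seq_along(acc)) {
    if (acc[e] >= fraction * top) return(list(top = top, epoch = e, acc = acc[e]))
  }
}

oracle_confusion <- function(actual, predicted, n) {
  cm <- matrix(0L, n, n)
  for (i in seq_along(actual)) {
    a <- actual[i]; p <- predicted[i]
    cm[a, p] <- cm[a, p] + 1L
  }
  cm
}

# random integer-valued planar map maker for equivariance checks
int_planar <- function(channels = 1, size = 8, lo = -9, hi = 9) {
  planar_map(array(sample(lo:hi, channels * size * size, replace = TRUE),
                   c(channels, size, size)))
}
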