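# Batched forward/backward passes over the layer list built by
# build_classifier(). Activations are (H, W, C, N) arrays; for group layers
# the channel axis holds channel*group with the group index fastest, so the
# compiled planar primitives serve both network families.

as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("'x' must be an array of images")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d[1], d[2], 1L, d[3])
  else if (length(d) != 4L) stop("'x' must have dim (H, W, N) or (H, W, C, N)")
  x
}

expand_layer_weights <- function(ly, G) {
  dw <- dim(ly$w)
  if (ly$kind == "lift") {
    k <- dw[1]; cin <- dw[3]; cout <- dw[4]
    list(w = array(as.vector(ly$w)[ly$exp_idx], c(k, k, cin, cout * G)),
         b = rep(ly$b, each = G), cout = cout)
  } else {  # gconv
    k <- dw[1]; cin <- dw[4]; cout <- dw[5]
    list(w = array(as.vector(ly$w)[ly$exp_idx], c(k, k, cin * G, cout * G)),
         b = rep(ly$b, each = G), cout = cout)
  }
}

nn_forward <- function(model, x, train = FALSE) {
  G <- if (is.null(model$group)) 1L else model$group$order
  a <- as_batch(x)
  if (dim(a)[1] != model$config$input_size)
    stop(sprintf("input is %dx%d but the model expects %dx%d",
                 dim(a)[1], dim(a)[2], model$config$input_size, model$config$input_size))
  caches <- vector("list", length(model$layers))
  for (li in seq_along(model$layers)) {
    ly <- model$layers[[li]]
    if (ly$kind == "conv") {
      caches[[li]] <- list(x = a)
      a <- cpp_conv_fwd(a, ly$w, ly$b, ly$stride, ly$pad)
    } else if (ly$kind %in% c("lift", "gconv")) {
      ex <- expand_layer_weights(ly, G)
      caches[[li]] <- list(x = a, wexp = ex$w, cout = ex$cout)
      a <- cpp_conv_fwd(a, ex$w, ex$b, ly$stride, ly$pad)
    } else if (ly$kind %in% c("relu", "relu_vec")) {
      mask <- a > 0
      caches[[li]] <- list(mask = mask)
      a[!mask] <- 0
    } else if (ly$kind == "pool") {
      r <- cpp_maxpool_fwd(a, ly$size, ly$stride)
      caches[[li]] <- list(idx = r$idx, xdim = dim(a))
      a <- r$y
    } else if (ly$kind == "gpool") {
      d <- dim(a)  # (H, W, C*G, N)
      dim(a) <- c(d[1], d[2], G, d[3] %/% G, d[4])
      best <- a[, , 1L, , , drop = FALSE]
      arg <- array(1L, dim(best))
      for (g in seq_len(G)[-1L]) {
        s <- a[, , g, , , drop = FALSE]
        upd <- s > best
        best[upd] <- s[upd]
        arg[upd] <- g
      }
      caches[[li]] <- list(arg = arg, xdim = d, G = G)
      a <- best
      dim(a) <- c(d[1], d[2], d[3] %/% G, d[4])
    } else if (ly$kind == "flatten") {
      d <- dim(a)
      caches[[li]] <- list(xdim = d)
      dim(a) <- c(prod(d[1:3]), d[4])
    } else if (ly$kind == "linear") {
      caches[[li]] <- list(x = a)
      a <- crossprod(ly$w, a) + ly$b
    } else if (ly$kind == "dropout") {
      if (train && ly$rate > 0) {
        mask <- (stats::runif(length(a)) >= ly$rate) / (1 - ly$rate)
        dim(mask) <- dim(a)
        caches[[li]] <- list(mask = mask)
        a <- a * mask
      } else caches[[li]] <- list(mask = NULL)
    } else stop("unknown layer kind: ", ly$kind)
  }
  list(logits = a, caches = caches)
}

nn_backward <- function(model, caches, gy) {
  G <- if (is.null(model$group)) 1L else model$group$order
  grads <- vector("list", length(model$layers))
  g <- gy
  for (li in rev(seq_along(model$layers))) {
    ly <- model$layers[[li]]
    cc <- caches[[li]]
    if (ly$kind == "conv") {
      r <- cpp_conv_bwd(cc$x, ly$w, g, ly$stride, ly$pad)
      grads[[li]] <- list(gw = r$gw, gb = r$gb)
      g <- r$gx
    } else if (ly$kind %in% c("lift", "gconv")) {
      r <- cpp_conv_bwd(cc$x, cc$wexp, g, ly$stride, ly$pad)
      gw <- as.vector(rowsum(matrix(as.vector(r$gw), ncol = 1L), ly$exp_idx))
      dim(gw) <- dim(ly$w)
      gb <- as.vector(rowsum(matrix(r$gb, ncol = 1L), rep(seq_len(cc$cout), each = G)))
      grads[[li]] <- list(gw = gw, gb = gb)
      g <- r$gx
    } else if (ly$kind %in% c("relu", "relu_vec")) {
      g[!cc$mask] <- 0
    } else if (ly$kind == "pool") {
      g <- cpp_maxpool_bwd(g, cc$idx, cc$xdim)
    } else if (ly$kind == "gpool") {
      d <- cc$xdim
      gx <- array(0, c(d[1], d[2], G, d[3] %/% G, d[4]))
      dim(g) <- dim(cc$arg)
      for (gg in seq_len(G)) {
        sl <- gx[, , gg, , , drop = FALSE]
        upd <- cc$arg == gg
        sl[upd] <- g[upd]
        gx[, , gg, , ] <- sl
      }
      dim(gx) <- d
      g <- gx
    } else if (ly$kind == "flatten") {
      dim(g) <- cc$xdim
    } else if (ly$kind == "linear") {
      grads[[li]] <- list(gw = cc$x %*% t(g), gb = rowSums(g))
      g <- ly$w %*% g
    } else if (ly$kind == "dropout") {
      if (!is.null(cc$mask)) g <- g * cc$mask
    }
  }
  grads
}

# cross-entropy over softmax; logits (K, N), labels in 1..K
softmax_ce <- function(logits, labels) {
  K <- nrow(logits); N <- ncol(logits)
  shifted <- sweep(logits, 2L, apply(logits, 2L, max))
  expd <- exp(shifted)
  Z <- colSums(expd)
  probs <- sweep(expd, 2L, Z, "/")
  picked <- shifted[cbind(labels, seq_len(N))]
  loss <- mean(log(Z) - picked)
  grad <- probs
  grad[cbind(labels, seq_len(N))] <- grad[cbind(labels, seq_len(N))] - 1
  list(loss = loss, grad = grad / N, probs = probs)
}

#' Compute class logits for a batch of images
#'
#' Evaluation-mode forward pass (dropout disabled).
#'
#' @param model a [build_classifier()] result.
#' @param x image array with dim `(H, W, N)` (grayscale) or `(H, W, C, N)`;
#'   a single `(H, W)` matrix is accepted.
#' @return Numeric matrix with one row per image and one column per class.
#' @export
forward <- function(model, x) {
  out <- nn_forward(model, x, train = FALSE)
  t(out$logits)
}

#' Predict class labels for a batch of images
#'
#' @param model a [build_classifier()] result.
#' @param x image array, see [forward()].
#' @param batch_size evaluation batch size.
#' @return Integer vector of class labels in `1..n_classes`.
#' @export
predict_classes <- function(model, x, batch_size = 64L) {
  a <- as_batch(x)
  N <- dim(a)[4]
  out <- integer(N)
  for (start in seq(1L, N, by = batch_size)) {
    idx <- start:min(N, start + batch_size - 1L)
    lg <- nn_forward(model, a[, , , idx, drop = FALSE], train = FALSE)$logits
    out[idx] <- max.col(t(lg), ties.method = "first")
  }
  out
}

classification_accuracy <- function(model, x, y, batch_size = 64L) {
  mean(predict_classes(model, x, batch_size) == y)
}

#' Maximum logit deviation of a model under group transformations
#'
#' Applies every element of the model's symmetry group (or of `group`) to
#' each input image and reports the largest absolute change in any logit.
#' For an equivariant model this is the end-to-end invariance check.
#'
#' @param model a [build_classifier()] result.
#' @param x image array, see [forward()].
#' @param group optional [symmetry_group()]; defaults to the model's group
#'   (or p4 for a baseline model).
#' @return Largest absolute logit deviation over elements and images.
#' @export
logit_invariance_deviation <- function(model, x, group = NULL) {
  if (is.null(group)) group <- if (!is.null(model$group)) model$group else symmetry_group("p4")
  a <- as_batch(x)
  base <- forward(model, a)
  dev <- 0
  for (g in group$elements) {
    xt <- a
    for (n in seq_len(dim(a)[4])) for (c in seq_len(dim(a)[3]))
      xt[, , c, n] <- g_act(g, a[, , c, n])
    dev <- max(dev, max(abs(forward(model, xt) - base)))
  }
  dev
}
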