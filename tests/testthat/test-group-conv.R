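p4 <- symmetry_group("p4")
p4m <- symmetry_group("p4m")

test_that("a centred delta kernel reproduces the input in every group slice", {
  set.seed(1)
  f <- int_planar(1, 6)
  w <- array(0, c(1, 1, 3, 3)); w[1, 1, 2, 2] <- 1
  z <- lift_conv(f, w, p4, stride = 1, pad = 1)
  for (g in seq_len(4)) expect_equal(z$values[1, g, , ], f$values[1, , ])
})

test_that("a 4-fold symmetric kernel gives identical p4 slices", {
  set.seed(2)
  f <- int_planar(1, 6)
  w <- array(0, c(1, 1, 3, 3))
  w[1, 1, , ] <- matrix(c(0, 1, 0, 1, 5, 1, 0, 1, 0), 3, 3)
  z <- lift_conv(f, w, p4, stride = 1, pad = 1)
  for (g in 2:4) expect_equal(z$values[1, g, , ], z$values[1, 1, , ])
})

test_that("lift_conv matches the nested-loop oracle on random instances", {
  set.seed(3)
  for (rep in seq_len(20)) {
    group <- if (rep %% 2) p4 else p4m
    cin <- sample(1:2, 1); cout <- sample(1:2, 1)
    f <- int_planar(cin, 5)
    w <- array(sample(-3:3, cout * cin * 9, TRUE), c(cout, cin, 3, 3))
    b <- sample(-2:2, cout, TRUE)
    z <- lift_conv(f, w, group, stride = 1, pad = 1, bias = b)
    expect_equal(z$values, oracle_lift(f$values, w, group, 1, 1, b))
  }
})

test_that("lift_conv handles stride and valid padding like the oracle", {
  set.seed(4)
  f <- int_planar(1, 7)
  w <- array(sample(-3:3, 9, TRUE), c(1, 1, 3, 3))
  z <- lift_conv(f, w, p4, stride = 2, pad = 0)
  expect_equal(z$values, oracle_lift(f$values, w, p4, 2, 0))
  expect_equal(dim(z$values), c(1L, 4L, 3L, 3L))
})

test_that("group_conv delta kernels reduce to a sum over the group axis", {
  set.seed(5)
  G <- p4$order
  fv <- array(sample(-5:5, G * 25, TRUE), c(1, G, 5, 5))
  f <- group_map(fv, p4)
  w <- array(0, c(1, 1, G, 3, 3))
  for (h in seq_len(G)) w[1, 1, h, 2, 2] <- 1
  z <- group_conv(f, w, p4, stride = 1, pad = 1)
  expected <- apply(fv[1, , , ], c(2, 3), sum)
  for (g in seq_len(G)) expect_equal(z$values[1, g, , ], expected)
})

test_that("group_conv matches the nested-loop oracle on random instances", {
  set.seed(6)
  for (rep in seq_len(20)) {
    group <- if (rep %% 2) p4 else p4m
    G <- group$order
    cin <- sample(1:2, 1); cout <- sample(1:2, 1)
    fv <- array(sample(-4:4, cin * G * 25, TRUE), c(cin, G, 5, 5))
    f <- group_map(fv, group)
    w <- array(sample(-3:3, cout * cin * G * 9, TRUE), c(cout, cin, G, 3, 3))
    b <- sample(-2:2, cout, TRUE)
    z <- group_conv(f, w, group, stride = 1, pad = 1, bias = b)
    expect_equal(z$values, oracle_gconv(fv, w, group, 1, 1, b))
  }
})

test_that("lift and group convolutions are exactly equivariant on both groups", {
  set.seed(7)
  for (group in list(p4, p4m)) {
    G <- group$order
    w1 <- array(sample(-3:3, 2 * 9, TRUE), c(2, 1, 3, 3))
    w2 <- array(sample(-3:3, 2 * 2 * G * 9, TRUE), c(2, 2, G, 3, 3))
    rep1 <- check_equivariance(function(x) lift_conv(x, w1, group, 1, 1),
                               group, trials = 5, seed = 11)
    expect_equal(max(rep1$max_deviation), 0)
    rep2 <- check_equivariance(function(x)
      group_conv(lift_conv(x, w1, group, 1, 1), w2, group, 1, 1),
      group, trials = 5, seed = 12)
    expect_equal(max(rep2$max_deviation), 0)
  }
})

test_that("group_conv equivariance holds under the explicit regular action", {
  set.seed(8)
  G <- p4$order
  fv <- array(sample(-4:4, G * 25, TRUE), c(1, G, 5, 5))
  f <- group_map(fv, p4)
  w <- array(sample(-3:3, G * 9, TRUE), c(1, 1, G, 3, 3))
  for (g0 in p4$elements) {
    lhs <- group_conv(g_act_map(g0, f), w, p4, 1, 1)
    rhs <- g_act_map(g0, group_conv(f, w, p4, 1, 1))
    expect_equal(lhs$values, rhs$values)
  }
})

test_that("group pooling takes the elementwise max and commutes with the action", {
  set.seed(9)
  G <- p4m$order
  fv <- array(rnorm(2 * G * 16), c(2, G, 4, 4))
  f <- group_map(fv, p4m)
  pooled <- group_pool(f)
  for (g in seq_len(G))
    expect_true(all(pooled$values >= fv[, g, , ] - 1e-12))
  same <- group_map(aperm(array(fv[, 1, , ], c(2, 4, 4, G)), c(1, 4, 2, 3)), p4m)
  expect_equal(group_pool(same)$values, array(fv[, 1, , ], c(2, 4, 4)))
  for (g in p4m$elements) {
    lhs <- group_pool(g_act_map(g, f))
    rhs <- g_act_map(g, pooled)
    expect_equal(lhs$values, rhs$values)
  }
})

test_that("spatial max pooling matches examples and the brute-force oracle", {
  const <- planar_map(array(3, c(1, 8, 8)))
  expect_equal(spatial_max_pool(const, 2, 2)$values, array(3, c(1, 4, 4)))
  set.seed(10)
  big <- matrix(rnorm(169), 13, 13)
  gl <- spatial_max_pool(planar_map(array(big, c(1, 13, 13))), 13, 1)
  expect_equal(dim(gl$values), c(1L, 1L, 1L))
  expect_equal(gl$values[1, 1, 1], max(big))
  x <- matrix(rnorm(64), 8, 8)
  for (spec in list(c(2, 2), c(3, 1), c(4, 2))) {
    got <- spatial_max_pool(planar_map(array(x, c(1, 8, 8))), spec[1], spec[2])
    expect_equal(got$values[1, , ], oracle_maxpool(x, spec[1], spec[2]))
  }
  # group maps: pooling leaves the group axis untouched
  fv <- array(rnorm(4 * 64), c(1, 4, 8, 8))
  gp <- spatial_max_pool(group_map(fv, p4), 2, 2)
  for (g in 1:4) expect_equal(gp$values[1, g, , ], oracle_maxpool(fv[1, g, , ], 2, 2))
  expect_error(spatial_max_pool(planar_map(array(0, c(1, 4, 4))), 5), "larger")
})

test_that("lift_conv is linear in its input when bias is zero", {
  set.seed(11)
  w <- array(rnorm(2 * 9), c(2, 1, 3, 3))
  f1 <- int_planar(1, 6); f2 <- int_planar(1, 6)
  a <- 2; b <- -3
  combo <- planar_map(a * f1$values + b * f2$values)
  z <- lift_conv(combo, w, p4, 1, 1)
  z1 <- lift_conv(f1, w, p4, 1, 1)
  z2 <- lift_conv(f2, w, p4, 1, 1)
  expect_equal(z$values, a * z1$values + b * z2$values)
})

test_that("check_equivariance flags a plain convolution as non-equivariant", {
  idrep <- check_equivariance(identity, p4, trials = 3, seed = 13)
  expect_equal(max(idrep$max_deviation), 0)
  # translation-only convolution with an asymmetric kernel: rotating the
  # input does not permute any group axis, so equivariance fails
  ker <- array(0, c(1, 1, 3, 3)); ker[1, 1, 1, 1] <- 1; ker[1, 1, 2, 2] <- 2
  plain <- function(x) {
    xa <- aperm(x$values, c(2, 3, 1))
    dim(xa) <- c(dim(xa), 1L)
    y <- equivnet:::cpp_conv_fwd(xa, aperm(ker, c(3, 4, 2, 1)), 0, 1L, 1L)
    dim(y) <- dim(y)[1:3]
    planar_map(aperm(y, c(3, 1, 2)))
  }
  rep <- check_equivariance(plain, p4, trials = 3, seed = 14)
  expect_gt(rep$max_deviation[2], 0)  # fails already at the quarter turn
})

test_that("lift/conv/pool composition is invariant after global pooling", {
  set.seed(15)
  for (group in list(p4, p4m)) {
    G <- group$order
    w1 <- array(sample(-3:3, 2 * 9, TRUE), c(2, 1, 3, 3))
    w2 <- array(sample(-3:3, 2 * 2 * G * 9, TRUE), c(2, 2, G, 3, 3))
    net <- function(x) {
      z <- group_conv(lift_conv(x, w1, group, 1, 1), w2, group, 1, 1)
      p <- group_pool(z)
      spatial_max_pool(p, dim(p$values)[2], 1)  # global spatial max
    }
    x <- int_planar(1, 8)
    base <- net(x)$values
    for (g in group$elements)
      expect_equal(net(g_act_map(g, x))$values, base)
  }
})

test_that("float32-scale inputs keep relative equivariance error below 1e-5", {
  set.seed(16)
  w1 <- array(rnorm(2 * 9), c(2, 1, 3, 3))
  maker <- function(i) planar_map(array(rnorm(64), c(1, 8, 8)))
  rep <- check_equivariance(function(x) lift_conv(x, w1, p4m, 1, 1),
                            p4m, trials = 5, seed = 17, input_maker = maker)
  # double-precision arithmetic on permuted index sets: deviation stays tiny
  expect_lt(max(rep$max_deviation), 1e-5)
})

test_that("shape and group mismatches raise informative errors", {
  f <- int_planar(2, 5)
  w <- array(0, c(1, 3, 3, 3))
  expect_error(lift_conv(f, w, p4), "channel")
  big <- array(0, c(1, 2, 9, 9))
  expect_error(lift_conv(f, big, p4), "kernel larger|larger than")
  fv <- array(0, c(1, 4, 5, 5))
  expect_error(group_conv(group_map(fv, p4), array(0, c(1, 1, 8, 3, 3)), p4),
               "group")
  expect_error(group_map(array(0, c(1, 3, 5, 5)), p4), "order")
})
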