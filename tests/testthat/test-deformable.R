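test_that("bilinear sampling interpolates and zero-pads as specified", {
  g <- matrix(c(0, 2, 1, 3), 2, 2)   # [[0,1],[2,3]] in (y, x) indexing
  expect_identical(bilinear_sample(g, 0, 0), 0)
  expect_identical(bilinear_sample(g, 1, 1), 3)
  expect_equal(bilinear_sample(g, 0.5, 0.5), 1.5)
  expect_equal(bilinear_sample(g, 0.25, 0.75), 1.25)
  # outside the frame contributes zeros
  expect_identical(bilinear_sample(g, -1, 0), 0)
  expect_identical(bilinear_sample(g, 0, 5), 0)
  # half outside: only the in-frame corners contribute
  expect_equal(bilinear_sample(g, -0.5, 0), 0)
  expect_equal(bilinear_sample(g, 0.5, -0.5), 0.5 * (0.5 * 0 + 0.5 * 2))
})

test_that("zero offsets reduce the deformable conv to a dense conv", {
  worst <- 0
  with_seed(42, {
    for (case in 1:100) {
      C <- sample(1:4, 1); Co <- sample(1:3, 1)
      H <- sample(5:9, 1); W <- sample(5:9, 1)
      k <- sample(c(1, 3, 5), 1)
      x <- array(rnorm(H * W * C), c(H, W, C))
      w <- array(rnorm(k * k * C * Co), c(k, k, C, Co))
      b <- rnorm(Co)
      got <- deform_conv2d(x, w, array(0, c(H, W, 2 * k * k)), b)
      want <- conv_ref(x, w, b)
      worst <- max(worst, max(abs(got - want)))
    }
  })
  expect_lt(worst, 1e-5)
})

test_that("constant inputs pass through any bounded offsets", {
  k <- 3; C <- 2; Co <- 2
  x <- array(0.7, c(7, 7, C))
  w <- with_seed(1, array(rnorm(k * k * C * Co), c(k, k, C, Co)))
  b <- c(0.1, -0.2)
  off <- with_seed(2, array(runif(7 * 7 * 2 * k * k, -0.5, 0.5),
                            c(7, 7, 2 * k * k)))
  out <- deform_conv2d(x, w, off, b)
  want <- 0.7 * apply(w, 4, sum) + b
  # interior locations only: near the border, zero padding truncates
  for (o in 1:Co)
    expect_equal(out[3:5, 3:5, o], matrix(want[o], 3, 3), tolerance = 1e-9)
})

test_that("a 1x1 kernel with uniform offset samples half a pixel away", {
  x <- array(matrix(0:8, 3, 3, byrow = TRUE), c(3, 3, 1))
  w <- array(1, c(1, 1, 1, 1))
  off <- array(0, c(3, 3, 2))
  off[, , 2] <- 0.5                     # dx = +0.5 everywhere
  out <- deform_conv2d(x, w, off)
  for (y in 1:3) for (xc in 1:3) {
    want <- bilinear_sample(x[, , 1], y - 1, xc - 1 + 0.5)
    expect_equal(out[y, xc, 1], want, tolerance = 1e-12)
  }
})

test_that("analytic gradients match central finite differences", {
  with_seed(9, {
    H <- 5; W <- 5; C <- 2; Co <- 2; k <- 3
    x <- array(rnorm(H * W * C), c(H, W, C))
    w <- array(rnorm(k * k * C * Co) * 0.5, c(k, k, C, Co))
    b <- rnorm(Co)
    off <- array(rnorm(H * W * 2 * k * k) * 0.3, c(H, W, 2 * k * k))
    gy <- array(rnorm(H * W * Co), c(H, W, Co))
    got <- deform_conv2d_grad(x, w, off, gy)
    expect_lt(rel_err(got$gx,
                      fd_grad(x, function(a) sum(deform_conv2d(a, w, off, b) * gy))),
              1e-3)
    expect_lt(rel_err(got$gw,
                      fd_grad(w, function(a) sum(deform_conv2d(x, a, off, b) * gy))),
              1e-3)
    expect_lt(rel_err(got$goff,
                      fd_grad(off, function(a) sum(deform_conv2d(x, w, a, b) * gy))),
              1e-3)
  })
})

test_that("the operator is linear in its input with fixed offsets", {
  with_seed(14, {
    k <- 3; C <- 2; Co <- 2
    x1 <- array(rnorm(36 * C), c(6, 6, C))
    x2 <- array(rnorm(36 * C), c(6, 6, C))
    w <- array(rnorm(k * k * C * Co), c(k, k, C, Co))
    off <- array(rnorm(6 * 6 * 2 * k * k) * 0.4, c(6, 6, 2 * k * k))
    lhs <- deform_conv2d(2 * x1 - 3 * x2, w, off)
    rhs <- 2 * deform_conv2d(x1, w, off) - 3 * deform_conv2d(x2, w, off)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  })
})

test_that("fresh offset convolutions start at the regular grid", {
  layer <- with_seed(3, offset_conv_layer(4, 3))
  x <- with_seed(5, array(rnorm(6 * 6 * 4), c(6, 6, 4)))
  off <- offset_conv(layer, x)
  expect_identical(dim(off), c(6L, 6L, 18L))
  expect_true(all(off == 0))
  # hence a fresh deformable layer is exactly a standard convolution
  dc <- with_seed(6, sevgrade:::layer_dconv2d(4, 3, 3))
  got <- module_forward(dc, sevgrade:::as_batch(x))
  want <- conv_ref(x, dc$W, dc$b)
  expect_lt(max(abs(got[, , , 1] - want)), 1e-10)
})

test_that("offsets move off the regular grid after one update", {
  dc <- with_seed(21, sevgrade:::layer_dconv2d(2, 2, 3))
  x <- with_seed(22, array(rnorm(5 * 5 * 2, sd = 1), c(5, 5, 2, 1)))
  out <- module_forward(dc, x)
  gy <- array(1, dim(out))
  sevgrade:::zero_grads(dc)
  invisible(module_backward(dc, gy))
  # gradient reaches the offset conv, so a step changes the offsets
  expect_gt(max(abs(dc$offset_conv$gW)), 0)
  dc$offset_conv$W <- dc$offset_conv$W - 0.1 * dc$offset_conv$gW
  off2 <- module_forward(dc$offset_conv, x)
  expect_gt(max(abs(off2)), 0)
})
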