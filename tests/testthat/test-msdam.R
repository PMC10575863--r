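test_that("per-channel L2 normalization follows its definition", {
  ch <- matrix(c(3, 0, 4, 0), 2, 2)     # [[3,4],[0,0]]
  x <- array(0, c(2, 2, 2))
  x[, , 1] <- ch
  out <- l2_normalize(x)
  expect_equal(out[, , 1], matrix(c(0.6, 0, 0.8, 0), 2, 2))
  expect_identical(out[, , 2], x[, , 2])           # all-zero channel stays zero
  with_seed(2, {
    y <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
    n <- apply(l2_normalize(y), 3, function(p) sqrt(sum(p^2)))
    expect_equal(n, rep(1, 3), tolerance = 1e-6)
  })
})

test_that("an MS-DAM block preserves shape and keeps attention positive", {
  blk <- with_seed(5, msdam_block(16))
  x <- with_seed(6, array(rnorm(12 * 12 * 16 * 2), c(12, 12, 16, 2)))
  out <- msdam_forward(blk, x)
  expect_identical(dim(out), dim(x))
  expect_true(all(is.finite(out)))
  expect_true(min(softplus(blk$z)) > 0)
  # branch width rule and config validation
  expect_identical(blk$B, 4L)
  expect_identical(with_seed(1, msdam_block(64))$B, 16L)
  expect_error(msdam_block(2), "channels")
  expect_error(msdam_block(16, kernels = c(3, 5, 5)), "kernels")
  expect_error(msdam_block(16, width_ratio = 0), "width_ratio")
})

test_that("a silenced block reduces to normalized input times softplus bias", {
  blk <- with_seed(7, msdam_block(4, width_ratio = 1))
  # silence the fusion so R = X, and fix the attention to its bias
  blk$fuse$W[] <- 0; blk$fuse$b[] <- 0
  blk$att$W[] <- 0; blk$att$b[] <- c(0.5, -1, 0, 2)
  x <- array(0, c(2, 2, 4, 1))
  x[, , 1, 1] <- matrix(c(3, 0, 4, 0), 2, 2)
  x[, , 2, 1] <- 1
  x[, , 3, 1] <- matrix(c(1, -1, 1, -1), 2, 2)
  x[, , 4, 1] <- 0.25
  out <- msdam_forward(blk, x)
  a <- softplus(c(0.5, -1, 0, 2))
  for (c_ in 1:4) {
    nrm <- sqrt(sum(x[, , c_, 1]^2))
    expect_equal(out[, , c_, 1], x[, , c_, 1] / (nrm + 1e-12) * a[c_],
                 tolerance = 1e-9)
  }
})

test_that("stage fusion anchors on the stride-16 grid", {
  maps <- with_seed(8, list(array(rnorm(40 * 38 * 38), c(38, 38, 40)),
                            array(rnorm(112 * 19 * 19), c(19, 19, 112)),
                            array(rnorm(320 * 10 * 10), c(10, 10, 320))))
  fused <- fuse_stages(maps)
  expect_identical(dim(fused), c(19L, 19L, 472L))
  # the anchor stage's channel block is passed through untouched
  expect_identical(fused[, , 41:152], maps[[2]])
  # constants fuse to constants
  cst <- lapply(c(4, 6, 8), function(c_)
    array(0.3, c(c(24, 12, 6)[which(c(4, 6, 8) == c_)],
                 c(24, 12, 6)[which(c(4, 6, 8) == c_)], c_)))
  fc <- fuse_stages(cst)
  expect_lt(diff(range(fc)), 1e-9)
  expect_error(fuse_stages(list(sevgrade:::as_batch(maps[[1]]),
                                array(0, c(19, 19, 3, 2)),
                                sevgrade:::as_batch(maps[[3]]))),
               "batch")
})

test_that("the head produces normalized, deterministic probabilities", {
  head <- with_seed(9, sevgrade:::head_module(24))
  x <- with_seed(10, array(rnorm(6 * 6 * 24 * 3), c(6, 6, 24, 3)))
  p <- head_forward(head, x)
  expect_identical(dim(p), c(5L, 3L))
  expect_equal(colSums(p), rep(1, 3), tolerance = 1e-6)
  # zero classifier weights give the uniform distribution
  expect_equal(max(abs(p - 0.2)), 0, tolerance = 1e-12)
  # after perturbing the weights, eval mode stays bitwise deterministic
  head$fc$W[] <- with_seed(11, rnorm(length(head$fc$W)))
  p1 <- head_forward(head, x, training = FALSE)
  p2 <- head_forward(head, x, training = FALSE)
  expect_identical(p1, p2)
})

test_that("the full network emits five finite probabilities end to end", {
  net <- with_seed(12, severity_net(build_tiny_backbone(12), use_msdam = TRUE,
                                    seed = 12))
  x <- toy_batch(4, 96, seed = 13)
  p <- net_predict(net, x)
  expect_identical(dim(p), c(5L, 4L))
  expect_true(all(is.finite(p)))
  expect_equal(colSums(p), rep(1, 4), tolerance = 1e-6)
  # attention positivity on every stage
  for (blk in net$msdam) expect_gt(min(softplus(blk$z)), 0)
  # input size must be divisible by 32 far enough to form the taps; 64 works
  p64 <- net_predict(net, toy_batch(2, 64, seed = 14))
  expect_identical(dim(p64), c(5L, 2L))
})

test_that("gradient flows to the input even with silent branches", {
  net <- with_seed(15, severity_net(build_tiny_backbone(15), use_msdam = TRUE,
                                    seed = 15))
  for (blk in net$msdam) {                 # silence every deformable branch
    for (br in blk$branches) { br$W[] <- 0; br$b[] <- 0 }
  }
  x <- toy_batch(2, 64, seed = 16)
  p <- net_predict(net, x, training = FALSE)
  # make the classifier non-trivial so the loss has a gradient
  net$head$fc$W[] <- with_seed(17, rnorm(length(net$head$fc$W)) * 0.1)
  p <- net_predict(net, x, training = FALSE)
  sevgrade:::zero_grads(net)
  gx <- module_backward(net, sevgrade:::focal_loss_grad(p, c(0, 3), 1))
  expect_gt(max(abs(gx)), 0)
  # and the projection/backbone parameters still receive gradient via the
  # residual path
  expect_gt(max(abs(net$backbone$c1$gW)), 0)
})
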