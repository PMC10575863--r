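test_that("focal loss evaluates its closed forms", {
  p <- matrix(c(0.9, 0.025, 0.025, 0.025, 0.025), 5, 1)
  expect_equal(focal_loss(p, 0, gamma = 1), 0.1 * (-log(0.9)))
  expect_equal(focal_loss(p, 0, gamma = 1), 0.01053605, tolerance = 1e-6)
  # perfect prediction costs nothing
  perfect <- matrix(c(1, 0, 0, 0, 0), 5, 1)
  expect_equal(focal_loss(perfect, 0, gamma = 2), 0)
  expect_error(focal_loss(p, 7, gamma = 1), "range")
})

test_that("gamma = 0 recovers cross-entropy on random batches", {
  with_seed(3, {
    for (rep in 1:20) {
      z <- matrix(rnorm(5 * 8), 5, 8)
      p <- apply(z, 2, function(c_) { e <- exp(c_ - max(c_)); e / sum(e) })
      y <- sample(0:4, 8, replace = TRUE)
      ce <- mean(-log(pmax(p[cbind(y + 1, 1:8)], 1e-7)))
      expect_equal(focal_loss(p, y, gamma = 0), ce, tolerance = 1e-9)
    }
  })
})

test_that("focal loss decreases as the true-class probability grows", {
  pt <- seq(0.05, 0.99, by = 0.01)
  for (g in c(0, 1, 2)) {
    losses <- vapply(pt, function(q) {
      p <- matrix((1 - q) / 4, 5, 1); p[3, 1] <- q
      focal_loss(p, 2, gamma = g)
    }, 0)
    expect_true(all(diff(losses) < 0))
  }
})

test_that("focal gradients match finite differences through the softmax", {
  with_seed(6, {
    z <- matrix(rnorm(10), 5, 2)
    y <- c(1, 4)
    sm <- function(z) apply(z, 2, function(c_) { e <- exp(c_ - max(c_)); e / sum(e) })
    for (g in c(0, 1, 2)) {
      got <- sevgrade:::focal_loss_grad(sm(z), y, g)
      want <- fd_grad(z, function(a) focal_loss(sm(a), y, g), eps = 1e-6)
      expect_lt(rel_err(got, want), 1e-6)
    }
  })
})

test_that("the learning-rate schedule honors its endpoints and bounds", {
  expect_equal(lr_schedule(0), 1e-6)
  expect_equal(lr_schedule(5), 2e-3)                 # warmup end hits the cap
  # midpoint of the decay: floor + half the range
  expect_equal(lr_schedule(5 + (50 - 5) / 2), 1e-6 + 0.5 * (2e-3 - 1e-6))
  expect_equal(lr_schedule(5 + (50 - 5) / 2), 1.0005e-3, tolerance = 1e-9)
  lrs <- vapply(seq(0, 49.9, by = 0.1), lr_schedule, 0)
  expect_true(all(lrs >= 1e-6 - 1e-15 & lrs <= 2e-3 + 1e-15))
  # continuity at the warmup/decay junction
  expect_lt(abs(lr_schedule(4.999) - lr_schedule(5.001)), 1e-6)
  expect_error(lr_schedule(50), "epoch")
})

test_that("rectified Adam follows the published update rules", {
  # zero gradients leave parameters untouched
  p <- list(w = matrix(1:4 / 4, 2, 2))
  st <- NULL
  for (i in 1:5) {
    r <- radam_step(p, list(w = p$w * 0), st, lr = 0.1)
    p <- r$params; st <- r$state
  }
  expect_equal(p$w, matrix(1:4 / 4, 2, 2))
  # at t = 1, rho_1 = 1 <= 4: the non-adaptive branch applies and a
  # constant unit gradient moves a scalar by exactly -lr
  r1 <- radam_step(list(x = 0), list(x = 1), NULL, lr = 0.1)
  expect_equal(r1$params$x, -0.1)
  rho_inf <- 2 / (1 - 0.999) - 1
  rho_1 <- rho_inf - 2 * 0.999 / (1 - 0.999)
  expect_equal(rho_1, 1)
  # the adaptive branch engages once rho_t > 4 (t >= 5 for beta2 = 0.999)
  p <- list(x = 0); st <- NULL
  for (t in 1:6) {
    r <- radam_step(p, list(x = 1), st, lr = 0.1)
    p <- r$params; st <- r$state
    if (t <= 4) expect_equal(p$x, -0.1 * t)          # pure momentum steps
  }
  expect_gt(p$x, -0.6)                               # rectified, smaller step
  expect_error(radam_step(list(x = 0), list(x = NaN), NULL, lr = 0.1),
               "non-finite")
})

test_that("metric reports reproduce hand-computed macro scores", {
  # 2-class toy confusion [[2,0],[1,1]] embedded in the 2-class report
  r <- metrics_report(c(0, 0, 1, 1), c(0, 0, 0, 1), n_classes = 2)
  expect_equal(unname(r$f1), c(0.8, 2 / 3), tolerance = 1e-9)
  expect_equal(r$macro_f1, 0.73333, tolerance = 1e-4)
  # all predictions into one of two balanced classes
  r2 <- metrics_report(c(0, 0, 1, 1), c(0, 0, 0, 0), n_classes = 2)
  expect_equal(r2$macro_f1, 0.33333, tolerance = 1e-4)
  # perfect predictions
  r3 <- metrics_report(0:4, 0:4)
  expect_equal(r3$accuracy, 100)
  expect_equal(r3$macro_f1, 1)
  expect_error(metrics_report(integer(0), integer(0)), "empty")
})

test_that("macro F1 is invariant to class relabeling", {
  with_seed(8, {
    for (rep in 1:20) {
      truth <- sample(0:4, 60, replace = TRUE)
      pred <- sample(0:4, 60, replace = TRUE)
      perm <- sample(0:4)
      f1 <- metrics_report(truth, pred)$macro_f1
      f1p <- metrics_report(perm[truth + 1], perm[pred + 1])$macro_f1
      expect_equal(f1, f1p, tolerance = 1e-12)
    }
  })
})

test_that("early stopping counts patience epochs from the best epoch", {
  ds <- toy_dataset(per_class = 4, size = 32, seed = 31)
  imgs <- ds$images[ds$manifest$split == "train"]
  val <- ds$images[ds$manifest$split == "test"]
  net <- severity_net(build_tiny_backbone(31), use_msdam = FALSE, seed = 31)
  # a huge floor makes training diverge upward so validation loss only
  # worsens after the first epoch
  cfg <- train_config(epochs = 30, patience = 3, warmup = 0,
                      lr_floor = 0.5, lr_cap = 0.6, gamma = 0,
                      cutmix_prob = 0, augment = FALSE, seed = 31)
  fit <- train_model(net, imgs, val, cfg)
  expect_lt(fit$stopped_epoch, 29)
  expect_identical(nrow(fit$history), fit$stopped_epoch + 1L)
  expect_identical(fit$stopped_epoch, fit$best_epoch + 3L)
})

test_that("training is bitwise reproducible under a fixed seed", {
  ds <- toy_dataset(per_class = 4, size = 32, seed = 32)
  imgs <- ds$images[ds$manifest$split == "train"]
  val <- ds$images[ds$manifest$split == "test"]
  cfg <- train_config(epochs = 2, patience = 2, warmup = 1, gamma = 1,
                      cutmix_prob = 0.3, seed = 17)
  run_once <- function() {
    net <- severity_net(build_tiny_backbone(18), use_msdam = FALSE, seed = 18)
    fit <- train_model(net, imgs, val, cfg)
    list(h = fit$history, w = sevgrade:::state_dict(fit$net))
  }
  a <- run_once()
  b <- run_once()
  expect_identical(a$h, b$h)
  expect_identical(a$w, b$w)
})

test_that("checkpoints round-trip through JSON", {
  net <- severity_net(build_tiny_backbone(41), use_msdam = TRUE, seed = 41)
  x <- toy_batch(2, 64, seed = 42)
  p1 <- net_predict(net, x)
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(net, path)
  net2 <- severity_net(build_tiny_backbone(99), use_msdam = TRUE, seed = 99)
  load_checkpoint(net2, path)
  p2 <- net_predict(net2, x)
  expect_equal(p1, p2, tolerance = 1e-12)
})
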