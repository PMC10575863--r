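# Focal-loss training with rectified Adam, warmup + cosine learning-rate
# scheduling, early stopping on validation loss, and the evaluation
# metrics (overall accuracy, macro precision/recall/F1).

#' Focal loss
#'
#' `-(1 - p_t)^gamma * log(p_t)` averaged over the batch, where `p_t` is
#' the predicted probability of the true class (clipped to `[1e-7, 1]`).
#' No class weighting is applied; `gamma = 0` reduces exactly to
#' cross-entropy.
#'
#' @param probs matrix `n_classes x N` of class probabilities.
#' @param truth integer vector of true classes in `0..n_classes-1`.
#' @param gamma focusing exponent (default 1).
#' @return mean loss (scalar).
#' @export
focal_loss <- function(probs, truth, gamma = 1) {
  probs <- as.matrix(probs)
  n <- ncol(probs)
  stopifnot(length(truth) == n)
  if (any(truth < 0 | truth >= nrow(probs)))
    stop("class index out of range 0..", nrow(probs) - 1)
  pt <- pmin(pmax(probs[cbind(truth + 1L, seq_len(n))], 1e-7), 1)
  mean(-(1 - pt)^gamma * log(pt))
}

# gradient of the mean focal loss w.r.t. the logits (softmax input)
focal_loss_grad <- function(probs, truth, gamma = 1) {
  n <- ncol(probs)
  pt <- pmin(pmax(probs[cbind(truth + 1L, seq_len(n))], 1e-7), 1)
  # dL/dp_t, then chain through the softmax: dp_t/dz_j = p_t (1[t=j] - p_j)
  ct <- if (gamma > 0)
    gamma * (1 - pt)^(gamma - 1) * log(pt) - (1 - pt)^gamma / pt
  else -1 / pt
  gz <- probs * rep(ct * pt, each = nrow(probs)) * (-1)
  gz[cbind(truth + 1L, seq_len(n))] <-
    gz[cbind(truth + 1L, seq_len(n))] + ct * pt
  gz / n
}

#' Warmup + cosine learning-rate schedule
#'
#' Linear warmup from the floor to the cap over `warmup` epochs, then
#' cosine decay back to the floor at the final epoch:
#' `lr = floor + 0.5 (cap - floor) (1 + cos(pi t))` with `t` the
#' post-warmup progress. Continuous at the junction and bounded by
#' `[floor, cap]` throughout.
#'
#' @param epoch 0-based epoch index, `0 <= epoch < epochs`.
#' @param epochs total epochs.
#' @param lr_floor,lr_cap learning-rate bounds (defaults 1e-6 and 2e-3).
#' @param warmup warmup length in epochs (default 5).
#' @return learning rate for the epoch.
#' @export
lr_schedule <- function(epoch, epochs = 50L, lr_floor = 1e-6, lr_cap = 2e-3,
                        warmup = 5L) {
  stopifnot(epoch >= 0, epoch < epochs, lr_floor < lr_cap)
  if (epoch <= warmup && warmup > 0)
    return(lr_floor + (lr_cap - lr_floor) * epoch / warmup)
  if (epochs <= warmup + 1) return(lr_cap)
  # decay reaches the floor as training ends (fractional epochs allowed)
  t <- min(1, (epoch - warmup) / (epochs - warmup))
  lr_floor + 0.5 * (lr_cap - lr_floor) * (1 + cos(pi * t))
}

#' Rectified Adam update
#'
#' Variance-rectified Adam: while the second-moment estimate is unreliable
#' (`rho_t <= 4`) the update is plain bias-corrected momentum; afterwards
#' the adaptive step is scaled by the rectification factor `r_t`.
#'
#' @param params named list of numeric arrays.
#' @param grads matching list of gradients.
#' @param state optimizer state from a previous call, or `NULL` to start.
#' @param lr learning rate.
#' @param beta1,beta2,eps Adam constants (0.9 / 0.999 / 1e-8).
#' @return list with updated `params` and `state`.
#' @export
radam_step <- function(params, grads, state = NULL, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(state))
    state <- list(t = 0L,
                  m = lapply(params, function(p) p * 0),
                  v = lapply(params, function(p) p * 0))
  t <- state$t + 1L
  rho_inf <- 2 / (1 - beta2) - 1
  rho_t <- rho_inf - 2 * t * beta2^t / (1 - beta2^t)
  for (i in seq_along(params)) {
    g <- grads[[i]]
    if (any(!is.finite(g)))
      stop("non-finite gradient for parameter ",
           names(params)[i] %||% as.character(i))
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    mhat <- state$m[[i]] / (1 - beta1^t)
    if (rho_t > 4) {
      vhat <- sqrt(state$v[[i]] / (1 - beta2^t))
      rt <- sqrt(((rho_t - 4) * (rho_t - 2) * rho_inf) /
                   ((rho_inf - 4) * (rho_inf - 2) * rho_t))
      params[[i]] <- params[[i]] - lr * rt * mhat / (vhat + eps)
    } else {
      params[[i]] <- params[[i]] - lr * mhat
    }
  }
  state$t <- t
  list(params = params, state = state)
}

# apply one RAdam step in place over a module's parameter references
radam_step_module <- function(net, opt, lr) {
  refs <- module_params(net)
  params <- lapply(refs, function(p) p$env[[p$name]])
  grads <- lapply(refs, function(p) p$env[[paste0("g", p$name)]])
  res <- radam_step(params, grads, opt$state, lr)
  for (i in seq_along(refs))
    refs[[i]]$env[[refs[[i]]$name]] <- res$params[[i]]
  opt$state <- res$state
  invisible(opt)
}

#' Classification metrics report
#'
#' @param truth,pred integer class vectors in `0..n_classes-1`.
#' @param n_classes number of classes (default 5).
#' @return object of class `metrics_report`: confusion matrix (rows =
#'   true), overall accuracy in percent, per-class and macro
#'   precision/recall/F1 (zero convention for empty denominators).
#' @export
metrics_report <- function(truth, pred, n_classes = 5L) {
  if (!length(truth)) stop("empty evaluation set")
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = 0:(n_classes - 1),
                               pred = 0:(n_classes - 1)))
  for (i in seq_along(truth))
    cm[truth[i] + 1L, pred[i] + 1L] <- cm[truth[i] + 1L, pred[i] + 1L] + 1L
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(confusion = cm,
                 accuracy = 100 * sum(tp) / sum(cm),
                 precision = prec, recall = rec, f1 = f1,
                 macro_precision = mean(prec), macro_recall = mean(rec),
                 macro_f1 = mean(f1)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Accuracy: %.2f%%  macro PR %.4f  RE %.4f  F1 %.4f\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1))
  print(x$confusion)
  invisible(x)
}

#' Evaluate a model on labeled images
#'
#' @param net model from [severity_net()].
#' @param images list of [labeled_image()]s.
#' @param batch_size forward-pass batch size.
#' @return a [metrics_report()] over argmax predictions.
#' @export
evaluate_model <- function(net, images, batch_size = 16L) {
  if (!length(images)) stop("empty evaluation set")
  truth <- vapply(images, function(im) im$group, 0L)
  pred <- integer(length(images))
  i <- 1L
  while (i <= length(images)) {
    j <- min(i + batch_size - 1L, length(images))
    x <- stack_images(lapply(images[i:j], function(im) im$pixels))
    probs <- module_forward(net, x, training = FALSE)
    pred[i:j] <- apply(probs, 2, which.max) - 1L
    i <- j + 1L
  }
  metrics_report(truth, pred)
}

batch_loss <- function(net, images, gamma, batch_size = 16L) {
  total <- 0
  i <- 1L
  while (i <= length(images)) {
    j <- min(i + batch_size - 1L, length(images))
    x <- stack_images(lapply(images[i:j], function(im) im$pixels))
    probs <- module_forward(net, x, training = FALSE)
    truth <- vapply(images[i:j], function(im) im$group, 0L)
    total <- total + focal_loss(probs, truth, gamma) * (j - i + 1L)
    i <- j + 1L
  }
  total / length(images)
}

#' Training configuration
#'
#' @param epochs training epochs (default 50).
#' @param batch_size minibatch size (default 16).
#' @param lr_floor,lr_cap learning-rate bounds (1e-6 / 2e-3).
#' @param warmup warmup epochs (default 5).
#' @param patience early-stopping patience on validation loss (default 15).
#' @param gamma focal-loss exponent (default 1; 0 = cross-entropy).
#' @param cutmix_prob CutMix execution probability `P` (default 0.3;
#'   0 disables mixing).
#' @param augment apply geometric augmentation (default `TRUE`).
#' @param restore_best restore the best-validation-epoch weights at the
#'   end (default `TRUE`); short schedules whose learning rate decays to
#'   the floor may prefer the final iterate.
#' @param seed integer seed controlling batching, augmentation and dropout.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 16L, lr_floor = 1e-6,
                         lr_cap = 2e-3, warmup = 5L, patience = 15L,
                         gamma = 1, cutmix_prob = 0.3, augment = TRUE,
                         restore_best = TRUE, seed = 1L) {
  stopifnot(lr_floor < lr_cap, patience <= epochs, gamma >= 0,
            cutmix_prob >= 0, cutmix_prob <= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_floor = lr_floor, lr_cap = lr_cap,
                 warmup = as.integer(warmup), patience = as.integer(patience),
                 gamma = gamma, cutmix_prob = cutmix_prob,
                 augment = isTRUE(augment), restore_best = isTRUE(restore_best),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train a severity classifier
#'
#' Minibatch loop: geometric augmentation, severity-max CutMix with
#' execution probability `P`, focal loss, rectified Adam, warmup + cosine
#' learning rate. Training stops early when the validation loss fails to
#' improve for `patience` consecutive epochs; the best-epoch weights are
#' restored. Fully reproducible given `cfg$seed` (single-threaded).
#'
#' @param net model from [severity_net()] (modified in place and returned).
#' @param train_images,val_images lists of [labeled_image()]s from
#'   patient-disjoint manifests.
#' @param cfg a [train_config()].
#' @return list with `net`, `history` (per-epoch data.frame) and
#'   `stopped_epoch`.
#' @export
train_model <- function(net, train_images, val_images, cfg = train_config()) {
  stopifnot(inherits(cfg, "train_config"), length(train_images) > 0,
            length(val_images) > 0)
  opt <- new.env(parent = emptyenv())
  opt$state <- NULL
  hist <- list()
  best <- list(loss = Inf, params = NULL, epoch = -1L)
  bad <- 0L
  with_seed(derive_seed(cfg$seed, "train_loop"), {
    n_batches <- ceiling(length(train_images) / cfg$batch_size)
    for (epoch in seq_len(cfg$epochs) - 1L) {
      ord <- sample(length(train_images))
      ep_loss <- 0; n_seen <- 0L
      i <- 1L; step <- 0L
      while (i <= length(ord)) {
        # the schedule advances per step (fractional epochs)
        lr <- lr_schedule(epoch + step / n_batches, cfg$epochs,
                          cfg$lr_floor, cfg$lr_cap, cfg$warmup)
        step <- step + 1L
        j <- min(i + cfg$batch_size - 1L, length(ord))
        b <- train_images[ord[i:j]]
        if (cfg$augment) b <- lapply(b, geometric_augment)
        if (cfg$cutmix_prob > 0 && length(b) >= 2)
          b <- apply_batch(b, cfg$cutmix_prob)$batch
        x <- stack_images(lapply(b, function(im) im$pixels))
        truth <- vapply(b, function(im) im$group, 0L)
        probs <- module_forward(net, x, training = TRUE)
        loss <- focal_loss(probs, truth, cfg$gamma)
        if (!is.finite(loss)) {
          history <- do.call(rbind, hist)
          stop("training diverged (non-finite loss) at epoch ", epoch,
               "; history rows flushed: ", nrow(history))
        }
        zero_grads(net)
        module_backward(net, focal_loss_grad(probs, truth, cfg$gamma))
        radam_step_module(net, opt, lr)
        ep_loss <- ep_loss + loss * length(b)
        n_seen <- n_seen + length(b)
        i <- j + 1L
      }
      vl <- batch_loss(net, val_images, cfg$gamma, cfg$batch_size)
      hist[[length(hist) + 1L]] <- data.frame(
        epoch = epoch, lr = lr, train_loss = ep_loss / n_seen,
        val_loss = vl)
      if (vl < best$loss) {
        best <- list(loss = vl, params = state_dict(net), epoch = epoch)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= cfg$patience) break
      }
    }
  })
  if (cfg$restore_best && !is.null(best$params)) load_state(net, best$params)
  list(net = net, history = do.call(rbind, hist),
       stopped_epoch = hist[[length(hist)]]$epoch,
       best_epoch = best$epoch)
}

#' Save / load model weights
#'
#' Checkpoints are plain JSON (shapes plus flattened values), so they are
#' text-only and portable.
#'
#' @param net a trainable module.
#' @param path checkpoint file.
#' @return `net`, invisibly (load restores weights in place).
#' @export
save_checkpoint <- function(net, path) {
  params <- state_dict(net)
  payload <- lapply(params, function(p)
    list(dim = dim(p) %||% length(p), data = as.numeric(p)))
  jsonlite::write_json(payload, path, digits = NA)
  invisible(net)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(net, path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  params <- lapply(payload, function(p)
    array(unlist(p$data), unlist(p$dim)))
  load_state(net, params)
  invisible(net)
}
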