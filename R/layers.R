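# Minimal trainable-layer framework with explicit backprop.
#
# A layer is an environment of class c(<type>, "sg_module") holding its
# parameter arrays (W, b, ...), matching gradient arrays prefixed "g", and
# forward-pass caches. `module_forward()` / `module_backward()` dispatch on
# the type; `module_params()` enumerates parameter slots for the optimizer.
# All activations are H x W x C x N arrays.

new_module <- function(type) {
  self <- new.env(parent = emptyenv())
  class(self) <- c(type, "sg_module")
  self$param_names <- character()
  self
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

add_param <- function(self, name, value) {
  self[[name]] <- value
  self[[paste0("g", name)]] <- value * 0   # same shape and attributes
  self$param_names <- c(self$param_names, name)
  invisible(self)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
module_forward <- function(self, x, training = FALSE) UseMethod("module_forward")

#' @export
module_backward <- function(self, gy) UseMethod("module_backward")

# enumerate parameter references of a module tree
module_params <- function(self) {
  out <- list()
  for (nm in self$param_names)
    out[[length(out) + 1L]] <- list(env = self, name = nm)
  for (ch in self$children %||% list())
    out <- c(out, module_params(ch))
  out
}

zero_grads <- function(self) {
  for (p in module_params(self)) {
    g <- paste0("g", p$name)
    p$env[[g]][] <- 0
  }
  invisible(self)
}

n_params <- function(self) {
  sum(vapply(module_params(self), function(p) length(p$env[[p$name]]), 0))
}

# non-trainable state (e.g. normalization running statistics)
module_buffers <- function(self) {
  out <- list()
  for (nm in self$buffer_names %||% character())
    out[[length(out) + 1L]] <- list(env = self, name = nm)
  for (ch in self$children %||% list())
    out <- c(out, module_buffers(ch))
  out
}

# flat list of parameter and buffer arrays (for checkpointing)
state_dict <- function(self) {
  lapply(c(module_params(self), module_buffers(self)),
         function(p) p$env[[p$name]])
}

load_state <- function(self, params) {
  refs <- c(module_params(self), module_buffers(self))
  stopifnot(length(refs) == length(params))
  for (i in seq_along(refs)) {
    stopifnot(length(refs[[i]]$env[[refs[[i]]$name]]) == length(params[[i]]))
    refs[[i]]$env[[refs[[i]]$name]][] <- params[[i]]
  }
  invisible(self)
}

# ---- dense 2-D convolution --------------------------------------------

layer_conv2d <- function(cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L,
                         zero_init = FALSE) {
  self <- new_module("conv2d")
  self$cin <- cin; self$cout <- cout; self$k <- k
  self$stride <- as.integer(stride); self$pad <- as.integer(pad)
  W <- if (zero_init) array(0, c(k, k, cin, cout))
       else he_init(c(k, k, cin, cout), k * k * cin)
  add_param(self, "W", W)
  add_param(self, "b", numeric(cout))
  self
}

#' @export
module_forward.conv2d <- function(self, x, training = FALSE) {
  self$x <- x
  out <- cpp_conv2d_fw(x, self$W, self$b, self$stride, self$pad)
  d <- dim(out)
  audit_record(d[1] * d[2] * self$cout * self$k^2 * self$cin)
  out
}

#' @export
module_backward.conv2d <- function(self, gy) {
  bw <- cpp_conv2d_bw(self$x, self$W, gy, self$stride, self$pad)
  self$gW <- self$gW + bw$gw
  self$gb <- self$gb + bw$gb
  bw$gx
}

# ---- deformable convolution (offset conv + deformable sampling) -------

layer_dconv2d <- function(cin, cout, k) {
  self <- new_module("dconv2d")
  self$cin <- cin; self$cout <- cout; self$k <- k
  add_param(self, "W", he_init(c(k, k, cin, cout), k * k * cin))
  add_param(self, "b", numeric(cout))
  # offset branch starts at the regular sampling grid
  self$offset_conv <- layer_conv2d(cin, 2L * k * k, k, zero_init = TRUE)
  self$children <- list(self$offset_conv)
  self
}

#' @export
module_forward.dconv2d <- function(self, x, training = FALSE) {
  self$x <- x
  self$off <- module_forward(self$offset_conv, x, training)
  d <- dim(x)
  audit_record(d[1] * d[2] * self$cout * self$k^2 * self$cin)
  cpp_dconv2d_fw(x, self$W, self$b, self$off)
}

#' @export
module_backward.dconv2d <- function(self, gy) {
  bw <- cpp_dconv2d_bw(self$x, self$W, self$off, gy)
  self$gW <- self$gW + bw$gw
  self$gb <- self$gb + bw$gb
  bw$gx + module_backward(self$offset_conv, bw$goff)
}

# ---- batch normalization ----------------------------------------------

layer_bn <- function(channels, eps = 1e-5, momentum = 0.1) {
  self <- new_module("bn")
  self$C <- channels; self$eps <- eps; self$momentum <- momentum
  add_param(self, "gamma", rep(1, channels))
  add_param(self, "beta", numeric(channels))
  self$run_mean <- numeric(channels)       # buffers, not trainable
  self$run_var <- rep(1, channels)
  self$buffer_names <- c("run_mean", "run_var")
  self
}

#' @export
module_forward.bn <- function(self, x, training = FALSE) {
  d <- dim(x)
  m <- d[1] * d[2] * d[4]
  out <- x
  self$xhat <- x
  self$m <- m
  self$sd_cache <- numeric(d[3])
  for (c in seq_len(d[3])) {
    ch <- x[, , c, , drop = FALSE]
    if (training) {
      mu <- mean(ch)
      va <- mean((ch - mu)^2)
      self$run_mean[c] <- (1 - self$momentum) * self$run_mean[c] +
        self$momentum * mu
      self$run_var[c] <- (1 - self$momentum) * self$run_var[c] +
        self$momentum * va * m / max(1, m - 1)
    } else {
      mu <- self$run_mean[c]
      va <- self$run_var[c]
    }
    sd_c <- sqrt(va + self$eps)
    xh <- (ch - mu) / sd_c
    self$xhat[, , c, ] <- xh
    self$sd_cache[c] <- sd_c
    out[, , c, ] <- self$gamma[c] * xh + self$beta[c]
  }
  self$trained_pass <- training
  out
}

#' @export
module_backward.bn <- function(self, gy) {
  d <- dim(gy)
  gx <- gy
  for (c in seq_len(d[3])) {
    g <- gy[, , c, , drop = FALSE]
    xh <- self$xhat[, , c, , drop = FALSE]
    self$ggamma[c] <- self$ggamma[c] + sum(g * xh)
    self$gbeta[c] <- self$gbeta[c] + sum(g)
    if (self$trained_pass) {
      gx[, , c, ] <- (self$gamma[c] / self$sd_cache[c]) *
        (g - mean(g) - xh * mean(g * xh))
    } else {
      gx[, , c, ] <- (self$gamma[c] / self$sd_cache[c]) * g
    }
  }
  gx
}

# 1-D batch norm over feature x batch matrices (pooled features)
layer_bn1d <- function(features, eps = 1e-5, momentum = 0.1) {
  self <- new_module("bn1d")
  self$C <- features; self$eps <- eps; self$momentum <- momentum
  add_param(self, "gamma", rep(1, features))
  add_param(self, "beta", numeric(features))
  self$run_mean <- numeric(features)
  self$run_var <- rep(1, features)
  self$buffer_names <- c("run_mean", "run_var")
  self
}

#' @export
module_forward.bn1d <- function(self, x, training = FALSE) {
  n <- ncol(x)
  if (training && n > 1) {
    mu <- rowMeans(x)
    va <- rowMeans((x - mu)^2)
    self$run_mean <- (1 - self$momentum) * self$run_mean + self$momentum * mu
    self$run_var <- (1 - self$momentum) * self$run_var +
      self$momentum * va * n / (n - 1)
  } else {
    mu <- self$run_mean
    va <- self$run_var
  }
  self$sd_cache <- sqrt(va + self$eps)
  self$xhat <- (x - mu) / self$sd_cache
  self$trained_pass <- training && n > 1
  self$gamma * self$xhat + self$beta
}

#' @export
module_backward.bn1d <- function(self, gy) {
  self$ggamma <- self$ggamma + rowSums(gy * self$xhat)
  self$gbeta <- self$gbeta + rowSums(gy)
  if (self$trained_pass) {
    (self$gamma / self$sd_cache) *
      (gy - rowMeans(gy) - self$xhat * rowMeans(gy * self$xhat))
  } else {
    (self$gamma / self$sd_cache) * gy
  }
}

# ---- pointwise nonlinearities -----------------------------------------

layer_relu <- function() new_module("relu")

#' @export
module_forward.relu <- function(self, x, training = FALSE) {
  self$mask <- x > 0
  x * self$mask
}

#' @export
module_backward.relu <- function(self, gy) gy * self$mask

layer_dropout <- function(p = 0.2) {
  self <- new_module("dropout")
  self$p <- p
  self
}

#' @export
module_forward.dropout <- function(self, x, training = FALSE) {
  if (!training || self$p <= 0) {
    self$mask <- NULL
    return(x)
  }
  self$mask <- array(rbinom(length(x), 1L, 1 - self$p), dim(x)) / (1 - self$p)
  x * self$mask
}

#' @export
module_backward.dropout <- function(self, gy) {
  if (is.null(self$mask)) gy else gy * self$mask
}

# ---- global average pooling: H x W x C x N -> C x N -------------------

layer_gap <- function() new_module("gap")

#' @export
module_forward.gap <- function(self, x, training = FALSE) {
  d <- dim(x)
  self$in_dim <- d
  apply(x, c(3, 4), mean)
}

#' @export
module_backward.gap <- function(self, gy) {
  d <- self$in_dim
  gx <- array(0, d)
  for (n in seq_len(d[4])) for (c in seq_len(d[3]))
    gx[, , c, n] <- gy[c, n] / (d[1] * d[2])
  gx
}

# ---- dense layer on C x N matrices ------------------------------------

layer_dense <- function(nin, nout, zero_init = FALSE, bias = TRUE) {
  self <- new_module("dense")
  self$nin <- nin; self$nout <- nout
  W <- if (zero_init) matrix(0, nout, nin)
       else matrix(rnorm(nout * nin, sd = sqrt(2 / nin)), nout, nin)
  add_param(self, "W", W)
  if (bias) add_param(self, "b", numeric(nout)) else self$b <- numeric(nout)
  self
}

#' @export
module_forward.dense <- function(self, x, training = FALSE) {
  self$x <- x                      # nin x N
  audit_record(self$nin * self$nout)
  self$W %*% x + self$b
}

#' @export
module_backward.dense <- function(self, gy) {
  self$gW <- self$gW + gy %*% t(self$x)
  if (!is.null(self$gb)) self$gb <- self$gb + rowSums(gy)
  t(self$W) %*% gy
}

# ---- per-channel L2 normalization over space --------------------------

#' L2-normalize each channel plane of a feature map
#'
#' Divides every channel by its Euclidean norm over spatial positions plus
#' a small epsilon, so each nonzero channel plane has unit energy and an
#' all-zero channel stays zero.
#'
#' @param x array `H x W x C` or `H x W x C x N`.
#' @param eps stabiliser added to the norm (default `1e-12`).
#' @return array of the same shape.
#' @export
l2_normalize <- function(x, eps = 1e-12) {
  single <- length(dim(x)) == 3L
  x <- as_batch(x)
  d <- dim(x)
  out <- x
  for (n in seq_len(d[4])) for (c in seq_len(d[3])) {
    nrm <- sqrt(sum(x[, , c, n]^2))
    out[, , c, n] <- x[, , c, n] / (nrm + eps)
  }
  if (single) dim(out) <- d[1:3]
  out
}

layer_l2norm <- function(eps = 1e-12) {
  self <- new_module("l2norm")
  self$eps <- eps
  self
}

#' @export
module_forward.l2norm <- function(self, x, training = FALSE) {
  d <- dim(x)
  self$x <- x
  self$nrm <- array(0, d[3:4])
  out <- x
  for (n in seq_len(d[4])) for (c in seq_len(d[3])) {
    nrm <- sqrt(sum(x[, , c, n]^2))
    self$nrm[c, n] <- nrm
    out[, , c, n] <- x[, , c, n] / (nrm + self$eps)
  }
  out
}

#' @export
module_backward.l2norm <- function(self, gy) {
  d <- dim(self$x)
  gx <- gy
  for (n in seq_len(d[4])) for (c in seq_len(d[3])) {
    nrm <- self$nrm[c, n]
    den <- nrm + self$eps
    gx[, , c, n] <- gy[, , c, n] / den
    if (nrm > 0) {
      ip <- sum(gy[, , c, n] * self$x[, , c, n])
      gx[, , c, n] <- gx[, , c, n] -
        self$x[, , c, n] * (ip / (nrm * den^2))
    }
  }
  gx
}

# ---- bilinear resize with adjoint backward ----------------------------

layer_resize <- function(out_h, out_w) {
  self <- new_module("resize")
  self$out_h <- out_h; self$out_w <- out_w
  self
}

#' @export
module_forward.resize <- function(self, x, training = FALSE) {
  self$in_h <- dim(x)[1]; self$in_w <- dim(x)[2]
  if (self$in_h == self$out_h && self$in_w == self$out_w) return(x)
  resize_bilinear(x, self$out_h, self$out_w)
}

#' @export
module_backward.resize <- function(self, gy) {
  if (self$in_h == self$out_h && self$in_w == self$out_w) return(gy)
  resize_bilinear_bw(gy, self$in_h, self$in_w)
}
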