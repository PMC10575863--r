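# Multi-scale deformable attention module (MS-DAM) and the hierarchical
# fusion + classification head.
#
# One MS-DAM instance sits on each backbone stage output (strides 8/16/32).
# Inside a block: a 1x1 projection to the branch width, three parallel
# deformable convolutions with distinct odd kernels, channel concatenation,
# a 1x1 fusion convolution back to the stage width, and a residual add
# giving R. A channel-attention vector softplus(1x1conv(GAP(R))) — strictly
# positive, so no channel is annihilated — scales the L2-normalized R
# elementwise. The three per-stage outputs are resized to the stride-16
# grid, concatenated along channels, and classified by GAP -> dropout ->
# dense(5) -> softmax.

cat_channels <- function(maps) {
  d <- dim(maps[[1]])
  cs <- vapply(maps, function(m) dim(m)[3], 0L)
  out <- array(0, c(d[1], d[2], sum(cs), d[4]))
  at <- 0L
  for (m in maps) {
    out[, , at + seq_len(dim(m)[3]), ] <- m
    at <- at + dim(m)[3]
  }
  out
}

split_channels <- function(x, sizes) {
  at <- 0L
  lapply(sizes, function(s) {
    blk <- x[, , at + seq_len(s), , drop = FALSE]
    at <<- at + s
    blk
  })
}

#' Construct a multi-scale deformable attention block
#'
#' @param channels stage channel count `C`.
#' @param kernels three distinct odd kernel sizes (default `c(3, 5, 7)`).
#' @param width_ratio branch width ratio `r`; branch channels are
#'   `max(4, floor(r * C))` after a 1x1 entry projection.
#' @return a trainable module; apply with [msdam_forward()].
#' @export
msdam_block <- function(channels, kernels = c(3L, 5L, 7L), width_ratio = 0.25) {
  stopifnot(length(kernels) == 3, all(kernels %% 2 == 1),
            !anyDuplicated(kernels), width_ratio > 0, width_ratio <= 1)
  if (channels < 4L)
    stop("msdam_block: stage must have at least 4 channels, got ", channels)
  self <- new_module("msdam")
  B <- max(4L, as.integer(floor(width_ratio * channels)))
  self$C <- channels; self$B <- B; self$kernels <- as.integer(kernels)
  self$proj <- layer_conv2d(channels, B, 1L)
  self$branches <- lapply(self$kernels, function(k) layer_dconv2d(B, B, k))
  # zero-init residual fusion: the block starts as an identity-like
  # residual (R = X), the conventional initialization for residual branches
  self$fuse <- layer_conv2d(3L * B, channels, 1L, zero_init = TRUE)
  self$gap <- layer_gap()
  self$att <- layer_dense(channels, channels)   # the 1x1 conv on pooled features
  # scale-preserving start: a unit-norm channel plane has RMS 1/sqrt(H*W),
  # so the attention starts near sqrt(H*W) (~6 for the grids used here) to
  # hand the head features of order one
  self$att$b[] <- 6
  self$l2 <- layer_l2norm()
  self$children <- c(list(self$proj), self$branches, list(self$fuse, self$att))
  self
}

#' @export
module_forward.msdam <- function(self, x, training = FALSE) {
  p <- module_forward(self$proj, x, training)
  bs <- lapply(self$branches, module_forward, p, training)
  fz <- module_forward(self$fuse, cat_channels(bs), training)
  r <- fz + x                                   # residual path
  self$z <- module_forward(self$att, module_forward(self$gap, r, training),
                           training)
  self$a <- softplus(self$z)                    # C x N, strictly positive
  self$y <- module_forward(self$l2, r, training)
  d <- dim(r)
  out <- self$y * aperm(array(self$a, c(d[3], d[4], d[1], d[2])), c(3, 4, 1, 2))
  out
}

#' @export
module_backward.msdam <- function(self, gy) {
  d <- dim(self$y)
  abc <- aperm(array(self$a, c(d[3], d[4], d[1], d[2])), c(3, 4, 1, 2))
  gY <- gy * abc
  ga <- apply(gy * self$y, c(3, 4), sum)        # C x N
  gz <- ga * sigmoid(self$z)
  gR <- module_backward(self$gap, module_backward(self$att, gz)) +
    module_backward(self$l2, gY)
  gcat <- module_backward(self$fuse, gR)
  blocks <- split_channels(gcat, rep(self$B, 3))
  gP <- module_backward(self$branches[[1]], blocks[[1]])
  for (i in 2:3) gP <- gP + module_backward(self$branches[[i]], blocks[[i]])
  gR + module_backward(self$proj, gP)           # residual + projection paths
}

#' Apply an MS-DAM block to a stage feature map
#'
#' @param block module from [msdam_block()].
#' @param x feature map `H x W x C (x N)`.
#' @param training logical; enables training-time behaviour.
#' @return attention-weighted feature map of the same shape.
#' @export
msdam_forward <- function(block, x, training = FALSE) {
  single <- length(dim(x)) == 3L
  out <- module_forward(block, as_batch(x), training)
  if (single) dim(out) <- dim(out)[1:3]
  out
}

#' Fuse hierarchical stage maps on the stride-16 grid
#'
#' Bilinearly resizes the stride-8 and stride-32 maps to the spatial grid
#' of the stride-16 (middle) map — the anchor stage passes through
#' unchanged — and concatenates all three along channels.
#'
#' @param maps list of three feature maps ordered stride 8, 16, 32.
#' @return fused map with `sum(C_s)` channels at the stride-16 grid.
#' @export
fuse_stages <- function(maps) {
  stopifnot(length(maps) == 3)
  single <- length(dim(maps[[1]])) == 3L
  maps <- lapply(maps, as_batch)
  ns <- vapply(maps, function(m) dim(m)[4], 0L)
  if (length(unique(ns)) != 1) stop("fuse_stages: inconsistent batch sizes")
  anchor <- dim(maps[[2]])[1:2]
  maps <- lapply(maps, resize_bilinear, out_h = anchor[1], out_w = anchor[2])
  out <- cat_channels(maps)
  if (single) dim(out) <- dim(out)[1:3]
  out
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# classification head: GAP -> feature norm -> dropout -> bias-free dense
# -> softmax. The pooled features are batch-normalized and the classifier
# carries no bias, so class priors cannot be absorbed into the logits and
# the gradient budget goes entirely into discrimination; the dense layer
# starts at zero so training begins from uniform class probabilities.
head_module <- function(cin, n_classes = 5L, dropout = 0.2) {
  self <- new_module("clshead")
  self$gap <- layer_gap()
  self$norm <- layer_bn1d(cin)
  self$drop <- layer_dropout(dropout)
  self$fc <- layer_dense(cin, n_classes, zero_init = TRUE, bias = FALSE)
  self$children <- list(self$norm, self$fc)
  self
}

#' @export
module_forward.clshead <- function(self, x, training = FALSE) {
  h <- module_forward(self$gap, x, training)
  h <- module_forward(self$norm, h, training)
  h <- module_forward(self$drop, h, training)
  self$logits <- module_forward(self$fc, h, training)
  softmax_cols(self$logits)
}

# backward from gradient w.r.t. logits (loss handles the softmax jacobian)
#' @export
module_backward.clshead <- function(self, gy) {
  module_backward(self$gap,
    module_backward(self$norm,
      module_backward(self$drop, module_backward(self$fc, gy))))
}

#' Run the classification head on a fused feature map
#'
#' @param head module from the network builder (GAP, dropout, dense, softmax).
#' @param fused fused feature map `H x W x C (x N)`.
#' @param training logical; dropout is active only when `TRUE`.
#' @return matrix `5 x N` of class probabilities (columns sum to 1).
#' @export
head_forward <- function(head, fused, training = FALSE) {
  module_forward(head, as_batch(fused), training)
}

# ---- full severity classification network -----------------------------

#' Build the severity classification network
#'
#' Wires a stage-tapped backbone, optional per-stage MS-DAM blocks
#' (parameters not shared across stages), stride-16 fusion, and the
#' classification head into a single trainable model.
#'
#' @param backbone module exposing stage outputs (see [build_tiny_backbone()]).
#' @param use_msdam logical; when `FALSE` the raw stage maps are fused
#'   directly (the ablation baseline).
#' @param kernels,width_ratio MS-DAM branch configuration.
#' @param dropout head dropout probability.
#' @param n_classes number of severity groups.
#' @param seed integer seed for weight initialisation.
#' @return a trainable model of class `severity_net`.
#' @export
severity_net <- function(backbone, use_msdam = TRUE, kernels = c(3L, 5L, 7L),
                         width_ratio = 0.25, dropout = 0.2, n_classes = 5L,
                         seed = 1L) {
  self <- new_module("severity_net")
  with_seed(derive_seed(seed, "severity_net"), {
    self$backbone <- backbone
    self$use_msdam <- use_msdam
    cs <- backbone$stage_channels
    if (use_msdam)
      self$msdam <- lapply(cs, msdam_block, kernels = kernels,
                           width_ratio = width_ratio)
    self$head <- head_module(sum(cs), n_classes, dropout)
  })
  self$children <- c(list(self$backbone), if (use_msdam) self$msdam,
                     list(self$head))
  self
}

#' @export
module_forward.severity_net <- function(self, x, training = FALSE) {
  x <- as_batch(x)
  taps <- module_forward(self$backbone, x, training)
  z <- if (self$use_msdam)
    Map(function(b, t) module_forward(b, t, training), self$msdam, taps)
  else taps
  anchor <- dim(z[[2]])[1:2]
  self$resizers <- lapply(z, function(m) layer_resize(anchor[1], anchor[2]))
  rs <- Map(function(r, m) module_forward(r, m, training), self$resizers, z)
  self$stage_maps <- z
  self$fused <- cat_channels(rs)
  self$stage_channels <- vapply(z, function(m) dim(m)[3], 0L)
  module_forward(self$head, self$fused, training)
}

# backward from gradient w.r.t. the logits; returns gradient w.r.t. input
#' @export
module_backward.severity_net <- function(self, gy) {
  gfused <- module_backward(self$head, gy)
  blocks <- split_channels(gfused, self$stage_channels)
  gz <- Map(function(r, b) module_backward(r, b), self$resizers, blocks)
  gt <- if (self$use_msdam)
    Map(function(m, g) module_backward(m, g), self$msdam, gz)
  else gz
  module_backward(self$backbone, gt)
}

#' Class probabilities for a batch of images
#'
#' @param net model from [severity_net()].
#' @param x image array `H x W x 3 (x N)`, values in `[0, 1]`.
#' @param training logical.
#' @return matrix `n_classes x N` of probabilities.
#' @export
net_predict <- function(net, x, training = FALSE) {
  module_forward(net, x, training)
}
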