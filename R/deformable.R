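# Public surface of the deformable convolution.
#
# Semantics follow the original deformable convolutional network (v1):
# one learned (dy, dx) displacement per kernel tap and output location,
# shared across input channels, no modulation mask. The sampled value at a
# fractional location is the bilinear interpolation of its four neighbours
# with zero padding outside the frame, so the operator reduces exactly to a
# standard convolution when all offsets are zero.

#' Deformable 2-D convolution (stride 1, 'same' padding)
#'
#' Computes `y(p0) = sum_n w(p_n) x(p0 + p_n + dp_n)` over input channels,
#' where `p_n` ranges over the regular kernel grid (row-major) and `dp_n`
#' is the per-location learned displacement of tap `n`.
#'
#' @param x input array `H x W x C_in` or `H x W x C_in x N`.
#' @param weights array `k x k x C_in x C_out`, `k` odd.
#' @param offsets array `H x W x 2k^2` (or batched): channels `2t, 2t+1`
#'   hold `(dy, dx)` for tap `t` (0-based, row-major over the window).
#' @param bias numeric length `C_out` (default zeros).
#' @return array `H x W x C_out (x N)`.
#' @export
deform_conv2d <- function(x, weights, offsets, bias = NULL) {
  single <- length(dim(x)) == 3L
  x <- as_batch(x)
  offsets <- as_batch(offsets)
  k <- dim(weights)[1]
  stopifnot(k %% 2 == 1, dim(weights)[2] == k,
            dim(weights)[3] == dim(x)[3],
            dim(offsets)[3] == 2 * k * k,
            dim(offsets)[4] == dim(x)[4])
  if (is.null(bias)) bias <- numeric(dim(weights)[4])
  out <- cpp_dconv2d_fw(x, weights, bias, offsets)
  if (single) dim(out) <- dim(out)[1:3]
  out
}

#' Gradients of the deformable convolution
#'
#' Analytic gradients with respect to the input, the weights, the bias and
#' the offset field, given the upstream gradient of the output.
#'
#' @inheritParams deform_conv2d
#' @param gy upstream gradient, same shape as the forward output.
#' @return list with elements `gx`, `gw`, `gb`, `goff`.
#' @export
deform_conv2d_grad <- function(x, weights, offsets, gy) {
  single <- length(dim(x)) == 3L
  x <- as_batch(x); offsets <- as_batch(offsets); gy <- as_batch(gy)
  bw <- cpp_dconv2d_bw(x, weights, offsets, gy)
  if (single) {
    dim(bw$gx) <- dim(bw$gx)[1:3]
    dim(bw$goff) <- dim(bw$goff)[1:3]
  }
  bw
}

#' Build the offset-prediction convolution of a deformable layer
#'
#' A standard `k x k` convolution with `2k^2` output channels whose weights
#' and bias are initialised to zero, so a fresh deformable layer starts at
#' the regular sampling grid and is exactly a standard convolution.
#'
#' @param cin input channels.
#' @param k kernel size (odd).
#' @return a trainable module; apply with [offset_conv()].
#' @export
offset_conv_layer <- function(cin, k) layer_conv2d(cin, 2L * k * k, k, zero_init = TRUE)

#' Predict an offset field from a feature map
#'
#' @param layer module from [offset_conv_layer()].
#' @param x input array `H x W x C_in (x N)`.
#' @return offset field `H x W x 2k^2 (x N)`.
#' @export
offset_conv <- function(layer, x) {
  single <- length(dim(x)) == 3L
  out <- module_forward(layer, as_batch(x))
  if (single) dim(out) <- dim(out)[1:3]
  out
}

#' Standard 2-D convolution (functional form)
#'
#' Same tensor conventions as [deform_conv2d()]; used by the backbone and
#' exposed for direct comparison with the zero-offset deformable operator.
#'
#' @param x input array `H x W x C_in (x N)`.
#' @param weights array `k x k x C_in x C_out`.
#' @param bias numeric length `C_out` (default zeros).
#' @param stride integer stride.
#' @param pad integer zero padding (default 'same' for stride 1).
#' @return output array.
#' @export
conv2d <- function(x, weights, bias = NULL, stride = 1L,
                   pad = (dim(weights)[1] - 1L) %/% 2L) {
  single <- length(dim(x)) == 3L
  x <- as_batch(x)
  if (is.null(bias)) bias <- numeric(dim(weights)[4])
  out <- cpp_conv2d_fw(x, weights, bias, as.integer(stride), as.integer(pad))
  if (single) dim(out) <- dim(out)[1:3]
  out
}
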