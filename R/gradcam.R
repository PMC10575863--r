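# Grad-CAM over the fused (or per-stage) feature maps, and the
# patch-localization statistic used to check that a trained model attends
# to the higher-severity region of a mixed image.

#' Grad-CAM heatmap
#'
#' Channel weights are the spatial means of the gradient of the
#' pre-softmax logit of the target class with respect to the target
#' layer's activations; the heatmap is the ReLU of the weighted channel
#' sum, bilinearly upsampled to image size for the overlay.
#'
#' @param net model from [severity_net()].
#' @param image a [labeled_image()] or `H x W x 3` array.
#' @param target_class class index in `0..4`.
#' @param layer `"fused"` (default) or `"stage1"`/`"stage2"`/`"stage3"`
#'   for the per-stage attention outputs.
#' @return object of class `gradcam_heatmap`: `grid` (non-negative, at
#'   the target layer's spatial size), `overlay` (image-sized), plus the
#'   class and layer.
#' @export
grad_cam <- function(net, image, target_class, layer = "fused") {
  px <- if (inherits(image, "labeled_image")) image$pixels else image
  stopifnot(target_class %in% 0:4,
            layer %in% c("fused", "stage1", "stage2", "stage3"))
  x <- as_batch(px)
  module_forward(net, x, training = FALSE)
  glogits <- matrix(0, 5, 1)
  glogits[target_class + 1L, 1] <- 1
  zero_grads(net)
  gfused <- module_backward(net$head, glogits)
  if (layer == "fused") {
    A <- net$fused[, , , 1]
    G <- gfused[, , , 1]
  } else {
    idx <- as.integer(sub("stage", "", layer))
    blocks <- split_channels(gfused, net$stage_channels)
    gz <- module_backward(net$resizers[[idx]], blocks[[idx]])
    A <- net$stage_maps[[idx]][, , , 1]
    G <- gz[, , , 1]
  }
  zero_grads(net)
  alpha <- apply(G, 3, mean)
  L <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_along(alpha)) L <- L + alpha[k] * A[, , k]
  L <- pmax(L, 0)
  ov <- resize_bilinear(array(L, c(dim(L), 1L)), dim(px)[1], dim(px)[2])
  structure(list(grid = L, overlay = ov[, , 1], target_class = target_class,
                 layer = layer),
            class = "gradcam_heatmap")
}

#' Localization score of a mixed image
#'
#' Ratio of the mean heatmap value inside the higher-severity parent's
#' pixel region to the mean outside. Values above 1 indicate the model
#' attends to the representative (higher-severity) region.
#'
#' @param heat a [grad_cam()] result on the mixed image.
#' @param plan the `mix_plan` that produced the image.
#' @return scalar score; `+Inf` when all heat lies inside the region,
#'   `NA` (with a warning) for degenerate masks or tied parent labels.
#' @export
patch_localization_score <- function(heat, plan) {
  stopifnot(inherits(heat, "gradcam_heatmap"), inherits(plan, "mix_plan"))
  if (plan$y_a == plan$y_b) {
    warning("tied parent labels: no higher-severity region")
    return(NA_real_)
  }
  region <- if (plan$y_a > plan$y_b) plan$M == 1 else plan$M == 0
  if (!any(region) || all(region)) {
    warning("degenerate mask: one side is empty")
    return(NA_real_)
  }
  h <- heat$overlay
  stopifnot(identical(dim(h), dim(plan$M)))
  inside <- mean(h[region])
  outside <- mean(h[!region])
  if (outside == 0) return(if (inside > 0) Inf else NA_real_)
  inside / outside
}

#' Write a Grad-CAM overlay PNG
#'
#' The heatmap is min-max normalized per image, colorized with a
#' blue-to-red ramp and alpha-blended over the input.
#'
#' @param heat a [grad_cam()] result.
#' @param image the image the heatmap was computed on.
#' @param path output PNG path.
#' @param alpha blend weight of the heat layer.
#' @return invisibly, `path`.
#' @export
write_gradcam_overlay <- function(heat, image, path, alpha = 0.45) {
  px <- if (inherits(image, "labeled_image")) image$pixels else image
  h <- heat$overlay
  rng <- range(h)
  h <- if (diff(rng) > 0) (h - rng[1]) / diff(rng) else h * 0
  ramp <- grDevices::colorRamp(c("#2166ac", "#f7f7f7", "#b2182b"))
  cols <- ramp(as.vector(h)) / 255
  out <- px
  for (c in 1:3) {
    layer <- matrix(cols[, c], nrow(h), ncol(h))
    out[, , c] <- (1 - alpha) * px[, , c] + alpha * layer
  }
  png::writePNG(out, path)
  invisible(path)
}
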