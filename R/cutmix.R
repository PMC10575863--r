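# Severity-max CutMix.
#
# A rectangular patch of image B is pasted into host image A:
# x~ = M * x_A + (1 - M) * x_B with a binary mask M that is 1 outside the
# patch. Unlike area-weighted CutMix, the label of the mixed image is the
# HIGHER of the two severity labels, independent of patch area — the
# higher-severity parent is the representative region a clinician would
# grade. Applied per sample with execution probability P.

#' Sample a CutMix mask
#'
#' The original CutMix box rule: draw `lambda ~ Uniform(0, 1)`, cut a
#' rectangle of side lengths `W * sqrt(1 - lambda)` and
#' `H * sqrt(1 - lambda)` centred uniformly at random, clipped to the
#' frame. `M` is 1 outside the pasted patch (selecting the host image).
#'
#' @param H,W mask dimensions.
#' @return list with `M` (binary `H x W` matrix), `lambda_area`
#'   (`mean(M)`, the host-pixel fraction after clipping) and the box
#'   corners `y0, y1, x0, x1` (1-based, inclusive; zero-area boxes give
#'   `y1 < y0`).
#' @export
sample_box <- function(H, W) {
  stopifnot(H >= 1, W >= 1)
  lam <- runif(1)
  cut_h <- as.integer(round(H * sqrt(1 - lam)))
  cut_w <- as.integer(round(W * sqrt(1 - lam)))
  cy <- sample.int(H, 1)
  cx <- sample.int(W, 1)
  y0 <- max(1L, cy - cut_h %/% 2L)
  x0 <- max(1L, cx - cut_w %/% 2L)
  y1 <- min(H, y0 + cut_h - 1L)
  x1 <- min(W, x0 + cut_w - 1L)
  M <- matrix(1, H, W)
  if (cut_h > 0 && cut_w > 0) M[y0:y1, x0:x1] <- 0
  list(M = M, lambda_area = mean(M), y0 = y0, y1 = y1, x0 = x0, x1 = x1)
}

#' Mix two labeled images with the severity-max rule
#'
#' @param a,b [labeled_image()]s of identical shape: `a` is the host, the
#'   pasted patch comes from `b`.
#' @return list with `image` (the mixed [labeled_image()], labeled by the
#'   higher-severity parent) and `plan` (class `mix_plan`: the mask, area
#'   fraction, parent labels and provenance).
#' @export
mix <- function(a, b) {
  stopifnot(inherits(a, "labeled_image"), inherits(b, "labeled_image"))
  if (!identical(dim(a$pixels), dim(b$pixels)))
    stop("mix: images must share a shape")
  d <- dim(a$pixels)
  box <- sample_box(d[1], d[2])
  px <- a$pixels
  for (c in 1:3) px[, , c] <- box$M * a$pixels[, , c] +
      (1 - box$M) * b$pixels[, , c]
  y_tilde <- if (a$group > b$group) a$group else b$group
  hi <- if (a$group > b$group) a else b
  mixed <- labeled_image(px, hi$erythema, hi$scaling,
                         paste0(a$patient_id, "+", b$patient_id))
  mixed$group <- y_tilde
  plan <- structure(list(M = box$M, lambda_area = box$lambda_area,
                         y_a = a$group, y_b = b$group, y_tilde = y_tilde,
                         parents = c(a$patient_id, b$patient_id)),
                    class = "mix_plan")
  list(image = mixed, plan = plan)
}

#' Severity-max label rule
#'
#' @param y_a,y_b parent severity labels.
#' @return `y_a` if `y_a > y_b`, else `y_b` — i.e. `max(y_a, y_b)`.
#' @export
cutmix_label <- function(y_a, y_b) ifelse(y_a > y_b, y_a, y_b)

#' Apply CutMix across a batch
#'
#' Each sample is independently replaced, with probability `prob`, by a
#' mix of itself (host) and a uniformly drawn other sample of the batch;
#' otherwise it passes through unchanged.
#'
#' @param batch list of [labeled_image()]s (length >= 2 for mixing).
#' @param prob execution probability `P` in `[0, 1]` (default 0.3).
#' @return list with `batch` (same length) and `plans` (a `mix_plan` or
#'   `NULL` per slot).
#' @export
apply_batch <- function(batch, prob = 0.3) {
  stopifnot(prob >= 0, prob <= 1)
  n <- length(batch)
  plans <- vector("list", n)
  if (n < 2) {
    if (prob > 0 && n == 1)
      warning("CutMix skipped: batch of one has no mixing partner")
    return(list(batch = batch, plans = plans))
  }
  out <- batch
  for (i in seq_len(n)) {
    if (runif(1) < prob) {
      j <- sample(seq_len(n)[-i], 1)
      mx <- mix(batch[[i]], batch[[j]])
      out[[i]] <- mx$image
      plans[[i]] <- mx$plan
    }
  }
  list(batch = out, plans = plans)
}

#' Dump a mixed image and its plan for inspection
#'
#' @param mixed result of [mix()].
#' @param path_prefix file prefix; writes `<prefix>.png` and
#'   `<prefix>.json`.
#' @return invisibly, the two paths.
#' @export
dump_mix <- function(mixed, path_prefix) {
  png_path <- paste0(path_prefix, ".png")
  json_path <- paste0(path_prefix, ".json")
  png::writePNG(mixed$image$pixels, png_path)
  p <- mixed$plan
  jsonlite::write_json(list(lambda_area = p$lambda_area, y_a = p$y_a,
                            y_b = p$y_b, y_tilde = p$y_tilde,
                            parents = p$parents),
                       json_path, auto_unbox = TRUE)
  invisible(c(png_path, json_path))
}
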