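# Severity grouping, manifest handling, patient-wise splitting, image
# loading and geometric augmentation.

#' Five-level severity group from PASI sub-scores
#'
#' The erythema and scaling sub-scores (0-4 each) are summed and banded:
#' healthy (0 points), mild (1-2), moderate (3-4), severe (5-6), very
#' severe (7-8).
#'
#' @param erythema,scaling integer sub-scores in 0..4 (vectorised).
#' @return integer group in 0..4.
#' @export
severity_group <- function(erythema, scaling) {
  if (any(erythema < 0 | erythema > 4 | scaling < 0 | scaling > 4) ||
      any(erythema != floor(erythema)) || any(scaling != floor(scaling)))
    stop("sub-scores must be integers in 0..4")
  total <- as.integer(erythema + scaling)
  as.integer(ifelse(total == 0L, 0L, pmin(4L, (total + 1L) %/% 2L)))
}

#' Read a dataset manifest
#'
#' @param path CSV with header
#'   `image_path,patient_id,erythema,scaling,group,split`.
#' @return data.frame manifest; group consistency is validated.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(m)
  m
}

#' Write a dataset manifest
#' @param manifest data.frame manifest.
#' @param path output CSV path.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_manifest <- function(m) {
  need <- c("image_path", "patient_id", "erythema", "scaling", "group", "split")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(m$image_path)) stop("manifest image paths must be unique")
  if (!all(m$group %in% 0:4)) stop("group must be in 0..4")
  if (!all(m$group == severity_group(m$erythema, m$scaling)))
    stop("group column inconsistent with erythema + scaling banding")
  if (!all(m$split %in% c("train", "test"))) stop("split must be train/test")
  leak <- intersect(m$patient_id[m$split == "train"],
                    m$patient_id[m$split == "test"])
  if (length(leak)) stop("patient(s) in both splits: ",
                         paste(head(leak, 3), collapse = ", "))
  invisible(m)
}

#' Patient-wise train/test split
#'
#' Shuffles patients and assigns whole patients to the test side until the
#' test row count reaches the target fraction, so the two sides partition
#' the rows with disjoint patient sets and the test fraction lands within
#' one patient's worth of images of the target.
#'
#' @param manifest data.frame with at least `patient_id`.
#' @param test_fraction target fraction of rows in the test side.
#' @param seed integer seed for the patient shuffle.
#' @return list with `train` and `test` data.frames.
#' @export
split_by_patient <- function(manifest, test_fraction = 0.2, seed = 1L) {
  stopifnot(nrow(manifest) > 0, test_fraction > 0, test_fraction < 1)
  patients <- unique(manifest$patient_id)
  if (length(patients) < 2)
    stop("patient-wise split impossible with a single patient")
  ord <- with_seed(derive_seed(seed, "patient_split"), sample(patients))
  target <- test_fraction * nrow(manifest)
  rows_of <- table(manifest$patient_id)
  test_ids <- character(0)
  got <- 0
  for (p in ord) {
    if (got >= target) break
    test_ids <- c(test_ids, p)
    got <- got + rows_of[[p]]
  }
  if (length(test_ids) == length(patients))
    test_ids <- test_ids[-length(test_ids)]
  is_test <- manifest$patient_id %in% test_ids
  list(train = manifest[!is_test, , drop = FALSE],
       test = manifest[is_test, , drop = FALSE])
}

# mirror-pad bilinear rotation about the image centre
rotate_image <- function(px, angle_deg) {
  d <- dim(px)
  H <- d[1]; W <- d[2]
  if (angle_deg == 0 || H == 1 || W == 1) return(px)
  th <- angle_deg * pi / 180
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  yy <- matrix(0:(H - 1), H, W) - cy
  xx <- matrix(0:(W - 1), H, W, byrow = TRUE) - cx
  sy <- cy + cos(th) * yy - sin(th) * xx
  sx <- cx + sin(th) * yy + cos(th) * xx
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  iy0 <- reflect_index(as.integer(y0), H) + 1L
  iy1 <- reflect_index(as.integer(y0) + 1L, H) + 1L
  ix0 <- reflect_index(as.integer(x0), W) + 1L
  ix1 <- reflect_index(as.integer(x0) + 1L, W) + 1L
  out <- px
  for (c in seq_len(d[3])) {
    pl <- px[, , c]
    out[, , c] <- (1 - fy) * ((1 - fx) * pl[cbind(c(iy0), c(ix0))] +
                              fx * pl[cbind(c(iy0), c(ix1))]) +
                  fy * ((1 - fx) * pl[cbind(c(iy1), c(ix0))] +
                        fx * pl[cbind(c(iy1), c(ix1))])
  }
  out
}

#' Geometric augmentation: bounded rotation and random flips
#'
#' Rotation angle drawn uniformly from `[-max_rotation, +max_rotation]`
#' degrees (bilinear, reflection padding so no dark corners appear), then
#' independent vertical and horizontal flips each with probability
#' `flip_prob`. Labels are untouched. Uses the current RNG stream; seed
#' the caller for reproducibility.
#'
#' @param img a `labeled_image` or an `H x W x 3` array.
#' @param max_rotation degrees (default 15).
#' @param flip_prob per-axis flip probability (default 0.5).
#' @return augmented object of the same type and shape.
#' @export
geometric_augment <- function(img, max_rotation = 15, flip_prob = 0.5) {
  px <- if (inherits(img, "labeled_image")) img$pixels else img
  angle <- runif(1, -max_rotation, max_rotation)
  px <- rotate_image(px, angle)
  if (runif(1) < flip_prob) px <- px[rev(seq_len(dim(px)[1])), , , drop = FALSE]
  if (runif(1) < flip_prob) px <- px[, rev(seq_len(dim(px)[2])), , drop = FALSE]
  if (inherits(img, "labeled_image")) {
    img$pixels <- px
    img
  } else px
}

#' Load a PNG and resize to a square side
#'
#' Pixels come back as floats in `[0, 1]`; grayscale is replicated to RGB
#' and an alpha channel is dropped; resizing is bilinear.
#'
#' @param path PNG file path.
#' @param size target side length (default 300).
#' @return array `size x size x 3`.
#' @export
load_and_resize <- function(path, size = 300L) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), c(dim(px), 3L))
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]
  if (dim(px)[3] == 2L) px <- array(rep(px[, , 1], 3), c(dim(px)[1:2], 3L))
  out <- resize_bilinear(px, size, size)
  pmin(pmax(out, 0), 1)
}

#' Per-channel standardization for pretrained backbones
#'
#' @param x image array `H x W x 3 (x N)` in `[0, 1]`.
#' @param mean,std per-channel statistics (ImageNet defaults).
#' @return standardized array.
#' @export
normalize_channels <- function(x, mean = c(0.485, 0.456, 0.406),
                               std = c(0.229, 0.224, 0.225)) {
  single <- length(dim(x)) == 3L
  x <- as_batch(x)
  for (c in 1:3) x[, , c, ] <- (x[, , c, ] - mean[c]) / std[c]
  if (single) dim(x) <- dim(x)[1:3]
  x
}

#' Construct a labeled image
#'
#' @param pixels `H x W x 3` array in `[0, 1]`.
#' @param erythema,scaling integer sub-scores 0..4.
#' @param patient_id opaque identifier.
#' @return object of class `labeled_image`; `$group` is derived.
#' @export
labeled_image <- function(pixels, erythema, scaling, patient_id = "anon") {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L,
            all(is.finite(pixels)))
  structure(list(pixels = pixels, erythema = as.integer(erythema),
                 scaling = as.integer(scaling),
                 group = severity_group(erythema, scaling),
                 patient_id = patient_id),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<labeled_image %dx%d group=%d (erythema=%d scaling=%d) patient=%s>\n",
              d[1], d[2], x$group, x$erythema, x$scaling, x$patient_id))
  invisible(x)
}
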