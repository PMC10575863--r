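# Severity-graded synthetic lesion-image generator.
#
# Emulates the appearance regime of local psoriasis photographs at five
# severity levels: a flat skin-tone background with low-amplitude
# correlated noise; for the non-healthy groups a blob-shaped lesion built
# from 1-4 jittered ellipses; redness excess inside the lesion growing
# linearly with the erythema sub-score; small bright speckles whose
# within-lesion density grows linearly with the scaling sub-score; and
# additive Gaussian sensor noise. Every image is a pure function of its
# recipe seed, so datasets regenerate bit-identically. The two sub-scores,
# not lesion area, carry the severity signal: the lesion area fraction is
# drawn from a band that is deliberately independent of the group.

GEN <- list(
  area_range = c(0.20, 0.22),      # lesion area fraction band (all groups)
  # erythema: mild red gain (kept clear of the 8-bit ceiling) plus a
  # stronger green/blue suppression, so the red-channel excess grows
  # linearly with the sub-score without clipping
  red_base = 0.02, red_per_e = 0.050,
  green_base = 0.01, green_per_e = 0.100,
  blue_base = 0.005, blue_per_e = 0.085,
  speckle_frac_per_s = 0.12,       # within-lesion speckle pixel fraction / score
  speckle_col = c(0.93, 0.92, 0.88),
  noise_sd = 0.015, bg_noise = 0.015,
  skin_tone = c(0.78, 0.62, 0.52),
  # patient-to-patient tone variation is mostly brightness (shared across
  # channels) with only a small hue component
  tone_brightness_jitter = 0.06, tone_hue_jitter = 0.01
)

# valid (erythema, scaling) pairs for a severity group
score_pairs <- function(group) {
  g <- expand.grid(e = 0:4, s = 0:4)
  g[severity_group(g$e, g$s) == group, , drop = FALSE]
}

# erythema and scaling are strongly correlated in practice: a heavily
# erythematous plaque usually also scales heavily, so balanced pairs are
# far more common than extreme ones
sample_scores <- function(group, corr = 4) {
  p <- score_pairs(group)
  w <- exp(-corr * abs(p$e - p$s))
  p[sample(nrow(p), 1L, prob = w), ]
}

#' Construct a lesion image recipe
#'
#' @param group severity group 0..4.
#' @param erythema,scaling sub-scores 0..4; when `NULL` they are drawn
#'   (seeded) uniformly from the pairs consistent with `group`.
#' @param patient_id opaque id; also fixes the patient's base skin tone.
#' @param seed integer seed; the rendered image is deterministic in it.
#' @param size side length in pixels (default 300, minimum 32).
#' @param hair add dark hair-like strokes (off by default).
#' @return object of class `lesion_recipe`.
#' @export
lesion_recipe <- function(group, erythema = NULL, scaling = NULL,
                          patient_id = "P000", seed = 1L, size = 300L,
                          hair = FALSE) {
  if (!(length(group) == 1 && group %in% 0:4))
    stop("group must be a single integer in 0..4")
  if (size < 32) stop("size must be at least 32 pixels")
  if (is.null(erythema) || is.null(scaling)) {
    es <- with_seed(derive_seed(seed, "scores"), sample_scores(group))
    erythema <- es$e; scaling <- es$s
  }
  if (severity_group(erythema, scaling) != group)
    stop("scores (", erythema, ",", scaling, ") do not band to group ", group)
  structure(list(group = as.integer(group), erythema = as.integer(erythema),
                 scaling = as.integer(scaling), patient_id = patient_id,
                 seed = as.integer(seed), size = as.integer(size),
                 hair = isTRUE(hair)),
            class = "lesion_recipe")
}

# smooth correlated noise: coarse white noise upsampled bilinearly
smooth_noise <- function(size, coarse = 8L) {
  n <- max(2L, size %/% coarse)
  g <- matrix(rnorm(n * n), n, n)
  A <- resize_matrix(n, size)
  A %*% g %*% t(A)
}

# union of jittered ellipses as a feathered alpha mask in [0,1]
lesion_alpha <- function(size) {
  n_ell <- sample(1:2, 1)
  target <- runif(1, GEN$area_range[1], GEN$area_range[2]) * size^2
  per <- target / n_ell
  yy <- matrix(0:(size - 1), size, size)
  xx <- matrix(0:(size - 1), size, size, byrow = TRUE)
  alpha <- matrix(0, size, size)
  for (i in seq_len(n_ell)) {
    ecc <- runif(1, 0.7, 1)                      # axis ratio
    a <- sqrt(per / (pi * ecc)); b <- a * ecc    # pixel semi-axes
    th <- runif(1, 0, pi)
    cy <- runif(1, 0.3, 0.7) * size; cx <- runif(1, 0.3, 0.7) * size
    u <- (cos(th) * (yy - cy) + sin(th) * (xx - cx)) / a
    v <- (-sin(th) * (yy - cy) + cos(th) * (xx - cx)) / b
    rad <- sqrt(u^2 + v^2)
    ang <- atan2(v, u)
    edge <- rep(1, length(ang))
    for (h in 2:5) edge <- edge + runif(1, -0.04, 0.04) * cos(h * ang + runif(1, 0, 2 * pi))
    feather <- (matrix(edge, size, size) - rad) / 0.12
    alpha <- pmax(alpha, pmin(pmax(feather, 0), 1))
  }
  alpha
}

#' Render a synthetic lesion image from a recipe
#'
#' Deterministic in `recipe$seed`. Group 0 contains no lesion pixels; for
#' groups 1-4 the within-lesion red-channel excess grows with the erythema
#' score and the bright-speckle density with the scaling score.
#'
#' @param recipe a [lesion_recipe()].
#' @return a [labeled_image()]; attributes `lesion_mask` and
#'   `speckle_mask` (logical matrices) expose the generator's geometry.
#' @export
generate_image <- function(recipe) {
  stopifnot(inherits(recipe, "lesion_recipe"))
  S <- recipe$size
  tone <- with_seed(derive_seed(1L, paste0("tone:", recipe$patient_id)),
    GEN$skin_tone +
      runif(1, -GEN$tone_brightness_jitter, GEN$tone_brightness_jitter) +
      runif(3, -GEN$tone_hue_jitter, GEN$tone_hue_jitter))
  with_seed(derive_seed(recipe$seed, "render"), {
    px <- array(0, c(S, S, 3L))
    bg <- smooth_noise(S)
    for (c in 1:3) px[, , c] <- tone[c] + GEN$bg_noise * bg
    if (recipe$hair) {
      for (k in 1:3) {
        y0 <- runif(1, 0, S); sl <- tan(runif(1, -1, 1))
        xs <- seq_len(S)
        ys <- round(y0 + sl * xs)
        ok <- ys >= 1 & ys <= S
        for (c in 1:3) px[cbind(ys[ok], xs[ok], c)] <-
            px[cbind(ys[ok], xs[ok], c)] * 0.55
      }
    }
    lesion <- matrix(FALSE, S, S)
    speckle <- matrix(FALSE, S, S)
    if (recipe$group > 0) {
      alpha <- lesion_alpha(S)
      lesion <- alpha > 0.5
      e <- recipe$erythema
      px[, , 1] <- px[, , 1] + alpha * (GEN$red_base + GEN$red_per_e * e)
      px[, , 2] <- px[, , 2] - alpha * (GEN$green_base + GEN$green_per_e * e)
      px[, , 3] <- px[, , 3] - alpha * (GEN$blue_base + GEN$blue_per_e * e)
      s <- recipe$scaling
      if (s > 0 && any(lesion)) {
        # paint small bright discs until the within-lesion speckle pixel
        # fraction reaches its score-proportional target
        r_spk <- max(1L, round(S / 100))
        n_px <- sum(lesion)
        target <- round(GEN$speckle_frac_per_s * s * n_px)
        idx <- which(lesion)
        it <- 0L
        while (sum(speckle) < target && it < 20L * target) {
          it <- it + 1L
          centre <- idx[sample.int(length(idx), 1L)]
          cy <- (centre - 1L) %% S
          cx <- (centre - 1L) %/% S
          ys <- max(0L, cy - r_spk):min(S - 1L, cy + r_spk)
          xs <- max(0L, cx - r_spk):min(S - 1L, cx + r_spk)
          sub <- expand.grid(y = ys, x = xs)
          d2 <- (sub$y - cy)^2 + (sub$x - cx)^2
          sub <- sub[d2 <= r_spk^2, , drop = FALSE]
          speckle[cbind(sub$y + 1L, sub$x + 1L)] <- TRUE
        }
        w <- 0.9 * speckle
        for (c in 1:3) px[, , c] <- (1 - w) * px[, , c] + w * GEN$speckle_col[c]
      }
    }
    px <- px + array(rnorm(S * S * 3, sd = GEN$noise_sd), c(S, S, 3L))
    px <- pmin(pmax(px, 0), 1)
    img <- labeled_image(px, recipe$erythema, recipe$scaling,
                         recipe$patient_id)
    attr(img, "lesion_mask") <- lesion
    attr(img, "speckle_mask") <- speckle
    img
  })
}

# partition a class count into per-patient image counts in 2..8,
# guaranteeing at least two patients per class
patient_sizes <- function(count) {
  if (count < 4) return(c(count - count %/% 2, count %/% 2))
  sizes <- integer(0)
  rem <- count
  while (rem > 0) {
    if (rem <= 8 && length(sizes) == 0) {        # force >= 2 patients
      k <- rem %/% 2
    } else if (rem <= 9) {
      k <- if (rem <= 8) rem else 5L
    } else {
      k <- sample(2:8, 1)
    }
    if (rem - k == 1) k <- if (k < 8) k + 1L else k - 1L
    sizes <- c(sizes, k)
    rem <- rem - k
  }
  sizes
}

#' Assemble a synthetic manifest with given per-class counts
#'
#' Each synthetic patient contributes 2-8 images of one severity group
#' and one base skin tone; patient ids never cross splits, and every
#' class in every split is covered by at least two patients.
#'
#' @param train_counts,test_counts integer vectors, images per group 0..4.
#' @param seed integer seed.
#' @param dir prefix recorded in `image_path` entries.
#' @return data.frame manifest (schema
#'   `image_path,patient_id,erythema,scaling,group,split`).
#' @export
build_synthetic_manifest <- function(train_counts, test_counts, seed = 1L,
                                     dir = ".") {
  stopifnot(length(train_counts) == 5, length(test_counts) == 5)
  rows <- list()
  pat_n <- 0L
  with_seed(derive_seed(seed, "manifest"), {
    for (split in c("train", "test")) {
      counts <- if (split == "train") train_counts else test_counts
      for (g in 0:4) {
        if (counts[g + 1] == 0) next
        for (np in patient_sizes(counts[g + 1])) {
          pat_n <- pat_n + 1L
          pid <- sprintf("SP%03d", pat_n)
          for (i in seq_len(np)) {
            es <- sample_scores(g)
            rows[[length(rows) + 1L]] <- data.frame(
              image_path = file.path(split,
                                     sprintf("g%d_%s_%02d.png", g, pid, i)),
              patient_id = pid, erythema = es$e, scaling = es$s,
              group = g, split = split, stringsAsFactors = FALSE)
          }
        }
      }
    }
  })
  m <- do.call(rbind, rows)
  rownames(m) <- NULL
  m$image_path <- file.path(dir, m$image_path)
  m$seed <- vapply(m$image_path, function(p) derive_seed(seed, p), 0L,
                   USE.NAMES = FALSE)
  validate_manifest(m)
  m
}

#' Render every manifest row to an 8-bit RGB PNG
#'
#' @param manifest data.frame from [build_synthetic_manifest()] (its
#'   `seed` column fixes each image).
#' @param size side length of the rendered images.
#' @return invisibly, the vector of written file paths.
#' @export
render_dataset <- function(manifest, size = 300L) {
  if (anyDuplicated(manifest$image_path))
    stop("manifest image paths collide")
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    dir.create(dirname(r$image_path), recursive = TRUE, showWarnings = FALSE)
    img <- generate_image(lesion_recipe(r$group, r$erythema, r$scaling,
                                        r$patient_id, r$seed, size))
    png::writePNG(img$pixels, r$image_path)
  }
  invisible(manifest$image_path)
}

#' Default-count synthetic dataset on disk
#'
#' Builds the study-sized manifest — 640 training images with class counts
#' 41/141/186/206/66 and 152 test images with 16/20/45/52/19 — renders the
#' PNGs under `out_dir` and writes `manifest.csv` beside them.
#'
#' @param out_dir writable output directory.
#' @param seed integer seed.
#' @param size rendered side length (default 300).
#' @param render set `FALSE` to write only the manifest.
#' @return the manifest data.frame, invisibly.
#' @export
build_default_manifest <- function(out_dir, seed = 1L, size = 300L,
                                   render = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0) stop("directory not writable: ", out_dir)
  m <- build_synthetic_manifest(default_train_counts(), default_test_counts(),
                                seed = seed, dir = out_dir)
  if (render) render_dataset(m, size)
  write_manifest(m[setdiff(names(m), "seed")],
                 file.path(out_dir, "manifest.csv"))
  invisible(m)
}

#' @rdname build_default_manifest
#' @export
default_train_counts <- function() c(41L, 141L, 186L, 206L, 66L)

#' @rdname build_default_manifest
#' @export
default_test_counts <- function() c(16L, 20L, 45L, 52L, 19L)

#' In-memory synthetic image set
#'
#' Generates the manifest and images without touching disk — the form the
#' trainer consumes directly.
#'
#' @inheritParams build_synthetic_manifest
#' @param size side length in pixels.
#' @return list with `manifest` and `images` (list of [labeled_image()]
#'   in manifest row order).
#' @export
generate_lesion_set <- function(train_counts, test_counts, seed = 1L,
                                size = 96L) {
  m <- build_synthetic_manifest(train_counts, test_counts, seed = seed)
  imgs <- lapply(seq_len(nrow(m)), function(i) {
    r <- m[i, ]
    generate_image(lesion_recipe(r$group, r$erythema, r$scaling,
                                 r$patient_id, r$seed, size))
  })
  list(manifest = m, images = imgs)
}
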