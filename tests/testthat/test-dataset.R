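test_that("severity grouping reproduces the printed score bands", {
  # exhaustive over all 25 sub-score pairs
  grid <- expand.grid(e = 0:4, s = 0:4)
  g <- severity_group(grid$e, grid$s)
  total <- grid$e + grid$s
  band <- ifelse(total == 0, 0,
          ifelse(total <= 2, 1,
          ifelse(total <= 4, 2,
          ifelse(total <= 6, 3, 4))))
  expect_identical(as.integer(g), as.integer(band))
  # monotone in the score sum
  expect_true(all(diff(g[order(total)]) >= 0))
  expect_error(severity_group(5, 0), "0..4")
  expect_error(severity_group(-1, 2), "0..4")
})

test_that("patient-wise split partitions rows with disjoint patients", {
  man <- data.frame(
    image_path = sprintf("img%03d.png", 1:100),
    patient_id = rep(sprintf("P%02d", 1:10), each = 10),
    erythema = 1L, scaling = 1L, group = 1L, split = "train",
    stringsAsFactors = FALSE)
  # 10 patients x 10 images at fraction 0.3: always exactly 3 test patients
  for (seed in 1:100) {
    sp <- split_by_patient(man, 0.3, seed)
    expect_identical(nrow(sp$train) + nrow(sp$test), 100L)
    expect_length(intersect(sp$train$patient_id, sp$test$patient_id), 0)
    expect_identical(length(unique(sp$test$patient_id)), 3L)
  }
  # two patients at 0.5: one per side
  man2 <- man[man$patient_id %in% c("P01", "P02"), ]
  sp2 <- split_by_patient(man2, 0.5, 1)
  expect_identical(length(unique(sp2$test$patient_id)), 1L)
  expect_error(split_by_patient(man[man$patient_id == "P01", ], 0.5, 1),
               "single patient")
})

test_that("geometric augmentation preserves labels, shape and energy", {
  img <- generate_image(lesion_recipe(2, seed = 3, size = 64))
  with_seed(11, {
    out <- geometric_augment(img)
    expect_s3_class(out, "labeled_image")
    expect_identical(out$group, img$group)
    expect_identical(dim(out$pixels), dim(img$pixels))
  })
  # identity path: zero rotation, no flips
  expect_identical(sevgrade:::rotate_image(img$pixels, 0), img$pixels)
  # a double horizontal flip is the identity
  flip_h <- function(px) px[, rev(seq_len(dim(px)[2])), , drop = FALSE]
  expect_identical(flip_h(flip_h(img$pixels)), img$pixels)
  # rotation by reflection padding keeps mean energy (no injected black)
  rot <- sevgrade:::rotate_image(img$pixels, 15)
  expect_lt(abs(mean(rot) - mean(img$pixels)), 0.02)
})

test_that("flip rate matches its nominal probability", {
  px <- array(runif(4 * 4 * 3), c(4, 4, 3))
  flipped <- with_seed(21, vapply(1:4000, function(i) {
    out <- geometric_augment(px, max_rotation = 0, flip_prob = 0.5)
    # vertical flip detectable on an asymmetric image
    !identical(out[1, 1, 1], px[1, 1, 1]) ||
      !identical(out[4, 4, 1], px[4, 4, 1])
  }, logical(1)))
  # two independent flips at 0.5: P(changed) = 3/4; 3 sigma binomial band
  expect_lt(abs(mean(flipped) - 0.75), 3 * sqrt(0.75 * 0.25 / 4000))
})

test_that("PNG loading resizes, converts and preserves values", {
  dir <- withr::local_tempdir()
  big <- file.path(dir, "big.png")
  png::writePNG(array(runif(64 * 64 * 3), c(64, 64, 3)), big)
  out <- load_and_resize(big, 32)
  expect_identical(dim(out), c(32L, 32L, 3L))
  expect_true(all(out >= 0 & out <= 1))
  # no-op resize keeps 8-bit values exactly
  px <- array(round(runif(16 * 16 * 3) * 255) / 255, c(16, 16, 3))
  same <- file.path(dir, "same.png")
  png::writePNG(px, same)
  expect_equal(load_and_resize(same, 16), px, tolerance = 1 / 255)
  # constant image stays constant at any size (interpolation of a constant)
  cst <- file.path(dir, "cst.png")
  png::writePNG(array(0.5, c(20, 20, 3)), cst)
  out2 <- load_and_resize(cst, 33)
  expect_lt(diff(range(out2)), 1e-6)
  # grayscale converted to RGB
  gry <- file.path(dir, "gray.png")
  png::writePNG(matrix(runif(100), 10, 10), gry)
  expect_identical(dim(load_and_resize(gry, 10))[3], 3L)
  expect_error(load_and_resize(file.path(dir, "absent.png"), 32), "cannot read")
})

test_that("manifest validation rejects leaks and inconsistencies", {
  m <- data.frame(image_path = c("a.png", "b.png"),
                  patient_id = c("P1", "P1"),
                  erythema = c(1L, 2L), scaling = c(1L, 2L),
                  group = c(1L, 2L), split = c("train", "test"),
                  stringsAsFactors = FALSE)
  expect_error(sevgrade:::validate_manifest(m), "both splits")
  m$patient_id <- c("P1", "P2")
  expect_silent(sevgrade:::validate_manifest(m))
  m$group <- c(2L, 2L)
  expect_error(sevgrade:::validate_manifest(m), "inconsistent")
})
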