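test_that("heatmaps are non-negative and sized to the target layer", {
  net <- severity_net(build_tiny_backbone(51), use_msdam = TRUE, seed = 51)
  net$head$fc$W[] <- with_seed(52, rnorm(length(net$head$fc$W)) * 0.3)
  img <- generate_image(lesion_recipe(3, seed = 53, size = 64))
  heat <- grad_cam(net, img, 3, layer = "fused")
  expect_true(all(heat$grid >= 0))
  expect_identical(dim(heat$grid), dim(net$fused)[1:2])
  expect_identical(dim(heat$overlay), dim(img$pixels)[1:2])
  # per-stage layers expose their native resolutions
  h1 <- grad_cam(net, img, 3, layer = "stage1")
  expect_identical(dim(h1$grid), c(8L, 8L))
  expect_error(grad_cam(net, img, 3, layer = "stage9"), "layer")
})

test_that("a zero-weight head yields an identically zero heatmap", {
  net <- severity_net(build_tiny_backbone(54), use_msdam = FALSE, seed = 54)
  net$head$fc$W[] <- 0
  img <- generate_image(lesion_recipe(2, seed = 55, size = 64))
  heat <- grad_cam(net, img, 2)
  expect_identical(max(abs(heat$grid)), 0)
})

test_that("heatmaps ignore constant shifts of other classes' logits", {
  net <- severity_net(build_tiny_backbone(56), use_msdam = FALSE, seed = 56)
  net$head$fc$W[] <- with_seed(57, rnorm(length(net$head$fc$W)) * 0.3)
  img <- generate_image(lesion_recipe(4, seed = 58, size = 64))
  h1 <- grad_cam(net, img, 4)
  # shifting the other classes' rows cannot change d(logit_4)/dA
  net$head$fc$W[1:4, ] <- net$head$fc$W[1:4, ] + 0.7
  h2 <- grad_cam(net, img, 4)
  expect_equal(h1$grid, h2$grid, tolerance = 1e-12)
})

test_that("a linear GAP head reproduces the closed-form heatmap", {
  # logit = sum_k w_k GAP(A^k): alpha_k = w_k / Z, L = ReLU(sum alpha_k A_k)
  net <- severity_net(build_tiny_backbone(59), use_msdam = FALSE, seed = 59)
  # make the head a pure linear readout of the fused map
  net$head$norm$param_names <- character()
  net$head$norm$run_mean[] <- 0
  net$head$norm$run_var[] <- 1 - net$head$norm$eps
  W <- with_seed(60, matrix(rnorm(5 * 112) * 0.2, 5, 112))
  net$head$fc$W[] <- W
  img <- generate_image(lesion_recipe(1, seed = 61, size = 64))
  heat <- grad_cam(net, img, 2)
  A <- net$fused[, , , 1]
  Z <- dim(A)[1] * dim(A)[2]
  want <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_len(dim(A)[3])) want <- want + (W[3, k] / Z) * A[, , k]
  expect_equal(heat$grid, pmax(want, 0), tolerance = 1e-9)
})

test_that("the localization score reads the higher-severity region", {
  M <- matrix(1, 10, 10); M[3:6, 3:6] <- 0
  plan <- structure(list(M = M, lambda_area = mean(M), y_a = 1L, y_b = 3L,
                         y_tilde = 3L, parents = c("a", "b")),
                    class = "mix_plan")
  mk_heat <- function(h) structure(list(grid = h, overlay = h,
                                        target_class = 3L, layer = "fused"),
                                   class = "gradcam_heatmap")
  # uniform heat: ratio of equal means
  expect_equal(patch_localization_score(mk_heat(matrix(1, 10, 10)), plan), 1)
  # heat entirely inside the patch region (y_b higher: region is M == 0)
  inside <- matrix(0, 10, 10); inside[4:5, 4:5] <- 2
  expect_identical(patch_localization_score(mk_heat(inside), plan), Inf)
  # concentrated outside: score below 1
  outside <- matrix(1, 10, 10); outside[3:6, 3:6] <- 0
  expect_lt(patch_localization_score(mk_heat(outside), plan), 1)
  # ties and degenerate masks are flagged
  tie <- plan; tie$y_a <- 3L
  expect_warning(s <- patch_localization_score(mk_heat(inside), tie), "tied")
  expect_true(is.na(s))
  degen <- plan; degen$M <- matrix(1, 10, 10)
  expect_warning(s2 <- patch_localization_score(mk_heat(inside), degen),
                 "degenerate")
  expect_true(is.na(s2))
})

test_that("overlays are written as valid PNGs", {
  net <- severity_net(build_tiny_backbone(62), use_msdam = FALSE, seed = 62)
  net$head$fc$W[] <- with_seed(63, rnorm(length(net$head$fc$W)) * 0.2)
  img <- generate_image(lesion_recipe(2, seed = 64, size = 64))
  heat <- grad_cam(net, img, 2)
  path <- withr::local_tempfile(fileext = ".png")
  write_gradcam_overlay(heat, img, path)
  px <- png::readPNG(path)
  expect_identical(dim(px)[1:2], c(64L, 64L))
})
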