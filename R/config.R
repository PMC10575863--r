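# Run configuration: YAML with schema validation, a single global seed
# fanned out to per-module streams (see derive_seed), and the thin
# command functions the exec/sevgrade script dispatches to.

default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "sevgrade_out",
    dataset = list(image_size = 300L, rotation_degrees = 15,
                   flip_prob = 0.5, test_fraction = 0.2),
    cutmix = list(enabled = TRUE, prob = 0.3),
    msdam = list(kernels = c(3L, 5L, 7L), width_ratio = 0.25, dropout = 0.2),
    backbone = list(variant = "tiny"),
    training = list(epochs = 50L, batch_size = 16L, lr_floor = 1e-6,
                    lr_cap = 2e-3, warmup = 5L, patience = 15L, gamma = 1)
  )
}

merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base))
      stop("unknown config key: ", here, call. = FALSE)
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], here)
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Load and validate a run configuration
#'
#' Unknown keys are rejected; omitted keys take their defaults.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return validated nested configuration list.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  stopifnot(cfg$cutmix$prob >= 0, cfg$cutmix$prob <= 1,
            cfg$training$lr_floor < cfg$training$lr_cap)
  cfg
}

run_log <- function(...) {
  cat(sprintf("[%s] ", format(Sys.time(), "%H:%M:%S")), sprintf(...), "\n",
      sep = "")
}

#' Generate the synthetic dataset from a run configuration
#'
#' @param cfg configuration from [load_run_config()].
#' @param counts optional `list(train=, test=)` per-class counts
#'   overriding the study defaults.
#' @param force overwrite a non-empty output directory.
#' @return the manifest, invisibly.
#' @export
cmd_generate_data <- function(cfg = load_run_config(), counts = NULL,
                              force = FALSE) {
  out <- file.path(cfg$out_dir, "data")
  if (dir.exists(out) && length(dir(out)) > 0 && !force)
    stop("output directory ", out, " is not empty (use force)")
  tr <- counts$train %||% default_train_counts()
  te <- counts$test %||% default_test_counts()
  m <- build_synthetic_manifest(tr, te, seed = cfg$seed, dir = out)
  render_dataset(m, cfg$dataset$image_size)
  write_manifest(m[setdiff(names(m), "seed")], file.path(out, "manifest.csv"))
  run_log("wrote %d train + %d test images to %s",
          sum(m$split == "train"), sum(m$split == "test"), out)
  print(table(group = m$group, split = m$split))
  invisible(m)
}

load_split_images <- function(manifest_path, split, size) {
  m <- read_manifest(manifest_path)
  m <- m[m$split == split, , drop = FALSE]
  if (!nrow(m)) stop("no '", split, "' rows in ", manifest_path)
  root <- dirname(manifest_path)
  imgs <- lapply(seq_len(nrow(m)), function(i) {
    p <- m$image_path[i]
    if (!file.exists(p)) p <- file.path(root, m$image_path[i])
    px <- load_and_resize(p, size)
    labeled_image(px, m$erythema[i], m$scaling[i], m$patient_id[i])
  })
  list(manifest = m, images = imgs)
}

#' Train a model from a rendered dataset
#'
#' Loads the train split of a manifest, carves a patient-wise validation
#' fold, trains the configured model and writes a JSON checkpoint plus
#' the training history.
#'
#' @param cfg configuration from [load_run_config()].
#' @param manifest_path path to a `manifest.csv` (defaults to the
#'   location [cmd_generate_data()] writes).
#' @return list with the trained net, history and checkpoint path.
#' @export
cmd_train <- function(cfg = load_run_config(),
                      manifest_path = file.path(cfg$out_dir, "data",
                                                "manifest.csv")) {
  ds <- load_split_images(manifest_path, "train", cfg$dataset$image_size)
  folds <- carve_validation(ds$manifest, ds$images,
                            cfg$dataset$test_fraction,
                            derive_seed(cfg$seed, "val_fold"))
  net <- severity_net(build_tiny_backbone(derive_seed(cfg$seed, "net")),
                      use_msdam = TRUE, kernels = cfg$msdam$kernels,
                      width_ratio = cfg$msdam$width_ratio,
                      dropout = cfg$msdam$dropout,
                      seed = derive_seed(cfg$seed, "net"))
  tc <- train_config(epochs = cfg$training$epochs,
                     batch_size = cfg$training$batch_size,
                     lr_floor = cfg$training$lr_floor,
                     lr_cap = cfg$training$lr_cap,
                     warmup = cfg$training$warmup,
                     patience = cfg$training$patience,
                     gamma = cfg$training$gamma,
                     cutmix_prob = if (cfg$cutmix$enabled) cfg$cutmix$prob else 0,
                     seed = derive_seed(cfg$seed, "train"))
  run_log("training on %d images (val %d), seed %d",
          length(folds$train), length(folds$val), cfg$seed)
  fit <- train_model(net, folds$train, folds$val, tc)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  ckpt <- file.path(cfg$out_dir, "checkpoint.json")
  save_checkpoint(fit$net, ckpt)
  write.csv(fit$history, file.path(cfg$out_dir, "history.csv"),
            row.names = FALSE)
  run_log("checkpoint written to %s", ckpt)
  list(net = fit$net, history = fit$history, checkpoint = ckpt)
}

#' Evaluate a checkpoint on a manifest split
#'
#' @param cfg configuration from [load_run_config()].
#' @param checkpoint JSON checkpoint from [cmd_train()].
#' @param manifest_path manifest whose `test` split is evaluated.
#' @param out optional JSON report path.
#' @return the [metrics_report()].
#' @export
cmd_evaluate <- function(cfg = load_run_config(),
                         checkpoint = file.path(cfg$out_dir, "checkpoint.json"),
                         manifest_path = file.path(cfg$out_dir, "data",
                                                   "manifest.csv"),
                         out = NULL) {
  ds <- load_split_images(manifest_path, "test", cfg$dataset$image_size)
  net <- severity_net(build_tiny_backbone(derive_seed(cfg$seed, "net")),
                      use_msdam = TRUE, kernels = cfg$msdam$kernels,
                      width_ratio = cfg$msdam$width_ratio,
                      dropout = cfg$msdam$dropout,
                      seed = derive_seed(cfg$seed, "net"))
  load_checkpoint(net, checkpoint)
  rep <- evaluate_model(net, ds$images)
  if (!is.null(out))
    jsonlite::write_json(list(
      accuracy = rep$accuracy, macro_precision = rep$macro_precision,
      macro_recall = rep$macro_recall, macro_f1 = rep$macro_f1,
      confusion = rep$confusion), out, auto_unbox = TRUE, digits = NA)
  rep
}

#' Render a Grad-CAM overlay for one image
#'
#' @param cfg configuration from [load_run_config()].
#' @param checkpoint JSON checkpoint from [cmd_train()].
#' @param image_path input PNG.
#' @param target_class class index 0..4.
#' @param layer heatmap layer (see [grad_cam()]).
#' @param out overlay PNG path; the raw heatmap goes to `<out>.json`.
#' @return the heatmap object, invisibly.
#' @export
cmd_gradcam <- function(cfg = load_run_config(), checkpoint, image_path,
                        target_class, layer = "fused",
                        out = "gradcam_overlay.png") {
  px <- load_and_resize(image_path, cfg$dataset$image_size)
  net <- severity_net(build_tiny_backbone(derive_seed(cfg$seed, "net")),
                      use_msdam = TRUE, kernels = cfg$msdam$kernels,
                      width_ratio = cfg$msdam$width_ratio,
                      dropout = cfg$msdam$dropout,
                      seed = derive_seed(cfg$seed, "net"))
  load_checkpoint(net, checkpoint)
  heat <- grad_cam(net, px, target_class, layer)
  write_gradcam_overlay(heat, px, out)
  jsonlite::write_json(list(layer = layer, target_class = target_class,
                            grid = heat$grid),
                       paste0(out, ".json"), digits = NA)
  run_log("overlay written to %s", out)
  invisible(heat)
}

#' Complexity audit for a named backbone variant
#'
#' @param variant a [supported_backbones()] name.
#' @param input_size audit input side (default 300).
#' @param with_msdam audit the MS-DAM-equipped model instead of the
#'   baseline (runnable variants only).
#' @return a [complexity_report()] (specification variants) or list.
#' @export
cmd_stats <- function(variant, input_size = 300L, with_msdam = FALSE) {
  if (variant == "tiny") {
    net <- severity_net(build_tiny_backbone(1L), use_msdam = with_msdam)
    return(complexity_report(net, input_size))
  }
  if (!variant %in% effnet_variants()$variant)
    stop("complexity audit supports EfficientNet variants and 'tiny'; ",
         "supported: ", paste(supported_backbones(), collapse = ", "))
  if (with_msdam)
    stop("the MS-DAM audit is available for the runnable 'tiny' variant")
  complexity_report(efficientnet_spec(variant), input_size)
}
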