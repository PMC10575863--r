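# Backbone adapters and model-complexity audits.
#
# Two kinds of backbone live here. build_tiny_backbone() is a small
# runnable CNN (stride-2 conv stages tapping strides 8/16/32 at channels
# 16/32/64) used for desk-scale training and tests. efficientnet_spec()
# constructs the EfficientNet family as architecture specification tables
# (layer-by-layer shapes following the compound-scaling construction:
# width/depth multipliers, channel rounding to multiples of 8, MBConv
# blocks with squeeze-excitation) from which trainable-parameter and MAC
# counts are computed exactly — no weights are involved, so the audits run
# offline. Counting conventions: trainable parameters only (batch-norm
# scale/shift included, running statistics excluded); MACs from the
# multiplies of convolution and dense layers only (no activations, no
# normalization); a deformable convolution contributes its main conv MACs
# plus its offset conv MACs, interpolation arithmetic excluded.

# ---- tiny runnable backbone -------------------------------------------

#' Build the tiny test backbone
#'
#' A five-conv CNN (stem + four stages, all stride 2, each
#' conv/batch-norm/ReLU) exposing stage outputs at strides 8/16/32 with
#' 16/32/64 channels. The stride-8 tap reserves its last three channels
#' for a bilinearly pooled, batch-normalized copy of the input image (an
#' input skip path), so low-level color statistics reach the attention
#' and fusion stages without passing through the deep filter stack. Under 100k parameters,
#' deterministic in its seed.
#'
#' @param seed integer seed for weight initialisation.
#' @return backbone module usable with [severity_net()].
#' @export
build_tiny_backbone <- function(seed = 1L) {
  self <- new_module("tiny_backbone")
  widths <- c(8L, 16L, 13L, 32L, 64L)   # stage 3 tops up to 16 with the skip
  with_seed(derive_seed(seed, "tiny_backbone"), {
    cin <- 3L
    for (i in seq_along(widths)) {
      cin_i <- if (i == 4L) 16L else cin
      self[[paste0("c", i)]] <- layer_conv2d(cin_i, widths[i], 3L, stride = 2L)
      self[[paste0("n", i)]] <- layer_bn(widths[i])
      self[[paste0("r", i)]] <- layer_relu()
      cin <- widths[i]
    }
    self$skip_bn <- layer_bn(3L)
  })
  self$children <- c(unlist(lapply(seq_along(widths), function(i)
    list(self[[paste0("c", i)]], self[[paste0("n", i)]])), recursive = FALSE),
    list(self$skip_bn))
  self$stage_channels <- c(16L, 32L, 64L)
  self$stage_strides <- c(8L, 16L, 32L)
  self
}

#' @export
module_forward.tiny_backbone <- function(self, x, training = FALSE) {
  taps <- list()
  h <- x
  for (i in 1:5) {
    h <- module_forward(self[[paste0("c", i)]], h, training)
    h <- module_forward(self[[paste0("n", i)]], h, training)
    h <- module_forward(self[[paste0("r", i)]], h, training)
    if (i == 3L) {
      self$skip <- layer_resize(dim(h)[1], dim(h)[2])
      pooled <- module_forward(self$skip, x, training)
      h <- cat_channels(list(h, module_forward(self$skip_bn, pooled, training)))
      taps[[1L]] <- h
    }
    if (i >= 4L) taps[[i - 2L]] <- h
  }
  taps
}

# gy is a list of three tap gradients
#' @export
module_backward.tiny_backbone <- function(self, gy) {
  g <- gy[[3]]
  gskip <- NULL
  for (i in 5:1) {
    if (i == 3L) {
      parts <- split_channels(g, c(13L, 3L))
      gskip <- module_backward(self$skip,
                               module_backward(self$skip_bn, parts[[2]]))
      g <- parts[[1]]
    }
    g <- module_backward(self[[paste0("r", i)]], g)
    g <- module_backward(self[[paste0("n", i)]], g)
    g <- module_backward(self[[paste0("c", i)]], g)
    if (i >= 4L) g <- g + gy[[i - 3L]]
  }
  g + gskip
}

#' Stage feature maps of a backbone
#'
#' Runs a forward pass and returns the three hierarchical feature maps at
#' strides 8, 16 and 32 that feed the attention module.
#'
#' @param backbone a runnable backbone module.
#' @param x image batch `H x W x 3 (x N)` with side divisible by 32.
#' @return list of three feature maps, strictly decreasing spatial size.
#' @export
stage_outputs <- function(backbone, x) {
  stopifnot(inherits(backbone, "sg_module"))
  module_forward(backbone, as_batch(x))
}

# ---- EfficientNet architecture specification --------------------------

# channel rounding used by the compound-scaling construction
round_channels <- function(c, width, divisor = 8) {
  v <- c * width
  out <- max(divisor, floor(v + divisor / 2) %/% divisor * divisor)
  if (out < 0.9 * v) out <- out + divisor
  as.integer(out)
}

effnet_variants <- function() {
  data.frame(
    variant = c("efficientnet_b0", "efficientnet_b1", "efficientnet_b2",
                "efficientnet_b3", "efficientnet_b4", "efficientnet_b5"),
    width = c(1.0, 1.0, 1.1, 1.2, 1.4, 1.6),
    depth = c(1.0, 1.1, 1.2, 1.4, 1.8, 2.2),
    resolution = c(224L, 240L, 260L, 300L, 380L, 456L)
  )
}

regnety_taps <- function() {
  # stage widths (strides 4/8/16/32) of the RegNetY design space; taps are
  # the stride-8/16/32 stages. Provided for adapter completeness; the
  # complexity audit is specified for the EfficientNet family only.
  list(
    regnety_400mf = c(104L, 208L, 440L),
    regnety_600mf = c(112L, 256L, 608L),
    regnety_800mf = c(128L, 320L, 768L),
    regnety_1.6gf = c(120L, 336L, 888L),
    regnety_4.0gf = c(192L, 512L, 1088L),
    regnety_8.0gf = c(448L, 896L, 2016L)
  )
}

#' Supported backbone variant names
#' @return character vector of variant identifiers.
#' @export
supported_backbones <- function() {
  c(effnet_variants()$variant, names(regnety_taps()), "tiny")
}

# one spec row per parameterised layer
spec_row <- function(name, type, cin, cout, k = 1L, stride = 1L,
                     groups = 1L, bias = FALSE) {
  data.frame(name = name, type = type, cin = cin, cout = cout, k = k,
             stride = stride, groups = groups, bias = bias,
             stringsAsFactors = FALSE)
}

#' EfficientNet architecture specification table
#'
#' Reconstructs the layer table of an EfficientNet variant under compound
#' scaling: stem, MBConv stages (expansion, depthwise, squeeze-excitation,
#' projection, each followed by batch norm), 1x1 head convolution, global
#' pool and an `n_classes` dense classifier replacing the original
#' 1000-class head.
#'
#' @param variant one of `"efficientnet_b0"` ... `"efficientnet_b5"`.
#' @param n_classes classifier width (default 5 severity groups).
#' @return object of class `backbone_spec`: the layer table plus stage-tap
#'   metadata (channels at strides 8/16/32, pooled feature width).
#' @export
efficientnet_spec <- function(variant, n_classes = 5L) {
  vt <- effnet_variants()
  if (!variant %in% vt$variant)
    stop("unknown variant '", variant, "'; supported: ",
         paste(supported_backbones(), collapse = ", "))
  v <- vt[vt$variant == variant, ]
  base <- data.frame(
    expand = c(1L, 6L, 6L, 6L, 6L, 6L, 6L),
    k = c(3L, 3L, 5L, 3L, 5L, 5L, 3L),
    stride = c(1L, 2L, 2L, 2L, 1L, 2L, 1L),
    out = c(16L, 24L, 40L, 80L, 112L, 192L, 320L),
    reps = c(1L, 2L, 2L, 3L, 3L, 4L, 1L)
  )
  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- r
  c_stem <- round_channels(32, v$width)
  add(spec_row("stem", "conv", 3L, c_stem, 3L, 2L))
  add(spec_row("stem_bn", "bn", c_stem, c_stem))
  cin <- c_stem
  stride_now <- 2L
  taps <- integer(0)
  for (s in seq_len(nrow(base))) {
    cout <- round_channels(base$out[s], v$width)
    reps <- as.integer(ceiling(base$reps[s] * v$depth))
    for (rblk in seq_len(reps)) {
      bin <- if (rblk == 1L) cin else cout
      bstr <- if (rblk == 1L) base$stride[s] else 1L
      cexp <- if (base$expand[s] == 1L) bin
              else round_channels(bin * base$expand[s], 1.0)
      pre <- sprintf("s%d_b%d", s, rblk)
      if (base$expand[s] != 1L) {
        add(spec_row(paste0(pre, "_exp"), "conv", bin, cexp))
        add(spec_row(paste0(pre, "_exp_bn"), "bn", cexp, cexp))
      }
      add(spec_row(paste0(pre, "_dw"), "conv", cexp, cexp, base$k[s], bstr,
                   groups = cexp))
      add(spec_row(paste0(pre, "_dw_bn"), "bn", cexp, cexp))
      cse <- max(1L, bin %/% 4L)
      add(spec_row(paste0(pre, "_se_red"), "se_conv", cexp, cse, bias = TRUE))
      add(spec_row(paste0(pre, "_se_exp"), "se_conv", cse, cexp, bias = TRUE))
      add(spec_row(paste0(pre, "_proj"), "conv", cexp, cout))
      add(spec_row(paste0(pre, "_proj_bn"), "bn", cout, cout))
      if (rblk == 1L) stride_now <- stride_now * base$stride[s]
    }
    # record the last stage output seen at each tapped stride
    taps[as.character(stride_now)] <- cout
    cin <- cout
  }
  c_head <- round_channels(1280, v$width)
  add(spec_row("head", "conv", cin, c_head))
  add(spec_row("head_bn", "bn", c_head, c_head))
  add(spec_row("classifier", "dense", c_head, as.integer(n_classes),
               bias = TRUE))
  spec <- do.call(rbind, rows)
  structure(list(variant = variant, layers = spec,
                 stage_channels = unname(taps[c("8", "16", "32")]),
                 stage_strides = c(8L, 16L, 32L),
                 pooled_width = c_head,
                 resolution = v$resolution),
            class = "backbone_spec")
}

#' Stage-tap shapes of a specification backbone
#'
#' Shape inference for the three hierarchical taps: spatial size follows
#' ceiling division of the input side by the stage stride schedule.
#'
#' @param variant a supported variant name or a `backbone_spec`.
#' @param input_size input side length in pixels.
#' @return data.frame with stride, channels, height, width per tap.
#' @export
stage_shapes <- function(variant, input_size = 300L) {
  if (is.character(variant)) {
    if (variant %in% names(regnety_taps())) {
      ch <- regnety_taps()[[variant]]
    } else if (variant == "tiny") {
      ch <- c(16L, 32L, 64L)
    } else {
      ch <- efficientnet_spec(variant)$stage_channels
    }
  } else ch <- variant$stage_channels
  side <- input_size
  for (i in 1:3) side <- as.integer(ceiling(side / 2))  # stride 8
  s8 <- side; s16 <- as.integer(ceiling(s8 / 2)); s32 <- as.integer(ceiling(s16 / 2))
  data.frame(stride = c(8L, 16L, 32L), channels = ch,
             height = c(s8, s16, s32), width = c(s8, s16, s32))
}

spec_layer_params <- function(l) {
  p <- switch(l$type,
    conv = , se_conv = l$k^2 * l$cin * l$cout / l$groups,
    dense = l$cin * l$cout,
    bn = 2 * l$cout,
    0)
  if (isTRUE(l$bias)) p <- p + l$cout
  p
}

#' Trainable parameter count
#'
#' Counts trainable parameter elements: all convolution/dense weights and
#' biases plus batch-norm scale and shift; normalization running statistics
#' are excluded. Works on runnable modules and on specification tables.
#'
#' @param model a trainable module or a `backbone_spec`.
#' @return integer parameter count.
#' @export
count_params <- function(model) {
  if (inherits(model, "sg_module")) return(n_params(model))
  stopifnot(inherits(model, "backbone_spec"))
  L <- model$layers
  total <- 0
  for (i in seq_len(nrow(L))) total <- total + spec_layer_params(L[i, ])
  total
}

#' MAC count at a stated input size
#'
#' Multiply-accumulate operations of convolution and dense layers:
#' `H_out * W_out * C_out * k^2 * C_in / groups` per convolution and
#' `n_in * n_out` per dense layer. A deformable convolution contributes its
#' main convolution plus its offset convolution; interpolation arithmetic,
#' activations and normalization are excluded by convention. Runnable
#' modules are audited by a recorded shape-inference forward pass.
#'
#' @param model a trainable module or a `backbone_spec`.
#' @param input_size input side length in pixels.
#' @return numeric MAC count.
#' @export
count_macs <- function(model, input_size = 300L) {
  if (inherits(model, "sg_module")) return(audit_module_macs(model, input_size))
  stopifnot(inherits(model, "backbone_spec"))
  L <- model$layers
  side <- as.integer(input_size)
  total <- 0
  for (i in seq_len(nrow(L))) {
    l <- L[i, ]
    if (l$type == "conv") {
      side <- as.integer(ceiling(side / l$stride))
      total <- total + side^2 * l$cout * l$k^2 * l$cin / l$groups
    } else if (l$type == "se_conv") {
      total <- total + l$cout * l$k^2 * l$cin   # acts on pooled 1x1 features
    } else if (l$type == "dense") {
      total <- total + l$cin * l$cout
    }
  }
  total
}

# audit a runnable module by forwarding zeros with the recorder on
.audit <- new.env(parent = emptyenv())
.audit$on <- FALSE
.audit$macs <- 0

audit_record <- function(macs) {
  if (isTRUE(.audit$on)) .audit$macs <- .audit$macs + macs
  invisible(NULL)
}

audit_module_macs <- function(model, input_size) {
  x <- array(0, c(input_size, input_size, 3L, 1L))
  .audit$on <- TRUE
  .audit$macs <- 0
  on.exit(.audit$on <- FALSE)
  module_forward(model, x, training = FALSE)
  .audit$macs
}

#' Round half-up on the printed scale
#' @param x numeric. @param digits decimal places.
#' @return numeric rounded half-up.
#' @export
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Model complexity report
#'
#' @param model a trainable module or `backbone_spec`.
#' @param input_size input side length for the MAC audit.
#' @return list with raw counts and the 2-decimal millions/giga renderings,
#'   plus the counting conventions used.
#' @export
complexity_report <- function(model, input_size = 300L) {
  p <- count_params(model)
  m <- count_macs(model, input_size)
  structure(list(
    params = p, macs = m, input_size = input_size,
    params_m = round_half_up(p / 1e6, 2),
    macs_g = round_half_up(m / 1e9, 2),
    conventions = paste("trainable parameters only (batch-norm statistics",
                        "excluded); MACs from conv/dense multiplies only",
                        "(no activations, no normalization)")
  ), class = "complexity_report")
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf("Params: %s (%.2fM)  MACs @ %dpx: %s (%.2fG)\n",
              format(x$params, big.mark = ","), x$params_m, x$input_size,
              format(x$macs, big.mark = ","), x$macs_g))
  cat("Conventions:", x$conventions, "\n")
  invisible(x)
}
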