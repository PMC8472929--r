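# Declarative network specifications: the canonical post-activation
# ResNet-50 baseline and the improved variant with five auxiliary shortcut
# groups, pre-activation bottlenecks, downsampling on the 3x3 convolutions,
# and average-pool bypasses.

resnet_activation <- function(kind = c("relu", "selu"), params = selu_params()) {
  kind <- match.arg(kind)
  list(kind = kind, alpha = params$alpha, lambda = params$lambda)
}

# Channel plan: canonical ResNet-50 widths scaled by a multiplier.
resnet_channels <- function(width = 1) {
  mids <- pmax(1L, as.integer(round(c(64, 128, 256, 512) * width)))
  list(stem = mids[1], mids = mids, outs = 4L * mids)
}

make_block <- function(in_ch, mid, out_ch, stride, preactivation, bypass) {
  list(kind = "bottleneck",
       channels = c(in_ch = in_ch, mid = mid, out = out_ch),
       # strides of the 1x1 / 3x3 / 1x1 trunk convolutions
       trunk_strides = if (preactivation) c(1L, stride, 1L) else c(stride, 1L, 1L),
       preactivation = preactivation,
       bypass = bypass,            # "identity", "conv1x1", "avgpool2x2+conv1x1"
       bypass_stride = stride)
}

make_resnet_spec <- function(variant, n_classes, activation, block_plan,
                             width, in_channels) {
  stopifnot(n_classes >= 2, length(block_plan) == 4, all(block_plan >= 1))
  ch <- resnet_channels(width)
  preact <- variant == "improved"
  stage_strides <- c(1L, 2L, 2L, 2L)
  stages <- vector("list", 4)
  in_ch <- ch$stem
  for (s in 1:4) {
    blocks <- vector("list", block_plan[s])
    for (b in seq_len(block_plan[s])) {
      first <- b == 1L
      stride <- if (first) stage_strides[s] else 1L
      bypass <- if (!first) "identity"
        else if (!preact) "conv1x1"            # baseline projection
        else if (s == 1L) "conv1x1"            # improved: no pooling where the
        else "avgpool2x2+conv1x1"              # spatial size is unchanged
      blocks[[b]] <- make_block(in_ch, ch$mids[s], ch$outs[s], stride,
                                preact, bypass)
      in_ch <- ch$outs[s]
    }
    stages[[s]] <- list(n_blocks = block_plan[s], mid = ch$mids[s],
                        out = ch$outs[s], stride = stage_strides[s],
                        blocks = blocks)
  }
  shortcuts <- list()
  if (variant == "improved") {
    ins <- c(ch$stem, ch$outs[1:3])
    for (s in 1:4) {
      shortcuts[[s]] <- list(name = sprintf("stage%d", s),
                             span = sprintf("Conv%d_x", s + 1L),
                             stride = stage_strides[s], kernel = 1L,
                             in_ch = ins[s], out_ch = ch$outs[s])
    }
    shortcuts[[5]] <- list(name = "global", span = "Conv2_x-Conv5_x",
                           stride = 8L, kernel = 1L,
                           in_ch = ch$stem, out_ch = ch$outs[4])
  }
  structure(list(variant = variant,
                 preactivation = preact,
                 activation = activation,
                 in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 width = width,
                 block_plan = as.integer(block_plan),
                 stem = list(kernel = 7L, stride = 2L, out_ch = ch$stem,
                             pool = list(kind = "max", kernel = 3L, stride = 2L)),
                 stages = stages,
                 shortcuts = shortcuts),
            class = "resnet_spec")
}

#' Baseline ResNet-50 specification
#'
#' The canonical 50-layer residual network: post-activation bottleneck blocks
#' in four stages of (3, 4, 6, 3) blocks, stride-2 downsampling on the first
#' 1x1 convolution of each downsampling block, 1x1 stride-2 projection
#' bypasses, no auxiliary shortcuts, and a global-average-pool + linear head.
#'
#' @param n_classes number of output classes (>= 2).
#' @param activation `"relu"` (canonical) or `"selu"`.
#' @param block_plan residual blocks per stage; `c(3, 4, 6, 3)` is ResNet-50,
#'   smaller plans give reduced-depth variants of the same topology.
#' @param width channel-width multiplier (1 = canonical 64/128/256/512 mid
#'   widths).
#' @param in_channels input image channels (GASF images are single-channel).
#' @return A `resnet_spec`.
#' @export
build_baseline_resnet50 <- function(n_classes = 7, activation = "relu",
                                    block_plan = c(3, 4, 6, 3), width = 1,
                                    in_channels = 1) {
  make_resnet_spec("baseline", n_classes, resnet_activation(activation),
                   block_plan, width, in_channels)
}

#' Improved residual network specification
#'
#' The modified ResNet-50: pre-activation bottlenecks (batch norm and
#' activation moved before each trunk convolution), downsampling relocated
#' from the first 1x1 to the 3x3 convolution so that no information is
#' discarded by a strided 1x1, a 2x2 average-pool + stride-1 1x1 bypass in
#' the first block of stages 2-4 (stage 1 keeps a plain 1x1 since its
#' spatial size is unchanged), and five auxiliary 1x1-convolution shortcut
#' groups: one across each of the four stages (strides 1, 2, 2, 2) and one
#' global branch from the stem output to the last stage output (stride 8).
#' All auxiliary branches merge by addition. SELU is the default activation.
#'
#' @inheritParams build_baseline_resnet50
#' @return A `resnet_spec`.
#' @export
build_improved_resnet <- function(n_classes = 7, activation = "selu",
                                  block_plan = c(3, 4, 6, 3), width = 1,
                                  in_channels = 1) {
  make_resnet_spec("improved", n_classes, resnet_activation(activation),
                   block_plan, width, in_channels)
}

#' Number of auxiliary shortcut groups in a specification
#' @param spec a `resnet_spec`.
#' @return Integer (0 for the baseline, 5 for the improved variant).
#' @export
n_shortcuts <- function(spec) length(spec$shortcuts)

#' Strides of the auxiliary shortcut groups
#' @param spec a `resnet_spec`.
#' @return Integer vector (stage-level strides then the global stride).
#' @export
shortcut_strides <- function(spec) {
  vapply(spec$shortcuts, function(s) as.integer(s$stride), integer(1))
}

#' @export
print.resnet_spec <- function(x, ...) {
  cat(sprintf("<resnet_spec '%s': stages (%s), width %g, %s activation, %d classes>\n",
              x$variant, paste(x$block_plan, collapse = ","), x$width,
              x$activation$kind, x$n_classes))
  if (length(x$shortcuts)) {
    cat("  auxiliary shortcut groups:\n")
    for (s in x$shortcuts) {
      cat(sprintf("    %-7s span %-15s 1x1, stride %d, %d -> %d channels\n",
                  s$name, s$span, s$stride, s$in_ch, s$out_ch))
    }
  }
  cat(sprintf("  parameters: %s\n", format(count_params(x), big.mark = ",")))
  invisible(x)
}

#' Trainable parameter count of a specification
#'
#' Sum over all convolution kernels, batch-norm scale/shift pairs, and the
#' classifier head, computed from the materialization graph so that it is
#' exactly the number of values the optimizer updates.
#'
#' @param spec a `resnet_spec`.
#' @return Numeric count.
#' @export
count_params <- function(spec) {
  g <- build_graph(spec)
  sum(vapply(g$nodes, function(nd) {
    switch(nd$op,
           conv = prod(nd$kernel, nd$kernel, nd$in_ch, nd$out_ch),
           bn = 2 * nd$ch,
           linear = nd$in_ch * nd$out_ch + nd$out_ch,
           0)
  }, numeric(1)))
}

#' Spatial shape trace through a specification
#'
#' Follows the stride bookkeeping of the stem and the four stages for a
#' square input and checks that every merge junction (residual bypasses and
#' auxiliary shortcuts) joins tensors of identical shape.
#'
#' @param spec a `resnet_spec`.
#' @param input_shape `c(side, side)`; the side must be divisible by 32.
#' @return `data.frame` with columns `stage`, `side`, `channels`, plus an
#'   attribute `logits` giving the classifier output length.
#' @export
forward_shapes <- function(spec, input_shape = c(224, 224)) {
  side <- input_shape[1]
  if (length(input_shape) >= 2 && input_shape[2] != side) {
    stop("input must be square")
  }
  if (side %% 32 != 0) stop("input side must be divisible by 32")
  ch <- resnet_channels(spec$width)
  stem_side <- side / 4  # 7x7 stride-2 conv then stride-2 pool
  sides <- stem_side / c(1, 2, 4, 8)
  # merge checks: bypass and shortcut outputs must match trunk outputs
  stage_in_sides <- c(stem_side, sides[1:3])
  for (s in 1:4) {
    blk <- spec$stages[[s]]$blocks[[1]]
    bypass_side <- stage_in_sides[s] / blk$bypass_stride
    if (bypass_side != sides[s]) {
      stop(sprintf("shape mismatch in stage %d bypass", s))
    }
  }
  for (sc in spec$shortcuts) {
    from_side <- if (sc$name == "global") stem_side
      else stage_in_sides[match(sc$name, sprintf("stage%d", 1:4))]
    to_side <- if (sc$name == "global") sides[4]
      else sides[match(sc$name, sprintf("stage%d", 1:4))]
    if (from_side / sc$stride != to_side) {
      stop(sprintf("shape mismatch in shortcut branch '%s'", sc$name))
    }
  }
  out <- data.frame(
    stage = c("stem", sprintf("Conv%d_x", 2:5)),
    side = c(stem_side, sides),
    channels = c(ch$stem, ch$outs))
  attr(out, "logits") <- spec$n_classes
  out
}
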