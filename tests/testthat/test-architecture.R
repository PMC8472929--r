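# Network specifications, shape traces, materialization, and gradients.

test_that("baseline spec is canonical ResNet-50", {
  spec <- build_baseline_resnet50(n_classes = 7)
  expect_equal(spec$block_plan, c(3L, 4L, 6L, 3L))
  expect_equal(n_shortcuts(spec), 0L)
  expect_false(spec$preactivation)
  # baseline keeps the stride on the first 1x1 of each downsampling block
  expect_equal(spec$stages[[2]]$blocks[[1]]$trunk_strides, c(2L, 1L, 1L))
  tr <- forward_shapes(spec, c(224, 224))
  expect_equal(attr(tr, "logits"), 7L)
})

test_that("baseline parameter count matches the published ResNet-50 reference", {
  # torchvision resnet50: 25,557,032 trainable parameters (1000 classes, RGB)
  spec <- build_baseline_resnet50(n_classes = 1000, in_channels = 3)
  expect_equal(count_params(spec), 25557032)
})

test_that("improved spec has exactly five 1x1 shortcut groups with strides 1,2,2,2,8", {
  spec <- build_improved_resnet(n_classes = 7)
  expect_equal(n_shortcuts(spec), 5L)
  expect_equal(shortcut_strides(spec), c(1L, 2L, 2L, 2L, 8L))
  expect_true(all(vapply(spec$shortcuts, function(s) s$kernel, integer(1)) == 1L))
  expect_true(spec$preactivation)
  expect_equal(spec$activation$kind, "selu")
  # stage-level branch of the first stage maps stem width to stage width
  expect_equal(spec$shortcuts[[1]]$in_ch, 64L)
  expect_equal(spec$shortcuts[[1]]$out_ch, 256L)
  expect_equal(spec$shortcuts[[5]]$in_ch, 64L)
  expect_equal(spec$shortcuts[[5]]$out_ch, 2048L)
})

test_that("improved blocks relocate downsampling and pool in the bypass", {
  spec <- build_improved_resnet(n_classes = 7)
  # stride 2 moved to the 3x3 conv; the 1x1 convs stay at stride 1
  b31 <- spec$stages[[2]]$blocks[[1]]
  expect_equal(b31$trunk_strides, c(1L, 2L, 1L))
  # first blocks of stages 2-4 use the avgpool bypass; stage 1 does not
  expect_equal(spec$stages[[3]]$blocks[[1]]$bypass, "avgpool2x2+conv1x1")
  expect_equal(spec$stages[[1]]$blocks[[1]]$bypass, "conv1x1")
  expect_equal(spec$stages[[2]]$blocks[[2]]$bypass, "identity")
  expect_gt(count_params(spec),
            count_params(build_baseline_resnet50(n_classes = 7)))
})

test_that("shape trace gives 56/28/14/7 for 224 input and checks divisibility", {
  tr <- forward_shapes(build_improved_resnet(7), c(224, 224))
  expect_equal(tr$side, c(56, 56, 28, 14, 7))
  expect_equal(tr$channels, c(64, 256, 512, 1024, 2048))
  # global shortcut output side equals the last stage side (stride 8 from stem)
  expect_equal(tr$side[1] / 8, tr$side[5])
  expect_error(forward_shapes(build_improved_resnet(7), c(100, 100)),
               "divisible by 32")
  expect_error(forward_shapes(build_improved_resnet(7), c(224, 96)), "square")
})

test_that("materialization is seed-deterministic and counts match the spec", {
  spec <- build_improved_resnet(n_classes = 4, block_plan = c(1, 1, 1, 1),
                                width = 0.1)
  m1 <- materialize(spec, 42)
  m2 <- materialize(spec, 42)
  expect_identical(param_checksum(m1), param_checksum(m2))
  expect_identical(m1$params, m2$params)
  m3 <- materialize(spec, 43)
  expect_false(param_checksum(m1) == param_checksum(m3))
  expect_equal(n_params(m1), count_params(spec))
})

test_that("a shape-inconsistent specification fails naming the branch", {
  spec <- build_improved_resnet(n_classes = 3, block_plan = c(1, 1, 1, 1),
                                width = 0.1)
  spec$shortcuts[[5]]$stride <- 4L  # break the global branch
  expect_error(materialize(spec, 1), "gsc")
})

test_that("zeroing the trunk of an identity-bypass block yields the identity map", {
  spec <- build_improved_resnet(n_classes = 3, block_plan = c(2, 1, 1, 1),
                                width = 0.1)
  m <- materialize(spec, 7)
  # zero every trunk conv of block 2 in stage 1 (its bypass is the identity)
  for (id in c("s1b2_conv1", "s1b2_conv2", "s1b2_conv3")) {
    m$params[[id]]$w[] <- 0
  }
  x <- array(rnorm(32 * 32 * 1 * 2), c(32, 32, 1, 2))
  fwd <- gasfnet:::nn_forward(m$graph, m$params, x, train = FALSE)
  expect_equal(fwd$outs[["s1b2_add"]], fwd$outs[["s1b1_add"]],
               tolerance = 1e-12)
})

test_that("analytic gradients match numerical differentiation through the graph", {
  spec <- build_improved_resnet(n_classes = 3, block_plan = c(1, 1, 1, 1),
                                width = 0.05)
  m <- materialize(spec, 42)
  x <- array(rnorm(32 * 32 * 1 * 2), c(32, 32, 1, 2))
  y <- c(1L, 3L)
  fwd <- gasfnet:::nn_forward(m$graph, m$params, x, train = TRUE)
  ls <- gasfnet:::softmax_xent(fwd$out, y)
  gr <- gasfnet:::nn_backward(m$graph, m$params, fwd, ls$dlogits)
  loss_at <- function(params) {
    gasfnet:::softmax_xent(
      gasfnet:::nn_forward(m$graph, params, x, train = TRUE)$out, y)$loss
  }
  set.seed(2)
  eps <- 1e-5
  for (id in sample(names(gr), 10)) {
    f <- names(gr[[id]])[1]
    k <- sample(length(m$params[[id]][[f]]), 1)
    pp <- m$params; pp[[id]][[f]][k] <- pp[[id]][[f]][k] + eps
    pm <- m$params; pm[[id]][[f]][k] <- pm[[id]][[f]][k] - eps
    num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
    expect_equal(gr[[id]][[f]][k], num, tolerance = 1e-4)
  }
})

test_that("every merge point in both variants joins identical shapes at runtime", {
  for (builder in list(build_baseline_resnet50, build_improved_resnet)) {
    spec <- builder(n_classes = 3, block_plan = c(1, 2, 1, 1), width = 0.1)
    m <- materialize(spec, 3)
    x <- array(rnorm(32 * 32 * 2), c(32, 32, 1, 2))
    fwd <- gasfnet:::nn_forward(m$graph, m$params, x, train = FALSE)
    for (nd in m$graph$nodes) {
      if (nd$op == "add") {
        dims <- lapply(fwd$outs[nd$inputs], dim)
        expect_identical(dims[[1]], dims[[2]])
      }
    }
    expect_equal(ncol(fwd$out), 3L)
  }
})
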