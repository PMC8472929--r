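# Stratified splitting and the deterministic training loop.

test_that("stratified split reproduces the development corpus allocation", {
  counts <- reference_class_counts()
  labels <- rep(names(counts), counts)
  sp <- stratified_split(labels, ratio = 0.8, seed = 1)
  pc <- sp$per_class_counts
  expect_equal(pc$n_train[pc$class == "AF"], 1472)
  expect_equal(pc$n_test[pc$class == "AF"], 369)
  expect_equal(setNames(pc$n_train, pc$class),
               c(AF = 1472, AT = 400, N = 3840, PAC = 262, PVC = 1684,
                 SBR = 1484, VT = 235))
  expect_equal(sum(pc$n_train), 9377)
  expect_equal(sum(pc$n_test), 2347)
})

test_that("the floor rule, disjointness and exhaustiveness hold for random labels", {
  set.seed(9)
  classes <- letters[1:5]
  for (k in 1:1000) {
    n <- sample(5:60, 1)
    labels <- sample(classes, n, replace = TRUE)
    labels <- c(labels, classes)  # ensure every class present
    ratio <- runif(1, 0.05, 0.95)
    sp <- stratified_split(labels, ratio, seed = k)
    expect_length(intersect(sp$train_indices, sp$test_indices), 0)
    expect_setequal(c(sp$train_indices, sp$test_indices),
                    seq_along(labels))
    for (cl in classes) {
      ncl <- sum(labels == cl)
      expect_equal(sp$per_class_counts$n_train[sp$per_class_counts$class == cl],
                   floor(ratio * ncl))
    }
  }
})

test_that("splits are seed-deterministic and fail on absent classes", {
  labels <- rep(c("N", "AF"), c(10, 6))
  s1 <- stratified_split(labels, 0.5, seed = 3)
  s2 <- stratified_split(labels, 0.5, seed = 3)
  expect_identical(s1$train_indices, s2$train_indices)
  expect_equal(sum(labels[s1$train_indices] == "N"), 5)  # floor(0.5 * 10)
  expect_error(stratified_split(labels, 0.8, seed = 1,
                                classes = c("N", "AF", "VT")),
               "0 samples: VT")
  # ratio 0.5 on 3 samples: 1 train, 2 test
  s3 <- stratified_split(rep("N", 3), 0.5, seed = 1)
  expect_length(s3$train_indices, 1)
  expect_length(s3$test_indices, 2)
})

test_that("zero epochs return an untrained model with empty history", {
  d <- toy_blob_data(n = 8)
  spec <- build_improved_resnet(2, block_plan = c(1, 1, 1, 1), width = 0.05)
  fit <- train_model(spec, d, train_config(epochs = 0, seed = 1))
  expect_s3_class(fit, "gasfnet_fit")
  expect_equal(nrow(fit$history), 0)
  expect_identical(fit$model$params, materialize(spec, 1)$params)
})

test_that("training errors on empty data and mismatched image sizes", {
  spec <- build_improved_resnet(2, block_plan = c(1, 1, 1, 1), width = 0.05)
  d <- toy_blob_data(n = 8)
  bad <- c(d, list(x_test = array(0, c(16, 16, 1, 2)), y_test = c("a", "b")))
  expect_error(train_model(spec, bad, train_config(epochs = 1)),
               "image-size mismatch")
  expect_error(train_model(spec, list(x = array(0, c(32, 32, 1, 0)),
                                      y = character(0)),
                           train_config(epochs = 1)),
               "empty")
})

test_that("a separable toy task trains to 100% within 50 epochs with falling loss", {
  d <- toy_blob_data(n = 20, seed = 1)
  spec <- build_improved_resnet(2, block_plan = c(1, 1, 1, 1), width = 0.125)
  # full-batch steps: the per-epoch loss is then free of minibatch noise
  cfg <- train_config(learning_rate = 1e-3, batch_size = 20, epochs = 40,
                      seed = 3)
  fit <- train_model(spec, c(d, list(x_test = d$x, y_test = d$y)), cfg)
  expect_equal(mean(predict(fit, d$x) == d$y), 1)
  expect_lte(nrow(fit$history), 50)
  # loss falls and settles: 10-epoch moving average never increases
  ma <- stats::filter(fit$history$loss, rep(0.1, 10), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_true(all(diff(ma) <= 1e-8))
})

test_that("training is reproducible per seed; batch order differs across seeds", {
  d <- toy_blob_data(n = 12, seed = 2)
  spec <- build_improved_resnet(2, block_plan = c(1, 1, 1, 1), width = 0.05)
  cfg <- train_config(learning_rate = 1e-3, batch_size = 4, epochs = 3,
                      seed = 5)
  f1 <- train_model(spec, d, cfg)
  f2 <- train_model(spec, d, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(param_checksum(f1$model), param_checksum(f2$model))
  cfg2 <- cfg; cfg2$seed <- 6L
  f3 <- train_model(spec, d, cfg2)
  expect_false(identical(f1$history$loss, f3$history$loss))
})

test_that("the variant-comparison harness shares one split and reports mean/sd", {
  set.seed(30)
  d <- toy_blob_data(n = 21, seed = 4)
  cfg <- train_config(learning_rate = 2e-3, batch_size = 8, epochs = 3,
                      seed = 2)
  tab <- run_variant_comparison(d, cfg = cfg, block_plan = c(1, 1, 1, 1),
                                width = 0.05)
  expect_equal(nrow(tab), 3)
  expect_setequal(tab$variant,
                  c("baseline-relu", "improved-relu", "improved-selu"))
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 1))
  expect_true(all(is.na(tab$sd)))  # single seed: no spread
  tab2 <- run_variant_comparison(d, variants = c("baseline-relu",
                                                 "improved-selu"),
                                 cfg = cfg, seeds = c(2, 3),
                                 block_plan = c(1, 1, 1, 1), width = 0.05)
  expect_equal(tab2$n_seeds, c(2, 2))
  expect_true(all(!is.na(tab2$sd)))
  expect_error(run_variant_comparison(d, variants = "baseline-relu"),
               "at least 2")
})

test_that("train_config validates its invariants", {
  expect_error(train_config(learning_rate = 0))
  expect_error(train_config(batch_size = 0))
  expect_error(train_config(epochs = -1))
  cfg <- train_config()
  expect_equal(cfg$learning_rate, 1e-4)
  expect_equal(cfg$batch_size, 32L)
  expect_equal(cfg$epochs, 150L)
})
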