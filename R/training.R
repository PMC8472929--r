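# Stratified splitting and the deterministic training loop.

#' Training configuration
#'
#' Defaults mirror the optimizer configuration the classifier was developed
#' with: Adam, initial learning rate 1e-4, batch size 32, 150 epochs,
#' cross-entropy loss. Short synthetic benchmarks typically override the
#' epoch count and learning rate.
#'
#' @param optimizer only `"adam"` is implemented.
#' @param learning_rate positive step size.
#' @param batch_size minibatch size, >= 1.
#' @param epochs number of passes over the training data, >= 0.
#' @param seed integer seed controlling initialization and batch order.
#' @param loss only `"cross-entropy"` is implemented.
#' @return Object of class `train_config`.
#' @export
train_config <- function(optimizer = "adam", learning_rate = 1e-4,
                         batch_size = 32L, epochs = 150L, seed = 1L,
                         loss = "cross-entropy") {
  stopifnot(identical(optimizer, "adam"), identical(loss, "cross-entropy"),
            learning_rate > 0, batch_size >= 1, epochs >= 0)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 loss = loss),
            class = "train_config")
}

#' Stratified train/test split
#'
#' Per class, a seeded random permutation of that class's indices is drawn
#' and the first `floor(ratio * n)` go to the training set; the remainder
#' form the test set. The floor-on-the-training-side rule is the one that
#' reproduces the development corpus's published 8:2 allocation for every
#' class.
#'
#' @param labels per-sample class labels (character or factor).
#' @param ratio training fraction, strictly between 0 and 1.
#' @param seed integer seed.
#' @param classes optional class set that must all be present.
#' @return Object of class `split_result`: `train_indices`, `test_indices`
#'   (1-based, disjoint, exhaustive) and a `per_class_counts` data frame.
#' @export
stratified_split <- function(labels, ratio = 0.8, seed = 1L, classes = NULL) {
  stopifnot(ratio > 0, ratio < 1)
  labels <- as.character(labels)
  if (is.null(classes)) {
    classes <- intersect(arrhythmia_classes(), unique(labels))
    if (length(classes) == 0) classes <- sort(unique(labels))
    classes <- union(classes, sort(unique(labels)))
  }
  missing_cls <- setdiff(classes, unique(labels))
  if (length(missing_cls)) {
    stop("class with 0 samples: ", missing_cls[1])
  }
  set.seed(seed)
  train <- integer(0); test <- integer(0)
  counts <- data.frame(class = classes, n_total = 0L, n_train = 0L,
                       n_test = 0L, stringsAsFactors = FALSE)
  for (k in seq_along(classes)) {
    idx <- which(labels == classes[k])
    perm <- if (length(idx) == 1) idx else sample(idx)
    ntr <- floor(ratio * length(idx))
    train <- c(train, perm[seq_len(ntr)])
    test <- c(test, perm[setdiff(seq_along(perm), seq_len(ntr))])
    counts[k, 2:4] <- c(length(idx), ntr, length(idx) - ntr)
  }
  structure(list(train_indices = sort(train), test_indices = sort(test),
                 per_class_counts = counts, ratio = ratio, seed = seed),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result %g:%g, seed %d>\n", x$ratio * 10,
              (1 - x$ratio) * 10, x$seed))
  print(x$per_class_counts, row.names = FALSE)
  cat(sprintf("  total: %d train / %d test\n",
              sum(x$per_class_counts$n_train),
              sum(x$per_class_counts$n_test)))
  invisible(x)
}

# Fields the optimizer updates, per op.
.trainable <- c(conv = "w", linear = "w,b", bn = "gamma,beta")

adam_init <- function(params) {
  lapply(params, function(p) {
    lapply(p[setdiff(names(p), c("rm", "rv"))], function(v) {
      list(m = v * 0, v = v * 0)
    })
  })
}

adam_step <- function(params, grads, state, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (id in names(grads)) {
    for (f in names(grads[[id]])) {
      g <- grads[[id]][[f]]
      st <- state[[id]][[f]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      params[[id]][[f]] <- params[[id]][[f]] - lr * mhat / (sqrt(vhat) + eps)
      state[[id]][[f]] <- st
    }
  }
  list(params = params, state = state)
}

#' Train a network on labeled GASF images
#'
#' Deterministic-seeded minibatch training with Adam and cross-entropy loss.
#' When a test set is supplied, test accuracy is evaluated after every epoch
#' (the historical protocol tracked test accuracy during training; the test
#' set therefore doubles as a validation set — interpret learning curves
#' accordingly). Identical seed, data and configuration reproduce the same
#' history on the same machine.
#'
#' @param spec a `resnet_spec` (or an already materialized `gasf_model`).
#' @param data list with `x` (array `H x W x C x N`), `y` (labels), and
#'   optionally `x_test` / `y_test`.
#' @param cfg a [train_config()].
#' @param classes class-label ordering; defaults to the canonical seven-class
#'   order restricted to the labels present.
#' @param verbose print per-epoch progress.
#' @return Object of class `gasfnet_fit` with elements `model`, `history`
#'   (data frame: epoch, loss, test_acc), `config`, `classes`.
#' @export
train_model <- function(spec, data, cfg = train_config(), classes = NULL,
                        verbose = FALSE) {
  stopifnot(is.list(data), !is.null(data$x), !is.null(data$y))
  x <- data$x
  if (dim(x)[4] == 0) stop("data is empty")
  if (is.null(classes)) {
    classes <- intersect(arrhythmia_classes(), unique(as.character(data$y)))
    if (length(classes) == 0) classes <- sort(unique(as.character(data$y)))
    classes <- union(classes, sort(unique(as.character(data$y))))
  }
  y <- match(as.character(data$y), classes)
  if (anyNA(y)) stop("label not in classes: ",
                     as.character(data$y)[which(is.na(y))[1]])
  has_test <- !is.null(data$x_test)
  if (has_test) {
    if (!identical(dim(data$x_test)[1:3], dim(x)[1:3])) {
      stop("image-size mismatch between training and test images")
    }
    y_test <- match(as.character(data$y_test), classes)
  }
  model <- if (inherits(spec, "gasf_model")) spec else materialize(spec, cfg$seed)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        test_acc = numeric(0))
  if (cfg$epochs == 0) {
    return(structure(list(model = model, history = history, config = cfg,
                          classes = classes),
                     class = "gasfnet_fit"))
  }
  params <- model$params
  state <- adam_init(params)
  n <- dim(x)[4]
  t_step <- 0L
  set.seed(derive_seed(cfg$seed, 7L))
  for (ep in seq_len(cfg$epochs)) {
    perm <- sample(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
      xb <- x[, , , idx, drop = FALSE]
      fwd <- nn_forward(model$graph, params, xb, train = TRUE)
      params <- fwd$params
      ls <- softmax_xent(fwd$out, y[idx])
      losses <- c(losses, ls$loss)
      grads <- nn_backward(model$graph, params, fwd, ls$dlogits)
      t_step <- t_step + 1L
      up <- adam_step(params, grads, state, t_step, cfg$learning_rate)
      params <- up$params; state <- up$state
    }
    model$params <- params
    acc <- NA_real_
    if (has_test) {
      pred <- max.col(model_logits(model, data$x_test), ties.method = "first")
      acc <- mean(pred == y_test)
    }
    history <- rbind(history,
                     data.frame(epoch = ep, loss = mean(losses),
                                test_acc = acc))
    if (verbose) {
      cat(sprintf("epoch %3d  loss %.4f  test_acc %s\n", ep, mean(losses),
                  ifelse(is.na(acc), "-", sprintf("%.3f", acc))))
    }
  }
  model$params <- params
  structure(list(model = model, history = history, config = cfg,
                 classes = classes),
            class = "gasfnet_fit")
}

#' @export
print.gasfnet_fit <- function(x, ...) {
  cat(sprintf("<gasfnet_fit: '%s' (%s), %d classes, %d epoch(s)>\n",
              x$model$spec$variant, x$model$spec$activation$kind,
              length(x$classes), nrow(x$history)))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final loss %.4f%s\n", last$loss,
                ifelse(is.na(last$test_acc), "",
                       sprintf(", test accuracy %.1f%%",
                               100 * last$test_acc))))
  }
  invisible(x)
}

#' @export
summary.gasfnet_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  parameters: %s; lr %g, batch %d, seed %d\n",
              format(n_params(object$model), big.mark = ","),
              object$config$learning_rate, object$config$batch_size,
              object$config$seed))
  invisible(object)
}

#' Plot training history
#'
#' Loss per epoch and, when recorded, test accuracy per epoch.
#'
#' @param x a `gasfnet_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gasfnet_fit <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) {
    warning("empty history")
    return(invisible(x))
  }
  has_acc <- any(!is.na(h$test_acc))
  old <- graphics::par(mfrow = c(1, if (has_acc) 2 else 1))
  on.exit(graphics::par(old))
  plot(h$epoch, h$loss, type = "l", xlab = "epoch", ylab = "loss", ...)
  if (has_acc) {
    plot(h$epoch, h$test_acc, type = "l", xlab = "epoch",
         ylab = "test accuracy", ylim = c(0, 1), ...)
  }
  invisible(x)
}

#' Predict rhythm classes from a fitted model
#'
#' @param object a `gasfnet_fit`.
#' @param newdata image array or `gaf_image` list (encode segments with
#'   [encode_segments()] first).
#' @param type `"class"` (labels), `"prob"` or `"logits"`.
#' @param ... unused.
#' @return Character vector of class labels, or a numeric matrix.
#' @export
predict.gasfnet_fit <- function(object, newdata,
                                type = c("class", "prob", "logits"), ...) {
  type <- match.arg(type)
  res <- predict(object$model, newdata, type = type)
  if (type == "class") object$classes[res] else res
}

#' Compare network variants on one shared split
#'
#' Trains each requested variant on the same stratified split (same seed)
#' and reports final test accuracy; with several seeds, mean and standard
#' deviation across seeds are reported per variant.
#'
#' @param data list with `x` (image array) and `y` (labels) for the whole
#'   dataset.
#' @param variants subset of `"baseline-relu"`, `"improved-relu"`,
#'   `"improved-selu"`.
#' @param cfg a [train_config()].
#' @param seeds integer vector of seeds; defaults to `cfg$seed`.
#' @param ratio train fraction for the shared split.
#' @param block_plan,width forwarded to the spec builders (smaller values
#'   give desk-scale benchmarks).
#' @return `data.frame` with one row per variant: `variant`, `accuracy`
#'   (mean over seeds), `sd`, `n_seeds`.
#' @export
run_variant_comparison <- function(data,
                                   variants = c("baseline-relu",
                                                "improved-relu",
                                                "improved-selu"),
                                   cfg = train_config(),
                                   seeds = cfg$seed,
                                   ratio = 0.8,
                                   block_plan = c(1, 1, 1, 1),
                                   width = 0.25) {
  if (length(variants) < 2) stop("need at least 2 variants to compare")
  classes <- intersect(arrhythmia_classes(), unique(as.character(data$y)))
  if (length(classes) == 0) classes <- sort(unique(as.character(data$y)))
  acc <- matrix(NA_real_, length(seeds), length(variants),
                dimnames = list(NULL, variants))
  for (i in seq_along(seeds)) {
    sp <- stratified_split(data$y, ratio = ratio, seed = seeds[i])
    d <- list(x = data$x[, , , sp$train_indices, drop = FALSE],
              y = data$y[sp$train_indices],
              x_test = data$x[, , , sp$test_indices, drop = FALSE],
              y_test = data$y[sp$test_indices])
    for (v in variants) {
      spec <- variant_spec(v, n_classes = length(classes),
                           block_plan = block_plan, width = width)
      cfg_i <- cfg; cfg_i$seed <- seeds[i]
      fit <- train_model(spec, d, cfg_i, classes = classes)
      acc[i, v] <- tail(fit$history$test_acc, 1)
    }
  }
  data.frame(variant = variants,
             accuracy = colMeans(acc),
             sd = apply(acc, 2, function(z) if (length(seeds) > 1) sd(z) else NA_real_),
             n_seeds = length(seeds),
             row.names = NULL)
}

# Map a variant name to a spec builder.
variant_spec <- function(variant, n_classes = 7, block_plan = c(3, 4, 6, 3),
                         width = 1, in_channels = 1) {
  switch(variant,
         "baseline-relu" = build_baseline_resnet50(n_classes, "relu",
                                                   block_plan, width, in_channels),
         "improved-relu" = build_improved_resnet(n_classes, "relu",
                                                 block_plan, width, in_channels),
         "improved-selu" = build_improved_resnet(n_classes, "selu",
                                                 block_plan, width, in_channels),
         stop("unknown variant: ", variant))
}
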