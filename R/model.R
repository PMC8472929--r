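# Materializing a network specification into a trainable model.

# Infer channel counts and cumulative downsampling factors through the graph
# and check that every merge junction adds tensors of identical shape.
validate_graph <- function(graph, in_channels) {
  ch <- list(); fac <- list()
  for (nd in graph$nodes) {
    id <- nd$id
    switch(nd$op,
      input = { ch[[id]] <- in_channels; fac[[id]] <- 1L },
      conv = {
        if (ch[[nd$inputs]] != nd$in_ch) {
          stop(sprintf("channel mismatch at branch '%s': got %d, expected %d",
                       id, ch[[nd$inputs]], nd$in_ch))
        }
        ch[[id]] <- nd$out_ch
        fac[[id]] <- fac[[nd$inputs]] * nd$stride
      },
      linear = { ch[[id]] <- nd$out_ch; fac[[id]] <- NA_integer_ },
      maxpool = , avgpool = {
        ch[[id]] <- ch[[nd$inputs]]
        fac[[id]] <- fac[[nd$inputs]] * nd$stride
      },
      add = {
        cs <- unlist(ch[nd$inputs]); fs <- unlist(fac[nd$inputs])
        if (length(unique(cs)) != 1 || length(unique(fs)) != 1) {
          stop(sprintf("shape mismatch at merge '%s' (channels %s, strides %s)",
                       id, paste(cs, collapse = "/"),
                       paste(fs, collapse = "/")))
        }
        ch[[id]] <- cs[1]; fac[[id]] <- fs[1]
      },
      { ch[[id]] <- ch[[nd$inputs]]; fac[[id]] <- fac[[nd$inputs]] })
  }
  invisible(TRUE)
}

init_params <- function(graph, spec, seed) {
  set.seed(seed)
  selu_init <- spec$activation$kind == "selu"
  params <- list()
  for (nd in graph$nodes) {
    params[[nd$id]] <- switch(nd$op,
      conv = {
        fan_in <- nd$kernel^2 * nd$in_ch
        sd <- sqrt((if (selu_init) 1 else 2) / fan_in)
        n <- nd$kernel^2 * nd$in_ch * nd$out_ch
        list(w = array(rnorm(n, sd = sd),
                       dim = c(nd$kernel, nd$kernel, nd$in_ch, nd$out_ch)))
      },
      bn = list(gamma = rep(1, nd$ch), beta = rep(0, nd$ch),
                rm = rep(0, nd$ch), rv = rep(1, nd$ch)),
      linear = list(w = matrix(rnorm(nd$in_ch * nd$out_ch,
                                     sd = sqrt(1 / nd$in_ch)),
                               nd$in_ch, nd$out_ch),
                    b = rep(0, nd$out_ch)),
      NULL)
  }
  params[!vapply(params, is.null, logical(1))]
}

#' Materialize a network specification
#'
#' Builds the computational graph, validates that every merge junction joins
#' tensors of identical shape, and initializes all parameters from a seed
#' (LeCun-normal fan-in scaling for SELU networks, He-normal for ReLU).
#' Identical `spec` and `seed` always give identical parameters.
#'
#' @param spec a `resnet_spec`.
#' @param seed integer RNG seed for the initialization.
#' @return Object of class `gasf_model`.
#' @export
materialize <- function(spec, seed = 1L) {
  graph <- build_graph(spec)
  validate_graph(graph, spec$in_channels)
  params <- init_params(graph, spec, seed)
  structure(list(spec = spec, graph = graph, params = params,
                 seed = as.integer(seed)),
            class = "gasf_model")
}

#' Number of trainable parameters of a materialized model
#' @param model a `gasf_model`.
#' @return Numeric count (excludes batch-norm running statistics).
#' @export
n_params <- function(model) {
  sum(vapply(names(model$params), function(id) {
    p <- model$params[[id]]
    sum(vapply(setdiff(names(p), c("rm", "rv")), function(f) length(p[[f]]),
               numeric(1)))
  }, numeric(1)))
}

#' Checksum of a model's parameters
#'
#' Order-sensitive digest used to verify that two materializations (or two
#' training runs) produced identical parameters.
#'
#' @param model a `gasf_model`.
#' @return A single numeric value.
#' @export
param_checksum <- function(model) {
  v <- unlist(lapply(model$params, function(p) {
    unlist(p[setdiff(names(p), c("rm", "rv"))], use.names = FALSE)
  }), use.names = FALSE)
  sum(v * seq(1.0, 2.0, length.out = length(v)))
}

#' @export
print.gasf_model <- function(x, ...) {
  cat(sprintf("<gasf_model '%s' (%s), %s parameters, seed %d>\n",
              x$spec$variant, x$spec$activation$kind,
              format(n_params(x), big.mark = ","), x$seed))
  invisible(x)
}

# Forward in evaluation mode, in chunks to bound memory.
model_logits <- function(model, x, chunk = 32L) {
  n <- dim(x)[4]
  out <- matrix(0, n, model$spec$n_classes)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    xb <- x[, , , i:j, drop = FALSE]
    out[i:j, ] <- nn_forward(model$graph, model$params, xb, train = FALSE)$out
    i <- j + 1L
  }
  out
}

#' Predict from a materialized model
#'
#' @param object a `gasf_model`.
#' @param newdata image array `(H, W, C, N)` or a list of `gaf_image`
#'   objects.
#' @param type `"class"` (integer class index), `"prob"` or `"logits"`.
#' @param ... unused.
#' @return Integer vector, or an `N x n_classes` matrix.
#' @export
predict.gasf_model <- function(object, newdata,
                               type = c("class", "prob", "logits"), ...) {
  type <- match.arg(type)
  x <- as_image_array(newdata)
  logits <- model_logits(object, x)
  switch(type,
         logits = logits,
         prob = {
           z <- exp(logits - apply(logits, 1, max))
           z / rowSums(z)
         },
         class = max.col(logits, ties.method = "first"))
}

# Coerce supported inputs to the (H, W, C, N) array layout.
as_image_array <- function(x) {
  if (is.array(x) && length(dim(x)) == 4) return(x)
  if (is.matrix(x)) return(array(x, dim = c(dim(x), 1L, 1L)))
  if (is.list(x) && length(x) && inherits(x[[1]], "gaf_image")) {
    s <- x[[1]]$size
    arr <- array(0, dim = c(s, s, 1L, length(x)))
    for (i in seq_along(x)) arr[, , 1L, i] <- x[[i]]$matrix
    return(arr)
  }
  if (inherits(x, "gaf_image")) return(array(x$matrix, dim = c(dim(x$matrix), 1L, 1L)))
  stop("cannot interpret newdata as images")
}
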