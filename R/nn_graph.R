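# Computational graph for the residual networks. A `resnet_spec` is lowered
# to a flat list of nodes in topological order (conv / batch-norm /
# activation / pooling / global-average-pool / linear / add); the executor
# walks the list forward caching what backpropagation needs, then walks it
# in reverse accumulating parameter and input gradients. Convolutions and
# pooling run in compiled code; batch norm and the rest are vectorized R.

node_conv <- function(id, input, kernel, stride, pad, in_ch, out_ch) {
  list(id = id, op = "conv", inputs = input, kernel = kernel, stride = stride,
       pad = pad, in_ch = in_ch, out_ch = out_ch)
}
node_bn <- function(id, input, ch) list(id = id, op = "bn", inputs = input, ch = ch)
node_act <- function(id, input) list(id = id, op = "act", inputs = input)
node_add <- function(id, inputs) list(id = id, op = "add", inputs = inputs)

# Lower a resnet_spec to the node list. Returns list(nodes, output).
build_graph <- function(spec) {
  nodes <- list()
  push <- function(nd) nodes[[nd$id]] <<- nd
  act <- spec$activation$kind

  push(list(id = "input", op = "input", inputs = character(0)))
  push(node_conv("stem_conv", "input", spec$stem$kernel, spec$stem$stride,
                 spec$stem$kernel %/% 2L, spec$in_channels, spec$stem$out_ch))
  push(node_bn("stem_bn", "stem_conv", spec$stem$out_ch))
  push(node_act("stem_act", "stem_bn"))
  push(list(id = "stem_pool", op = "maxpool", inputs = "stem_act",
            kernel = spec$stem$pool$kernel, stride = spec$stem$pool$stride,
            pad = 1L))
  cur <- "stem_pool"

  for (s in seq_along(spec$stages)) {
    stage_in <- cur
    st <- spec$stages[[s]]
    for (b in seq_len(st$n_blocks)) {
      blk <- st$blocks[[b]]
      p <- sprintf("s%db%d", s, b)
      ic <- blk$channels[["in_ch"]]; mid <- blk$channels[["mid"]]
      oc <- blk$channels[["out"]]
      ts <- blk$trunk_strides
      if (blk$preactivation) {
        push(node_bn(paste0(p, "_bn1"), cur, ic))
        push(node_act(paste0(p, "_act1"), paste0(p, "_bn1")))
        push(node_conv(paste0(p, "_conv1"), paste0(p, "_act1"), 1L, ts[1], 0L, ic, mid))
        push(node_bn(paste0(p, "_bn2"), paste0(p, "_conv1"), mid))
        push(node_act(paste0(p, "_act2"), paste0(p, "_bn2")))
        push(node_conv(paste0(p, "_conv2"), paste0(p, "_act2"), 3L, ts[2], 1L, mid, mid))
        push(node_bn(paste0(p, "_bn3"), paste0(p, "_conv2"), mid))
        push(node_act(paste0(p, "_act3"), paste0(p, "_bn3")))
        push(node_conv(paste0(p, "_conv3"), paste0(p, "_act3"), 1L, ts[3], 0L, mid, oc))
        trunk <- paste0(p, "_conv3")
      } else {
        push(node_conv(paste0(p, "_conv1"), cur, 1L, ts[1], 0L, ic, mid))
        push(node_bn(paste0(p, "_bn1"), paste0(p, "_conv1"), mid))
        push(node_act(paste0(p, "_act1"), paste0(p, "_bn1")))
        push(node_conv(paste0(p, "_conv2"), paste0(p, "_act1"), 3L, ts[2], 1L, mid, mid))
        push(node_bn(paste0(p, "_bn2"), paste0(p, "_conv2"), mid))
        push(node_act(paste0(p, "_act2"), paste0(p, "_bn2")))
        push(node_conv(paste0(p, "_conv3"), paste0(p, "_act2"), 1L, ts[3], 0L, mid, oc))
        push(node_bn(paste0(p, "_bn3"), paste0(p, "_conv3"), oc))
        trunk <- paste0(p, "_bn3")
      }
      bypass <- cur
      if (blk$bypass == "conv1x1") {
        push(node_conv(paste0(p, "_proj"), cur, 1L, blk$bypass_stride, 0L, ic, oc))
        push(node_bn(paste0(p, "_proj_bn"), paste0(p, "_proj"), oc))
        bypass <- paste0(p, "_proj_bn")
      } else if (blk$bypass == "avgpool2x2+conv1x1") {
        push(list(id = paste0(p, "_pool"), op = "avgpool", inputs = cur,
                  kernel = 2L, stride = blk$bypass_stride))
        push(node_conv(paste0(p, "_proj"), paste0(p, "_pool"), 1L, 1L, 0L, ic, oc))
        push(node_bn(paste0(p, "_proj_bn"), paste0(p, "_proj"), oc))
        bypass <- paste0(p, "_proj_bn")
      }
      push(node_add(paste0(p, "_add"), c(trunk, bypass)))
      cur <- paste0(p, "_add")
      if (!blk$preactivation) {
        push(node_act(paste0(p, "_out"), cur))
        cur <- paste0(p, "_out")
      }
    }
    # stage-level auxiliary shortcut (improved variant)
    sc <- Filter(function(z) z$name == sprintf("stage%d", s), spec$shortcuts)
    if (length(sc)) {
      sc <- sc[[1]]
      push(node_conv(sprintf("sc%d_conv", s), stage_in, 1L, sc$stride, 0L,
                     sc$in_ch, sc$out_ch))
      push(node_bn(sprintf("sc%d_bn", s), sprintf("sc%d_conv", s), sc$out_ch))
      push(node_add(sprintf("sc%d_add", s), c(cur, sprintf("sc%d_bn", s))))
      cur <- sprintf("sc%d_add", s)
    }
  }
  gsc <- Filter(function(z) z$name == "global", spec$shortcuts)
  if (length(gsc)) {
    gsc <- gsc[[1]]
    push(node_conv("gsc_conv", "stem_pool", 1L, gsc$stride, 0L,
                   gsc$in_ch, gsc$out_ch))
    push(node_bn("gsc_bn", "gsc_conv", gsc$out_ch))
    push(node_add("gsc_add", c(cur, "gsc_bn")))
    cur <- "gsc_add"
  }
  if (spec$preactivation) {
    out4 <- spec$stages[[4]]$out
    push(node_bn("final_bn", cur, out4))
    push(node_act("final_act", "final_bn"))
    cur <- "final_act"
  }
  push(list(id = "gap", op = "gap", inputs = cur))
  push(list(id = "head", op = "linear", inputs = "gap",
            in_ch = spec$stages[[4]]$out, out_ch = spec$n_classes))
  list(nodes = nodes, output = "head", activation = spec$activation)
}

# ---- batch norm (channel-wise over H, W, N) --------------------------------

.chan_stat <- function(z, HW, C, N) {
  rowMeans(matrix(.colMeans(z, HW, C * N), C, N))
}

bn_fwd <- function(x, pr, train, eps = 1e-5, momentum = 0.1) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  if (train) {
    mu <- .chan_stat(x, HW, C, N)
    v <- .chan_stat(x * x, HW, C, N) - mu^2
    v <- pmax(v, 0)
    pr$rm <- (1 - momentum) * pr$rm + momentum * mu
    pr$rv <- (1 - momentum) * pr$rv + momentum * v
  } else {
    mu <- pr$rm; v <- pr$rv
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- (x - rep(mu, each = HW)) * rep(ivar, each = HW)
  y <- xhat * rep(pr$gamma, each = HW) + rep(pr$beta, each = HW)
  list(y = y, cache = list(xhat = xhat, ivar = ivar, HW = HW, C = C, N = N),
       params = pr)
}

bn_bwd <- function(dout, pr, cache) {
  HW <- cache$HW; C <- cache$C; N <- cache$N; m <- HW * N
  xhat <- cache$xhat
  sum_dy <- m * .chan_stat(dout, HW, C, N)
  sum_dy_xhat <- m * .chan_stat(dout * xhat, HW, C, N)
  dx <- rep(pr$gamma * cache$ivar / m, each = HW) *
    (m * dout - rep(sum_dy, each = HW) - xhat * rep(sum_dy_xhat, each = HW))
  list(dx = dx, dgamma = sum_dy_xhat, dbeta = sum_dy)
}

# ---- global average pool / linear / loss -----------------------------------

gap_fwd <- function(x) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  t(matrix(.colMeans(x, HW, C * N), C, N))  # N x C
}

gap_bwd <- function(dout, xdim) {
  HW <- xdim[1] * xdim[2]
  array(rep(as.vector(t(dout)), each = HW) / HW, dim = xdim)
}

softmax_xent <- function(logits, y) {
  # logits: N x K, y: integer class in 1..K
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  n <- nrow(logits)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), y)], 1e-12)))
  dl <- p
  dl[cbind(seq_len(n), y)] <- dl[cbind(seq_len(n), y)] - 1
  list(loss = loss, dlogits = dl / n)
}

# ---- executor ---------------------------------------------------------------

act_fwd <- function(x, activation) {
  if (activation$kind == "relu") relu(x)
  else selu(x, list(alpha = activation$alpha, lambda = activation$lambda))
}

act_bwd <- function(dout, x, activation) {
  if (activation$kind == "relu") dout * (x > 0)
  else dout * selu_grad(x, list(alpha = activation$alpha,
                                lambda = activation$lambda))
}

# Forward pass. Returns list(out, outs, caches, params); `params` carries
# updated batch-norm running statistics when train = TRUE.
nn_forward <- function(graph, params, x, train = FALSE) {
  outs <- list(); caches <- list()
  for (nd in graph$nodes) {
    id <- nd$id
    val <- switch(nd$op,
      input = x,
      conv = conv2d_fwd(outs[[nd$inputs]], params[[id]]$w, nd$stride, nd$pad),
      bn = {
        r <- bn_fwd(outs[[nd$inputs]], params[[id]], train)
        params[[id]] <- r$params
        caches[[id]] <- r$cache
        r$y
      },
      act = act_fwd(outs[[nd$inputs]], graph$activation),
      maxpool = {
        r <- maxpool_fwd(outs[[nd$inputs]], nd$kernel, nd$stride, nd$pad)
        caches[[id]] <- list(argmax = r$argmax, xdim = dim(outs[[nd$inputs]]))
        r$out
      },
      avgpool = avgpool_fwd(outs[[nd$inputs]], nd$kernel, nd$stride),
      gap = gap_fwd(outs[[nd$inputs]]),
      linear = outs[[nd$inputs]] %*% params[[id]]$w +
        matrix(params[[id]]$b, nrow(outs[[nd$inputs]]), nd$out_ch, byrow = TRUE),
      add = Reduce(`+`, outs[nd$inputs]),
      stop("unknown op: ", nd$op))
    outs[[id]] <- val
  }
  list(out = outs[[graph$output]], outs = outs, caches = caches,
       params = params)
}

# Backward pass from the gradient at the output node. Returns list(grads)
# keyed like params.
nn_backward <- function(graph, params, fwd, dout) {
  outs <- fwd$outs; caches <- fwd$caches
  douts <- list(); grads <- list()
  douts[[graph$output]] <- dout
  acc <- function(id, g) {
    douts[[id]] <<- if (is.null(douts[[id]])) g else douts[[id]] + g
  }
  for (nd in rev(graph$nodes)) {
    id <- nd$id
    g <- douts[[id]]
    if (is.null(g) || nd$op == "input") next
    switch(nd$op,
      conv = {
        r <- conv2d_bwd(outs[[nd$inputs]], params[[id]]$w, g, nd$stride, nd$pad)
        grads[[id]] <- list(w = r$dw)
        acc(nd$inputs, r$dx)
      },
      bn = {
        r <- bn_bwd(g, params[[id]], caches[[id]])
        grads[[id]] <- list(gamma = r$dgamma, beta = r$dbeta)
        acc(nd$inputs, r$dx)
      },
      act = acc(nd$inputs, act_bwd(g, outs[[nd$inputs]], graph$activation)),
      maxpool = acc(nd$inputs,
                    maxpool_bwd(g, caches[[id]]$argmax, caches[[id]]$xdim)),
      avgpool = acc(nd$inputs,
                    avgpool_bwd(g, dim(outs[[nd$inputs]]), nd$kernel, nd$stride)),
      gap = acc(nd$inputs, gap_bwd(g, dim(outs[[nd$inputs]]))),
      linear = {
        xin <- outs[[nd$inputs]]
        grads[[id]] <- list(w = crossprod(xin, g), b = colSums(g))
        acc(nd$inputs, g %*% t(params[[id]]$w))
      },
      add = for (inp in nd$inputs) acc(inp, g))
    douts[[id]] <- NULL  # free
  }
  grads
}
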