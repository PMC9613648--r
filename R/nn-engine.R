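# Minimal neural-net engine used by the WGAN loop and the toy classifier.
# Batches are n x D matrices; image tensors are flattened column-major in
# (H, W, C) order. Everything runs on base matrix ops so training is
# deterministic under a fixed RNG seed on one CPU.

nn_dense <- function(d_in, d_out, init_scale = sqrt(2 / d_in)) {
  list(
    type = "dense",
    W = matrix(rnorm(d_in * d_out, sd = init_scale), d_in, d_out),
    b = numeric(d_out)
  )
}

nn_act <- function(kind = c("relu", "lrelu", "tanh"), alpha = 0.2) {
  kind <- match.arg(kind)
  list(type = kind, alpha = alpha)
}

# Valid convolution (no padding) with square kernel `k` and given stride.
# Weights are (k*k*c_in) x filters; the precomputed gather index turns the
# batch matrix into im2col patches with one indexing operation.
nn_conv <- function(h, w, c_in, filters, k = 3L, stride = 2L,
                    init_scale = sqrt(2 / (k * k * c_in))) {
  oh <- (h - k) %/% stride + 1L
  ow <- (w - k) %/% stride + 1L
  stopifnot(oh >= 1L, ow >= 1L)
  kk <- k * k * c_in
  idx <- integer(kk * oh * ow)
  pos <- 1L
  for (ocol in seq_len(ow)) {
    for (orow in seq_len(oh)) {
      r0 <- (orow - 1L) * stride
      c0 <- (ocol - 1L) * stride
      for (ch in seq_len(c_in)) {
        for (dj in seq_len(k)) {
          for (di in seq_len(k)) {
            idx[pos] <- (r0 + di) + (c0 + dj - 1L) * h + (ch - 1L) * h * w
            pos <- pos + 1L
          }
        }
      }
    }
  }
  # idx was filled kernel-fastest within each output location, locations in
  # (orow, ocol) column-major order -> matches the reshape in the forward pass
  list(
    type = "conv", h = h, w = w, c_in = c_in, k = k, stride = stride,
    filters = filters, oh = oh, ow = ow, kk = kk, idx = idx,
    W = matrix(rnorm(kk * filters, sd = init_scale), kk, filters),
    b = numeric(filters),
    d_out = oh * ow * filters
  )
}

nn_net <- function(layers) structure(list(layers = layers), class = "nn_net")

layer_forward <- function(layer, x) {
  switch(layer$type,
    dense = list(out = sweep(x %*% layer$W, 2, layer$b, "+"), cache = x),
    relu = list(out = pmax(x, 0), cache = x),
    lrelu = list(out = ifelse(x > 0, x, layer$alpha * x), cache = x),
    tanh = {
      t <- tanh(x)
      list(out = t, cache = t)
    },
    conv = {
      n <- nrow(x)
      l <- layer$oh * layer$ow
      cols <- x[, layer$idx, drop = FALSE]
      p <- matrix(aperm(array(cols, c(n, layer$kk, l)), c(1, 3, 2)),
                  n * l, layer$kk)
      z <- sweep(p %*% layer$W, 2, layer$b, "+")
      out <- z
      dim(out) <- c(n, l * layer$filters)
      list(out = out, cache = p)
    },
    abort(sprintf("unknown layer type '%s'", layer$type))
  )
}

layer_backward <- function(layer, cache, dy, d_in) {
  switch(layer$type,
    dense = list(
      dx = dy %*% t(layer$W),
      dW = crossprod(cache, dy),
      db = colSums(dy)
    ),
    relu = list(dx = dy * (cache > 0)),
    lrelu = list(dx = dy * ifelse(cache > 0, 1, layer$alpha)),
    tanh = list(dx = dy * (1 - cache^2)),
    conv = {
      n <- nrow(dy)
      l <- layer$oh * layer$ow
      dz <- dy
      dim(dz) <- c(n * l, layer$filters)
      dW <- crossprod(cache, dz)
      db <- colSums(dz)
      dp <- dz %*% t(layer$W)
      dcols <- matrix(aperm(array(dp, c(n, l, layer$kk)), c(1, 3, 2)),
                      n, layer$kk * l)
      acc <- rowsum(t(dcols), group = layer$idx)
      dx <- matrix(0, n, d_in)
      dx[, as.integer(rownames(acc))] <- t(acc)
      list(dx = dx, dW = dW, db = db)
    }
  )
}

nn_forward <- function(net, x, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(net$layers)) else NULL
  for (i in seq_along(net$layers)) {
    fw <- layer_forward(net$layers[[i]], x)
    if (keep_cache) caches[[i]] <- fw$cache
    x <- fw$out
  }
  list(out = x, caches = caches)
}

# Returns per-layer parameter gradients and (optionally) the gradient with
# respect to the input batch.
nn_backward <- function(net, x, caches, dy, input_grad = FALSE) {
  n_layers <- length(net$layers)
  grads <- vector("list", n_layers)
  widths <- c(ncol(x), vapply(seq_len(n_layers), function(i) {
    ly <- net$layers[[i]]
    if (ly$type == "dense") as.integer(ncol(ly$W))
    else if (ly$type == "conv") as.integer(ly$d_out)
    else NA_integer_
  }, integer(1)))
  # propagate activation widths through shape-preserving layers
  for (i in seq_len(n_layers)) if (is.na(widths[i + 1])) widths[i + 1] <- widths[i]
  for (i in rev(seq_len(n_layers))) {
    bw <- layer_backward(net$layers[[i]], caches[[i]], dy, widths[i])
    grads[[i]] <- bw[c("dW", "db")]
    if (i > 1L || input_grad) dy <- bw$dx
  }
  list(grads = grads, dx = if (input_grad) dy else NULL)
}

# --- optimisers -------------------------------------------------------------

opt_new <- function(net, method = c("adam", "rmsprop", "sgdm"),
                    lr = 2e-4, beta1 = 0.5, beta2 = 0.999, eps = 1e-8,
                    momentum = 0.9, weight_decay = 0) {
  method <- match.arg(method)
  slot <- function(ly) {
    if (!ly$type %in% c("dense", "conv")) return(NULL)
    z <- list(mW = ly$W * 0, mb = ly$b * 0)
    if (method == "adam") {
      z$vW <- z$mW; z$vb <- z$mb
    }
    z
  }
  list(
    method = method, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
    momentum = momentum, weight_decay = weight_decay, t = 0L,
    state = lapply(net$layers, slot)
  )
}

opt_step <- function(net, opt, grads, lr = NULL) {
  lr <- lr %||% opt$lr
  opt$t <- opt$t + 1L
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (!ly$type %in% c("dense", "conv")) next
    g <- grads[[i]]
    if (is.null(g$dW)) next
    gW <- g$dW; gb <- g$db
    if (opt$weight_decay > 0) gW <- gW + opt$weight_decay * ly$W
    st <- opt$state[[i]]
    if (opt$method == "adam") {
      st$mW <- opt$beta1 * st$mW + (1 - opt$beta1) * gW
      st$mb <- opt$beta1 * st$mb + (1 - opt$beta1) * gb
      st$vW <- opt$beta2 * st$vW + (1 - opt$beta2) * gW^2
      st$vb <- opt$beta2 * st$vb + (1 - opt$beta2) * gb^2
      c1 <- 1 - opt$beta1^opt$t
      c2 <- 1 - opt$beta2^opt$t
      ly$W <- ly$W - lr * (st$mW / c1) / (sqrt(st$vW / c2) + opt$eps)
      ly$b <- ly$b - lr * (st$mb / c1) / (sqrt(st$vb / c2) + opt$eps)
    } else if (opt$method == "rmsprop") {
      st$mW <- 0.9 * st$mW + 0.1 * gW^2
      st$mb <- 0.9 * st$mb + 0.1 * gb^2
      ly$W <- ly$W - lr * gW / (sqrt(st$mW) + opt$eps)
      ly$b <- ly$b - lr * gb / (sqrt(st$mb) + opt$eps)
    } else { # sgd with momentum
      st$mW <- opt$momentum * st$mW - lr * gW
      st$mb <- opt$momentum * st$mb - lr * gb
      ly$W <- ly$W + st$mW
      ly$b <- ly$b + st$mb
    }
    opt$state[[i]] <- st
    net$layers[[i]] <- ly
  }
  list(net = net, opt = opt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
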