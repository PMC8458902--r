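# Small conv-net engine with manual backpropagation.
#
# Tensors are numeric arrays in (H, W, C, N) layout; convolution kernels are
# (kh, kw, Cin, Cout). Convolutions run through compiled im2col kernels; all
# other layers are vectorized R. Every layer has a forward returning
# list(out, cache) and a backward returning list(gx, grads). Networks are
# ordered lists of layers; `net_backward()` supports gradient injection at
# intermediate outputs, which is what the multi-level feature loss needs.

as_tensor <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L, 1L))
  if (length(dim(x)) == 3L) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(length(dim(x)) == 4L)
  x
}

he_init <- function(kh, kw, cin, cout, gain = 1) {
  array(rnorm(kh * kw * cin * cout, sd = gain * sqrt(2 / (kh * kw * cin))),
        dim = c(kh, kw, cin, cout))
}

layer_conv <- function(cin, cout, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L,
                       gain = 1) {
  list(type = "conv", stride = as.integer(stride), pad = as.integer(pad),
       params = list(w = he_init(k, k, cin, cout, gain), b = numeric(cout)))
}
layer_inorm   <- function() list(type = "inorm", params = list())
layer_relu    <- function() list(type = "relu", params = list())
layer_lrelu   <- function(alpha = 0.2) list(type = "lrelu", alpha = alpha, params = list())
layer_sigmoid <- function() list(type = "sigmoid", params = list())
layer_up2     <- function() list(type = "up2", params = list())
layer_pool2   <- function() list(type = "pool2", params = list())
layer_gap     <- function() list(type = "gap", params = list())
layer_maxpool2 <- function() list(type = "maxpool2", params = list())
layer_flatten <- function() list(type = "flatten", params = list())
layer_dense   <- function(cin, cout) {
  list(type = "dense",
       params = list(w = matrix(rnorm(cout * cin, sd = sqrt(2 / cin)), cout, cin),
                     b = numeric(cout)))
}
layer_resblock <- function(ch, k = 3L) {
  list(type = "resblock", stride = 1L, pad = (k - 1L) %/% 2L,
       params = list(w1 = he_init(k, k, ch, ch), b1 = numeric(ch),
                     w2 = he_init(k, k, ch, ch), b2 = numeric(ch)))
}

# ---- instance normalization (non-affine), per sample and channel ----

inorm_fwd <- function(x, eps = 1e-5) {
  d <- dim(x); m <- d[1] * d[2]
  xm <- matrix(x, nrow = m)
  mu <- colMeans(xm)
  v <- colMeans(xm * xm) - mu * mu
  s <- sqrt(pmax(v, 0) + eps)
  y <- sweep(sweep(xm, 2, mu, "-"), 2, s, "/")
  list(out = array(y, dim = d), cache = list(y = y, s = s, d = d))
}
inorm_bwd <- function(cache, gy) {
  d <- cache$d; m <- d[1] * d[2]
  g <- matrix(gy, nrow = m)
  y <- cache$y
  gm <- colMeans(g)
  gym <- colMeans(g * y)
  gx <- sweep(sweep(g, 2, gm, "-") - sweep(y, 2, gym, "*"), 2, cache$s, "/")
  array(gx, dim = d)
}

# ---- spatial 2x resampling ----

up2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , , drop = FALSE]
}
up2_bwd <- function(gy) {
  d <- dim(gy)
  io <- seq(1L, d[1], by = 2L); jo <- seq(1L, d[2], by = 2L)
  gy[io, jo, , , drop = FALSE] + gy[io + 1L, jo, , , drop = FALSE] +
    gy[io, jo + 1L, , , drop = FALSE] + gy[io + 1L, jo + 1L, , , drop = FALSE]
}
pool2_fwd <- function(x) up2_bwd(x) / 4
pool2_bwd <- function(gy) up2_fwd(gy) / 4

# 2x2 max pooling; ties route the gradient to the first block in scan order.
maxpool2_fwd <- function(x) {
  d <- dim(x)
  io <- seq(1L, d[1], by = 2L); jo <- seq(1L, d[2], by = 2L)
  blocks <- list(x[io, jo, , , drop = FALSE], x[io + 1L, jo, , , drop = FALSE],
                 x[io, jo + 1L, , , drop = FALSE], x[io + 1L, jo + 1L, , , drop = FALSE])
  y <- pmax(blocks[[1]], blocks[[2]], blocks[[3]], blocks[[4]])
  taken <- array(FALSE, dim(y))
  masks <- vector("list", 4L)
  for (k in 1:4) {
    m <- (blocks[[k]] == y) & !taken
    taken <- taken | m
    masks[[k]] <- m
  }
  list(out = y, cache = masks)
}
maxpool2_bwd <- function(cache, gy) {
  d <- dim(gy)
  gx <- array(0, dim = c(2L * d[1], 2L * d[2], d[3], d[4]))
  io <- seq(1L, 2L * d[1], by = 2L); jo <- seq(1L, 2L * d[2], by = 2L)
  gx[io, jo, , ] <- gy * cache[[1]]
  gx[io + 1L, jo, , ] <- gy * cache[[2]]
  gx[io, jo + 1L, , ] <- gy * cache[[3]]
  gx[io + 1L, jo + 1L, , ] <- gy * cache[[4]]
  gx
}

# ---- single-layer dispatch ----

layer_fwd <- function(layer, x) {
  switch(layer$type,
    conv = {
      y <- .nn_conv_fwd(x, layer$params$w, layer$params$b, layer$stride, layer$pad)
      list(out = y, cache = x)
    },
    inorm = inorm_fwd(x),
    relu = { y <- pmax(x, 0); list(out = y, cache = (x > 0)) },
    lrelu = {
      pos <- x > 0
      y <- x; y[!pos] <- layer$alpha * x[!pos]
      list(out = y, cache = pos)
    },
    sigmoid = { y <- 1 / (1 + exp(-x)); list(out = y, cache = y) },
    up2 = list(out = up2_fwd(x), cache = NULL),
    pool2 = list(out = pool2_fwd(x), cache = NULL),
    maxpool2 = maxpool2_fwd(x),
    flatten = list(out = matrix(x, ncol = dim(x)[4]), cache = dim(x)),
    gap = {
      d <- dim(x)
      y <- matrix(colMeans(matrix(x, nrow = d[1] * d[2])), nrow = d[3])
      list(out = y, cache = d)
    },
    dense = list(out = sweep(layer$params$w %*% x, 1, layer$params$b, "+"), cache = x),
    resblock = {
      c1 <- .nn_conv_fwd(x, layer$params$w1, layer$params$b1, 1L, layer$pad)
      n1 <- inorm_fwd(c1)
      a1 <- pmax(n1$out, 0)
      c2 <- .nn_conv_fwd(a1, layer$params$w2, layer$params$b2, 1L, layer$pad)
      n2 <- inorm_fwd(c2)
      list(out = x + n2$out,
           cache = list(x = x, n1 = n1, mask = n1$out > 0, a1 = a1, n2 = n2))
    },
    stop("unknown layer type: ", layer$type))
}

layer_bwd <- function(layer, cache, gy, need_gx = TRUE) {
  switch(layer$type,
    conv = {
      r <- .nn_conv_bwd(cache, layer$params$w, gy, layer$stride, layer$pad, need_gx)
      list(gx = r$gx, grads = list(w = r$gw, b = r$gb))
    },
    inorm = list(gx = inorm_bwd(cache, gy), grads = list()),
    relu = list(gx = gy * cache, grads = list()),
    lrelu = {
      g <- gy; g[!cache] <- layer$alpha * g[!cache]
      list(gx = g, grads = list())
    },
    sigmoid = list(gx = gy * cache * (1 - cache), grads = list()),
    up2 = list(gx = up2_bwd(gy), grads = list()),
    pool2 = list(gx = pool2_bwd(gy), grads = list()),
    maxpool2 = list(gx = maxpool2_bwd(cache, gy), grads = list()),
    flatten = list(gx = array(gy, dim = cache), grads = list()),
    gap = {
      d <- cache
      g <- array(rep(as.vector(gy), each = d[1] * d[2]) / (d[1] * d[2]), dim = d)
      list(gx = g, grads = list())
    },
    dense = list(gx = if (need_gx) crossprod(layer$params$w, gy) else NULL,
                 grads = list(w = tcrossprod(gy, cache), b = rowSums(gy))),
    resblock = {
      g2 <- inorm_bwd(cache$n2$cache, gy)
      r2 <- .nn_conv_bwd(cache$a1, layer$params$w2, g2, 1L, layer$pad, TRUE)
      ga1 <- r2$gx * cache$mask
      g1 <- inorm_bwd(cache$n1$cache, ga1)
      r1 <- .nn_conv_bwd(cache$x, layer$params$w1, g1, 1L, layer$pad, need_gx)
      gx <- if (need_gx) gy + r1$gx else NULL
      list(gx = gx, grads = list(w1 = r1$gw, b1 = r1$gb, w2 = r2$gw, b2 = r2$gb))
    },
    stop("unknown layer type: ", layer$type))
}

# ---- sequential networks ----

net_forward <- function(net, x, keep = TRUE) {
  caches <- vector("list", length(net))
  outs <- vector("list", length(net))
  for (i in seq_along(net)) {
    r <- layer_fwd(net[[i]], x)
    x <- r$out
    if (keep) { caches[i] <- list(r$cache); outs[[i]] <- x }
  }
  list(out = x, caches = caches, outs = outs)
}

# inject: optional list mapping layer index -> gradient added at that layer's
# output (used for multi-level feature taps). gy may be NULL when all gradient
# enters through injections.
net_backward <- function(net, fwd, gy = NULL, inject = NULL, need_gx = TRUE) {
  grads <- vector("list", length(net))
  g <- gy
  for (i in rev(seq_along(net))) {
    if (!is.null(inject) && !is.null(inject[[as.character(i)]])) {
      g <- if (is.null(g)) inject[[as.character(i)]] else g + inject[[as.character(i)]]
    }
    if (is.null(g)) { grads[[i]] <- list(); next }
    r <- layer_bwd(net[[i]], fwd$caches[[i]], g, need_gx = (need_gx || i > 1L))
    grads[[i]] <- r$grads
    g <- r$gx
  }
  list(gx = g, grads = grads)
}

net_params <- function(net) lapply(net, function(l) l$params)
net_set_params <- function(net, params) {
  for (i in seq_along(net)) net[[i]]$params <- params[[i]]
  net
}

# ---- Adam over nested parameter lists ----

zeros_like <- function(p) rapply(p, function(a) a * 0, how = "replace")

adam_init <- function(params) list(m = zeros_like(params), v = zeros_like(params), t = 0L)

map2_rec <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- map2_rec(a[[i]], b[[i]], f)
    out
  } else f(a, b)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map2_rec(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map2_rec(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g * g)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  upd <- map2_rec(state$m, state$v, function(m, v) (m / bc1) / (sqrt(v / bc2) + eps))
  params <- map2_rec(params, upd, function(p, u) p - lr * u)
  list(params = params, state = state)
}

# ---- losses on raw arrays ----

softmax_ce <- function(logits, labels) {
  # logits: n_classes x N; labels: integer 1..n_classes
  z <- sweep(logits, 2, apply(logits, 2, max), "-")
  ez <- exp(z)
  p <- sweep(ez, 2, colSums(ez), "/")
  n <- ncol(logits)
  idx <- cbind(labels, seq_len(n))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  g <- p
  g[idx] <- g[idx] - 1
  list(loss = loss, grad = g / n, prob = p)
}
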