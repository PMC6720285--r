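# Minimal neural-network engine: dense / conv2d (stride 1, same padding) /
# 2x2 max-pool / nearest-neighbour upsample layers with ReLU-sigmoid
# activations, softmax cross-entropy and MSE losses, and Adam. Sized for the
# small CPU-trainable networks this package ships (supervised CNN, stacked
# auto-encoder, convolutional auto-encoder); gradients are verified
# numerically in the test suite.
#
# Data conventions: dense layers take matrices (n x d); convolutional layers
# take arrays (n, H, W, C). `nn_reshape` converts a day-major flattened
# window matrix into (n, days, slots, 1) image arrays.

nn_dense <- function(n_in, n_out) {
  list(type = "dense", n_in = n_in, n_out = n_out)
}
nn_relu <- function() list(type = "relu")
nn_sigmoid <- function() list(type = "sigmoid")
nn_flatten <- function() list(type = "flatten")
nn_unflatten <- function(h, w, c) list(type = "unflatten", h = h, w = w, c = c)
nn_reshape <- function(h, w, c = 1L) list(type = "reshape", h = h, w = w, c = c)
nn_conv2d <- function(kh, kw, c_in, c_out) {
  stopifnot(kh %% 2 == 1, kw %% 2 == 1)
  list(type = "conv2d", kh = kh, kw = kw, c_in = c_in, c_out = c_out)
}
nn_maxpool2 <- function() list(type = "maxpool2")
nn_upsample2 <- function(out_h = NULL, out_w = NULL)
  list(type = "upsample2", out_h = out_h, out_w = out_w)

# Glorot-uniform initialization of all parametric layers.
nn_network <- function(layers, seed = 1L) {
  set.seed(seed)
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "dense") {
      s <- sqrt(6 / (l$n_in + l$n_out))
      layers[[i]]$W <- matrix(stats::runif(l$n_in * l$n_out, -s, s), l$n_in, l$n_out)
      layers[[i]]$b <- numeric(l$n_out)
    } else if (l$type == "conv2d") {
      fan <- l$kh * l$kw * (l$c_in + l$c_out)
      s <- sqrt(6 / fan)
      layers[[i]]$W <- matrix(stats::runif(l$kh * l$kw * l$c_in * l$c_out, -s, s),
                              l$kh * l$kw * l$c_in, l$c_out)
      layers[[i]]$b <- numeric(l$c_out)
    }
  }
  structure(list(layers = layers), class = "nn_network")
}

.im2col <- function(xp, H, W, kh, kw, C) {
  col <- matrix(0, H * W, kh * kw * C)
  k <- 0L
  for (c in seq_len(C)) for (j in seq_len(kw)) for (i in seq_len(kh)) {
    k <- k + 1L
    col[, k] <- as.vector(xp[i:(i + H - 1L), j:(j + W - 1L), c])
  }
  col
}

.col2im <- function(dcol, H, W, kh, kw, C, Hp, Wp) {
  dxp <- array(0, dim = c(Hp, Wp, C))
  k <- 0L
  for (c in seq_len(C)) for (j in seq_len(kw)) for (i in seq_len(kh)) {
    k <- k + 1L
    dxp[i:(i + H - 1L), j:(j + W - 1L), c] <-
      dxp[i:(i + H - 1L), j:(j + W - 1L), c] + matrix(dcol[, k], H, W)
  }
  dxp
}

.layer_forward <- function(l, x) {
  switch(l$type,
    dense = {
      y <- x %*% l$W
      y <- sweep(y, 2, l$b, `+`)
      list(y = y, cache = x)
    },
    relu = list(y = pmax(x, 0), cache = x > 0),
    sigmoid = {
      y <- 1 / (1 + exp(-x))
      list(y = y, cache = y)
    },
    flatten = {
      d <- dim(x)
      y <- x
      dim(y) <- c(d[1], prod(d[-1]))
      list(y = y, cache = d)
    },
    reshape = {
      n <- nrow(x)
      # per-sample feature layout is row-major over (h, w, c): h slowest
      tmp <- array(as.vector(t(x)), dim = c(l$c, l$w, l$h, n))
      y <- aperm(tmp, c(4, 3, 2, 1))
      list(y = y, cache = dim(x))
    },
    unflatten = {
      # column-major inverse of `flatten` (dim<- based)
      d <- dim(x)
      y <- x
      dim(y) <- c(d[1], l$h, l$w, l$c)
      list(y = y, cache = d)
    },
    conv2d = {
      d <- dim(x); n <- d[1]; H <- d[2]; W <- d[3]
      ph <- (l$kh - 1L) %/% 2L; pw <- (l$kw - 1L) %/% 2L
      y <- array(0, dim = c(n, H, W, l$c_out))
      cols <- vector("list", n)
      for (s in seq_len(n)) {
        xp <- array(0, dim = c(H + 2 * ph, W + 2 * pw, l$c_in))
        xp[ph + seq_len(H), pw + seq_len(W), ] <- x[s, , , ]
        col <- .im2col(xp, H, W, l$kh, l$kw, l$c_in)
        ys <- col %*% l$W
        ys <- sweep(ys, 2, l$b, `+`)
        y[s, , , ] <- array(ys, dim = c(H, W, l$c_out))
        cols[[s]] <- col
      }
      list(y = y, cache = list(cols = cols, dim_in = d))
    },
    maxpool2 = {
      d <- dim(x); n <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
      H2 <- max(1L, H %/% 2L); W2 <- max(1L, W %/% 2L)
      ih <- function(k) pmin(2 * (seq_len(H2) - 1) + k, H)
      iw <- function(k) pmin(2 * (seq_len(W2) - 1) + k, W)
      a <- x[, ih(1), iw(1), , drop = FALSE]
      b <- x[, ih(1), iw(2), , drop = FALSE]
      cc <- x[, ih(2), iw(1), , drop = FALSE]
      dd <- x[, ih(2), iw(2), , drop = FALSE]
      y <- pmax(a, b, cc, dd)
      ma <- a == y; mb <- b == y & !ma
      mc <- cc == y & !ma & !mb; md <- !ma & !mb & !mc
      list(y = y, cache = list(ma = ma, mb = mb, mc = mc, md = md, dim_in = d))
    },
    upsample2 = {
      d <- dim(x); n <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
      oh <- l$out_h %||% (2L * H); ow <- l$out_w %||% (2L * W)
      rh <- pmin(ceiling(seq_len(oh) / 2), H)
      rw <- pmin(ceiling(seq_len(ow) / 2), W)
      y <- x[, rh, rw, , drop = FALSE]
      list(y = y, cache = list(rh = rh, rw = rw, dim_in = d))
    },
    stop("unknown layer type ", l$type))
}

.layer_backward <- function(l, cache, dy) {
  switch(l$type,
    dense = list(dx = dy %*% t(l$W), dW = t(cache) %*% dy, db = colSums(dy)),
    relu = list(dx = dy * cache),
    sigmoid = list(dx = dy * cache * (1 - cache)),
    flatten = { dim(dy) <- cache; list(dx = dy) },
    unflatten = { dim(dy) <- cache; list(dx = dy) },
    reshape = {
      tmp <- aperm(dy, c(4, 3, 2, 1))
      dx <- t(matrix(as.vector(tmp), ncol = cache[1]))
      list(dx = dx)
    },
    conv2d = {
      d <- cache$dim_in; n <- d[1]; H <- d[2]; W <- d[3]
      ph <- (l$kh - 1L) %/% 2L; pw <- (l$kw - 1L) %/% 2L
      dW <- matrix(0, nrow(l$W), ncol(l$W)); db <- numeric(l$c_out)
      dx <- array(0, dim = d)
      for (s in seq_len(n)) {
        dys <- matrix(dy[s, , , ], H * W, l$c_out)
        col <- cache$cols[[s]]
        dW <- dW + t(col) %*% dys
        db <- db + colSums(dys)
        dxp <- .col2im(dys %*% t(l$W), H, W, l$kh, l$kw, l$c_in,
                       H + 2 * ph, W + 2 * pw)
        dx[s, , , ] <- dxp[ph + seq_len(H), pw + seq_len(W), , drop = FALSE]
      }
      list(dx = dx, dW = dW, db = db)
    },
    maxpool2 = {
      d <- cache$dim_in; H <- d[2]; W <- d[3]
      H2 <- max(1L, H %/% 2L); W2 <- max(1L, W %/% 2L)
      dx <- array(0, dim = d)
      ih <- function(k) pmin(2 * (seq_len(H2) - 1) + k, H)
      iw <- function(k) pmin(2 * (seq_len(W2) - 1) + k, W)
      add <- function(m, ri, ci) {
        dx[, ri, ci, ] <<- dx[, ri, ci, , drop = FALSE] + dy * m
      }
      add(cache$ma, ih(1), iw(1)); add(cache$mb, ih(1), iw(2))
      add(cache$mc, ih(2), iw(1)); add(cache$md, ih(2), iw(2))
      list(dx = dx)
    },
    upsample2 = {
      d <- cache$dim_in
      dx <- array(0, dim = d)
      for (i in seq_along(cache$rh)) for (j in seq_along(cache$rw)) {
        dx[, cache$rh[i], cache$rw[j], ] <-
          dx[, cache$rh[i], cache$rw[j], , drop = FALSE] +
          dy[, i, j, , drop = FALSE]
      }
      list(dx = dx)
    },
    stop("unknown layer type ", l$type))
}

nn_forward <- function(net, x, with_cache = FALSE) {
  caches <- if (with_cache) vector("list", length(net$layers)) else NULL
  for (i in seq_along(net$layers)) {
    f <- .layer_forward(net$layers[[i]], x)
    x <- f$y
    if (with_cache) caches[[i]] <- f$cache
  }
  if (with_cache) list(out = x, caches = caches) else x
}

nn_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  dy <- dout
  for (i in rev(seq_along(net$layers))) {
    g <- .layer_backward(net$layers[[i]], caches[[i]], dy)
    dy <- g$dx
    grads[[i]] <- g[c("dW", "db")]
  }
  list(grads = grads, dx = dy)
}

# Losses return list(loss, dout) given network output and target.
.loss_mse <- function(out, target) {
  diff <- out - target
  list(loss = mean(diff^2), dout = 2 * diff / length(diff))
}

.loss_softmax_xent <- function(logits, onehot) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  p <- e / rowSums(e)
  n <- nrow(logits)
  list(loss = -sum(onehot * log(pmax(p, 1e-12))) / n,
       dout = (p - onehot) / n, probs = p)
}

nn_softmax <- function(logits) {
  e <- exp(logits - apply(logits, 1, max))
  e / rowSums(e)
}

.adam_init <- function(net) {
  lapply(net$layers, function(l) {
    if (!is.null(l$W))
      list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
    else NULL
  })
}

.adam_step <- function(net, grads, state, lr, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g) || is.null(g$dW)) next
    st <- state[[i]]
    st$mW <- beta1 * st$mW + (1 - beta1) * g$dW
    st$vW <- beta2 * st$vW + (1 - beta2) * g$dW^2
    st$mb <- beta1 * st$mb + (1 - beta1) * g$db
    st$vb <- beta2 * st$vb + (1 - beta2) * g$db^2
    corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
    net$layers[[i]]$W <- net$layers[[i]]$W -
      lr * (st$mW / corr1) / (sqrt(st$vW / corr2) + eps)
    net$layers[[i]]$b <- net$layers[[i]]$b -
      lr * (st$mb / corr1) / (sqrt(st$vb / corr2) + eps)
    state[[i]] <- st
  }
  list(net = net, state = state)
}

# Mini-batch Adam training. `x` is a matrix or 4D array; `target` a matrix
# (MSE) or one-hot matrix (softmax cross-entropy).
nn_train <- function(net, x, target, loss = c("mse", "xent"), epochs = 20L,
                     batch_size = 32L, lr = 1e-3, seed = 1L) {
  loss <- match.arg(loss)
  lossfun <- if (loss == "mse") .loss_mse else .loss_softmax_xent
  n <- if (is.matrix(x)) nrow(x) else dim(x)[1]
  state <- .adam_init(net)
  set.seed(seed)
  t <- 0L
  take <- function(a, idx) {
    if (is.matrix(a)) a[idx, , drop = FALSE]
    else a[idx, , , , drop = FALSE]
  }
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
      f <- nn_forward(net, take(x, b), with_cache = TRUE)
      l <- lossfun(f$out, take(target, b))
      bk <- nn_backward(net, f$caches, l$dout)
      t <- t + 1L
      upd <- .adam_step(net, bk$grads, state, lr, t)
      net <- upd$net; state <- upd$state
    }
  }
  net
}
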