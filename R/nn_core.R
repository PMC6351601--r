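# Minimal feed-forward network engine: dense, locally connected and
# convolutional layers over a (lag x electrode) grid, batch normalization,
# dropout, additive Gaussian noise, LeakyReLU/ELU/tanh nonlinearities, Adam
# with L2 weight decay, and reverse-mode gradients. All data flows as
# n x features matrices; grid layers carry their own geometry.

nn_seeded_matrix <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

# He (rectifier) or Xavier (tanh/linear output) initialization scale
nn_init_sd <- function(fan_in, fan_out, kind) {
  if (kind == "he") sqrt(2 / fan_in) else sqrt(2 / (fan_in + fan_out))
}

nn_dense <- function(d_in, d_out, init = "he") {
  sd <- nn_init_sd(d_in, d_out, init)
  list(type = "dense", d_in = d_in, d_out = d_out,
       W = nn_seeded_matrix(d_in, d_out, sd), b = numeric(d_out))
}

nn_act <- function(kind, alpha = 0.1) {
  list(type = "act", kind = kind, alpha = alpha)
}

nn_batchnorm <- function(d, momentum = 0.9) {
  list(type = "bn", d = d, gamma = rep(1, d), beta = numeric(d),
       run_mean = numeric(d), run_var = rep(1, d), momentum = momentum,
       eps = 1e-5)
}

nn_dropout <- function(p) list(type = "dropout", p = p)

nn_noise <- function(sd) list(type = "noise", sd = sd)

# grid layers: input columns ordered lag-fastest, then electrode, then channel
# (col = i + (j-1)*H + (c-1)*H*W with i over H lags, j over W electrodes)
nn_grid_offsets <- function(H, W, kh, kw) {
  oi <- seq_len(kh) - 1L - kh %/% 2L
  oj <- seq_len(kw) - 1L - kw %/% 2L
  offs <- expand.grid(di = oi, dj = oj)
  idx <- lapply(seq_len(nrow(offs)), function(o) {
    di <- offs$di[o]; dj <- offs$dj[o]
    pos <- expand.grid(i = seq_len(H), j = seq_len(W))
    si <- pos$i + di; sj <- pos$j + dj
    ok <- si >= 1 & si <= H & sj >= 1 & sj <= W
    src <- ifelse(ok, si + (sj - 1L) * H, NA_integer_)
    src
  })
  list(offsets = offs, src = idx)
}

nn_conv <- function(H, W, c_in, c_out, kh = 5L, kw = 5L) {
  if (kh > H || kw > W) stop("receptive field larger than input grid")
  g <- nn_grid_offsets(H, W, kh, kw)
  fan_in <- kh * kw * c_in
  K <- array(stats::rnorm(kh * kw * c_in * c_out, 0, sqrt(2 / fan_in)),
             dim = c(kh * kw, c_in, c_out))
  list(type = "conv", H = H, W = W, c_in = c_in, c_out = c_out,
       kh = kh, kw = kw, grid = g, K = K, b = numeric(c_out))
}

nn_lcn <- function(H, W, c_in, c_out, kh = 3L, kw = 3L) {
  if (kh > H || kw > W) stop("receptive field larger than input grid")
  g <- nn_grid_offsets(H, W, kh, kw)
  P <- H * W
  fan_in <- kh * kw * c_in
  K <- array(stats::rnorm(kh * kw * c_in * c_out * P, 0, sqrt(2 / fan_in)),
             dim = c(kh * kw, c_in, c_out, P))
  list(type = "lcn", H = H, W = W, c_in = c_in, c_out = c_out,
       kh = kh, kw = kw, grid = g, K = K, b = matrix(0, c_out, P))
}

nn_param_count <- function(layers) {
  sum(vapply(layers, function(l) {
    switch(l$type,
           dense = length(l$W) + length(l$b),
           conv = length(l$K) + length(l$b),
           lcn = length(l$K) + length(l$b),
           bn = length(l$gamma) + length(l$beta),
           0L)
  }, numeric(1)))
}

# ---- forward passes -------------------------------------------------------

nn_forward_layer <- function(l, x, training) {
  cache <- NULL
  out <- switch(l$type,
    dense = x %*% l$W + rep(l$b, each = nrow(x)),
    act = {
      if (l$kind == "leakyrelu") {
        cache <- x
        ifelse(x > 0, x, l$alpha * x)
      } else if (l$kind == "elu") {
        cache <- x
        ifelse(x > 0, x, exp(pmin(x, 30)) - 1)
      } else if (l$kind == "tanh") {
        y <- tanh(x); cache <- y; y
      } else x
    },
    bn = {
      if (training) {
        mu <- colMeans(x)
        xc <- sweep(x, 2, mu)
        v <- colMeans(xc^2)
        inv <- 1 / sqrt(v + l$eps)
        xh <- sweep(xc, 2, inv, "*")
        cache <- list(xh = xh, inv = inv, xc = xc)
        sweep(sweep(xh, 2, l$gamma, "*"), 2, l$beta, "+")
      } else {
        xh <- sweep(sweep(x, 2, l$run_mean), 2,
                    1 / sqrt(l$run_var + l$eps), "*")
        sweep(sweep(xh, 2, l$gamma, "*"), 2, l$beta, "+")
      }
    },
    dropout = {
      if (training && l$p > 0) {
        mask <- matrix(stats::runif(length(x)) >= l$p, nrow(x)) / (1 - l$p)
        cache <- mask
        x * mask
      } else x
    },
    noise = {
      if (training && l$sd > 0) x + stats::rnorm(length(x), 0, l$sd) else x
    },
    conv = nn_conv_forward(l, x),
    lcn = nn_lcn_forward(l, x),
    stop("unknown layer type ", l$type))
  if (l$type %in% c("dense", "conv", "lcn")) cache <- x
  list(out = out, cache = cache)
}

nn_conv_forward <- function(l, x) {
  n <- nrow(x); P <- l$H * l$W
  out <- matrix(rep(rep(l$b, each = P), each = n), n, P * l$c_out)
  for (o in seq_along(l$grid$src)) {
    src <- l$grid$src[[o]]
    ok <- !is.na(src)
    for (ci in seq_len(l$c_in)) {
      xs <- matrix(0, n, P)
      xs[, ok] <- x[, src[ok] + (ci - 1L) * P, drop = FALSE]
      for (co in seq_len(l$c_out)) {
        k <- l$K[o, ci, co]
        if (k != 0) {
          cols <- ((co - 1L) * P + 1L):(co * P)
          out[, cols] <- out[, cols] + xs * k
        }
      }
    }
  }
  out
}

nn_lcn_forward <- function(l, x) {
  n <- nrow(x); P <- l$H * l$W
  out <- matrix(0, n, P * l$c_out)
  for (co in seq_len(l$c_out))
    out[, ((co - 1L) * P + 1L):(co * P)] <- rep(l$b[co, ], each = n)
  for (o in seq_along(l$grid$src)) {
    src <- l$grid$src[[o]]
    ok <- !is.na(src)
    for (ci in seq_len(l$c_in)) {
      xs <- matrix(0, n, P)
      xs[, ok] <- x[, src[ok] + (ci - 1L) * P, drop = FALSE]
      for (co in seq_len(l$c_out)) {
        cols <- ((co - 1L) * P + 1L):(co * P)
        out[, cols] <- out[, cols] + sweep(xs, 2, l$K[o, ci, co, ], "*")
      }
    }
  }
  out
}

# ---- backward passes ------------------------------------------------------

nn_backward_layer <- function(l, dout, cache, training) {
  grads <- NULL
  dx <- switch(l$type,
    dense = {
      grads <- list(W = t(cache) %*% dout, b = colSums(dout))
      dout %*% t(l$W)
    },
    act = {
      if (l$kind == "leakyrelu") dout * ifelse(cache > 0, 1, l$alpha)
      else if (l$kind == "elu") dout * ifelse(cache > 0, 1, exp(pmin(cache, 30)))
      else if (l$kind == "tanh") dout * (1 - cache^2)
      else dout
    },
    bn = {
      if (training) {
        n <- nrow(dout)
        dgamma <- colSums(dout * cache$xh)
        dbeta <- colSums(dout)
        grads <- list(gamma = dgamma, beta = dbeta)
        dxh <- sweep(dout, 2, l$gamma, "*")
        t1 <- sweep(dxh, 2, colMeans(dxh))
        t2 <- sweep(cache$xh, 2, colMeans(dxh * cache$xh), "*")
        sweep(t1 - t2, 2, cache$inv, "*")
      } else {
        sweep(sweep(dout, 2, l$gamma, "*"), 2,
              1 / sqrt(l$run_var + l$eps), "*")
      }
    },
    dropout = if (training && l$p > 0) dout * cache else dout,
    noise = dout,
    conv = {
      r <- nn_conv_backward(l, dout, cache)
      grads <- r$grads
      r$dx
    },
    lcn = {
      r <- nn_lcn_backward(l, dout, cache)
      grads <- r$grads
      r$dx
    },
    dout)
  list(dx = dx, grads = grads)
}

nn_conv_backward <- function(l, dout, x) {
  n <- nrow(x); P <- l$H * l$W
  dK <- array(0, dim = dim(l$K))
  db <- numeric(l$c_out)
  dx <- matrix(0, n, ncol(x))
  for (co in seq_len(l$c_out))
    db[co] <- sum(dout[, ((co - 1L) * P + 1L):(co * P)])
  for (o in seq_along(l$grid$src)) {
    src <- l$grid$src[[o]]
    ok <- !is.na(src)
    for (ci in seq_len(l$c_in)) {
      xs <- matrix(0, n, P)
      xs[, ok] <- x[, src[ok] + (ci - 1L) * P, drop = FALSE]
      for (co in seq_len(l$c_out)) {
        cols <- ((co - 1L) * P + 1L):(co * P)
        dK[o, ci, co] <- sum(xs * dout[, cols])
        dxs <- dout[, cols, drop = FALSE] * l$K[o, ci, co]
        tgt <- src[ok] + (ci - 1L) * P
        dx[, tgt] <- dx[, tgt] + dxs[, ok, drop = FALSE]
      }
    }
  }
  list(grads = list(K = dK, b = db), dx = dx)
}

nn_lcn_backward <- function(l, dout, x) {
  n <- nrow(x); P <- l$H * l$W
  dK <- array(0, dim = dim(l$K))
  db <- matrix(0, l$c_out, P)
  dx <- matrix(0, n, ncol(x))
  for (co in seq_len(l$c_out))
    db[co, ] <- colSums(dout[, ((co - 1L) * P + 1L):(co * P), drop = FALSE])
  for (o in seq_along(l$grid$src)) {
    src <- l$grid$src[[o]]
    ok <- !is.na(src)
    for (ci in seq_len(l$c_in)) {
      xs <- matrix(0, n, P)
      xs[, ok] <- x[, src[ok] + (ci - 1L) * P, drop = FALSE]
      for (co in seq_len(l$c_out)) {
        cols <- ((co - 1L) * P + 1L):(co * P)
        dK[o, ci, co, ] <- colSums(xs * dout[, cols, drop = FALSE])
        dxs <- sweep(dout[, cols, drop = FALSE], 2, l$K[o, ci, co, ], "*")
        tgt <- src[ok] + (ci - 1L) * P
        dx[, tgt] <- dx[, tgt] + dxs[, ok, drop = FALSE]
      }
    }
  }
  list(grads = list(K = dK, b = db), dx = dx)
}

# ---- network-level forward/backward --------------------------------------

nn_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- nn_forward_layer(layers[[i]], x, training)
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

# forward that also refreshes batch-norm running statistics (training step)
nn_forward_train <- function(layers, x) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "bn") {
      mu <- colMeans(x)
      v <- colMeans(sweep(x, 2, mu)^2)
      layers[[i]]$run_mean <- l$momentum * l$run_mean + (1 - l$momentum) * mu
      layers[[i]]$run_var <- l$momentum * l$run_var + (1 - l$momentum) * v
    }
    r <- nn_forward_layer(layers[[i]], x, training = TRUE)
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches, layers = layers)
}

nn_backward <- function(layers, caches, dout, training = TRUE) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- nn_backward_layer(layers[[i]], dout, caches[[i]], training)
    dout <- r$dx
    if (!is.null(r$grads)) grads[[i]] <- r$grads
  }
  list(grads = grads, dx = dout)
}

# ---- Adam optimizer -------------------------------------------------------

nn_adam_init <- function(layers) {
  lapply(layers, function(l) {
    nm <- switch(l$type, dense = c("W", "b"), conv = c("K", "b"),
                 lcn = c("K", "b"), bn = c("gamma", "beta"), NULL)
    if (is.null(nm)) return(NULL)
    st <- lapply(nm, function(p) list(m = l[[p]] * 0, v = l[[p]] * 0))
    names(st) <- nm
    st
  })
}

nn_adam_step <- function(layers, grads, state, lr, t, l2 = 0,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  corr <- sqrt(1 - beta2^t) / (1 - beta1^t)
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (p in names(g)) {
      gr <- g[[p]]
      # L2 penalty on weights only (not biases / batch-norm parameters)
      if (l2 > 0 && p %in% c("W", "K")) gr <- gr + l2 * layers[[i]][[p]]
      st <- state[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * gr
      st$v <- beta2 * st$v + (1 - beta2) * gr^2
      layers[[i]][[p]] <- layers[[i]][[p]] -
        lr * corr * st$m / (sqrt(st$v) + eps)
      state[[i]][[p]] <- st
    }
  }
  list(layers = layers, state = state)
}
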