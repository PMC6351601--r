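# Two-stage deep decoder: a feature-extraction network (FCN, LCN, CNN, or a
# concatenation of FCN with one of the grid networks) followed by a two-layer
# fully connected feature-summation network, trained with a combined
# MSE-minus-Pearson-correlation loss under Adam with a plateau learning-rate
# schedule.

#' Architecture specification for the deep decoder
#'
#' @param extractor_kind one of `"FCN"`, `"LCN"`, `"CNN"`, `"FCN+CNN"`,
#'   `"FCN+LCN"`. Grid extractors (LCN/CNN) keep the full (lag x electrode)
#'   spatial extent — no striding or downsampling — and are flattened only at
#'   their output.
#' @param fcn_widths widths of the fully connected extractor layers.
#' @param grid_filters channels per position for the LCN/CNN extractor layers.
#' @param grid_kernel receptive field (height = lags, width = electrodes); 3x3
#'   for LCN, 5x5 for CNN by default.
#' @param summation_width width of the first feature-summation layer (the
#'   second is the output layer).
#' @param output_dim output dimensionality (128 spectrogram channels or 256
#'   bottleneck codes).
#' @param output_nonlinearity `"identity"` (spectrogram) or `"tanh"`
#'   (bottleneck codes).
#' @return object of class `architecture_spec`.
#' @export
architecture_spec <- function(extractor_kind = c("FCN", "LCN", "CNN",
                                                 "FCN+CNN", "FCN+LCN"),
                              fcn_widths = c(512, 256),
                              grid_filters = c(16, 16),
                              grid_kernel = NULL,
                              summation_width = 256,
                              output_dim = 128,
                              output_nonlinearity = c("identity", "tanh")) {
  extractor_kind <- match.arg(extractor_kind)
  output_nonlinearity <- match.arg(output_nonlinearity)
  if (is.null(grid_kernel))
    grid_kernel <- if (grepl("LCN", extractor_kind)) c(3L, 3L) else c(5L, 5L)
  structure(list(extractor_kind = extractor_kind,
                 fcn_widths = as.integer(fcn_widths),
                 grid_filters = as.integer(grid_filters),
                 grid_kernel = as.integer(grid_kernel),
                 summation_width = as.integer(summation_width),
                 output_dim = as.integer(output_dim),
                 output_nonlinearity = output_nonlinearity),
            class = "architecture_spec")
}

#' Training configuration
#'
#' Defaults mirror the study protocol: batches of 256 frames, Adam at 1e-4
#' halved after four epochs without validation improvement, dropout 0.3, L2
#' penalty 1e-3, 150 epochs.
#'
#' @param batch_size frames per batch.
#' @param lr initial Adam learning rate.
#' @param lr_decay_factor multiplicative decay on plateau.
#' @param lr_patience_epochs epochs without improvement before decay.
#' @param epochs training epochs.
#' @param dropout dropout probability between layers.
#' @param l2 L2 penalty multiplier on layer weights.
#' @param seed integer seed controlling initialization, shuffling and dropout.
#' @return object of class `training_config`.
#' @export
training_config <- function(batch_size = 256, lr = 1e-4,
                            lr_decay_factor = 0.5, lr_patience_epochs = 4,
                            epochs = 150, dropout = 0.3, l2 = 1e-3,
                            seed = 1L) {
  stopifnot(batch_size > 0, lr > 0, lr_decay_factor > 0,
            lr_patience_epochs > 0, epochs > 0, dropout >= 0, dropout < 1,
            l2 >= 0)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 lr_decay_factor = lr_decay_factor,
                 lr_patience_epochs = as.integer(lr_patience_epochs),
                 epochs = as.integer(epochs), dropout = dropout, l2 = l2,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Combined MSE and correlation loss
#'
#' For each sample (row), the mean squared error between target and
#' prediction minus the Pearson correlation across output dimensions; the
#' returned loss is the average over samples. A zero-variance sample (target
#' or prediction constant) contributes a correlation of 0. Perfect
#' predictions of a non-constant target give -1.
#'
#' @param y frames x outputs target matrix.
#' @param y_hat frames x outputs prediction matrix.
#' @return scalar loss.
#' @export
combined_loss <- function(y, y_hat) {
  y <- as.matrix(y); y_hat <- as.matrix(y_hat)
  if (!identical(dim(y), dim(y_hat))) stop("shape mismatch")
  if (ncol(y) < 2) stop("need at least 2 output dimensions per sample")
  mse <- rowMeans((y - y_hat)^2)
  yc <- y - rowMeans(y)
  hc <- y_hat - rowMeans(y_hat)
  num <- rowSums(yc * hc)
  den <- sqrt(rowSums(yc^2) * rowSums(hc^2))
  r <- ifelse(den > 1e-300, num / den, 0)
  mean(mse - r)
}

# gradient of combined_loss with respect to y_hat (same shape)
combined_loss_grad <- function(y, y_hat) {
  n <- nrow(y); d <- ncol(y)
  g_mse <- 2 * (y_hat - y) / d
  yc <- y - rowMeans(y)
  hc <- y_hat - rowMeans(y_hat)
  ny <- sqrt(rowSums(yc^2))
  nh <- sqrt(rowSums(hc^2))
  den <- ny * nh
  ok <- den > 1e-300
  r <- ifelse(ok, rowSums(yc * hc) / den, 0)
  g_cor <- matrix(0, n, d)
  if (any(ok)) {
    g_cor[ok, ] <- yc[ok, , drop = FALSE] / den[ok] -
      hc[ok, , drop = FALSE] * (r[ok] / nh[ok]^2)
  }
  (g_mse - g_cor) / n
}

# map windowed-design columns (electrode-major: e, band, lag) to the grid
# order used by grid layers (lag fastest, then electrode, then band channel)
design_grid_permutation <- function(wd) {
  fi <- wd$feature_index
  L <- wd$lag_count
  els <- unique(fi$electrode)           # already in spatial order
  E <- length(els)
  perm <- integer(nrow(fi))
  for (b in 1:2) {
    band <- c("lf", "hg")[b]
    for (e_i in seq_len(E)) {
      for (l_i in seq_len(L)) {
        col_src <- which(fi$electrode == els[e_i] & fi$band == band &
                           fi$lag == wd$offsets[l_i])
        perm[l_i + (e_i - 1L) * L + (b - 1L) * L * E] <- col_src
      }
    }
  }
  perm
}

#' Build a two-stage reconstruction network
#'
#' The feature extractor is an FCN (flattened input through fully connected
#' layers), an LCN or CNN over the (lag x electrode) grid with the two neural
#' bands as input channels, or the concatenation of an FCN with one grid
#' network. The feature summation stage is a two-layer fully connected
#' network (ELU) ending in the output nonlinearity. LeakyReLU, batch
#' normalization and dropout sit between extractor layers; He initialization
#' for rectified layers, Xavier for the output.
#'
#' @param arch an [architecture_spec()].
#' @param input_shape integer vector `c(lags, electrodes, bands)`.
#' @param dropout dropout probability used between layers.
#' @param seed integer seed for weight initialization.
#' @return object of class `reconstruction_model`.
#' @export
build_model <- function(arch, input_shape, dropout = 0.3, seed = 1L) {
  stopifnot(inherits(arch, "architecture_spec"), length(input_shape) == 3)
  set.seed(seed)
  L <- input_shape[1]; E <- input_shape[2]; B <- input_shape[3]
  d_in <- L * E * B
  kinds <- strsplit(arch$extractor_kind, "+", fixed = TRUE)[[1]]
  paths <- lapply(kinds, function(kind) {
    layers <- list()
    if (kind == "FCN") {
      d <- d_in
      for (wdt in arch$fcn_widths) {
        layers <- c(layers, list(nn_dense(d, wdt, "he"),
                                 nn_batchnorm(wdt),
                                 nn_act("leakyrelu"),
                                 nn_dropout(dropout)))
        d <- wdt
      }
      attr(layers, "d_out") <- d
    } else {
      maker <- if (kind == "LCN") nn_lcn else nn_conv
      c_prev <- B
      for (cf in arch$grid_filters) {
        d_flat <- L * E * cf
        layers <- c(layers, list(
          maker(L, E, c_prev, cf, arch$grid_kernel[1], arch$grid_kernel[2]),
          nn_batchnorm(d_flat),
          nn_act("leakyrelu"),
          nn_dropout(dropout)))
        c_prev <- cf
      }
      attr(layers, "d_out") <- L * E * c_prev
    }
    layers
  })
  d_mid <- sum(vapply(paths, function(p) attr(p, "d_out"), numeric(1)))
  summation <- list(
    nn_dense(d_mid, arch$summation_width, "he"),
    nn_batchnorm(arch$summation_width),
    nn_act("elu"),
    nn_dropout(dropout),
    nn_dense(arch$summation_width, arch$output_dim, "xavier"))
  if (arch$output_nonlinearity == "tanh")
    summation <- c(summation, list(nn_act("tanh")))
  structure(list(arch = arch, input_shape = input_shape,
                 path_kinds = kinds, paths = paths, summation = summation,
                 grid_perm = NULL, init_seed = seed),
            class = "reconstruction_model")
}

#' Number of trainable parameters of a model
#' @param m a `reconstruction_model`.
#' @return integer parameter count (weights, biases, batch-norm affine).
#' @export
model_param_count <- function(m) {
  sum(vapply(m$paths, nn_param_count, numeric(1))) +
    nn_param_count(m$summation)
}

# run the two-stage network; x is n x (L*E*B) in grid order
model_forward <- function(m, x, training = FALSE, train_bn = FALSE) {
  outs <- list(); caches <- list(); layers_upd <- list()
  for (pi in seq_along(m$paths)) {
    r <- if (train_bn) nn_forward_train(m$paths[[pi]], x)
         else nn_forward(m$paths[[pi]], x, training)
    outs[[pi]] <- r$out
    caches[[pi]] <- r$caches
    layers_upd[[pi]] <- if (train_bn) r$layers else m$paths[[pi]]
  }
  mid <- do.call(cbind, outs)
  r2 <- if (train_bn) nn_forward_train(m$summation, mid)
        else nn_forward(m$summation, mid, training)
  if (train_bn) {
    m$paths <- layers_upd
    m$summation <- r2$layers
  }
  list(out = r2$out, mid = mid, path_caches = caches, sum_caches = r2$caches,
       model = m)
}

model_backward <- function(m, fwd, dout) {
  bs <- nn_backward(m$summation, fwd$sum_caches, dout, training = TRUE)
  dmid <- bs$dx
  path_grads <- list()
  dcol <- 0L
  for (pi in seq_along(m$paths)) {
    d_out_p <- attr(m$paths[[pi]], "d_out")
    dpi <- dmid[, (dcol + 1L):(dcol + d_out_p), drop = FALSE]
    dcol <- dcol + d_out_p
    bp <- nn_backward(m$paths[[pi]], fwd$path_caches[[pi]], dpi,
                      training = TRUE)
    path_grads[[pi]] <- bp$grads
  }
  list(sum_grads = bs$grads, path_grads = path_grads)
}

# reorder design-matrix columns into grid order, caching the permutation
model_input <- function(m, X) {
  if (inherits(X, "windowed_design")) {
    perm <- attr(X, "grid_perm")
    if (is.null(perm)) perm <- design_grid_permutation(X)
    X$X[, perm, drop = FALSE]
  } else as.matrix(X)
}

#' Train a reconstruction network
#'
#' Mini-batch Adam on the combined MSE-correlation loss. The validation
#' split is the final fraction of the frames (time-contiguous, no shuffling
#' across the boundary). The learning rate is multiplied by
#' `lr_decay_factor` whenever the validation loss has not improved (by at
#' least 1e-4) for `lr_patience_epochs` consecutive epochs. Fully
#' reproducible given `cfg$seed`.
#'
#' @param m a `reconstruction_model` from [build_model()].
#' @param X a [build_windows()] design (or a plain matrix already in grid
#'   order).
#' @param Y frames x outputs target matrix.
#' @param cfg a [training_config()].
#' @param val_frac fraction of final frames held out for validation.
#' @return the fitted model, with a `history` data.frame (epoch, train_loss,
#'   val_loss, lr) attached.
#' @export
train_model <- function(m, X, Y, cfg = training_config(), val_frac = 0.1) {
  stopifnot(inherits(m, "reconstruction_model"))
  Xg <- model_input(m, X)
  Y <- as.matrix(Y)
  if (nrow(Xg) != nrow(Y)) stop("X and Y must have the same number of frames")
  set.seed(cfg$seed)
  # standardize inputs (the two neural bands live on very different scales)
  in_mean <- colMeans(Xg)
  in_sd <- apply(Xg, 2, stats::sd)
  in_sd[in_sd < 1e-12] <- 1
  m$input_stats <- list(mean = in_mean, sd = in_sd)
  Xg <- sweep(sweep(Xg, 2, in_mean), 2, in_sd, "/")
  n <- nrow(Xg)
  n_val <- max(2L, as.integer(round(val_frac * n)))
  tr <- seq_len(n - n_val)
  va <- (n - n_val + 1L):n
  # warm-start batch-norm running statistics from one pass over the training
  # rows so that evaluation-mode losses are meaningful from epoch 1
  warm <- seq_len(min(length(tr), 2048L))
  set_mom <- function(layers, mom) {
    for (i in seq_along(layers))
      if (layers[[i]]$type == "bn") layers[[i]]$momentum <- mom
    layers
  }
  moms <- lapply(m$paths, function(p) vapply(p, function(l)
    if (l$type == "bn") l$momentum else NA_real_, numeric(1)))
  mom_sum <- vapply(m$summation, function(l)
    if (l$type == "bn") l$momentum else NA_real_, numeric(1))
  for (pi in seq_along(m$paths)) {
    ad <- attr(m$paths[[pi]], "d_out")
    m$paths[[pi]] <- set_mom(m$paths[[pi]], 0)
    attr(m$paths[[pi]], "d_out") <- ad
  }
  m$summation <- set_mom(m$summation, 0)
  m <- model_forward(m, Xg[tr[warm], , drop = FALSE],
                     training = TRUE, train_bn = TRUE)$model
  for (pi in seq_along(m$paths)) {
    ad <- attr(m$paths[[pi]], "d_out")
    for (i in seq_along(m$paths[[pi]]))
      if (m$paths[[pi]][[i]]$type == "bn")
        m$paths[[pi]][[i]]$momentum <- moms[[pi]][i]
    attr(m$paths[[pi]], "d_out") <- ad
  }
  for (i in seq_along(m$summation))
    if (m$summation[[i]]$type == "bn")
      m$summation[[i]]$momentum <- mom_sum[i]
  state <- list(paths = lapply(m$paths, nn_adam_init),
                summation = nn_adam_init(m$summation))
  lr <- cfg$lr
  best_val <- Inf
  stall <- 0L
  t_step <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), lr = numeric())
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(tr)
    n_batch <- ceiling(length(ord) / cfg$batch_size)
    ep_loss <- 0
    for (b in seq_len(n_batch)) {
      idx <- ord[((b - 1L) * cfg$batch_size + 1L):
                   min(b * cfg$batch_size, length(ord))]
      xb <- Xg[idx, , drop = FALSE]
      yb <- Y[idx, , drop = FALSE]
      fwd <- model_forward(m, xb, training = TRUE, train_bn = TRUE)
      m <- fwd$model
      loss_b <- combined_loss(yb, fwd$out)
      if (!is.finite(loss_b))
        stop("NaN/Inf loss at epoch ", ep, ", batch ", b,
             " (lr=", lr, "); check target scaling")
      ep_loss <- ep_loss + loss_b * length(idx)
      dout <- combined_loss_grad(yb, fwd$out)
      grads <- model_backward(m, fwd, dout)
      t_step <- t_step + 1L
      for (pi in seq_along(m$paths)) {
        up <- nn_adam_step(m$paths[[pi]], grads$path_grads[[pi]],
                           state$paths[[pi]], lr, t_step, cfg$l2)
        attr_d <- attr(m$paths[[pi]], "d_out")
        m$paths[[pi]] <- up$layers
        attr(m$paths[[pi]], "d_out") <- attr_d
        state$paths[[pi]] <- up$state
      }
      up <- nn_adam_step(m$summation, grads$sum_grads, state$summation,
                         lr, t_step, cfg$l2)
      m$summation <- up$layers
      state$summation <- up$state
    }
    val_out <- model_forward(m, Xg[va, , drop = FALSE], training = FALSE)$out
    val_loss <- combined_loss(Y[va, , drop = FALSE], val_out)
    history <- rbind(history,
                     data.frame(epoch = ep,
                                train_loss = ep_loss / length(tr),
                                val_loss = val_loss, lr = lr))
    # an epoch "improves" only when it beats the best by a minimum delta
    if (val_loss < best_val - 1e-4) {
      best_val <- val_loss
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$lr_patience_epochs) {
        lr <- lr * cfg$lr_decay_factor
        stall <- 0L
      }
    }
  }
  m$history <- history
  m$trained <- TRUE
  m
}

#' Reconstruct acoustic frames from windowed neural features
#'
#' Forward pass in evaluation mode: dropout off, batch normalization using
#' its running statistics. Deterministic.
#'
#' @param m a trained `reconstruction_model`.
#' @param X a [build_windows()] design or grid-ordered matrix.
#' @return frames x outputs matrix.
#' @export
reconstruct <- function(m, X) {
  stopifnot(inherits(m, "reconstruction_model"))
  Xg <- model_input(m, X)
  if (!is.null(m$input_stats)) {
    Xg <- sweep(sweep(Xg, 2, m$input_stats$mean), 2, m$input_stats$sd, "/")
  }
  model_forward(m, Xg, training = FALSE)$out
}
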