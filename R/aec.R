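# Autoencoder that compresses 516-dimensional normalized vocoder frames to a
# 256-dimensional tanh bottleneck and decodes back. Additive Gaussian noise
# is injected after the bottleneck during training (never at inference) so
# the decoder tolerates the amplitude jitter of neurally reconstructed codes.

#' Train the vocoder-frame autoencoder
#'
#' A fully connected ladder with descending (encoder) and ascending (decoder)
#' widths, LeakyReLU activations except for the tanh bottleneck, trained on
#' mean squared reconstruction error with Adam. Gaussian noise of standard
#' deviation `noise_sd` is added to the bottleneck codes during training
#' only.
#'
#' @param training_frames a `normalized_vocoder` object or a frames x
#'   dimensions matrix of z-scored vocoder parameters.
#' @param noise_sd bottleneck noise standard deviation (>= 0).
#' @param cfg a [training_config()]; `lr` around 1e-3 and a few tens of
#'   epochs suffice for the synthetic corpus.
#' @param widths encoder layer widths ending at the bottleneck; mirrored for
#'   the decoder.
#' @param val_frac final fraction of frames used for validation.
#' @param init `"pca"` (default) initializes the ladder in its linear regime
#'   at the nested principal-component solution — rectifier layers start with
#'   a positive bias shift so they act linearly, the bottleneck feeds tanh
#'   well inside its linear range, and the decoder mirrors the rotations —
#'   which the optimizer then fine-tunes; `"random"` uses He/Xavier draws.
#' @export
train_autoencoder <- function(training_frames, noise_sd = 0.1,
                              cfg = training_config(lr = 5e-4, epochs = 30,
                                                    l2 = 0, batch_size = 128,
                                                    lr_patience_epochs = 8),
                              widths = c(400, 320, 256), val_frac = 0.1,
                              init = c("pca", "random")) {
  init <- match.arg(init)
  if (inherits(training_frames, "normalized_vocoder"))
    training_frames <- training_frames$values
  X <- as.matrix(training_frames)
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  d_in <- ncol(X)
  bdim <- widths[length(widths)]
  set.seed(cfg$seed)
  if (init == "pca") {
    stopifnot(all(diff(widths) <= 0), widths[1] <= d_in)
    sub <- X[seq_len(min(nrow(X), 4000L)), , drop = FALSE]
    sv <- svd(sweep(sub, 2, colMeans(sub)), nu = 0)
    V <- sv$v[, seq_len(widths[1]), drop = FALSE]
    sd_pc <- pmax(sv$d / sqrt(nrow(sub) - 1), 1e-6)[seq_len(widths[1])]
    shift <- 4
    jitter <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, 1e-3), nr, nc)
    encoder <- list()
    d <- d_in
    for (i in seq_along(widths)) {
      w <- widths[i]
      lay <- nn_dense(d, w)
      if (i == 1) {
        # rotate onto whitened principal coordinates (unit variance), then
        # shift so the rectifier operates in its linear branch
        lay$W <- V %*% diag(1 / sd_pc) + jitter(d, w)
        lay$b <- rep(shift, w)
      } else if (i < length(widths)) {
        lay$W <- diag(1, d)[, seq_len(w), drop = FALSE] + jitter(d, w)
        lay$b <- numeric(w)     # the positive shift carries through
      } else {
        # tanh bottleneck: whitened inputs scaled into the linear range
        lay$W <- diag(1, d)[, seq_len(w), drop = FALSE] / 3 + jitter(d, w)
        lay$b <- rep(-shift / 3, w)
      }
      act <- if (i < length(widths)) nn_act("leakyrelu") else nn_act("tanh")
      encoder <- c(encoder, list(lay, act))
      d <- w
    }
    up <- c(rev(widths[-length(widths)]), d_in)
    decoder <- list()
    for (i in seq_along(up)) {
      w <- up[i]
      lay <- nn_dense(d, w)
      if (i == 1) {
        lay$W <- cbind(diag(3, d), matrix(0, d, w - d)) + jitter(d, w)
        lay$b <- rep(shift, w)
      } else if (i < length(up)) {
        lay$W <- rbind(diag(1, d)[, seq_len(min(d, w)), drop = FALSE]) + 0
        if (w > d) lay$W <- cbind(lay$W, matrix(0, d, w - d))
        lay$W <- lay$W + jitter(d, w)
        lay$b <- numeric(w)
      } else {
        Wd <- (diag(sd_pc) %*% t(V))[seq_len(min(d, widths[1])), ,
                                     drop = FALSE]
        lay$W <- rbind(Wd, matrix(0, max(0, d - nrow(Wd)), d_in)) +
          jitter(d, w)
        lay$b <- numeric(d_in)          # set empirically below
      }
      act <- if (i < length(up)) nn_act("leakyrelu") else NULL
      decoder <- c(decoder, if (is.null(act)) list(lay) else list(lay, act))
      d <- w
    }
    # calibrate the output bias so reconstruction means match the data
    out0 <- nn_forward(decoder, nn_forward(encoder, sub)$out)$out
    decoder[[length(decoder)]]$b <- colMeans(sub) - colMeans(out0)
  } else {
    encoder <- list()
    d <- d_in
    for (i in seq_along(widths)) {
      w <- widths[i]
      if (i < length(widths)) {
        encoder <- c(encoder, list(nn_dense(d, w, "he"), nn_batchnorm(w),
                                   nn_act("leakyrelu")))
      } else {
        encoder <- c(encoder, list(nn_dense(d, w, "xavier"), nn_batchnorm(w),
                                   nn_act("tanh")))
      }
      d <- w
    }
    decoder <- list()
    up <- c(rev(widths[-length(widths)]), d_in)
    for (i in seq_along(up)) {
      w <- up[i]
      if (i < length(up)) {
        decoder <- c(decoder, list(nn_dense(d, w, "he"), nn_batchnorm(w),
                                   nn_act("leakyrelu")))
      } else {
        decoder <- c(decoder, list(nn_dense(d, w, "xavier")))
      }
      d <- w
    }
  }
  n <- nrow(X)
  n_val <- max(2L, as.integer(round(val_frac * n)))
  tr <- seq_len(n - n_val)
  va <- (n - n_val + 1L):n
  st_enc <- nn_adam_init(encoder)
  st_dec <- nn_adam_init(decoder)
  lr <- cfg$lr
  best_val <- Inf; stall <- 0L; t_step <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), lr = numeric())
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(tr)
    n_batch <- ceiling(length(ord) / cfg$batch_size)
    ep_loss <- 0
    for (b in seq_len(n_batch)) {
      idx <- ord[((b - 1L) * cfg$batch_size + 1L):
                   min(b * cfg$batch_size, length(ord))]
      xb <- X[idx, , drop = FALSE]
      fe <- nn_forward_train(encoder, xb)
      encoder <- fe$layers
      code <- fe$out
      noise <- if (noise_sd > 0)
        matrix(stats::rnorm(length(code), 0, noise_sd), nrow(code)) else 0
      fd <- nn_forward_train(decoder, code + noise)
      decoder <- fd$layers
      err <- fd$out - xb
      loss_b <- mean(err^2)
      if (!is.finite(loss_b)) stop("NaN loss in autoencoder training")
      ep_loss <- ep_loss + loss_b * length(idx)
      dout <- 2 * err / length(err)
      bd <- nn_backward(decoder, fd$caches, dout, training = TRUE)
      be <- nn_backward(encoder, fe$caches, bd$dx, training = TRUE)
      t_step <- t_step + 1L
      upd <- nn_adam_step(decoder, bd$grads, st_dec, lr, t_step, cfg$l2)
      decoder <- upd$layers; st_dec <- upd$state
      upd <- nn_adam_step(encoder, be$grads, st_enc, lr, t_step, cfg$l2)
      encoder <- upd$layers; st_enc <- upd$state
    }
    fv <- nn_forward(decoder, nn_forward(encoder, X[va, , drop = FALSE])$out)
    val_loss <- mean((fv$out - X[va, , drop = FALSE])^2)
    history <- rbind(history, data.frame(epoch = ep,
                                         train_loss = ep_loss / length(tr),
                                         val_loss = val_loss, lr = lr))
    if (val_loss < best_val - 1e-6) {
      best_val <- val_loss; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$lr_patience_epochs) {
        lr <- lr * cfg$lr_decay_factor
        stall <- 0L
      }
    }
  }
  structure(list(encoder = encoder, decoder = decoder, dim_in = d_in,
                 bottleneck_dim = bdim, noise_sd = noise_sd,
                 history = history),
            class = "autoencoder")
}

#' Encode frames to bottleneck codes
#'
#' Deterministic forward pass through the encoder; every code lies in
#' (-1, 1) by the tanh bottleneck.
#'
#' @param aec an [train_autoencoder()] model.
#' @param frames `normalized_vocoder` or frames x dim matrix.
#' @return frames x bottleneck matrix of class `bottleneck_codes`.
#' @export
aec_encode <- function(aec, frames) {
  stopifnot(inherits(aec, "autoencoder"))
  if (inherits(frames, "normalized_vocoder")) frames <- frames$values
  codes <- nn_forward(aec$encoder, as.matrix(frames))$out
  structure(codes, class = c("bottleneck_codes", class(codes)))
}

#' Decode bottleneck codes back to normalized vocoder frames
#'
#' Deterministic; no noise is injected at inference.
#'
#' @param aec an [train_autoencoder()] model.
#' @param codes frames x bottleneck matrix.
#' @return frames x dim matrix of normalized vocoder parameters.
#' @export
aec_decode <- function(aec, codes) {
  stopifnot(inherits(aec, "autoencoder"))
  nn_forward(aec$decoder, unclass(as.matrix(codes)))$out
}

#' Relative reconstruction error of an autoencoder
#'
#' The norm of the reconstruction residual relative to the norm of the input:
#' `||X - decode(encode(X))||_F / ||X||_F` over a set of frames. (A per-frame
#' mean ratio is ill-conditioned for frames near the corpus mean, whose
#' z-scored norm approaches zero.)
#'
#' @param aec an [train_autoencoder()] model.
#' @param frames `normalized_vocoder` or frames x dim matrix.
#' @return scalar relative error.
#' @export
aec_relative_error <- function(aec, frames) {
  if (inherits(frames, "normalized_vocoder")) frames <- frames$values
  X <- as.matrix(frames)
  R <- aec_decode(aec, aec_encode(aec, X))
  sqrt(sum((X - R)^2) / max(sum(X^2), 1e-12))
}
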