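# Baseline linear stimulus reconstruction: one ridge-regularized
# spatiotemporal filter per output dimension, fitted in closed form.

#' Fit a regularized linear decoder
#'
#' Solves the ridge-regularized least-squares problem mapping windowed neural
#' features to acoustic frames. Features are centered and scaled to unit
#' variance and targets are z-scored per dimension before solving, so the
#' penalty acts evenly across features (the two neural bands live on very
#' different scales) and across output dimensions. `weights` and `bias` are
#' reported on the original scales.
#'
#' @param X a [build_windows()] design or a frames x features matrix.
#' @param Y frames x outputs matrix.
#' @param ridge_lambda nonnegative ridge penalty.
#' @return object of class `linear_decoder` with `weights`
#'   (features x outputs), `bias` (outputs), `ridge_lambda`, and the feature
#'   index when fitted from a windowed design.
#' @export
fit_linear <- function(X, Y, ridge_lambda = 1) {
  fi <- NULL
  if (inherits(X, "windowed_design")) {
    fi <- X$feature_index
    X <- X$X
  }
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have equal row counts")
  if (ridge_lambda < 0) stop("ridge_lambda must be nonnegative")
  xm <- colMeans(X)
  xs <- apply(X, 2, stats::sd)
  xs[xs < 1e-12] <- 1                 # constant columns carry no signal
  Xc <- sweep(sweep(X, 2, xm), 2, xs, "/")
  ym <- colMeans(Y)
  ys <- pmax(apply(Y, 2, stats::sd), 1e-12)
  Yz <- sweep(sweep(Y, 2, ym), 2, ys, "/")
  if (max(abs(Xc)) == 0) stop("degenerate all-zero design")
  if (ridge_lambda > 0 && nrow(Xc) > ncol(Xc)) {
    # overdetermined ridge: symmetric solve of the normal equations
    A <- crossprod(Xc)
    diag(A) <- diag(A) + ridge_lambda
    Wz <- solve(A, crossprod(Xc, Yz))
  } else {
    # SVD path: exact for any lambda and equal to the minimum-norm
    # least-squares solution at lambda = 0
    sv <- svd(Xc)
    keep <- sv$d > max(sv$d) * 1e-12
    if (ridge_lambda == 0 && sum(keep) < ncol(Xc) &&
        nrow(Xc) >= ncol(Xc))
      stop("singular design with lambda = 0")
    dd <- sv$d[keep]
    shrink <- dd / (dd^2 + ridge_lambda)
    Wz <- sv$v[, keep, drop = FALSE] %*%
      (shrink * (t(sv$u[, keep, drop = FALSE]) %*% Yz))
  }
  W <- sweep(Wz / xs, 2, ys, "*")
  bias <- ym - as.numeric(xm %*% W)
  structure(list(weights = W, bias = bias, ridge_lambda = ridge_lambda,
                 feature_index = fi),
            class = "linear_decoder")
}

#' Predict with a linear decoder
#'
#' @param d a `linear_decoder` from [fit_linear()].
#' @param X design matrix or [build_windows()] design with matching features.
#' @return frames x outputs matrix.
#' @export
predict_linear <- function(d, X) {
  stopifnot(inherits(d, "linear_decoder"))
  if (inherits(X, "windowed_design")) X <- X$X
  X <- as.matrix(X)
  if (ncol(X) != nrow(d$weights))
    stop("feature count mismatch: decoder has ", nrow(d$weights),
         ", input has ", ncol(X))
  sweep(X %*% d$weights, 2, d$bias, "+")
}

#' Select the ridge penalty on a validation split
#'
#' Fits the decoder on the first `1 - val_frac` of the frames for each
#' candidate penalty and scores mean squared error on the final
#' time-contiguous fraction.
#'
#' @param X design matrix or [build_windows()] design.
#' @param Y frames x outputs matrix.
#' @param lambdas candidate penalties.
#' @param val_frac validation fraction.
#' @return the selected penalty (scalar).
#' @export
select_ridge_lambda <- function(X, Y, lambdas = 10^seq(-2, 4, by = 1),
                                val_frac = 0.1) {
  if (inherits(X, "windowed_design")) X <- X$X
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  n_val <- max(2L, as.integer(round(val_frac * n)))
  tr <- seq_len(n - n_val)
  va <- (n - n_val + 1L):n
  # one SVD serves the whole penalty path
  xm <- colMeans(X[tr, , drop = FALSE])
  xs <- apply(X[tr, , drop = FALSE], 2, stats::sd)
  xs[xs < 1e-12] <- 1
  Xc <- sweep(sweep(X[tr, , drop = FALSE], 2, xm), 2, xs, "/")
  ym <- colMeans(Y[tr, , drop = FALSE])
  ys <- pmax(apply(Y[tr, , drop = FALSE], 2, stats::sd), 1e-12)
  Yz <- sweep(sweep(Y[tr, , drop = FALSE], 2, ym), 2, ys, "/")
  sv <- svd(Xc)
  keep <- sv$d > max(sv$d) * 1e-12
  UtY <- t(sv$u[, keep, drop = FALSE]) %*% Yz
  Xva <- sweep(sweep(X[va, , drop = FALSE], 2, xm), 2, xs, "/") %*%
    sv$v[, keep, drop = FALSE]
  errs <- vapply(lambdas, function(l) {
    shrink <- sv$d[keep] / (sv$d[keep]^2 + l)
    pred <- Xva %*% (shrink * UtY)
    pred <- sweep(sweep(pred, 2, ys, "*"), 2, ym, "+")
    mean((pred - Y[va, , drop = FALSE])^2)
  }, numeric(1))
  lambdas[which.min(errs)]
}
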