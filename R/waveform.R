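#' Waveform container
#'
#' A lightweight container for a mono audio signal: a numeric sample vector
#' plus its sampling rate in Hz. All audio entering the pipeline (stimuli,
#' vocoder resynthesis, spectrogram inversion output) is carried in this form.
#'
#' @param samples numeric vector of dimensionless amplitudes; must be finite.
#' @param rate sampling rate in samples/s; must be > 0.
#' @return An object of class `waveform` with elements `samples` and `rate`.
#' @export
waveform <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number (Hz)")
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("`samples` must be finite (no NA/NaN/Inf)")
  structure(list(samples = samples, rate = rate), class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param w a `waveform`.
#' @return duration in seconds.
#' @export
wav_duration <- function(w) length(w$samples) / w$rate

as_waveform <- function(x, rate = NULL) {
  if (inherits(x, "waveform")) return(x)
  if (is.null(rate)) stop("`rate` required when input is a bare vector")
  waveform(x, rate)
}

#' Resample a waveform to a new rate
#'
#' Exact Fourier-domain rational resampling: the spectrum is truncated (ideal
#' lowpass, alias-free) or zero-extended and re-synthesized at the new rate.
#' Reflection padding suppresses circular edge ringing; unit DC gain.
#'
#' @param w a `waveform`.
#' @param rate target sampling rate (Hz).
#' @return a `waveform` at `rate`.
#' @export
wav_resample <- function(w, rate) {
  if (w$rate == rate) return(w)
  waveform(fft_resample(w$samples, w$rate, rate), rate)
}

# Fourier-domain rational resampler (vector in, vector out).
fft_resample <- function(x, from, to) {
  if (from == to) return(x)
  n <- length(x)
  r <- rational_ratio(to, from)
  p <- r[1]; q <- r[2]
  pad0 <- min(n, max(64L, as.integer(round(0.02 * n))))
  padL <- as.integer(q * ceiling(pad0 / q))     # start maps to integer sample
  base <- n + padL + pad0
  np <- as.integer(q * ceiling(base / q))
  padR <- np - n - padL
  refl <- function(k) {  # reflection pad of length k (repeats if k > n)
    idx <- rep(c(seq_len(n), rev(seq_len(n))), length.out = k)
    idx
  }
  left <- x[rev(refl(padL))]
  right <- x[refl(padR)]
  xp <- c(left, x, right)
  m <- as.integer(np / q * p)
  X <- stats::fft(xp)
  Y <- complex(m)
  kmax <- min(np %/% 2L, m %/% 2L)   # retained positive-frequency bins
  Y[1] <- X[1]
  if (kmax >= 2) {
    Y[2:kmax] <- X[2:kmax]
    Y[m - (2:kmax) + 2L] <- X[np - (2:kmax) + 2L]
  }
  y <- Re(stats::fft(Y, inverse = TRUE)) / np
  start <- as.integer(padL / q * p)
  n_out <- as.integer(round(n * p / q))
  y[(start + 1L):(start + n_out)]
}

# reduced integer p/q approximating a/b exactly when both are integral
rational_ratio <- function(a, b) {
  g <- function(x, y) if (y == 0) x else g(y, x %% y)
  if (a == round(a) && b == round(b)) {
    d <- g(round(a), round(b))
    c(round(a) / d, round(b) / d)
  } else {
    f <- 10^6
    rational_ratio(round(a * f), round(b * f))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
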