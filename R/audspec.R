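AUD_N_CHANNELS <- 128L
AUD_FRAME_RATE <- 100
AUD_F_MIN <- 180
AUD_CH_PER_OCT <- 24

#' Center frequencies of the cochlear filterbank
#'
#' 128 constant-Q channels equally spaced on a logarithmic frequency axis:
#' 24 channels/octave starting near 180 Hz, spanning ~5.3 octaves (top channel
#' ~7 kHz, inside the Nyquist band of 16 kHz audio).
#'
#' @param n_channels number of channels.
#' @param f_min center frequency of the first channel (Hz).
#' @param channels_per_octave log-spacing density.
#' @return numeric vector of ascending center frequencies (Hz).
#' @export
aud_center_freqs <- function(n_channels = AUD_N_CHANNELS, f_min = AUD_F_MIN,
                             channels_per_octave = AUD_CH_PER_OCT) {
  f_min * 2^((seq_len(n_channels) - 1) / channels_per_octave)
}

#' Auditory spectrogram container
#' @param values time x frequency nonnegative matrix (frames x 128).
#' @param frame_rate frames per second (100).
#' @param center_freqs ascending log-spaced channel center frequencies (Hz).
#' @return object of class `auditory_spectrogram`.
#' @export
auditory_spectrogram <- function(values, frame_rate = AUD_FRAME_RATE,
                                 center_freqs = aud_center_freqs(ncol(values))) {
  values <- as.matrix(values)
  if (ncol(values) != length(center_freqs))
    stop("channel count does not match center_freqs")
  if (any(!is.finite(values))) stop("spectrogram values must be finite")
  if (any(values < -1e-12)) stop("spectrogram values must be nonnegative")
  values[values < 0] <- 0
  if (length(center_freqs) > 1) {
    ratios <- center_freqs[-1] / center_freqs[-length(center_freqs)]
    if (any(abs(ratios / ratios[1] - 1) > 1e-6) || any(diff(center_freqs) <= 0))
      stop("center_freqs must be strictly increasing and log-spaced")
  }
  structure(list(values = values, frame_rate = frame_rate,
                 center_freqs = center_freqs),
            class = "auditory_spectrogram")
}

#' @export
print.auditory_spectrogram <- function(x, ...) {
  cat(sprintf("<auditory_spectrogram> %d frames x %d channels @ %g frames/s\n",
              nrow(x$values), ncol(x$values), x$frame_rate))
  invisible(x)
}

# Gaussian constant-Q magnitude response of channel k over frequencies f (Hz).
# sigma_oct: response std in octaves (default one channel spacing).
aud_channel_response <- function(f, cf, sigma_oct = 1 / AUD_CH_PER_OCT) {
  w <- numeric(length(f))
  pos <- f > 0
  w[pos] <- exp(-0.5 * (log2(f[pos] / cf) / sigma_oct)^2)
  w
}

#' Compute the auditory spectrogram of a waveform
#'
#' A three-stage model of the auditory periphery: (1) a bank of 128 constant-Q
#' filters equally spaced on a log-frequency axis; (2) a hair-cell stage
#' (half-wave rectification, ~2 kHz lowpass, compressive nonlinearity);
#' (3) a lateral inhibitory network realized as a first-order derivative along
#' the spectral axis followed by half-wave rectification. Band envelopes are
#' averaged over 10 ms frames, giving a nonnegative time-frequency matrix at
#' 100 frames/s.
#'
#' @param w a [waveform()] with rate >= 8000 Hz, at least 50 ms long.
#' @param n_channels number of filterbank channels.
#' @param f_min first channel center frequency (Hz).
#' @param channels_per_octave log-frequency channel density.
#' @param compression `"cuberoot"` (default) or `"none"`.
#' @param sigma_oct filter bandwidth (std of the Gaussian log-frequency
#'   response, octaves).
#' @return an [auditory_spectrogram()].
#' @export
compute_auditory_spectrogram <- function(w, n_channels = AUD_N_CHANNELS,
                                         f_min = AUD_F_MIN,
                                         channels_per_octave = AUD_CH_PER_OCT,
                                         compression = c("cuberoot", "none"),
                                         sigma_oct = 1 / channels_per_octave) {
  compression <- match.arg(compression)
  E <- aud_band_envelopes(w, n_channels, f_min, channels_per_octave,
                          compression, sigma_oct)
  # lateral inhibition: first difference along ascending frequency, rectified
  S <- E - cbind(0, E[, -n_channels, drop = FALSE])
  S[S < 0] <- 0
  auditory_spectrogram(S, AUD_FRAME_RATE,
                       aud_center_freqs(n_channels, f_min, channels_per_octave))
}

# Framed, compressed band envelopes before lateral inhibition (frames x
# channels). Shared by the forward model and the inversion's correction step.
aud_band_envelopes <- function(w, n_channels = AUD_N_CHANNELS,
                               f_min = AUD_F_MIN,
                               channels_per_octave = AUD_CH_PER_OCT,
                               compression = "cuberoot",
                               sigma_oct = 1 / channels_per_octave) {
  w <- as_waveform(w)
  if (w$rate < 8000) stop("audspec requires rate >= 8000 Hz")
  n <- length(w$samples)
  if (n < 0.05 * w$rate)
    stop("input too short: need at least 50 ms of audio")
  cfs <- aud_center_freqs(n_channels, f_min, channels_per_octave)
  n_frames <- as.integer(round(n / w$rate * AUD_FRAME_RATE))
  if (n_frames < 1) stop("input too short for one 10 ms frame")
  # frame boundaries in samples (cumulative-sum framing)
  bounds <- round(seq(0, n, length.out = n_frames + 1))
  npad <- stats::nextn(n, c(2, 3, 5))
  X <- stats::fft(c(w$samples, numeric(npad - n)))
  freqs <- c(seq(0, floor(npad / 2)), -seq(ceiling(npad / 2) - 1, 1)) *
    (w$rate / npad)
  lp_len <- max(1L, as.integer(round(w$rate / 2000)))
  E <- matrix(0, n_frames, n_channels)
  for (k in seq_len(n_channels)) {
    if (cfs[k] >= w$rate / 2) next  # channel above Nyquist: no response
    h <- aud_channel_response(abs(freqs), cfs[k], sigma_oct)
    sub <- Re(stats::fft(X * h, inverse = TRUE)) / npad
    sub <- sub[seq_len(n)]
    sub[sub < 0] <- 0                      # hair-cell rectification
    if (lp_len > 1) {                      # ~2 kHz membrane lowpass
      cs <- cumsum(sub)
      sub <- (cs - c(numeric(lp_len), cs[seq_len(n - lp_len)])) / lp_len
    }
    if (compression == "cuberoot") sub <- sub^(1 / 3)
    cs0 <- c(0, cumsum(sub))
    E[, k] <- (cs0[bounds[-1] + 1] - cs0[bounds[-(n_frames + 1)] + 1]) /
      pmax(diff(bounds), 1)
  }
  E
}

# short-time Fourier transform: frames x (win/2 + 1) complex matrix.
# Frame t is centered at sample (t - 0.5) * hop of x (hann window).
stft_mat <- function(x, win, hop) {
  n <- length(x)
  Tn <- max(1L, as.integer(round(n / hop)))
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(win - 1)) / win)
  pad <- win
  xp <- c(numeric(pad), x, numeric(pad + win))
  S <- matrix(0i, Tn, win / 2 + 1)
  for (t in seq_len(Tn)) {
    start <- pad + round((t - 0.5) * hop) - win / 2 + 1
    fr <- stats::fft(xp[start:(start + win - 1)] * w)
    S[t, ] <- fr[seq_len(win / 2 + 1)]
  }
  S
}

istft_mat <- function(S, win, hop, n) {
  Tn <- nrow(S)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(win - 1)) / win)
  pad <- win
  y <- numeric(n + 2 * pad + win)
  norm <- numeric(n + 2 * pad + win)
  for (t in seq_len(Tn)) {
    full <- c(S[t, ], Conj(S[t, seq(win / 2, 2)]))
    fr <- Re(stats::fft(full, inverse = TRUE)) / win
    start <- pad + round((t - 0.5) * hop) - win / 2 + 1
    idx <- start:(start + win - 1)
    y[idx] <- y[idx] + fr * w
    norm[idx] <- norm[idx] + w^2
  }
  (y / pmax(norm, 1e-8))[(pad + 1):(pad + n)]
}

#' Invert an auditory spectrogram to a waveform
#'
#' The spectral-derivative and compression stages of the forward model are
#' undone in closed form (cumulative sum along frequency, then cubing), giving
#' target band envelopes. These are mapped onto a linear-frequency short-time
#' magnitude spectrum through the filterbank responses, and the waveform is
#' recovered by iterative phase retrieval: starting from seeded random phases,
#' the estimate is alternately projected onto the set of signals with the
#' target short-time magnitude and the set of consistent short-time
#' transforms. The phase of the original signal is lost, so the result
#' matches the target in the spectrogram domain, not sample-by-sample; the
#' output is peak-normalized to 0.95.
#'
#' @param s an [auditory_spectrogram()].
#' @param n_iter number of projection iterations (>= 1); more iterations give
#'   a closer spectrogram-domain match.
#' @param seed integer seed for the random phase initialization.
#' @param rate output sampling rate (canonical 16 kHz).
#' @return a [waveform()].
#' @export
invert_auditory_spectrogram <- function(s, n_iter = 200L, seed = 1L,
                                        rate = 16000) {
  stopifnot(inherits(s, "auditory_spectrogram"))
  if (n_iter < 1) stop("n_iter must be >= 1")
  Tn <- nrow(s$values)
  hop0 <- as.integer(round(rate / s$frame_rate))
  n <- Tn * hop0
  if (all(s$values == 0)) return(waveform(numeric(n), rate))
  Sv <- s$values
  nch <- ncol(Sv)
  # Undo lateral inhibition. Where the rectified spectral derivative is
  # positive the rising edge is exact (e_k = e_{k-1} + S_k); where it was
  # rectified to zero the falling edge is unobserved: initially filled with a
  # geometric decay, later replaced by envelopes measured from the running
  # estimate (constrained so rising edges stay exact).
  fill_envelope <- function(Em) {
    En <- matrix(0, Tn, nch)
    En[, 1] <- ifelse(Sv[, 1] > 0, Sv[, 1], Em[, 1])
    for (k in 2:nch) {
      rising <- Sv[, k] > 0
      En[, k] <- ifelse(rising, En[, k - 1] + Sv[, k],
                        pmin(Em[, k], En[, k - 1]))
    }
    En
  }
  decay <- 0.8
  Ec <- matrix(0, Tn, nch)
  Ec[, 1] <- Sv[, 1]
  for (k in 2:nch) {
    rising <- Sv[, k] > 0
    Ec[, k] <- ifelse(rising, Ec[, k - 1] + Sv[, k], Ec[, k - 1] * decay)
  }
  cfs <- s$center_freqs
  win <- 512L
  hop <- hop0 %/% 2L      # 2x temporal oversampling for the phase retrieval
  Tg <- 2L * Tn
  fbin <- seq(0, win / 2) * (rate / win)
  # squared filterbank responses relate STFT power to band envelope power
  W2 <- vapply(cfs, function(cf) aud_channel_response(fbin, cf)^2,
               numeric(length(fbin)))
  rs <- pmax(rowSums(W2), 1e-3)
  upsample_rows <- function(E) {
    tf <- (seq_len(Tn) - 0.5) / Tn
    tg <- (seq_len(Tg) - 0.5) / Tg
    apply(E, 2, function(cl) stats::approx(tf, cl, xout = tg, rule = 2)$y)
  }
  # multiplicative NNLS updates deconvolve channel overlap:
  # find P >= 0 (STFT power) with P %*% W2 ~ A2 (band envelope power)
  deconv <- function(P, A2, n_upd) {
    eps <- 1e-10 * max(A2)
    for (j in seq_len(n_upd)) {
      pred <- P %*% W2
      P <- P * (((A2 + eps) / (pred + eps)) %*% t(W2)) / rep(rs, each = Tg)
    }
    P
  }
  A2 <- upsample_rows(Ec^6)   # envelope power (cube then square)
  P <- deconv((A2 %*% t(W2)) / rep(rs, each = Tg)^2, A2, 40)
  M <- sqrt(pmax(P, 0))
  set.seed(seed)
  phase <- matrix(stats::runif(length(M), -pi, pi), nrow(M), ncol(M))
  x <- istft_mat(M * exp(1i * phase), win, hop, n)
  corr_every <- 25L
  for (it in seq_len(n_iter)) {
    S <- stft_mat(x, win, hop)
    S <- M * S / (Mod(S) + 1e-12)
    x <- istft_mat(S, win, hop, n)
    if (it %% corr_every == 0 && it < n_iter) {
      # measure the estimate through the full forward model and project the
      # measured envelopes onto the set consistent with the target derivative
      E2 <- aud_band_envelopes(waveform(x, rate), nch, cfs[1],
                               AUD_CH_PER_OCT)[seq_len(Tn), , drop = FALSE]
      gam <- sum(Ec * E2) / max(sum(E2^2), 1e-12)
      Ec <- fill_envelope(gam * E2)
      A2 <- upsample_rows(Ec^6)
      P <- deconv(P, A2, 10)
      M <- sqrt(pmax(P, 0))
    }
  }
  peak <- max(abs(x))
  if (peak > 0) x <- x / peak * 0.95
  waveform(x, rate)
}
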