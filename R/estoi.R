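# Extended short-time objective intelligibility (ESTOI).
#
# Both signals are resampled to 10 kHz, silent frames (more than 40 dB below
# the loudest clean frame) are removed from both, and band energies are
# computed in 15 third-octave bands starting at 150 Hz from 512-point FFTs of
# 256-sample hann frames (50% overlap). Spectrotemporal segments of 30 frames
# (384 ms) are then row- and column-normalized and correlated between clean
# and degraded signals; the score is the average segment correlation.

ESTOI_RATE <- 10000
ESTOI_WIN <- 256L
ESTOI_NFFT <- 512L
ESTOI_N_BANDS <- 15L
ESTOI_MIN_FREQ <- 150
ESTOI_SEG_LEN <- 30L
ESTOI_DYN_RANGE <- 40

# third-octave band edges and FFT-bin membership matrix (bins x bands)
estoi_band_matrix <- function() {
  cf <- ESTOI_MIN_FREQ * 2^((seq_len(ESTOI_N_BANDS) - 1) / 3)
  lo <- cf * 2^(-1 / 6)
  hi <- cf * 2^(1 / 6)
  fbin <- (0:(ESTOI_NFFT / 2)) * (ESTOI_RATE / ESTOI_NFFT)
  H <- matrix(0, length(fbin), ESTOI_N_BANDS)
  for (b in seq_len(ESTOI_N_BANDS)) H[fbin >= lo[b] & fbin < hi[b], b] <- 1
  H
}

# frames x bins magnitude spectra (hann window, 50% overlap)
estoi_frames <- function(x) {
  hop <- ESTOI_WIN / 2L
  n_frames <- max(0L, (length(x) - ESTOI_WIN) %/% hop + 1L)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(ESTOI_WIN) - 1) / (ESTOI_WIN - 1))
  out <- matrix(0, n_frames, ESTOI_NFFT / 2 + 1)
  for (t in seq_len(n_frames)) {
    seg <- x[((t - 1) * hop + 1):((t - 1) * hop + ESTOI_WIN)] * w
    out[t, ] <- Mod(stats::fft(c(seg, numeric(ESTOI_NFFT - ESTOI_WIN)))
                    [seq_len(ESTOI_NFFT / 2 + 1)])
  }
  out
}

#' Extended short-time objective intelligibility (ESTOI)
#'
#' Computes the ESTOI score between a clean reference and a degraded (for
#' example neurally reconstructed) version of the same utterance. The measure
#' compares normalized spectrotemporal modulation patterns in third-octave
#' bands over 384 ms segments; it is invariant to global gain and ranges from
#' 0 (unintelligible) to 1 (identical); raw negative values are clamped to 0.
#'
#' @param clean reference [waveform()].
#' @param degraded degraded [waveform()]; trimmed/padded to the reference
#'   length.
#' @return scalar ESTOI score in \[0, 1\].
#' @export
compute_estoi <- function(clean, degraded) {
  clean <- as_waveform(clean)
  degraded <- as_waveform(degraded)
  if (wav_duration(clean) < 1 || wav_duration(degraded) < 1)
    stop("ESTOI requires at least 1 s of audio")
  if (all(clean$samples == 0)) stop("silent clean reference")
  x <- wav_resample(clean, ESTOI_RATE)$samples
  y <- wav_resample(degraded, ESTOI_RATE)$samples
  n <- min(length(x), length(y))
  x <- x[seq_len(n)]; y <- y[seq_len(n)]
  X <- estoi_frames(x)
  Y <- estoi_frames(y)
  # silent-frame removal based on the clean reference frame energies
  fe <- 20 * log10(sqrt(rowSums(X^2)) + 1e-20)
  keep <- fe > (max(fe) - ESTOI_DYN_RANGE)
  if (sum(keep) < ESTOI_SEG_LEN)
    stop("too few audible frames for an ESTOI segment")
  X <- X[keep, , drop = FALSE]
  Y <- Y[keep, , drop = FALSE]
  H <- estoi_band_matrix()
  Xb <- sqrt(X^2 %*% H)   # frames x bands band-energy envelopes
  Yb <- sqrt(Y^2 %*% H)
  N <- ESTOI_SEG_LEN
  n_seg <- nrow(Xb) - N + 1L
  norm_seg <- function(Z) {
    # rows (bands over time), then columns (frames), to zero mean unit norm
    Z <- Z - rowMeans(Z)
    Z <- Z / pmax(sqrt(rowSums(Z^2)), 1e-20)
    Z <- sweep(Z, 2, colMeans(Z))
    sweep(Z, 2, pmax(sqrt(colSums(Z^2)), 1e-20), "/")
  }
  d <- numeric(n_seg)
  for (m in seq_len(n_seg)) {
    A <- norm_seg(t(Xb[m:(m + N - 1L), , drop = FALSE]))
    B <- norm_seg(t(Yb[m:(m + N - 1L), , drop = FALSE]))
    d[m] <- sum(A * B) / N
  }
  max(0, min(1, mean(d)))
}
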