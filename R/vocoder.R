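# Vocoder parameter contract: per 10 ms frame, 513 spectral-envelope bins
# (1024-point FFT at 16 kHz), fundamental frequency (Hz, 0 when unvoiced), a
# binary voiced/unvoiced flag, and one coarse band aperiodicity in [0, 1] —
# 516 parameters per frame in total.

VOC_RATE <- 16000
VOC_FFT <- 1024L
VOC_N_ENV <- 513L
VOC_FRAME_PERIOD <- 0.01
VOC_DIM <- 516L

#' Vocoder frame sequence container
#'
#' @param spectral_envelope frames x 513 nonnegative matrix.
#' @param f0 fundamental frequency per frame (Hz); 0 where unvoiced.
#' @param vuv binary voiced flag per frame.
#' @param band_aperiodicity frames x 1 matrix in \[0, 1\].
#' @param frame_rate frames per second.
#' @return object of class `vocoder_frames`.
#' @export
vocoder_frames <- function(spectral_envelope, f0, vuv, band_aperiodicity,
                           frame_rate = 1 / VOC_FRAME_PERIOD) {
  spectral_envelope <- as.matrix(spectral_envelope)
  band_aperiodicity <- as.matrix(band_aperiodicity)
  Tn <- nrow(spectral_envelope)
  if (ncol(spectral_envelope) != VOC_N_ENV)
    stop("spectral envelope must have ", VOC_N_ENV, " bins")
  if (length(f0) != Tn || length(vuv) != Tn || nrow(band_aperiodicity) != Tn)
    stop("parameter streams must share the frame count")
  if (any(spectral_envelope < 0)) stop("spectral envelope must be nonnegative")
  if (any(band_aperiodicity < -1e-9 | band_aperiodicity > 1 + 1e-9))
    stop("band aperiodicity must lie in [0, 1]")
  if (any((f0 > 0) != (vuv > 0.5)))
    stop("f0 > 0 must coincide with vuv = 1")
  structure(list(spectral_envelope = spectral_envelope,
                 f0 = as.numeric(f0), vuv = as.numeric(vuv),
                 band_aperiodicity = band_aperiodicity,
                 frame_rate = frame_rate),
            class = "vocoder_frames")
}

#' Total flattened parameter dimension of a vocoder frame
#' @param v a [vocoder_frames()] object.
#' @return integer: envelope bins + f0 + vuv + aperiodicity.
#' @export
vocoder_frame_dim <- function(v) {
  ncol(v$spectral_envelope) + 1L + 1L + ncol(v$band_aperiodicity)
}

#' Flatten a vocoder frame sequence to a frames x 516 matrix
#' @param v a [vocoder_frames()] object.
#' @return numeric matrix, columns: 513 envelope bins, f0, vuv, aperiodicity.
#' @export
vocoder_flatten <- function(v) {
  cbind(v$spectral_envelope, v$f0, v$vuv, v$band_aperiodicity)
}

#' Analyze a waveform into vocoder parameters
#'
#' Frame-wise speech analysis at 100 frames/s: fundamental frequency by
#' normalized autocorrelation over 60-400 Hz with parabolic refinement,
#' voicing by periodicity-and-energy gating, spectral envelope as the
#' across-harmonic smoothed short-time magnitude spectrum (1024-point FFT,
#' 513 bins), and one coarse band aperiodicity (1 minus the periodicity
#' strength of the frame).
#'
#' @param w a mono [waveform()]; resampled to 16 kHz if `resample = TRUE`,
#'   otherwise non-16 kHz input is an error.
#' @param resample logical.
#' @return a [vocoder_frames()] object.
#' @export
vocoder_analyze <- function(w, resample = TRUE) {
  w <- as_waveform(w)
  if (w$rate != VOC_RATE) {
    if (!resample) stop("vocoder requires 16 kHz input")
    w <- wav_resample(w, VOC_RATE)
  }
  x <- w$samples
  n <- length(x)
  hop <- as.integer(VOC_RATE * VOC_FRAME_PERIOD)
  Tn <- max(1L, as.integer(round(n / hop)))
  env <- matrix(0, Tn, VOC_N_ENV)
  f0 <- numeric(Tn)
  vuv <- numeric(Tn)
  ap <- numeric(Tn)
  awin <- as.integer(0.04 * VOC_RATE)          # 40 ms pitch window
  swin <- as.integer(0.032 * VOC_RATE)         # 32 ms spectral window
  hann_s <- 0.5 - 0.5 * cos(2 * pi * (0:(swin - 1)) / swin)
  lag_min <- as.integer(floor(VOC_RATE / 400))
  lag_max <- as.integer(ceiling(VOC_RATE / 60))
  # frame energies for the voicing gate
  rms <- numeric(Tn)
  for (t in seq_len(Tn)) {
    ctr <- as.integer(round((t - 0.5) * hop))
    idx <- max(1, ctr - awin %/% 2):min(n, ctr + awin %/% 2)
    rms[t] <- sqrt(mean(x[idx]^2))
  }
  rms_gate <- 0.05 * max(rms)
  for (t in seq_len(Tn)) {
    ctr <- as.integer(round((t - 0.5) * hop))
    # --- pitch: normalized autocorrelation of the mean-removed frame
    idx <- max(1, ctr - awin %/% 2):min(n, ctr + awin %/% 2)
    fr <- x[idx] - mean(x[idx])
    r_max <- 0; lag_best <- 0
    if (length(fr) > lag_max + 2 && sum(fr^2) > 0) {
      npad <- stats::nextn(2 * length(fr), c(2, 3, 5))
      F <- stats::fft(c(fr, numeric(npad - length(fr))))
      ac <- Re(stats::fft(F * Conj(F), inverse = TRUE))[1:(lag_max + 2)] / npad
      acn <- ac / ac[1]
      sub <- acn[(lag_min + 1):(lag_max + 1)]
      i <- which.max(sub)
      r_max <- sub[i]
      lag_best <- lag_min + i - 1L
      # parabolic refinement around the peak
      if (lag_best > lag_min && lag_best < lag_max) {
        y0 <- acn[lag_best]; y1 <- acn[lag_best + 1]; y2 <- acn[lag_best + 2]
        denom <- y0 - 2 * y1 + y2
        if (abs(denom) > 1e-12)
          lag_best <- lag_best + 0.5 * (y0 - y2) / denom
      }
    }
    voiced <- r_max > 0.35 && rms[t] > rms_gate && lag_best > 0
    vuv[t] <- as.numeric(voiced)
    f0[t] <- if (voiced) VOC_RATE / lag_best else 0
    # the autocorrelation peak under-reports periodicity for modulated voiced
    # frames (vibrato, shimmer, formant ringing); the square compensates
    ap[t] <- min(1, max(0, 1 - max(r_max, 0)))^2
    # --- spectral envelope: smoothed short-time magnitude spectrum
    sidx <- (ctr - swin %/% 2):(ctr + swin %/% 2 - 1)
    seg <- numeric(swin)
    ok <- sidx >= 1 & sidx <= n
    seg[ok] <- x[sidx[ok]]
    mag <- Mod(stats::fft(c(seg * hann_s,
                            numeric(VOC_FFT - swin)))[seq_len(VOC_N_ENV)])
    # smooth across roughly one harmonic spacing to strip the fine structure
    bw_hz <- if (voiced) max(80, f0[t]) else 150
    klen <- max(1L, as.integer(round(bw_hz / (VOC_RATE / VOC_FFT))))
    if (klen > 1) {
      kern <- rep(1 / klen, klen)
      mag <- stats::filter(c(rep(mag[1], klen), mag, rep(mag[VOC_N_ENV], klen)),
                           kern, sides = 2)[(klen + 1):(klen + VOC_N_ENV)]
    }
    env[t, ] <- pmax(as.numeric(mag), 0)
  }
  vocoder_frames(env, f0, vuv, matrix(ap, ncol = 1))
}

#' Synthesize a waveform from vocoder parameters
#'
#' Pulse-plus-noise excitation synthesis: voiced frames drive a glottal pulse
#' train at the frame f0 (continuous phase across frames) mixed with white
#' noise according to the band aperiodicity; unvoiced frames are pure noise.
#' Each 20 ms excitation frame is shaped by the frame's spectral envelope in
#' the frequency domain and overlap-added (hann, 50% overlap).
#'
#' @param v a [vocoder_frames()] object.
#' @param seed integer seed for the excitation noise.
#' @return a 16 kHz [waveform()] of matching duration (within one frame).
#' @export
vocoder_synthesize <- function(v, seed = 1L) {
  stopifnot(inherits(v, "vocoder_frames"))
  Tn <- nrow(v$spectral_envelope)
  hop <- as.integer(VOC_RATE / v$frame_rate)
  n <- Tn * hop
  set.seed(seed)
  # continuous-phase excitation at sample resolution
  f0s <- stats::approx(seq_len(Tn), pmax(v$f0, 0), xout = (seq_len(n) - 0.5) / hop,
                       rule = 2)$y
  voiced_s <- stats::approx(seq_len(Tn), v$vuv, xout = (seq_len(n) - 0.5) / hop,
                            rule = 2)$y > 0.5
  ap_s <- stats::approx(seq_len(Tn), v$band_aperiodicity[, 1],
                        xout = (seq_len(n) - 0.5) / hop, rule = 2)$y
  f0s[!voiced_s] <- 0
  ph <- cumsum(pmax(f0s, 0)) / VOC_RATE
  pulses <- c(0, diff(floor(ph))) * sqrt(VOC_RATE / pmax(f0s, 1))
  noise <- stats::rnorm(n)
  exc <- ifelse(voiced_s,
                sqrt(pmax(1 - ap_s, 0)) * pulses + sqrt(pmax(ap_s, 0)) * noise,
                noise)
  # frame-wise envelope shaping with overlap-add; a linear-phase delay keeps
  # the (zero-phase) envelope impulse response inside the FFT buffer
  win <- 2L * hop
  hw <- 0.5 - 0.5 * cos(2 * pi * (0:(win - 1)) / win)
  d <- (VOC_FFT - win) %/% 2L
  off <- VOC_FFT
  y <- numeric(n + 2L * VOC_FFT)
  xp <- c(exc, numeric(win))
  delay_ph <- exp(-2i * pi * (0:(VOC_FFT - 1)) * d / VOC_FFT)
  for (t in seq_len(Tn)) {
    start <- (t - 1L) * hop + 1L
    seg <- xp[start:(start + win - 1)] * hw
    Fx <- stats::fft(c(seg, numeric(VOC_FFT - win)))
    shape <- c(v$spectral_envelope[t, ],
               rev(v$spectral_envelope[t, 2:(VOC_N_ENV - 1)]))
    out <- Re(stats::fft(Fx * shape * delay_ph, inverse = TRUE)) / VOC_FFT
    pos <- off + start - d + (0:(VOC_FFT - 1))
    y[pos] <- y[pos] + out
  }
  y <- y[(off + 1):(off + n)]
  peak <- max(abs(y))
  if (peak > 0) y <- y / peak * 0.5
  waveform(y, VOC_RATE)
}

#' Normalize vocoder frames for network training
#'
#' Builds the frames x 516 conditioning matrix: log spectral envelope, log f0
#' with unvoiced gaps filled by linear interpolation (the vuv column keeps the
#' voicing truth), vuv, and aperiodicity, each dimension z-scored. Statistics
#' are computed from the input unless `stats` (from a training set) is given.
#'
#' @param v a [vocoder_frames()] object.
#' @param stats optional list with `mean` and `sd` vectors of length 516.
#' @return object of class `normalized_vocoder` with elements `values`
#'   (frames x 516) and `stats`.
#' @export
vocoder_normalize <- function(v, stats = NULL) {
  stopifnot(inherits(v, "vocoder_frames"))
  logenv <- log(v$spectral_envelope + 1e-10)
  lf0 <- log(pmax(v$f0, 1e-10))
  voiced <- v$f0 > 0
  if (any(voiced) && !all(voiced)) {
    lf0[!voiced] <- stats::approx(which(voiced), lf0[voiced],
                                  xout = which(!voiced), rule = 2)$y
  } else if (!any(voiced)) {
    lf0[] <- log(100)   # arbitrary reference pitch for fully unvoiced input
  }
  raw <- cbind(logenv, lf0, v$vuv, v$band_aperiodicity)
  if (is.null(stats)) {
    stats <- list(mean = colMeans(raw),
                  sd = pmax(apply(raw, 2, stats::sd), 1e-8))
  }
  values <- sweep(sweep(raw, 2, stats$mean), 2, stats$sd, "/")
  structure(list(values = values, stats = stats, frame_rate = v$frame_rate),
            class = "normalized_vocoder")
}

#' Invert [vocoder_normalize()]
#'
#' @param nv a `normalized_vocoder` object (or a raw frames x 516 matrix plus
#'   `stats`).
#' @param stats normalization statistics; taken from `nv` when absent.
#' @param frame_rate frames per second of the result.
#' @param clamp_z clip z-values to `[-clamp_z, clamp_z]` before inverting the
#'   log transforms. The default is no clipping (exact round trip); when
#'   denormalizing *regressed* parameters a finite clamp (e.g. 5) prevents
#'   stray predictions from exploding through `exp()`.
#' @return a [vocoder_frames()] object.
#' @export
vocoder_denormalize <- function(nv, stats = NULL, frame_rate = 100,
                                clamp_z = Inf) {
  if (inherits(nv, "normalized_vocoder")) {
    values <- nv$values
    if (is.null(stats)) stats <- nv$stats
    frame_rate <- nv$frame_rate
  } else {
    values <- as.matrix(nv)
    if (is.null(stats)) stop("stats required for a bare matrix")
  }
  if (is.finite(clamp_z)) values <- pmin(pmax(values, -clamp_z), clamp_z)
  raw <- sweep(sweep(values, 2, stats$sd, "*"), 2, stats$mean, "+")
  ne <- VOC_N_ENV
  envp <- exp(raw[, seq_len(ne), drop = FALSE]) - 1e-10
  envp[envp < 0] <- 0
  vuv <- as.numeric(raw[, ne + 2] > 0.5)
  f0 <- exp(raw[, ne + 1]) * vuv
  if (is.finite(clamp_z)) f0 <- pmin(pmax(f0, 50), 450) * vuv
  ap <- pmin(pmax(raw[, ne + 3], 0), 1)
  vocoder_frames(envp, f0, vuv, matrix(ap, ncol = 1), frame_rate)
}
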