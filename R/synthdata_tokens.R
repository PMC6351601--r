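# Synthetic speech-like token generation: harmonic-plus-noise source-filter
# synthesis with time-varying pitch and formants. These tokens stand in for
# recorded stories/digits so that every decoder can be trained and evaluated
# without any downloaded corpus.

# second-order resonator (formant) filter; returns filtered signal
biquad_resonator <- function(x, f, bw, rate) {
  r <- exp(-pi * bw / rate)
  th <- 2 * pi * f / rate
  a1 <- -2 * r * cos(th)
  a2 <- r^2
  b0 <- (1 - r) * sqrt(1 - 2 * r * cos(2 * th) + r^2)
  as.numeric(signal::filter(signal::Arma(b = b0, a = c(1, a1, a2)), x))
}

# glottal-ish pulse train with continuous phase for instantaneous f0 (Hz/sample
# vector), spectrally tilted by a leaky integrator
pulse_train <- function(f0_per_sample, rate) {
  ph <- cumsum(f0_per_sample) / rate
  p <- c(0, diff(floor(ph)))          # unit impulse at each cycle boundary
  as.numeric(signal::filter(signal::Arma(b = 1, a = c(1, -0.85)), p))
}

# smooth random trajectory in [lo, hi] (random nodes + cosine interpolation)
smooth_traj <- function(n, lo, hi, n_nodes = 6) {
  nodes <- stats::runif(n_nodes, lo, hi)
  tt <- seq(0, 1, length.out = n_nodes)
  y <- stats::spline(tt, nodes, xout = seq(0, 1, length.out = n))$y
  pmin(pmax(y, lo), hi)
}

#' Generate synthetic speech-like audio tokens
#'
#' Each token is a harmonic-plus-noise utterance at 16 kHz: a sequence of
#' voiced "syllables" (glottal pulse train with a smoothly varying fundamental
#' in 80-250 Hz, shaped by 3 formant resonators with per-syllable targets and
#' a small breathiness component) interleaved with unvoiced fricative-like
#' noise bursts and brief pauses. Tokens are deterministic given `seed`.
#'
#' @param n number of tokens.
#' @param seed integer seed.
#' @param duration_range token duration bounds in seconds.
#' @param rate sampling rate (Hz).
#' @return list of [waveform()] objects.
#' @export
make_speech_tokens <- function(n, seed = 1L, duration_range = c(0.9, 1.4),
                               rate = 16000) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    dur <- stats::runif(1, duration_range[1], duration_range[2])
    ns <- as.integer(round(dur * rate))
    x <- numeric(ns)
    vuv <- logical(ns)
    base_f0 <- stats::runif(1, 95, 210)
    f0_traj <- smooth_traj(ns, max(80, base_f0 * 0.75), min(250, base_f0 * 1.3))
    pos <- 1L
    while (pos < ns) {
      seg_kind <- if (stats::runif(1) < 0.72) "voiced" else
        if (stats::runif(1) < 0.65) "unvoiced" else "pause"
      seg_len <- as.integer(round(stats::runif(1,
        if (seg_kind == "voiced") 0.15 else 0.05,
        if (seg_kind == "voiced") 0.35 else 0.14) * rate))
      idx <- pos:min(pos + seg_len - 1L, ns)
      m <- length(idx)
      if (seg_kind == "voiced" && m > 0.04 * rate) {
        src <- pulse_train(f0_traj[idx], rate)
        F1 <- stats::runif(1, 300, 800)
        F2 <- stats::runif(1, 900, 2200)
        F3 <- stats::runif(1, 2300, 3100)
        seg <- biquad_resonator(src, F1, 90, rate) +
          0.6 * biquad_resonator(src, F2, 120, rate) +
          0.35 * biquad_resonator(src, F3, 160, rate)
        seg <- seg + 0.03 * stats::rnorm(m) * max(abs(seg))
        ramp <- pmin(1, seq_len(m) / (0.015 * rate),
                     rev(seq_len(m)) / (0.015 * rate))
        x[idx] <- seg * ramp
        vuv[idx] <- TRUE
      } else if (seg_kind == "unvoiced" && m > 0.02 * rate) {
        noise <- stats::rnorm(m)
        fc <- stats::runif(1, 2000, 5500)
        seg <- biquad_resonator(noise, fc, 1500, rate)
        ramp <- pmin(1, seq_len(m) / (0.01 * rate),
                     rev(seq_len(m)) / (0.01 * rate))
        x[idx] <- 0.4 * seg * ramp
      }
      pos <- pos + seg_len
    }
    x <- x / max(abs(x), 1e-9) * 0.5
    x <- x + 1e-5 * stats::rnorm(ns)   # tiny sensor-noise floor
    waveform(x, rate)
  })
}

#' Generate a synthetic vowel glide
#'
#' A voiced token whose formants glide through three vowel targets
#' (a - i - u) over the duration, with gentle vibrato and syllabic amplitude
#' modulation. Unlike a sustained vowel, the glide has rich spectrotemporal
#' modulation, which makes modulation-based intelligibility scores such as
#' ESTOI well conditioned; it is the canonical probe for vocoder round trips.
#'
#' @param f0 nominal fundamental frequency (Hz).
#' @param duration seconds.
#' @param rate sampling rate (Hz).
#' @param noise breathiness level relative to peak amplitude.
#' @param seed integer seed.
#' @return a [waveform()].
#' @export
make_vowel_glide <- function(f0 = 120, duration = 1.5, rate = 16000,
                             noise = 0.002, seed = 1L) {
  set.seed(seed)
  ns <- as.integer(round(duration * rate))
  tt <- (seq_len(ns) - 1) / rate
  f0_traj <- f0 * (1 + 0.015 * sin(2 * pi * 5 * tt))
  src <- pulse_train(f0_traj, rate)
  sub <- as.integer(0.06 * rate)      # 60 ms piecewise-constant formants
  nseg <- as.integer(ceiling(ns / sub))
  u <- seq(0, 1, length.out = nseg)
  F1t <- stats::approx(c(0, 0.5, 1), c(750, 300, 350), xout = u)$y
  F2t <- stats::approx(c(0, 0.5, 1), c(1200, 2300, 800), xout = u)$y
  F3t <- stats::approx(c(0, 0.5, 1), c(2600, 3000, 2400), xout = u)$y
  x <- numeric(ns)
  pad <- 400L                          # filter with context: no segment clicks
  for (si in seq_len(nseg)) {
    idx <- ((si - 1L) * sub + 1L):min(si * sub, ns)
    lo <- max(1L, min(idx) - pad)
    seg <- src[lo:min(ns, max(idx) + pad)]
    yy <- biquad_resonator(seg, F1t[si], 90, rate) +
      0.6 * biquad_resonator(seg, F2t[si], 120, rate) +
      0.35 * biquad_resonator(seg, F3t[si], 160, rate)
    x[idx] <- yy[idx - lo + 1L]
  }
  x <- x * (0.7 + 0.3 * sin(2 * pi * 2.5 * tt))
  x <- x + noise * stats::rnorm(ns) * max(abs(x))
  ramp <- pmin(1, seq_len(ns) / (0.02 * rate), rev(seq_len(ns)) / (0.02 * rate))
  waveform(x * ramp / max(abs(x)) * 0.5, rate)
}

#' Generate a sustained synthetic vowel
#'
#' A glottal pulse train at a nominal fundamental, shaped by fixed formant
#' resonators, with natural-sounding modulation (gentle vibrato and a slow
#' syllabic amplitude modulation) and a faint breathiness component; used as
#' a known-pitch probe for vocoder analysis and round-trip scoring.
#'
#' @param f0 nominal fundamental frequency (Hz).
#' @param duration seconds.
#' @param rate sampling rate (Hz).
#' @param formants formant center frequencies (Hz).
#' @param vibrato vibrato depth as a fraction of `f0` (5 Hz rate).
#' @param am_depth depth of the 2.5 Hz amplitude modulation in \[0, 1).
#' @param seed integer seed for the breathiness component.
#' @return a [waveform()].
#' @export
make_vowel <- function(f0 = 120, duration = 1, rate = 16000,
                       formants = c(500, 1500, 2500), vibrato = 0.015,
                       am_depth = 0.4, seed = 1L) {
  set.seed(seed)
  ns <- as.integer(round(duration * rate))
  tt <- (seq_len(ns) - 1) / rate
  f0_traj <- f0 * (1 + vibrato * sin(2 * pi * 5 * tt))
  src <- pulse_train(f0_traj, rate)
  x <- biquad_resonator(src, formants[1], 90, rate)
  if (length(formants) > 1)
    x <- x + 0.6 * biquad_resonator(src, formants[2], 120, rate)
  if (length(formants) > 2)
    x <- x + 0.35 * biquad_resonator(src, formants[3], 160, rate)
  x <- x * (1 - am_depth / 2 + (am_depth / 2) * sin(2 * pi * 2.5 * tt))
  x <- x + 0.01 * stats::rnorm(ns) * max(abs(x))
  ramp <- pmin(1, seq_len(ns) / (0.02 * rate), rev(seq_len(ns)) / (0.02 * rate))
  waveform(x * ramp / max(abs(x)) * 0.5, rate)
}
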