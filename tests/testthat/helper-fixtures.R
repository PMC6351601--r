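# Shared fixtures, built in code and cached for the session.

fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, force(expr), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

# modulated broadband harmonic token: harmonic stack with vibrato, syllabic
# amplitude modulation and a band-noise floor — rich spectrotemporal content
harmonic_token <- function(seed = 42, duration = 1) {
  set.seed(seed)
  rate <- 16000
  n <- round(duration * rate)
  t <- (0:(n - 1)) / rate
  f0 <- 120 + 40 * sin(2 * pi * 1.3 * t)
  ph <- 2 * pi * cumsum(f0) / rate
  x <- numeric(n)
  for (h in 1:40) x <- x + sin(h * ph) * exp(-h / 8)
  x <- x * (0.5 + 0.5 * sin(2 * pi * 2 * t)^2)
  noise <- rnorm(n)
  hp <- noise - stats::filter(noise, rep(1 / 8, 8), sides = 2)
  hp[is.na(hp)] <- 0
  waveform(x / max(abs(x)) * 0.5 + hp * 0.045 * (1 + sin(2 * pi * 1.7 * t + 1)),
           rate)
}

# small decoding dataset reused across decoder tests
small_dataset <- function() {
  cached("small_ds", make_decoding_dataset(
    n_tokens = 6, n_electrodes = 8, noise_sd = 0.05, seed = 3))
}

# mean per-channel correlation between two spectrograms (skips flat channels)
channel_correlation <- function(S_true, S_hat) {
  n <- min(nrow(S_true), nrow(S_hat))
  cc <- vapply(seq_len(ncol(S_true)), function(k) {
    a <- S_true[seq_len(n), k]
    b <- S_hat[seq_len(n), k]
    if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  mean(cc, na.rm = TRUE)
}

# normalized vocoder corpus from generator tokens (pooled statistics)
vocoder_corpus <- function(n_tokens, seed) {
  toks <- make_speech_tokens(n_tokens, seed = seed,
                             duration_range = c(1.0, 1.5))
  raw <- do.call(rbind, lapply(toks, function(w) {
    vocoder_normalize(vocoder_analyze(w),
                      stats = list(mean = rep(0, 516),
                                   sd = rep(1, 516)))$values
  }))
  st <- list(mean = colMeans(raw), sd = pmax(apply(raw, 2, stats::sd), 1e-8))
  sweep(sweep(raw, 2, st$mean), 2, st$sd, "/")
}
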