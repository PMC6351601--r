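# Forward encoding simulator: spectrotemporal receptive fields (STRFs) map
# an auditory spectrogram to two neural feature bands — a signed, smoothed
# low-frequency band and a rectified high-gamma envelope band — with optional
# saturating nonlinearities, per-band gains, trial noise, and a silent
# prelude used for baseline statistics. Each band has its own STRF
# population (the low-frequency signal and the high-gamma envelope reflect
# different neural sources, so the two bands carry complementary stimulus
# information). Ground truth is retained so decoder tests can verify exact
# recovery.

#' Sample ground-truth encoders for a synthetic electrode population
#'
#' Each electrode gets one STRF per neural band: a Gabor-like patch over
#' (lag, frequency channel) — a Gaussian envelope with configurable spectral
#' bandwidth, response latency, and temporal width, optionally multiplied by
#' a cosine carrier along the spectral axis. Center frequencies tile the
#' tonotopic axis (stratified with jitter), with the two bands' centers
#' interleaved so the population covers all spectrogram channels; with
#' `complementary = TRUE` the low-frequency band instead tiles only the
#' lower half of the channels and high gamma the upper half (strictly
#' disjoint information). Nonlinearity is `"identity"` or `"saturating"`
#' (scaled tanh).
#'
#' @param n_electrodes electrode count.
#' @param n_channels spectrogram channels the STRFs act on.
#' @param n_lags STRF lag span in frames (<= 30, i.e. 300 ms).
#' @param nonlinearity `"identity"` or `"saturating"`.
#' @param noise_sd per-band additive Gaussian noise SD (relative to the
#'   typical drive scale; see [simulate_neural()]).
#' @param lf_gain,hg_gain per-band output gains.
#' @param bw_range spectral bandwidth range (channels).
#' @param latency_range response latency range (frames; stays inside a
#'   centered 300 ms decoding window).
#' @param lw_range temporal width range (frames).
#' @param carrier_prob probability that a patch carries a spectral cosine
#'   carrier (classic multi-lobed Gabor); 0 gives unimodal patches.
#' @param sat_scale saturation scale of the `"saturating"` nonlinearity as a
#'   fraction of the drive SD; smaller values saturate harder.
#' @param complementary split the spectrum between the bands.
#' @param seed integer seed.
#' @return object of class `encoder_ground_truth` with per-band STRF lists
#'   `strfs_lf`, `strfs_hg`.
#' @export
make_encoder_ground_truth <- function(n_electrodes, n_channels = 128,
                                      n_lags = 20,
                                      nonlinearity = c("identity",
                                                       "saturating"),
                                      noise_sd = 0.05, lf_gain = 1,
                                      hg_gain = 1,
                                      bw_range = c(0.6, 1.2),
                                      latency_range = c(1, 12),
                                      lw_range = c(0.4, 0.8),
                                      carrier_prob = 0, sat_scale = 0.5,
                                      complementary = FALSE, seed = 1L) {
  nonlinearity <- match.arg(nonlinearity)
  if (n_electrodes < 1) stop("need at least one electrode")
  if (n_lags > 30) stop("STRF lag span must stay within 300 ms (30 frames)")
  set.seed(seed)
  ch <- seq_len(n_channels)
  lg <- seq_len(n_lags)
  patch <- function(c0) {
    bw <- stats::runif(1, bw_range[1], bw_range[2])
    l0 <- stats::runif(1, latency_range[1], latency_range[2])
    lw <- stats::runif(1, lw_range[1], lw_range[2])
    fshape <- exp(-0.5 * ((ch - c0) / bw)^2)
    if (stats::runif(1) < carrier_prob)
      fshape <- fshape * cos(2 * pi * (ch - c0) / stats::runif(1, 8, 40) +
                               stats::runif(1, 0, 2 * pi))
    s <- outer(exp(-0.5 * ((lg - l0) / lw)^2), fshape)
    s / sqrt(sum(s^2))
  }
  spc <- n_channels / n_electrodes
  if (complementary) {
    # strictly disjoint information: lf tiles odd channels, hg even ones,
    # with tuning narrowed so neighboring-channel leakage is negligible
    bw_range <- pmin(bw_range, 0.5)
    lf_centers <- seq(1, n_channels - 1, length.out = n_electrodes)
    lf_centers <- 2 * round((lf_centers + 1) / 2) - 1
    hg_centers <- pmin(lf_centers + 1, n_channels)
  } else {
    lf_centers <- spc * (seq_len(n_electrodes) - 1) + 1 +
      stats::runif(n_electrodes, -0.4, 0.4)
    hg_centers <- spc * (seq_len(n_electrodes) - 1) + 1 + spc / 2 +
      stats::runif(n_electrodes, -0.4, 0.4)
  }
  clamp <- function(x) pmin(pmax(x, 1), n_channels)
  structure(list(strfs_lf = lapply(clamp(lf_centers), patch),
                 strfs_hg = lapply(clamp(hg_centers), patch),
                 nonlinearity = nonlinearity, sat_scale = sat_scale,
                 noise_sd = noise_sd, lf_gain = lf_gain, hg_gain = hg_gain,
                 n_lags = n_lags, n_channels = n_channels,
                 complementary = complementary, seed = seed),
            class = "encoder_ground_truth")
}

# causal STRF drive: d[t] = sum_{lag, ch} strf[lag, ch] * S[t - lag + 1, ch]
strf_drive <- function(S, strf) {
  Tn <- nrow(S)
  n_lags <- nrow(strf)
  d <- numeric(Tn)
  for (l in seq_len(n_lags)) {
    proj <- as.numeric(S %*% strf[l, ])
    if (l == 1) d <- d + proj
    else d[l:Tn] <- d[l:Tn] + proj[1:(Tn - l + 1)]
  }
  d
}

#' Simulate two-band neural responses to an auditory spectrogram
#'
#' Per electrode and band, the stimulus drive is the causal STRF convolution
#' of the spectrogram. The low-frequency band is `lf_gain * f(drive_lf)`
#' smoothed by a short moving average (signed); the high-gamma band is
#' `hg_gain * max(f(drive_hg), 0)` (rectified, nonnegative before
#' normalization), where `f` is the electrode nonlinearity. Independent
#' Gaussian noise of SD `noise_sd * sd(drive)` is added per band, and a
#' silent prelude (noise only) is prepended for baseline statistics. With
#' `normalize = TRUE` the hg band is z-scored against the prelude, mirroring
#' the silence normalization applied to recordings.
#'
#' @param spec an [auditory_spectrogram()].
#' @param g an [make_encoder_ground_truth()] object.
#' @param prelude_s silent prelude duration in seconds (default 12).
#' @param lf_smooth_frames moving-average length for the lf band (frames);
#'   0 or 1 disables smoothing.
#' @param normalize z-score hg against the prelude and drop the prelude from
#'   the returned features.
#' @param seed integer seed for the trial noise.
#' @return a list with `features` (a [neural_features()] aligned to the
#'   stimulus frames), `prelude_frames`, and `drive_lf`/`drive_hg`
#'   (electrodes x frames noiseless drive matrices, for oracle checks).
#' @export
simulate_neural <- function(spec, g, prelude_s = 12, lf_smooth_frames = 3,
                            normalize = TRUE, seed = 1L) {
  stopifnot(inherits(spec, "auditory_spectrogram"),
            inherits(g, "encoder_ground_truth"))
  if (!length(g$strfs_lf)) stop("empty electrode set")
  if (ncol(spec$values) != g$n_channels)
    stop("spectrogram channel count does not match the encoders")
  set.seed(seed)
  Tn <- nrow(spec$values)
  P <- as.integer(round(prelude_s * spec$frame_rate))
  n_el <- length(g$strfs_lf)
  lf <- matrix(0, n_el, P + Tn)
  hg <- matrix(0, n_el, P + Tn)
  drive_lf <- matrix(0, n_el, Tn)
  drive_hg <- matrix(0, n_el, Tn)
  scale_ref <- 0
  for (e in seq_len(n_el)) {
    dl <- strf_drive(spec$values, g$strfs_lf[[e]])
    dh <- strf_drive(spec$values, g$strfs_hg[[e]])
    drive_lf[e, ] <- dl
    drive_hg[e, ] <- dh
    f <- if (g$nonlinearity == "saturating") {
      a <- max(stats::sd(dl) * (g$sat_scale %||% 0.5), 1e-12)
      function(x, s = a) s * tanh(x / s)
    } else function(x) x
    lf_resp <- g$lf_gain * f(dl)
    hg_resp <- g$hg_gain * pmax(f(dh), 0)
    if (lf_smooth_frames > 1) {
      k <- rep(1 / lf_smooth_frames, lf_smooth_frames)
      pad <- stats::filter(c(rep(0, lf_smooth_frames), lf_resp,
                             rep(0, lf_smooth_frames)), k, sides = 2)
      lf_resp <- as.numeric(pad[(lf_smooth_frames + 1):
                                  (lf_smooth_frames + Tn)])
    }
    lf[e, ] <- c(numeric(P), lf_resp)
    hg[e, ] <- c(numeric(P), hg_resp)
    scale_ref <- scale_ref + stats::sd(dl) / n_el
  }
  if (g$noise_sd > 0) {
    nsd <- g$noise_sd * max(scale_ref, 1e-12)
    lf <- lf + matrix(stats::rnorm(length(lf), 0, nsd), n_el)
    hg <- hg + matrix(stats::rnorm(length(hg), 0, nsd), n_el)
  }
  if (normalize && P >= 10 && g$noise_sd > 0) {
    for (e in seq_len(n_el)) {
      mu <- mean(hg[e, seq_len(P)])
      sd_e <- stats::sd(hg[e, seq_len(P)])
      hg[e, ] <- (hg[e, ] - mu) / sd_e
    }
  }
  keep <- (P + 1L):(P + Tn)
  feats <- neural_features(lf[, keep, drop = FALSE],
                           hg[, keep, drop = FALSE])
  list(features = feats, prelude_frames = P,
       drive_lf = drive_lf, drive_hg = drive_hg)
}

#' Render a raw multichannel recording from simulated band features
#'
#' Upsamples the lf band to the target rate and adds a high-gamma carrier
#' (a 110 Hz tone plus band noise) scaled by the hg band, plus broadband
#' sensor noise — producing a [neural_recording()] whose band extraction
#' approximately recovers the simulated features. The silent prelude serves
#' as the recording's silence span.
#'
#' @param sim result of [simulate_neural()] with `normalize = FALSE`.
#' @param rate output sampling rate (Hz, >= 500).
#' @param spec_frame_rate frame rate of the simulated features.
#' @param noise_uv broadband sensor noise SD.
#' @param seed integer seed.
#' @return a [neural_recording()].
#' @export
render_neural_recording <- function(sim, rate = 1000, spec_frame_rate = 100,
                                    noise_uv = 0.05, seed = 1L) {
  set.seed(seed)
  P <- sim$prelude_frames
  lf <- sim$features$lf
  hg <- sim$features$hg
  n_el <- nrow(lf)
  total_frames <- P + ncol(lf)
  n <- as.integer(total_frames / spec_frame_rate * rate)
  sig <- matrix(0, n_el, n)
  tt <- (seq_len(n) - 0.5) / rate
  for (e in seq_len(n_el)) {
    fr_full <- c(numeric(P), lf[e, ])
    lf_s <- stats::approx((seq_len(total_frames) - 0.5) / spec_frame_rate,
                          fr_full, xout = tt, rule = 2)$y
    hg_full <- c(numeric(P), pmax(hg[e, ], 0))
    hg_s <- stats::approx((seq_len(total_frames) - 0.5) / spec_frame_rate,
                          hg_full, xout = tt, rule = 2)$y
    carrier <- sin(2 * pi * 110 * tt + stats::runif(1, 0, 2 * pi)) +
      0.3 * stats::rnorm(n)
    sig[e, ] <- lf_s + 0.5 * hg_s * carrier + noise_uv * stats::rnorm(n)
  }
  neural_recording(sig, rate,
                   silence_span = c(1L, as.integer(P / spec_frame_rate * rate)))
}
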