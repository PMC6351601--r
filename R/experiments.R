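# Experiment orchestration on synthetic data: dataset assembly, the four
# model x target comparisons, neural-band ablation, and electrode-count /
# training-duration curves. Every run is reproducible from a master seed and
# every score row records its condition and seed.

#' Assemble a synthetic decoding dataset
#'
#' Generates speech-like tokens, concatenates them into one stimulus,
#' computes the auditory spectrogram and vocoder targets, simulates two-band
#' neural responses through ground-truth STRF encoders, and windows the
#' neural features. Token boundaries are retained so train/test splits stay
#' token-aligned.
#'
#' @param n_tokens number of speech tokens.
#' @param n_electrodes simulated electrode count.
#' @param nonlinearity encoder nonlinearity (`"identity"` or `"saturating"`).
#' @param noise_sd neural noise SD.
#' @param complementary disjoint lf/hg STRF populations (band-ablation
#'   datasets).
#' @param duration_range token duration bounds (s).
#' @param seed master seed (tokens, encoders, noise).
#' @param ... further arguments passed to [make_encoder_ground_truth()]
#'   (e.g. `carrier_prob`, `sat_scale`, `bw_range`).
#' @return a list of class `decoding_dataset` with the stimulus waveform,
#'   spectrogram, vocoder frames, neural features, windowed design, token
#'   frame spans and the ground truth.
#' @export
make_decoding_dataset <- function(n_tokens = 12, n_electrodes = 24,
                                  nonlinearity = "identity", noise_sd = 0.05,
                                  complementary = FALSE,
                                  duration_range = c(0.9, 1.4), seed = 1L,
                                  ...) {
  toks <- make_speech_tokens(n_tokens, seed = seed,
                             duration_range = duration_range)
  samples <- unlist(lapply(toks, `[[`, "samples"))
  stim <- waveform(samples, 16000)
  spec <- compute_auditory_spectrogram(stim)
  voc <- vocoder_analyze(stim)
  g <- make_encoder_ground_truth(n_electrodes,
                                 nonlinearity = nonlinearity,
                                 noise_sd = noise_sd,
                                 complementary = complementary,
                                 seed = seed + 1L, ...)
  sim <- simulate_neural(spec, g, seed = seed + 2L)
  feats <- sim$features
  n_frames <- min(ncol(feats$lf), nrow(spec$values), length(voc$f0))
  feats <- neural_features(feats$lf[, seq_len(n_frames), drop = FALSE],
                           feats$hg[, seq_len(n_frames), drop = FALSE],
                           feats$layout)
  # token frame spans (for token-aligned splits)
  durs <- vapply(toks, wav_duration, numeric(1))
  ends <- pmin(round(cumsum(durs) * 100), n_frames)
  starts <- c(1, head(ends, -1) + 1)
  structure(list(stimulus = stim, tokens = toks, spectrogram = spec,
                 vocoder = voc, features = feats, ground_truth = g,
                 token_spans = data.frame(start = starts, end = ends),
                 n_frames = n_frames, seed = seed),
            class = "decoding_dataset")
}

# frames of the final `n_test` tokens (test split); remainder is training
dataset_split <- function(ds, n_test = 2L) {
  n_tok <- nrow(ds$token_spans)
  te_tok <- (n_tok - n_test + 1L):n_tok
  te <- unlist(lapply(te_tok, function(i)
    ds$token_spans$start[i]:ds$token_spans$end[i]))
  tr <- setdiff(seq_len(ds$n_frames), te)
  list(train = tr, test = te, test_tokens = te_tok)
}

#' Mean reconstruction correlation between two spectrograms
#'
#' `by = "channel"` correlates each frequency channel's time course and
#' averages over channels (sensitive to temporal tracking, the quantity a
#' mean-squared-error fit optimizes); `by = "frame"` correlates each frame's
#' spectral profile across channels and averages over frames (the
#' correlation the combined training loss itself targets, sample-wise).
#' Degenerate (constant) rows/columns are skipped.
#'
#' @param S_true,S_hat frames x channels matrices (rows beyond the shorter
#'   matrix are ignored).
#' @param by `"channel"` or `"frame"`.
#' @return scalar mean correlation.
#' @export
reconstruction_correlation <- function(S_true, S_hat,
                                       by = c("channel", "frame")) {
  by <- match.arg(by)
  n <- min(nrow(S_true), nrow(S_hat))
  S_true <- S_true[seq_len(n), , drop = FALSE]
  S_hat <- S_hat[seq_len(n), , drop = FALSE]
  if (by == "frame") {
    S_true <- t(S_true)
    S_hat <- t(S_hat)
  }
  cc <- vapply(seq_len(ncol(S_true)), function(k) {
    a <- S_true[, k]; b <- S_hat[, k]
    if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  mean(cc, na.rm = TRUE)
}

# mean per-channel correlation (the historical default used by the curves)
spectrogram_correlation <- function(S_true, S_hat) {
  reconstruction_correlation(S_true, S_hat, by = "channel")
}

# nonnegative clamp for predicted spectrograms
clamp_spec <- function(M) { M[M < 0] <- 0; M }

# score a predicted spectrogram against the true one: channel correlation or
# ESTOI of the inverted waveforms against the clean stimulus
score_reconstruction <- function(ds, te, S_hat, metric, invert_iter = 30L,
                                 seed = 1L) {
  S_true <- ds$spectrogram$values[te, , drop = FALSE]
  if (metric == "correlation")
    return(spectrogram_correlation(S_true, S_hat))
  wa <- invert_auditory_spectrogram(
    auditory_spectrogram(clamp_spec(S_hat)), n_iter = invert_iter, seed = seed)
  clean <- waveform(ds$stimulus$samples[
    ((te[1] - 1) * 160 + 1):min(length(ds$stimulus$samples),
                                te[length(te)] * 160)], 16000)
  compute_estoi(clean, wa)
}

# band-restricted copy of a windowed design (zero out the other band)
restrict_band <- function(wd, bands) {
  drop_cols <- which(!(wd$feature_index$band %in% bands))
  if (length(drop_cols)) wd$X[, drop_cols] <- 0
  wd
}

#' Run the four model-by-target comparison
#'
#' Trains and evaluates \{linear, DNN\} x \{auditory spectrogram,
#' autoencoder bottleneck -> vocoder\} on one synthetic dataset, renders
#' audio for each condition (spectrogram inversion or vocoder synthesis) and
#' scores it with ESTOI against the clean stimulus; also reports per-vocoder-
#' parameter correlations (envelope, f0, aperiodicity, vuv) for the vocoder
#' path.
#'
#' @param ds a [make_decoding_dataset()].
#' @param seeds integer vector of training seeds.
#' @param cfg a [training_config()] for the deep spectrogram model
#'   (desk-scale epochs).
#' @param cfg_voc a [training_config()] for the deep vocoder-code model;
#'   defaults to `cfg` (the code target typically needs more epochs).
#' @param arch_spec,arch_voc [architecture_spec()]s for the two targets;
#'   desk-scale FCN extractors by default.
#' @param aec a pre-trained [train_autoencoder()]; trained on the dataset's
#'   vocoder frames when `NULL`.
#' @param invert_iter spectrogram-inversion iterations for audio rendering.
#' @param n_test_tokens tokens held out for evaluation.
#' @return list of class `experiment_report`: `scores` (condition, seed,
#'   estoi), `vocoder_param_cor`, `configs`.
#' @export
run_four_models <- function(ds, seeds = 1:3,
                            cfg = training_config(lr = 2e-3, epochs = 15,
                                                  dropout = 0.2),
                            cfg_voc = cfg,
                            arch_spec = NULL, arch_voc = NULL, aec = NULL,
                            invert_iter = 30L, n_test_tokens = 2L) {
  stopifnot(inherits(ds, "decoding_dataset"))
  sp <- dataset_split(ds, n_test_tokens)
  wd <- build_windows(ds$features)
  n_el <- nrow(ds$features$lf)
  shape <- c(wd$lag_count, n_el, 2L)
  Y_spec <- ds$spectrogram$values[seq_len(ds$n_frames), , drop = FALSE]
  nv <- vocoder_normalize(subset_vocoder(ds$vocoder, seq_len(ds$n_frames)))
  if (is.null(aec))
    aec <- train_autoencoder(nv$values[sp$train, , drop = FALSE],
                             cfg = training_config(lr = 5e-4, epochs = 30,
                                                   l2 = 0, batch_size = 128,
                                                   lr_patience_epochs = 8,
                                                   seed = ds$seed))
  Y_code <- unclass(aec_encode(aec, nv$values))
  if (is.null(arch_spec))
    arch_spec <- architecture_spec("FCN", fcn_widths = 128,
                                   summation_width = 64, output_dim = 128)
  if (is.null(arch_voc))
    arch_voc <- architecture_spec("FCN", fcn_widths = 128,
                                  summation_width = 64,
                                  output_dim = aec$bottleneck_dim,
                                  output_nonlinearity = "tanh")
  lam <- select_ridge_lambda(wd$X[sp$train, , drop = FALSE],
                             Y_spec[sp$train, , drop = FALSE])
  clean <- test_audio(ds, sp)
  scores <- NULL
  param_cors <- NULL
  Xtr <- wd$X[sp$train, , drop = FALSE]
  Xte <- wd$X[sp$test, , drop = FALSE]
  wd_tr <- wd; wd_tr$X <- Xtr
  perm <- design_grid_permutation(wd)
  for (sd_i in seeds) {
    # linear -> spectrogram
    dl <- fit_linear(Xtr, Y_spec[sp$train, , drop = FALSE], lam)
    S_lin <- clamp_spec(predict_linear(dl, Xte))
    est <- estoi_from_spec(ds, clean, S_lin, invert_iter, sd_i)
    scores <- rbind(scores, data.frame(condition = "linear-spectrogram",
                                       seed = sd_i, estoi = est))
    # linear -> vocoder code
    dv <- fit_linear(Xtr, Y_code[sp$train, , drop = FALSE], lam)
    code_lin <- predict_linear(dv, Xte)
    vf_lin <- decode_codes(aec, code_lin, nv)
    est <- compute_estoi(clean, vocoder_synthesize(vf_lin, seed = sd_i))
    scores <- rbind(scores, data.frame(condition = "linear-vocoder",
                                       seed = sd_i, estoi = est))
    pc_lin <- vocoder_param_correlations(ds, sp$test, vf_lin)
    pc_lin$model <- "linear"; pc_lin$seed <- sd_i
    # DNN -> spectrogram
    cfg_i <- cfg; cfg_i$seed <- sd_i
    m1 <- build_model(arch_spec, shape, dropout = cfg$dropout, seed = sd_i)
    m1 <- train_model(m1, Xtr[, perm, drop = FALSE],
                      Y_spec[sp$train, , drop = FALSE], cfg_i)
    S_dnn <- clamp_spec(reconstruct(m1, Xte[, perm, drop = FALSE]))
    est <- estoi_from_spec(ds, clean, S_dnn, invert_iter, sd_i)
    scores <- rbind(scores, data.frame(condition = "dnn-spectrogram",
                                       seed = sd_i, estoi = est))
    # DNN -> vocoder code
    cfg_v <- cfg_voc; cfg_v$seed <- sd_i
    m2 <- build_model(arch_voc, shape, dropout = cfg_voc$dropout, seed = sd_i)
    m2 <- train_model(m2, Xtr[, perm, drop = FALSE],
                      Y_code[sp$train, , drop = FALSE], cfg_v)
    code_dnn <- reconstruct(m2, Xte[, perm, drop = FALSE])
    vf_dnn <- decode_codes(aec, code_dnn, nv)
    est <- compute_estoi(clean, vocoder_synthesize(vf_dnn, seed = sd_i))
    scores <- rbind(scores, data.frame(condition = "dnn-vocoder",
                                       seed = sd_i, estoi = est))
    pc_dnn <- vocoder_param_correlations(ds, sp$test, vf_dnn)
    pc_dnn$model <- "dnn"; pc_dnn$seed <- sd_i
    param_cors <- rbind(param_cors, pc_lin, pc_dnn)
  }
  structure(list(scores = scores, vocoder_param_cor = param_cors,
                 configs = list(cfg = cfg, ridge_lambda = lam,
                                seeds = seeds, dataset_seed = ds$seed)),
            class = "experiment_report")
}

# clean concatenated test audio
test_audio <- function(ds, sp) {
  te <- sp$test
  waveform(ds$stimulus$samples[
    ((te[1] - 1) * 160 + 1):min(length(ds$stimulus$samples),
                                te[length(te)] * 160)], 16000)
}

estoi_from_spec <- function(ds, clean, S_hat, invert_iter, seed) {
  wa <- invert_auditory_spectrogram(auditory_spectrogram(clamp_spec(S_hat)),
                                    n_iter = invert_iter, seed = seed)
  compute_estoi(clean, wa)
}

# slice a vocoder_frames object by frame indices
subset_vocoder <- function(v, idx) {
  vocoder_frames(v$spectral_envelope[idx, , drop = FALSE], v$f0[idx],
                 v$vuv[idx], v$band_aperiodicity[idx, , drop = FALSE],
                 v$frame_rate)
}

# decode bottleneck codes into vocoder frames on the test span; regressed
# codes can stray, so the z-range is clamped before exponentiation
decode_codes <- function(aec, codes, nv) {
  vocoder_denormalize(aec_decode(aec, codes), stats = nv$stats,
                      frame_rate = nv$frame_rate, clamp_z = 5)
}

# correlations between true and reconstructed vocoder parameter groups on the
# test frames: envelope (pooled log-envelope cells), f0 (voiced frames),
# aperiodicity, vuv
vocoder_param_correlations <- function(ds, te, v_hat) {
  v_true <- subset_vocoder(ds$vocoder, te)
  n <- min(nrow(v_true$spectral_envelope), nrow(v_hat$spectral_envelope))
  le_t <- log(v_true$spectral_envelope[seq_len(n), ] + 1e-10)
  le_h <- log(v_hat$spectral_envelope[seq_len(n), ] + 1e-10)
  env_cor <- stats::cor(as.vector(le_t), as.vector(le_h))
  voiced <- v_true$f0[seq_len(n)] > 0
  f0_cor <- if (sum(voiced) > 2 && stats::sd(v_hat$f0[voiced]) > 1e-9)
    stats::cor(v_true$f0[voiced], v_hat$f0[voiced]) else 0
  ap_cor <- if (stats::sd(v_hat$band_aperiodicity[seq_len(n), 1]) > 1e-9)
    stats::cor(v_true$band_aperiodicity[seq_len(n), 1],
               v_hat$band_aperiodicity[seq_len(n), 1]) else 0
  vuv_cor <- if (stats::sd(v_hat$vuv[seq_len(n)]) > 1e-9)
    stats::cor(v_true$vuv[seq_len(n)], v_hat$vuv[seq_len(n)]) else 0
  data.frame(parameter = c("envelope", "f0", "aperiodicity", "vuv"),
             correlation = c(env_cor, f0_cor, ap_cor, vuv_cor))
}

#' Neural-band ablation with the deep spectrogram decoder
#'
#' Trains the DNN-spectrogram model on high gamma only, low frequency only,
#' and both bands, and scores each reconstruction. Scoring uses mean
#' spectrogram-channel correlation by default (`metric = "estoi"` renders
#' audio instead).
#'
#' @param ds a [make_decoding_dataset()] (use `complementary = TRUE` to give
#'   the bands disjoint information).
#' @param seeds training seeds.
#' @param cfg a [training_config()].
#' @param metric `"correlation"` or `"estoi"`.
#' @param arch an [architecture_spec()]; small FCN by default.
#' @param n_test_tokens held-out tokens.
#' @return `experiment_report` with per-condition scores.
#' @export
run_band_ablation <- function(ds, seeds = 1:10,
                              cfg = training_config(lr = 2e-3, epochs = 12,
                                                    dropout = 0.2),
                              metric = c("correlation", "estoi"),
                              arch = NULL, n_test_tokens = 2L) {
  metric <- match.arg(metric)
  sp <- dataset_split(ds, n_test_tokens)
  wd <- build_windows(ds$features)
  n_el <- nrow(ds$features$lf)
  shape <- c(wd$lag_count, n_el, 2L)
  if (is.null(arch))
    arch <- architecture_spec("FCN", fcn_widths = 96, summation_width = 64,
                              output_dim = 128)
  Y <- ds$spectrogram$values[seq_len(ds$n_frames), , drop = FALSE]
  perm <- design_grid_permutation(wd)
  scores <- NULL
  conds <- list(hg = "hg", lf = "lf", both = c("lf", "hg"))
  for (cn in names(conds)) {
    wd_b <- restrict_band(wd, conds[[cn]])
    Xtr <- wd_b$X[sp$train, perm, drop = FALSE]
    Xte <- wd_b$X[sp$test, perm, drop = FALSE]
    for (sd_i in seeds) {
      cfg_i <- cfg; cfg_i$seed <- sd_i
      m <- build_model(arch, shape, dropout = cfg$dropout, seed = sd_i)
      m <- train_model(m, Xtr, Y[sp$train, , drop = FALSE], cfg_i)
      S_hat <- clamp_spec(reconstruct(m, Xte))
      sc <- score_reconstruction(ds, sp$test, S_hat, metric, seed = sd_i)
      scores <- rbind(scores, data.frame(condition = cn, seed = sd_i,
                                         score = sc))
    }
  }
  structure(list(scores = scores,
                 configs = list(cfg = cfg, metric = metric, seeds = seeds,
                                dataset_seed = ds$seed)),
            class = "experiment_report")
}

#' Reconstruction accuracy versus electrode count
#'
#' For each electrode count N, draws `n_resamples` random electrode subsets
#' and scores a decoder trained on that subset. The linear decoder keeps the
#' curve tractable at 160 fits; the score is mean spectrogram-channel
#' correlation (or ESTOI with `metric = "estoi"`).
#'
#' @param ds a [make_decoding_dataset()] with at least `max(counts)`
#'   electrodes.
#' @param counts electrode counts (paper protocol: 1, 2, 4, ..., 128).
#' @param n_resamples random subsets per count (paper protocol: 20).
#' @param metric `"correlation"` or `"estoi"`.
#' @param master_seed seed controlling every subset draw.
#' @param n_test_tokens held-out tokens.
#' @return `experiment_report`; `scores` has one row per (count, resample).
#' @export
run_electrode_curve <- function(ds, counts = c(1, 2, 4, 8, 16, 32, 64, 128),
                                n_resamples = 20,
                                metric = c("correlation", "estoi"),
                                master_seed = 1L, n_test_tokens = 2L) {
  metric <- match.arg(metric)
  n_el <- nrow(ds$features$lf)
  counts <- counts[counts <= n_el]
  sp <- dataset_split(ds, n_test_tokens)
  wd <- build_windows(ds$features)
  Y <- ds$spectrogram$values[seq_len(ds$n_frames), , drop = FALSE]
  lam <- select_ridge_lambda(wd$X[sp$train, , drop = FALSE],
                             Y[sp$train, , drop = FALSE])
  scores <- NULL
  set.seed(master_seed)
  for (N in counts) {
    for (r in seq_len(n_resamples)) {
      sub <- sort(sample(n_el, N))
      cols <- which(wd$feature_index$electrode %in% sub)
      Xtr <- wd$X[sp$train, cols, drop = FALSE]
      Xte <- wd$X[sp$test, cols, drop = FALSE]
      d <- fit_linear(Xtr, Y[sp$train, , drop = FALSE], lam)
      S_hat <- clamp_spec(predict_linear(d, Xte))
      sc <- score_reconstruction(ds, sp$test, S_hat, metric, seed = r)
      scores <- rbind(scores, data.frame(n_electrodes = N, resample = r,
                                         score = sc))
    }
  }
  structure(list(scores = scores,
                 configs = list(counts = counts, n_resamples = n_resamples,
                                metric = metric, master_seed = master_seed,
                                ridge_lambda = lam, dataset_seed = ds$seed)),
            class = "experiment_report")
}

#' Reconstruction accuracy versus training duration
#'
#' For each duration, draws `n_resamples` random contiguous training segments
#' of that length, fits the decoder on the segment and scores the held-out
#' tokens. Synthetic durations are desk-scaled (tens of seconds) relative to
#' the minutes-long recordings the protocol emulates.
#'
#' @param ds a [make_decoding_dataset()].
#' @param durations_s training segment durations in seconds.
#' @param n_resamples random segments per duration.
#' @param metric `"correlation"` or `"estoi"`.
#' @param master_seed seed controlling segment draws.
#' @param n_test_tokens held-out tokens.
#' @return `experiment_report`; `scores` has one row per (duration, resample).
#' @export
run_duration_curve <- function(ds, durations_s = c(5, 10, 20, 40),
                               n_resamples = 20,
                               metric = c("correlation", "estoi"),
                               master_seed = 1L, n_test_tokens = 2L) {
  metric <- match.arg(metric)
  sp <- dataset_split(ds, n_test_tokens)
  wd <- build_windows(ds$features)
  Y <- ds$spectrogram$values[seq_len(ds$n_frames), , drop = FALSE]
  lam <- select_ridge_lambda(wd$X[sp$train, , drop = FALSE],
                             Y[sp$train, , drop = FALSE])
  tr <- sp$train
  scores <- NULL
  set.seed(master_seed)
  for (dur in durations_s) {
    n_seg <- as.integer(round(dur * 100))
    if (n_seg > length(tr)) n_seg <- length(tr)
    for (r in seq_len(n_resamples)) {
      start <- sample(length(tr) - n_seg + 1L, 1L)
      idx <- tr[start:(start + n_seg - 1L)]
      d <- fit_linear(wd$X[idx, , drop = FALSE], Y[idx, , drop = FALSE], lam)
      S_hat <- clamp_spec(predict_linear(d, wd$X[sp$test, , drop = FALSE]))
      sc <- score_reconstruction(ds, sp$test, S_hat, metric, seed = r)
      scores <- rbind(scores, data.frame(duration_s = dur, resample = r,
                                         score = sc))
    }
  }
  structure(list(scores = scores,
                 configs = list(durations_s = durations_s,
                                n_resamples = n_resamples, metric = metric,
                                master_seed = master_seed,
                                ridge_lambda = lam, dataset_seed = ds$seed)),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  print(utils::head(x$scores, 12))
  if (nrow(x$scores) > 12) cat("...", nrow(x$scores), "rows\n")
  invisible(x)
}
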