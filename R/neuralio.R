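# Neural-band feature extraction: low-frequency (0-50 Hz) and high-gamma
# (70-150 Hz envelope) features at 100 frames/s, silence-baseline
# normalization, repetition averaging and sliding-window design matrices.

NEURAL_FRAME_RATE <- 100

#' Neural recording container
#'
#' Electrodes x samples field-potential matrix with per-electrode grid layout
#' and a pre-stimulus quiet interval used for baseline normalization.
#'
#' @param signal electrodes x samples numeric matrix (microvolts).
#' @param rate sampling rate in Hz; must be >= 500 so that the 70-150 Hz band
#'   exists.
#' @param layout data.frame with columns `label`, `grid_row`, `grid_col`, one
#'   row per electrode; a square-ish grid is generated when omitted.
#' @param silence_span length-2 integer vector, start/end sample indices of a
#'   quiet interval of at least 10 s.
#' @return object of class `neural_recording`.
#' @export
neural_recording <- function(signal, rate, layout = NULL, silence_span = NULL) {
  signal <- as.matrix(signal)
  if (!is.numeric(rate) || rate < 500)
    stop("rate must be >= 500 Hz (the 70-150 Hz band must exist)")
  n_el <- nrow(signal)
  if (is.null(layout)) {
    ncols <- ceiling(sqrt(n_el))
    layout <- data.frame(
      label = sprintf("E%03d", seq_len(n_el)),
      grid_row = (seq_len(n_el) - 1L) %/% ncols + 1L,
      grid_col = (seq_len(n_el) - 1L) %% ncols + 1L)
  }
  if (nrow(layout) != n_el)
    stop("layout rows must correspond one-to-one with signal rows")
  if (!all(c("label", "grid_row", "grid_col") %in% names(layout)))
    stop("layout needs columns label, grid_row, grid_col")
  if (!is.null(silence_span)) {
    silence_span <- as.integer(silence_span)
    if (length(silence_span) != 2L || silence_span[1] < 1 ||
        silence_span[2] > ncol(signal) || silence_span[2] <= silence_span[1])
      stop("silence_span must be valid sample indices within the recording")
    if ((silence_span[2] - silence_span[1] + 1) / rate < 10)
      stop("silence_span must cover at least 10 s")
  }
  structure(list(signal = signal, rate = rate, layout = layout,
                 silence_span = silence_span),
            class = "neural_recording")
}

#' @export
print.neural_recording <- function(x, ...) {
  cat(sprintf("<neural_recording> %d electrodes x %d samples @ %g Hz\n",
              nrow(x$signal), ncol(x$signal), x$rate))
  invisible(x)
}

# zero-phase FIR lowpass (Hamming design, >= 40 dB stopband at `stop_hz`)
fir_lowpass_zerophase <- function(x, rate, cutoff, stop_hz) {
  trans <- (stop_hz - cutoff) / rate
  ord <- ceiling(3.3 / trans)
  ord <- ord + ord %% 2L            # even order, symmetric filter
  h <- signal::fir1(ord, (cutoff + (stop_hz - cutoff) / 2) / (rate / 2),
                    type = "low")
  as.numeric(signal::filtfilt(signal::Ma(h), x))
}

# Fourier-domain rational resampling of each row to `to_rate`
resample_rows <- function(M, from_rate, to_rate) {
  out <- NULL
  for (i in seq_len(nrow(M))) {
    y <- fft_resample(M[i, ], from_rate, to_rate)
    if (is.null(out)) out <- matrix(0, nrow(M), length(y))
    out[i, ] <- y
  }
  out
}

#' Extract the low-frequency (0-50 Hz) neural band
#'
#' Zero-phase FIR lowpass at 50 Hz (Hamming design, at least 40 dB of
#' stopband attenuation by 60 Hz), then polyphase resampling to 100 frames/s.
#'
#' @param r a [neural_recording()].
#' @return electrodes x frames numeric matrix.
#' @export
extract_low_frequency <- function(r) {
  stopifnot(inherits(r, "neural_recording"))
  if (r$rate < 100) stop("unsupported rate: need >= 100 Hz")
  lp <- t(apply(r$signal, 1, fir_lowpass_zerophase,
                rate = r$rate, cutoff = 50, stop_hz = 60))
  resample_rows(lp, r$rate, NEURAL_FRAME_RATE)
}

# analytic-signal envelope via frequency-domain Hilbert mask
hilbert_env <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Extract the high-gamma (70-150 Hz) envelope
#'
#' The signal is filtered into eight equal-width bands spanning 70-150 Hz
#' (4th-order Butterworth, zero-phase), the Hilbert envelope of each band is
#' computed, the eight envelopes are averaged, resampled to 100 frames/s and
#' z-scored per electrode using the mean and SD of the frames inside the
#' recording's silence interval.
#'
#' @param r a [neural_recording()] with a `silence_span`.
#' @param normalize z-score by silence statistics (default TRUE).
#' @return electrodes x frames numeric matrix (z-units when normalized).
#' @export
extract_high_gamma <- function(r, normalize = TRUE) {
  stopifnot(inherits(r, "neural_recording"))
  if (normalize && is.null(r$silence_span))
    stop("silence_span required for baseline normalization")
  edges <- seq(70, 150, length.out = 9L)
  n_el <- nrow(r$signal)
  env_sum <- matrix(0, n_el, ncol(r$signal))
  for (b in seq_len(8L)) {
    bf <- signal::butter(4, c(edges[b], edges[b + 1]) / (r$rate / 2),
                         type = "pass")
    for (i in seq_len(n_el)) {
      xb <- as.numeric(signal::filtfilt(bf, r$signal[i, ]))
      env_sum[i, ] <- env_sum[i, ] + hilbert_env(xb)
    }
  }
  env <- env_sum / 8
  hg <- resample_rows(env, r$rate, NEURAL_FRAME_RATE)
  if (!normalize) return(hg)
  f0 <- max(1L, as.integer(floor((r$silence_span[1] - 1) / r$rate *
                                   NEURAL_FRAME_RATE) + 1L))
  f1 <- min(ncol(hg), as.integer(floor(r$silence_span[2] / r$rate *
                                         NEURAL_FRAME_RATE)))
  if (f1 - f0 + 1 < 10 * NEURAL_FRAME_RATE * 0.9)
    stop("silence interval too short after framing")
  for (i in seq_len(n_el)) {
    mu <- mean(hg[i, f0:f1])
    sd_i <- stats::sd(hg[i, f0:f1])
    if (sd_i < 1e-12)
      stop("zero-variance silence baseline at electrode ", r$layout$label[i])
    hg[i, ] <- (hg[i, ] - mu) / sd_i
  }
  hg
}

#' Neural feature set container
#'
#' @param lf electrodes x frames low-frequency matrix (signed).
#' @param hg electrodes x frames high-gamma envelope matrix.
#' @param layout per-electrode layout table (see [neural_recording()]).
#' @param frame_rate frames per second.
#' @return object of class `neural_features`.
#' @export
neural_features <- function(lf, hg, layout = NULL,
                            frame_rate = NEURAL_FRAME_RATE) {
  lf <- as.matrix(lf); hg <- as.matrix(hg)
  if (!identical(dim(lf), dim(hg)))
    stop("lf and hg must share shape")
  n_el <- nrow(lf)
  if (is.null(layout)) {
    ncols <- ceiling(sqrt(n_el))
    layout <- data.frame(
      label = sprintf("E%03d", seq_len(n_el)),
      grid_row = (seq_len(n_el) - 1L) %/% ncols + 1L,
      grid_col = (seq_len(n_el) - 1L) %% ncols + 1L)
  }
  if (nrow(layout) != n_el) stop("layout rows must match electrode count")
  structure(list(lf = lf, hg = hg, layout = layout, frame_rate = frame_rate),
            class = "neural_features")
}

#' @export
print.neural_features <- function(x, ...) {
  cat(sprintf("<neural_features> %d electrodes x %d frames @ %g frames/s\n",
              nrow(x$lf), ncol(x$lf), x$frame_rate))
  invisible(x)
}

#' Extract both neural bands from a recording
#'
#' @param r a [neural_recording()].
#' @return a [neural_features()] with matched frame counts.
#' @export
extract_neural_features <- function(r) {
  lf <- extract_low_frequency(r)
  hg <- extract_high_gamma(r)
  n <- min(ncol(lf), ncol(hg))
  neural_features(lf[, seq_len(n), drop = FALSE],
                  hg[, seq_len(n), drop = FALSE], r$layout)
}

#' Average feature sets over stimulus repetitions
#'
#' Element-wise mean of both bands across repeated presentations of the same
#' stimulus, reducing trial-to-trial neural noise (residual noise SD scales
#' as 1/sqrt(n)).
#'
#' @param feature_sets list of [neural_features()] with identical shapes.
#' @return a [neural_features()].
#' @export
average_repetitions <- function(feature_sets) {
  if (!length(feature_sets)) stop("empty feature set list")
  ref <- feature_sets[[1]]
  for (fs in feature_sets) {
    if (!inherits(fs, "neural_features")) stop("inputs must be neural_features")
    if (!identical(dim(fs$lf), dim(ref$lf)))
      stop("shape mismatch across repetitions")
  }
  lf <- Reduce(`+`, lapply(feature_sets, `[[`, "lf")) / length(feature_sets)
  hg <- Reduce(`+`, lapply(feature_sets, `[[`, "hg")) / length(feature_sets)
  neural_features(lf, hg, ref$layout, ref$frame_rate)
}

#' Build the sliding-window design matrix
#'
#' Row t of `X` is the concatenation over electrodes (in spatial order), bands
#' (lf then hg), and lags of the feature frames inside a `window`-second
#' context centered on target frame t (150 ms before to 140 ms after at the
#' defaults, 30 lags). Windows reaching outside the recording are zero-padded
#' so the row count equals the frame count. Electrodes are ordered by
#' (grid_row, grid_col) so that spatially adjacent electrodes occupy adjacent
#' feature blocks.
#'
#' @param f a [neural_features()].
#' @param window context duration in seconds (default 0.3).
#' @param hop hop between target frames in seconds (default 0.01 = one frame).
#' @return object of class `windowed_design` with elements `X` (frames x
#'   features), `feature_index` (data.frame electrode/band/lag per column),
#'   `lag_count`, `offsets`, `window`, `hop`, `layout`, `electrode_order`.
#' @export
build_windows <- function(f, window = 0.3, hop = 0.01) {
  stopifnot(inherits(f, "neural_features"))
  lag_count <- as.integer(round(window * f$frame_rate))
  if (lag_count < 1) stop("window shorter than one frame")
  step <- max(1L, as.integer(round(hop * f$frame_rate)))
  n_frames <- ncol(f$lf)
  if (n_frames < lag_count) stop("need at least lag_count frames")
  offsets <- seq_len(lag_count) - 1L - lag_count %/% 2L
  ord <- order(f$layout$grid_row, f$layout$grid_col)
  targets <- seq(1L, n_frames, by = step)
  n_el <- nrow(f$lf)
  bands <- list(lf = f$lf, hg = f$hg)
  X <- matrix(0, length(targets), n_el * 2L * lag_count)
  fi_el <- integer(0); fi_band <- character(0); fi_lag <- integer(0)
  col <- 0L
  for (e in ord) {
    for (b in c("lf", "hg")) {
      series <- bands[[b]][e, ]
      for (l in seq_len(lag_count)) {
        col <- col + 1L
        src <- targets + offsets[l]
        ok <- src >= 1L & src <= n_frames
        X[ok, col] <- series[src[ok]]
        fi_el[col] <- e; fi_band[col] <- b; fi_lag[col] <- offsets[l]
      }
    }
  }
  structure(list(X = X,
                 feature_index = data.frame(electrode = fi_el, band = fi_band,
                                            lag = fi_lag),
                 lag_count = lag_count, offsets = offsets,
                 window = window, hop = hop,
                 layout = f$layout, electrode_order = ord,
                 frame_rate = f$frame_rate),
            class = "windowed_design")
}

#' @export
print.windowed_design <- function(x, ...) {
  cat(sprintf("<windowed_design> %d frames x %d features (%d lags)\n",
              nrow(x$X), ncol(x$X), x$lag_count))
  invisible(x)
}

#' Write / read a neural recording as a plain-text container
#'
#' The on-disk form is a directory with `signal.csv` (electrodes x samples),
#' `layout.csv` and `meta.json` (rate, silence span) — a portable text mirror
#' of the matrix-container layout.
#'
#' @param r a [neural_recording()].
#' @param path directory to create/overwrite.
#' @return `path` invisibly.
#' @export
write_neural_recording <- function(r, path) {
  stopifnot(inherits(r, "neural_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(r$signal, file.path(path, "signal.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.csv(r$layout, file.path(path, "layout.csv"), row.names = FALSE)
  meta <- list(rate = r$rate, silence_span = r$silence_span)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, null = "null"),
             file.path(path, "meta.json"))
  invisible(path)
}

#' @rdname write_neural_recording
#' @param path directory produced by [write_neural_recording()].
#' @export
read_neural_recording <- function(path) {
  sig <- as.matrix(utils::read.table(file.path(path, "signal.csv"), sep = ","))
  dimnames(sig) <- NULL
  layout <- utils::read.csv(file.path(path, "layout.csv"))
  meta <- jsonlite::fromJSON(file.path(path, "meta.json"))
  neural_recording(sig, meta$rate, layout,
                   if (!is.null(meta$silence_span)) meta$silence_span)
}
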