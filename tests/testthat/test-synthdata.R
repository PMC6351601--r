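# Synthetic stimulus tokens and the forward neural simulator.

test_that("token generation is deterministic and respects duration bounds", {
  t1 <- make_speech_tokens(3, seed = 9, duration_range = c(0.8, 1.2))
  t2 <- make_speech_tokens(3, seed = 9, duration_range = c(0.8, 1.2))
  for (i in 1:3) {
    expect_identical(t1[[i]]$samples, t2[[i]]$samples)
    expect_gte(wav_duration(t1[[i]]), 0.8 - 1e-6)
    expect_lte(wav_duration(t1[[i]]), 1.2 + 1e-6)
  }
  t3 <- make_speech_tokens(1, seed = 10)
  expect_false(identical(t1[[1]]$samples, t3[[1]]$samples))
})

test_that("tokens are mostly voiced under vocoder analysis", {
  toks <- make_speech_tokens(3, seed = 4, duration_range = c(1.0, 1.4))
  for (w in toks) {
    v <- vocoder_analyze(w)
    expect_gte(mean(v$vuv), 0.5)
  }
})

test_that("noiseless identity encoding equals the brute-force STRF oracle", {
  ds <- small_dataset()
  spec <- ds$spectrogram
  g <- make_encoder_ground_truth(3, noise_sd = 0, seed = 6)
  sim <- simulate_neural(spec, g, lf_smooth_frames = 0, normalize = FALSE,
                         seed = 1)
  Tn <- nrow(spec$values)
  for (e in 1:3) {
    strf <- g$strfs_lf[[e]]
    oracle <- vapply(seq_len(Tn), function(t) {
      acc <- 0
      for (l in seq_len(nrow(strf)))
        if (t - l + 1 >= 1) acc <- acc + sum(strf[l, ] * spec$values[t - l + 1, ])
      acc
    }, numeric(1))
    expect_lt(max(abs(sim$features$lf[e, ] - oracle)), 1e-10)
  }
})

test_that("hg band is rectified (nonnegative) and gain-linear", {
  ds <- small_dataset()
  g <- make_encoder_ground_truth(4, noise_sd = 0, seed = 6)
  s1 <- simulate_neural(ds$spectrogram, g, lf_smooth_frames = 0,
                        normalize = FALSE, seed = 1)
  expect_true(all(s1$features$hg >= 0))
  g2 <- g; g2$hg_gain <- 2
  s2 <- simulate_neural(ds$spectrogram, g2, lf_smooth_frames = 0,
                        normalize = FALSE, seed = 1)
  expect_equal(s2$features$hg, 2 * s1$features$hg, tolerance = 1e-12)
})

test_that("simulation is reproducible and rejects empty populations", {
  ds <- small_dataset()
  g <- make_encoder_ground_truth(2, noise_sd = 0.1, seed = 6)
  a <- simulate_neural(ds$spectrogram, g, seed = 5)
  b <- simulate_neural(ds$spectrogram, g, seed = 5)
  expect_identical(a$features$lf, b$features$lf)
  g$strfs_lf <- list()
  expect_error(simulate_neural(ds$spectrogram, g), "empty")
})

test_that("STRF lag spans are capped at the 300 ms window", {
  expect_error(make_encoder_ground_truth(2, n_lags = 40), "300 ms")
  g <- make_encoder_ground_truth(2, n_lags = 20, seed = 1)
  expect_equal(nrow(g$strfs_lf[[1]]), 20L)
})

test_that("a rendered raw recording approximately recovers the hg band", {
  ds <- small_dataset()
  g <- make_encoder_ground_truth(4, noise_sd = 0.02, seed = 8)
  sim <- simulate_neural(ds$spectrogram, g, normalize = FALSE, seed = 2)
  rec <- render_neural_recording(sim, rate = 1000, noise_uv = 0.01, seed = 3)
  hg <- extract_high_gamma(rec, normalize = FALSE)
  Tn <- ncol(sim$features$hg)
  P <- sim$prelude_frames
  rec_hg <- hg[, (P + 1):min(P + Tn, ncol(hg)), drop = FALSE]
  m <- ncol(rec_hg)
  cors <- vapply(1:4, function(e)
    cor(rec_hg[e, ], pmax(sim$features$hg[e, 1:m], 0)), numeric(1))
  # electrodes tuned to quiet spectral regions sit near the sensor-noise
  # floor, so the population median is the meaningful recovery statistic
  expect_gte(median(cors), 0.6)
})
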