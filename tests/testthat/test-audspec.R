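# Cochlear spectrogram model: contract, filterbank selectivity, gain
# behavior, and the iterative inversion.

test_that("spectrogram contract: 128 log-spaced channels at 100 frames/s", {
  w <- harmonic_token(1)
  s <- compute_auditory_spectrogram(w)
  expect_equal(ncol(s$values), 128L)
  expect_equal(s$frame_rate, 100)
  expect_equal(nrow(s$values), 100, tolerance = 0.011)  # 100 +/- 1 frames
  expect_true(all(s$values >= 0))
  ratios <- s$center_freqs[-1] / s$center_freqs[-128]
  expect_lt(max(abs(ratios / ratios[1] - 1)), 1e-6)
})

test_that("pure tones excite the matching channel (every 8th channel)", {
  rate <- 16000
  cfs <- aud_center_freqs()
  t <- seq(0, 1, length.out = rate)
  for (k in seq(8, 120, by = 8)) {
    s <- compute_auditory_spectrogram(waveform(sin(2 * pi * cfs[k] * t), rate))
    expect_lte(abs(which.max(colMeans(s$values)) - k), 1L)
  }
})

test_that("silence maps to an all-zero spectrogram and inverts to silence", {
  s <- compute_auditory_spectrogram(waveform(numeric(16000), 16000))
  expect_true(all(s$values == 0))
  w0 <- invert_auditory_spectrogram(s, n_iter = 5, seed = 1)
  expect_true(all(w0$samples == 0))
})

test_that("input validation rejects short and non-finite audio", {
  expect_error(compute_auditory_spectrogram(waveform(numeric(100), 16000)),
               "short")
  expect_error(waveform(c(1, NA, 3), 16000), "finite")
})

test_that("scaling the waveform never decreases any spectrogram cell", {
  w <- harmonic_token(7, duration = 0.5)
  s1 <- compute_auditory_spectrogram(w)
  s2 <- compute_auditory_spectrogram(waveform(w$samples * 2.5, w$rate))
  expect_true(all(s2$values >= s1$values - 1e-12))
})

test_that("round-trip spectrogram error is non-increasing in iterations", {
  s <- compute_auditory_spectrogram(harmonic_token(42))
  rel_err <- vapply(c(3L, 15L, 60L), function(ni) {
    mean_err <- 0
    for (seed in 1:3) {
      wi <- invert_auditory_spectrogram(s, n_iter = ni, seed = seed)
      s2 <- compute_auditory_spectrogram(wi)
      Tm <- min(nrow(s$values), nrow(s2$values))
      mean_err <- mean_err +
        sum((s$values[1:Tm, ] - s2$values[1:Tm, ])^2) / sum(s$values[1:Tm, ]^2)
    }
    mean_err / 3
  }, numeric(1))
  expect_true(all(diff(rel_err) <= 0.01))
})

test_that("inversion is deterministic given a seed", {
  s <- compute_auditory_spectrogram(harmonic_token(5, duration = 0.5))
  w1 <- invert_auditory_spectrogram(s, n_iter = 10, seed = 9)
  w2 <- invert_auditory_spectrogram(s, n_iter = 10, seed = 9)
  expect_identical(w1$samples, w2$samples)
})
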