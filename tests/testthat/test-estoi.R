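# Extended short-time objective intelligibility scoring.

test_that("self-comparison of speech attains the top of the range", {
  x <- make_speech_tokens(1, seed = 11, duration_range = c(1.3, 1.5))[[1]]
  expect_equal(compute_estoi(x, x), 1, tolerance = 1e-6)
})

test_that("independent white noise scores near the bottom", {
  x <- make_speech_tokens(1, seed = 12, duration_range = c(1.3, 1.5))[[1]]
  scores <- vapply(1:20, function(s) {
    set.seed(s)
    compute_estoi(x, waveform(rnorm(length(x$samples)) * 0.1, 16000))
  }, numeric(1))
  expect_lte(max(scores), 0.1)
})

test_that("the score is invariant to global gain of the degraded signal", {
  x <- make_speech_tokens(1, seed = 13, duration_range = c(1.3, 1.5))[[1]]
  set.seed(1)
  noisy <- waveform(x$samples + rnorm(length(x$samples)) * 0.02, 16000)
  s1 <- compute_estoi(x, noisy)
  s2 <- compute_estoi(x, waveform(noisy$samples * 0.5, 16000))
  s3 <- compute_estoi(x, waveform(noisy$samples * 4, 16000))
  expect_lt(abs(s1 - s2), 1e-3)
  expect_lt(abs(s1 - s3), 1e-3)
  expect_gte(compute_estoi(x, waveform(x$samples * 0.5, 16000)), 0.99)
})

test_that("scores degrade monotonically with SNR", {
  for (seed in 1:3) {
    x <- make_speech_tokens(1, seed = seed + 20,
                            duration_range = c(1.3, 1.5))[[1]]
    set.seed(seed)
    nn <- rnorm(length(x$samples))
    scores <- vapply(c(20, 10, 0, -10), function(snr) {
      scaled <- nn * sqrt(mean(x$samples^2) / mean(nn^2)) * 10^(-snr / 20)
      compute_estoi(x, waveform(x$samples + scaled, 16000))
    }, numeric(1))
    expect_true(all(diff(scores) <= 0))
  }
})

test_that("invalid inputs are rejected", {
  x <- make_vowel(120, duration = 1.2)
  expect_error(compute_estoi(waveform(numeric(16000), 16000), x), "silent")
  short <- waveform(rnorm(4000), 16000)
  expect_error(compute_estoi(short, short), "1 s")
})
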