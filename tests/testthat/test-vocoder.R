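# Vocoder parameter contract: 516 parameters per frame, pitch and voicing
# estimation, synthesis, and normalization round trips.

test_that("every analysis yields the 516-parameter contract (513 envelope)", {
  v <- vocoder_analyze(make_vowel(120, duration = 0.5))
  expect_equal(ncol(v$spectral_envelope), 513L)
  expect_equal(vocoder_frame_dim(v), 516L)
  expect_equal(ncol(vocoder_flatten(v)), 516L)
  expect_true(all((v$f0 > 0) == (v$vuv == 1)))
  expect_true(all(v$band_aperiodicity >= 0 & v$band_aperiodicity <= 1))
})

test_that("a 120 Hz vowel is voiced with the right pitch; noise is unvoiced", {
  v <- vocoder_analyze(make_vowel(120, duration = 1))
  expect_lt(abs(median(v$f0[v$f0 > 0]) - 120), 3)
  expect_gt(mean(v$vuv), 0.9)
  set.seed(2)
  vn <- vocoder_analyze(waveform(rnorm(16000) * 0.1, 16000))
  expect_gte(mean(vn$vuv == 0), 0.9)
})

test_that("durations are preserved within one frame", {
  w <- make_vowel(140, duration = 2)
  v <- vocoder_analyze(w)
  y <- vocoder_synthesize(v)
  expect_lt(abs(wav_duration(y) - 2), 0.011)
})

test_that("all-unvoiced flat-envelope synthesis is noise-like", {
  Tn <- 150
  env <- matrix(1, Tn, 513)
  v_unv <- vocoder_frames(env, numeric(Tn), numeric(Tn),
                          matrix(1, Tn, 1))
  v_voc <- vocoder_frames(env, rep(120, Tn), rep(1, Tn),
                          matrix(0, Tn, 1))
  zcr <- function(w) mean(abs(diff(sign(w$samples))) > 0)
  expect_gt(zcr(vocoder_synthesize(v_unv)), zcr(vocoder_synthesize(v_voc)))
})

test_that("round trip on a vowel glide is highly intelligible (ESTOI)", {
  w <- make_vowel_glide(120, duration = 1.5, seed = 1)
  v <- vocoder_analyze(w)
  y <- vocoder_synthesize(v)
  expect_gte(compute_estoi(w, y), 0.8)
})

test_that("normalization round-trips exactly and f0 gaps are interpolated", {
  v <- vocoder_analyze(make_speech_tokens(1, seed = 5,
                                          duration_range = c(1.2, 1.3))[[1]])
  nv <- vocoder_normalize(v)
  expect_lt(max(abs(colMeans(nv$values))), 1e-6)
  expect_lt(max(abs(apply(nv$values, 2, sd) - 1)), 1e-6)
  v2 <- vocoder_denormalize(nv)
  voiced <- v$f0 > 0
  expect_lt(max(abs(v2$f0[voiced] - v$f0[voiced])), 1e-8)
  expect_identical(v2$vuv, v$vuv)
  expect_lt(max(abs(v2$spectral_envelope - v$spectral_envelope)), 1e-8)
  expect_lt(max(abs(v2$band_aperiodicity - v$band_aperiodicity)), 1e-8)
  # reusing stored statistics on new data inverts exactly too
  nv2 <- vocoder_normalize(v, stats = nv$stats)
  expect_identical(nv2$values, nv$values)
})

test_that("synthesis is deterministic given the excitation seed", {
  v <- vocoder_analyze(make_vowel(120, duration = 0.6))
  expect_identical(vocoder_synthesize(v, seed = 7)$samples,
                   vocoder_synthesize(v, seed = 7)$samples)
})
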