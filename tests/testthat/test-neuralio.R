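# Neural band extraction, silence normalization, repetition averaging and
# sliding-window design matrices.

make_test_recording <- function(signals, rate = 1000, silence_s = 11) {
  n <- ncol(signals)
  neural_recording(signals, rate, silence_span = c(1, silence_s * rate))
}

test_that("low-frequency extraction passes 10 Hz and DC, rejects 120 Hz", {
  rate <- 1000
  n <- 15 * rate
  t <- (0:(n - 1)) / rate
  sig <- rbind(sin(2 * pi * 10 * t), sin(2 * pi * 120 * t), rep(5, n))
  r <- make_test_recording(sig)
  lf <- extract_low_frequency(r)
  expect_equal(ncol(lf), 1500L)
  mid <- 200:1300
  expect_gte(sqrt(mean(lf[1, mid]^2)) / sqrt(0.5), 0.95)
  expect_lte(sqrt(mean(lf[2, mid]^2)) / sqrt(0.5), 0.05)
  expect_lt(max(abs(lf[3, mid] - 5)), 0.05)   # DC within 1%
})

test_that("high-gamma envelope tracks amplitude modulation and rejects 30 Hz", {
  rate <- 1000
  n <- 15 * rate
  t <- (0:(n - 1)) / rate
  am <- 1 + 0.8 * sin(2 * pi * 2 * t)
  sig <- rbind(sin(2 * pi * 110 * t) * am, sin(2 * pi * 30 * t),
               sin(2 * pi * 110 * t))
  r <- make_test_recording(sig)
  hg <- extract_high_gamma(r, normalize = FALSE)
  fr_t <- (seq_len(ncol(hg)) - 0.5) / 100
  mid <- 100:1400
  expect_gte(cor(hg[1, mid], 1 + 0.8 * sin(2 * pi * 2 * fr_t[mid])), 0.9)
  expect_lte(sqrt(mean(hg[2, mid]^2)) / sqrt(mean(hg[3, mid]^2)), 0.05)
})

test_that("silence normalization yields ~zero mean, unit sd over the baseline", {
  rate <- 1000
  n <- 15 * rate
  set.seed(4)
  sig <- rbind(sin(2 * pi * 110 * (0:(n - 1)) / rate) * 0.3 + rnorm(n) * 0.5)
  r <- make_test_recording(sig)
  hg <- extract_high_gamma(r)
  base <- hg[1, 1:1080]
  expect_lt(abs(mean(base)), 0.1)
  expect_lt(abs(sd(base) - 1), 0.1)
})

test_that("recordings without a valid silence span are rejected", {
  sig <- matrix(rnorm(2 * 12000), 2)
  expect_error(neural_recording(sig, 1000, silence_span = c(1, 5000)),
               "at least 10 s")
  r <- neural_recording(sig, 1000)
  expect_error(extract_high_gamma(r), "silence_span")
  expect_error(neural_recording(sig, 400), "500")
})

test_that("zero-variance silence names the offending electrode", {
  sig <- rbind(rnorm(12000), numeric(12000))
  r <- neural_recording(sig, 1000, silence_span = c(1, 10000))
  expect_error(extract_high_gamma(r), "E002")
})

test_that("repetition averaging reduces independent noise as 1/sqrt(n)", {
  base_lf <- matrix(sin(2 * pi * 3 * (1:400) / 100), 2, 400, byrow = TRUE)
  base_hg <- abs(base_lf)
  set.seed(1)
  ratios <- replicate(20, {
    reps <- lapply(1:6, function(i)
      neural_features(base_lf + matrix(rnorm(800, 0, 0.5), 2),
                      base_hg + matrix(rnorm(800, 0, 0.5), 2)))
    avg <- average_repetitions(reps)
    sd(avg$lf - base_lf) / 0.5
  })
  expect_lt(abs(mean(ratios) - 1 / sqrt(6)), 0.2 / sqrt(6))
})

test_that("averaging identities: identical sets and cancellation", {
  f1 <- neural_features(matrix(1:12, 3), matrix(13:24, 3))
  expect_equal(average_repetitions(list(f1, f1, f1))$lf, f1$lf)
  f2 <- neural_features(-f1$lf, -f1$hg)
  expect_true(all(average_repetitions(list(f1, f2))$lf == 0))
  f3 <- neural_features(matrix(0, 2, 6), matrix(0, 2, 6))
  expect_error(average_repetitions(list(f1, f3)), "mismatch")
})

test_that("windowing reproduces lagged slices exactly, 30 lags at defaults", {
  set.seed(8)
  lf <- matrix(rnorm(300), 3)
  hg <- matrix(rnorm(300), 3)
  f <- neural_features(lf, hg)
  wd <- build_windows(f)
  expect_equal(wd$lag_count, 30L)
  expect_equal(nrow(wd$X), 100L)
  # row 50 equals the lagged slices, cell by cell
  for (e in 1:3) for (b in c("lf", "hg")) {
    cols <- which(wd$feature_index$electrode == e & wd$feature_index$band == b)
    series <- if (b == "lf") lf[e, ] else hg[e, ]
    expected <- vapply(wd$offsets, function(o) {
      s <- 50 + o
      if (s >= 1 && s <= 100) series[s] else 0
    }, numeric(1))
    expect_identical(wd$X[50, cols], expected)
  }
  # un-windowing through the lag-0 columns reproduces the feature matrix
  lag0 <- which(wd$feature_index$lag == 0 & wd$feature_index$band == "lf" &
                  wd$feature_index$electrode == 2)
  expect_identical(wd$X[, lag0], lf[2, ])
})

test_that("a 10 ms window gives one lag; an impulse touches lag_count rows", {
  f <- neural_features(matrix(rnorm(200), 2), matrix(rnorm(200), 2))
  wd1 <- build_windows(f, window = 0.01)
  expect_equal(wd1$lag_count, 1L)
  expect_equal(ncol(wd1$X), 4L)
  lf <- matrix(0, 1, 100); lf[1, 40] <- 1
  fi <- neural_features(lf, matrix(0, 1, 100))
  wdi <- build_windows(fi)
  touched <- which(rowSums(wdi$X != 0) > 0)
  expect_equal(length(touched), wdi$lag_count)
  expect_error(build_windows(fi, window = 0.001), "shorter")
})

test_that("recording round-trips through the text container", {
  set.seed(2)
  r <- neural_recording(matrix(rnorm(2 * 11000), 2), 1000,
                        silence_span = c(1, 10500))
  p <- file.path(tempdir(), "rec_rt")
  write_neural_recording(r, p)
  r2 <- read_neural_recording(p)
  expect_equal(r2$signal, r$signal, tolerance = 1e-12)
  expect_equal(r2$rate, r$rate)
  expect_equal(r2$silence_span, r$silence_span)
  expect_equal(r2$layout$label, r$layout$label)
})
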