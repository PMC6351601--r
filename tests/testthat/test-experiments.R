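# Experiment orchestration: report structure, bookkeeping, reproducibility.
# The scientific orderings (deep vs linear, combined vs single band, resource
# curves) are exercised at full scale in test-acceptance.R; here a small
# dataset checks the machinery.

exp_dataset <- function() {
  cached("exp_ds", make_decoding_dataset(
    n_tokens = 8, n_electrodes = 12, noise_sd = 0.05, seed = 2,
    duration_range = c(0.9, 1.2)))
}

test_that("four-model report has one row per condition and seed", {
  ds <- exp_dataset()
  rep4 <- cached("rep4", run_four_models(
    ds, seeds = 1,
    cfg = training_config(lr = 2e-3, epochs = 4, dropout = 0.2),
    invert_iter = 10))
  expect_setequal(rep4$scores$condition,
                  c("linear-spectrogram", "linear-vocoder",
                    "dnn-spectrogram", "dnn-vocoder"))
  expect_equal(nrow(rep4$scores), 4L)
  expect_true(all(rep4$scores$estoi >= 0 & rep4$scores$estoi <= 1))
})

test_that("per-parameter correlation table covers the four vocoder streams", {
  rep4 <- cached("rep4", run_four_models(
    exp_dataset(), seeds = 1,
    cfg = training_config(lr = 2e-3, epochs = 4, dropout = 0.2),
    invert_iter = 10))
  tab <- rep4$vocoder_param_cor
  for (m in c("linear", "dnn")) {
    expect_setequal(tab$parameter[tab$model == m],
                    c("envelope", "f0", "aperiodicity", "vuv"))
  }
})

test_that("band ablation reports the three band conditions", {
  ds <- exp_dataset()
  rab <- run_band_ablation(ds, seeds = 1,
                           cfg = training_config(lr = 2e-3, epochs = 3,
                                                 dropout = 0.2))
  expect_setequal(rab$scores$condition, c("hg", "lf", "both"))
  expect_equal(nrow(rab$scores), 3L)
})

test_that("electrode and duration curves keep complete resample records", {
  ds <- exp_dataset()
  rec <- run_electrode_curve(ds, counts = c(1, 2, 4), n_resamples = 3,
                             master_seed = 1)
  expect_equal(nrow(rec$scores), 9L)
  expect_equal(sort(unique(rec$scores$n_electrodes)), c(1, 2, 4))
  expect_true(all(table(rec$scores$n_electrodes) == 3))
  rdur <- run_duration_curve(ds, durations_s = c(2, 4), n_resamples = 3,
                             master_seed = 1)
  expect_equal(nrow(rdur$scores), 6L)
  expect_true(all(table(rdur$scores$duration_s) == 3))
})

test_that("identical master seeds reproduce byte-identical reports", {
  ds <- exp_dataset()
  r1 <- run_electrode_curve(ds, counts = c(2, 4), n_resamples = 2,
                            master_seed = 7)
  r2 <- run_electrode_curve(ds, counts = c(2, 4), n_resamples = 2,
                            master_seed = 7)
  expect_identical(r1$scores, r2$scores)
  r3 <- run_electrode_curve(ds, counts = c(2, 4), n_resamples = 2,
                            master_seed = 8)
  expect_false(identical(r1$scores, r3$scores))
})

test_that("restricting the design to one band zeroes only that band", {
  ds <- exp_dataset()
  wd <- build_windows(ds$features)
  wd_hg <- neurovoc:::restrict_band(wd, "hg")
  lf_cols <- wd$feature_index$band == "lf"
  expect_true(all(wd_hg$X[, lf_cols] == 0))
  expect_identical(wd_hg$X[, !lf_cols], wd$X[, !lf_cols])
})
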