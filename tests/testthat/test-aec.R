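# Vocoder-frame autoencoder: bottleneck contract, determinism, robustness.

aec_fixture <- function() {
  cached("aec_small", {
    X <- cached("voc_corpus_small", vocoder_corpus(8, seed = 21))
    train_autoencoder(X, noise_sd = 0.1,
                      cfg = training_config(lr = 1e-3, epochs = 12, l2 = 0,
                                            seed = 2))
  })
}

test_that("codes are 256-dimensional and confined to (-1, 1)", {
  aec <- aec_fixture()
  X <- cached("voc_corpus_small", vocoder_corpus(8, seed = 21))
  codes <- aec_encode(aec, X[1:50, ])
  expect_equal(ncol(codes), 256L)
  expect_true(all(codes > -1 & codes < 1))
})

test_that("encode/decode are deterministic at inference", {
  aec <- aec_fixture()
  X <- cached("voc_corpus_small", vocoder_corpus(8, seed = 21))
  c1 <- aec_encode(aec, X[1:20, ])
  c2 <- aec_encode(aec, X[1:20, ])
  expect_identical(unclass(c1), unclass(c2))
  expect_identical(aec_decode(aec, c1), aec_decode(aec, c2))
})

test_that("training reduces reconstruction error; zero noise is accepted", {
  X <- cached("voc_corpus_small", vocoder_corpus(8, seed = 21))
  aec <- aec_fixture()
  h <- aec$history
  expect_lt(tail(h$val_loss, 1), h$val_loss[1])
  a0 <- train_autoencoder(X[1:400, ], noise_sd = 0,
                          cfg = training_config(lr = 5e-4, epochs = 8,
                                                batch_size = 128,
                                                l2 = 0, seed = 3))
  expect_lt(aec_relative_error(a0, X[1:100, ]), 1)
  expect_error(train_autoencoder(X[1:100, ], noise_sd = -0.1), "nonnegative")
})

test_that("noise-trained decoder tolerates code perturbations", {
  aec <- aec_fixture()
  X <- cached("voc_corpus_small", vocoder_corpus(8, seed = 21))
  heldout <- X[seq(nrow(X) - 199, nrow(X)), ]
  codes <- aec_encode(aec, heldout)
  clean <- aec_decode(aec, codes)
  clean_err <- sqrt(sum((heldout - clean)^2) / sum(heldout^2))
  set.seed(31)
  pert_errs <- vapply(1:20, function(i) {
    noisy <- codes + matrix(rnorm(length(codes), 0, aec$noise_sd / 2),
                            nrow(codes))
    out <- aec_decode(aec, noisy)
    sqrt(sum((heldout - out)^2) / sum(heldout^2))
  }, numeric(1))
  expect_lte(mean(pert_errs), 2 * clean_err)
})
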