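# small training fixtures: 16x16 cases keep these tests fast

tiny_case <- function(cs, strategy) {
  toy_case(cs, strategy, H = 16, W = 16)
}

tiny_net <- function() unroll_config(n_unrolls = 2, cg_iters = 5, lambda = 0.05)

test_that("supervised training reduces the training loss on a toy problem", {
  fx <- tiny_case(300, "SL")
  dp <- denoiser_params(4, n_filters = 8, n_blocks = 1, seed = 1)
  cfg <- train_config("SL", learning_rate = 5e-3, epochs = 4, batch_size = 1, seed = 1)
  fit <- train_supervised(list(fx$tc), list(fx$tc), dp, tiny_net(), cfg)
  h <- fit$history
  expect_length(h$train_loss, 4)
  expect_lt(tail(h$train_loss, 1), h$train_loss[1])
  expect_equal(h$best_epoch, which.min(h$val_loss))
})

test_that("training is deterministic for a fixed seed", {
  fx <- tiny_case(301, "SL")
  dp <- denoiser_params(4, n_filters = 6, n_blocks = 1, seed = 2)
  cfg <- train_config("SL", learning_rate = 1e-3, epochs = 3, batch_size = 1, seed = 5)
  f1 <- train_supervised(list(fx$tc), list(fx$tc), dp, tiny_net(), cfg)
  f2 <- train_supervised(list(fx$tc), list(fx$tc), dp, tiny_net(), cfg)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  expect_identical(qmapnet:::param_vector(f1$params), qmapnet:::param_vector(f2$params))
})

test_that("gradient accumulation reproduces the full-batch update", {
  fa <- tiny_case(302, "SL"); fb <- tiny_case(303, "SL")
  dp <- denoiser_params(4, n_filters = 6, n_blocks = 1, seed = 3)
  base <- train_config("SL", learning_rate = 1e-3, epochs = 2, batch_size = 2,
                       accumulation_steps = 1, seed = 1)
  acc <- train_config("SL", learning_rate = 1e-3, epochs = 2, batch_size = 2,
                      accumulation_steps = 2, seed = 1)
  f1 <- train_supervised(list(fa$tc, fb$tc), list(fa$tc), dp, tiny_net(), base)
  f2 <- train_supervised(list(fa$tc, fb$tc), list(fa$tc), dp, tiny_net(), acc)
  v1 <- qmapnet:::param_vector(f1$params); v2 <- qmapnet:::param_vector(f2$params)
  expect_lt(max(abs(v1 - v2)) / max(abs(v1)), 1e-6)
})

test_that("self-supervised cases refuse access to fully sampled data", {
  fx <- tiny_case(304, "SSL")
  expect_error(fx$tc$y_full, class = "qmapnet_data_error")
  expect_error(fx$tc[["kspace"]], class = "qmapnet_data_error")
  expect_silent(fx$tc$y_omega)
  # SL cases carry the reference openly
  fs <- tiny_case(304, "SL")
  expect_silent(fs$tc$y_full)
})

test_that("the self-supervised loss target is restricted to the Lambda subset", {
  fx <- tiny_case(305, "SSL")
  io <- qmapnet:::case_io(fx$tc, "SSL")
  lam <- fx$part$lam
  for (p in seq_len(dim(io$u)[1])) for (ci in seq_len(dim(io$u)[2])) {
    expect_true(all(io$u[p, ci, , ][!lam[p, , ]] == 0i))
  }
  # and the input is restricted to Theta
  th <- fx$part$theta
  for (p in seq_len(dim(io$y_in)[1]))
    expect_true(all(io$y_in[p, 1, , ][!th[p, , ]] == 0i))
  expect_identical(io$m_tgt, qmapnet:::as_mask3(lam, dim(io$u)[1], 16, 16))
})

test_that("self-supervised training decreases its training loss", {
  fx <- tiny_case(306, "SSL")
  dp <- denoiser_params(4, n_filters = 8, n_blocks = 1, seed = 4)
  cfg <- train_config("SSL", learning_rate = 5e-3, epochs = 5, batch_size = 1, seed = 1)
  fit <- train_ssl(list(fx$tc), list(fx$tc), dp, tiny_net(), cfg)
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
})

test_that("zero-shot training validates the partition nesting", {
  fx <- tiny_case(307, "ZSSSL")
  bad <- fx$tc
  # break nesting: move a xi point out
  part <- .subset2(bad, "part")
  part$xi[1, 1, 1] <- !part$xi[1, 1, 1]
  bad_tc <- bad
  bad_tc[["part"]] <- part
  dp <- denoiser_params(4, n_filters = 4, n_blocks = 1, seed = 5)
  expect_error(train_zsssl(bad_tc, dp, tiny_net(), train_config("ZSSSL", epochs = 1)),
               class = "qmapnet_invalid_argument")
})

test_that("frozen weights trigger early stopping after exactly patience + 1 misses", {
  fx <- tiny_case(308, "ZSSSL")
  dp <- denoiser_params(4, n_filters = 4, n_blocks = 1, seed = 6)
  cfg <- train_config("ZSSSL", learning_rate = 0, epochs = 100, patience = 5, seed = 1)
  fit <- train_zsssl(fx$tc, dp, tiny_net(), cfg)
  h <- fit$history
  # epoch 1 sets the best; then patience + 1 = 6 non-improving epochs
  expect_identical(length(h$val_loss), cfg$patience + 2L)
  expect_identical(h$best_epoch, 1L)
  expect_identical(h$stop_reason, "early_stop")
  expect_true(all(h$val_loss == h$val_loss[1]))
  # history never exceeds the epoch budget
  cfg2 <- train_config("ZSSSL", learning_rate = 0, epochs = 3, patience = 5, seed = 1)
  fit2 <- train_zsssl(fx$tc, dp, tiny_net(), cfg2)
  expect_lte(length(fit2$history$val_loss), 3L)
  expect_identical(fit2$history$stop_reason, "max_epochs")
})

test_that("strategy defaults follow the documented learning rates", {
  expect_equal(train_config("SL")$learning_rate, 1e-4)
  expect_equal(train_config("SSL")$learning_rate, 1e-4)
  expect_equal(train_config("ZSSSL")$learning_rate, 5e-4)
  expect_identical(train_config("SL")$epochs, 100L)
  expect_identical(train_config("SL")$batch_size, 2L)
  expect_identical(train_config("ZSSSL")$patience, 25L)
})
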