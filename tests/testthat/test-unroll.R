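unroll_fixture <- function(P = 2, H = 16, W = 16, C = 2, seed = 1) {
  set.seed(seed)
  S <- rand_sens(C, H, W)
  m <- rand_masks(P, H, W)
  x_true <- rand_complex(P, H, W)
  y <- apply_E(x_true, S, m)
  list(S = S, m = m, x_true = x_true, y = y, full = array(TRUE, c(P, H, W)))
}

test_that("a zero-weight denoiser leaves the adjoint reconstruction stationary", {
  fx <- unroll_fixture()
  p0 <- zero_denoiser_params(2)
  cfg <- unroll_config(n_unrolls = 3, cg_iters = 30, lambda = 0.05)
  x0 <- apply_EH(fx$y, fx$S, fx$m)
  out <- unrolled_recon(fx$y, fx$S, fx$m, p0, cfg)
  # z = x at every unroll, so x stays the solution of Q x = E^H y + lambda x0-ish;
  # with z = x the DC fixed point is x = E^H y in the unmeasured space
  # sanity: output stays finite and consistent on measured samples
  resid <- apply_E(out, fx$S, fx$m) - fx$y
  resid0 <- apply_E(x0, fx$S, fx$m) - fx$y
  expect_lte(qmapnet:::cnorm(resid), qmapnet:::cnorm(resid0) + 1e-10)
})

test_that("one unroll equals denoise followed by data consistency", {
  fx <- unroll_fixture(seed = 2)
  p <- denoiser_params(2, n_filters = 4, n_blocks = 2, seed = 3)
  cfg <- unroll_config(n_unrolls = 1, cg_iters = 10, lambda = 0.05)
  out <- unrolled_recon(fx$y, fx$S, fx$m, p, cfg)
  z <- denoise(apply_EH(fx$y, fx$S, fx$m), p)
  expect_identical(out, dc_solve(z, fx$y, fx$S, fx$m, cfg))
})

test_that("a fully sampled single-coil case is recovered exactly with a zero denoiser", {
  set.seed(4)
  H <- 12; W <- 12
  S <- uniform_sensitivities(H, W)
  full <- array(TRUE, c(1, H, W))
  x_true <- rand_complex(1, H, W)
  y <- apply_E(x_true, S, full)
  cfg <- unroll_config(n_unrolls = 2, cg_iters = 10, lambda = 0.05)
  out <- unrolled_recon(y, S, full, zero_denoiser_params(1), cfg)
  expect_lt(max(Mod(out - x_true)), 1e-6)
})

test_that("checkpointed forward output is bit-identical to the plain forward", {
  fx <- unroll_fixture(seed = 5)
  p <- denoiser_params(2, n_filters = 6, n_blocks = 2, seed = 6)
  cfg <- unroll_config(n_unrolls = 2, cg_iters = 8, lambda = 0.05)
  expect_identical(unrolled_recon(fx$y, fx$S, fx$m, p, cfg),
                   checkpointed_unrolled_recon(fx$y, fx$S, fx$m, p, cfg))
})

test_that("checkpointed gradients match the non-checkpointed computation", {
  fx <- unroll_fixture(P = 2, H = 16, W = 16, seed = 7)
  p <- denoiser_params(2, n_filters = 6, n_blocks = 2, seed = 8)
  cfg <- unroll_config(n_unrolls = 2, cg_iters = 8, lambda = 0.05)
  u <- apply_E(fx$x_true, fx$S, fx$full)
  grad_of <- function(checkpoint) {
    fw <- recon_forward(fx$y, fx$S, fx$m, p, cfg, tape = TRUE, checkpoint = checkpoint)
    v <- apply_E(fw$x, fx$S, fx$full)
    g_x <- apply_EH(qmapnet:::recon_loss_grad(u, v), fx$S, fx$full)
    qmapnet:::param_vector(recon_backward(g_x, fw, fx$S, fx$m, p, cfg))
  }
  g_plain <- grad_of(FALSE)
  g_ckpt <- grad_of(TRUE)
  scale <- max(abs(g_plain))
  expect_gt(scale, 0)
  expect_lt(max(abs(g_plain - g_ckpt)) / scale, 1e-5)
})

test_that("checkpointing performs one forward plus one recomputation per unroll", {
  fx <- unroll_fixture(seed = 9)
  p <- denoiser_params(2, n_filters = 4, n_blocks = 2, seed = 10)
  cfg <- unroll_config(n_unrolls = 3, cg_iters = 4, lambda = 0.05)
  g_x <- rand_complex(2, 16, 16)

  reset_denoiser_counter()
  fw <- recon_forward(fx$y, fx$S, fx$m, p, cfg, tape = TRUE, checkpoint = TRUE)
  invisible(recon_backward(g_x, fw, fx$S, fx$m, p, cfg))
  expect_identical(denoiser_eval_count(), 2L * cfg$n_unrolls)

  reset_denoiser_counter()
  fw2 <- recon_forward(fx$y, fx$S, fx$m, p, cfg, tape = TRUE, checkpoint = FALSE)
  invisible(recon_backward(g_x, fw2, fx$S, fx$m, p, cfg))
  expect_identical(denoiser_eval_count(), cfg$n_unrolls)
})

test_that("the checkpointed tape size is independent of the block count", {
  fx <- unroll_fixture(seed = 11)
  cfg <- unroll_config(n_unrolls = 2, cg_iters = 4, lambda = 0.05)
  counts <- sapply(c(2, 4), function(nb) {
    p <- denoiser_params(2, n_filters = 4, n_blocks = nb, seed = 12)
    ck <- tape_array_count(recon_forward(fx$y, fx$S, fx$m, p, cfg,
                                         tape = TRUE, checkpoint = TRUE))
    pl <- tape_array_count(recon_forward(fx$y, fx$S, fx$m, p, cfg,
                                         tape = TRUE, checkpoint = FALSE))
    c(ck = ck, pl = pl)
  })
  expect_identical(counts["ck", 1], counts["ck", 2])     # bounded: n_unrolls arrays
  expect_identical(unname(counts["ck", 1]), cfg$n_unrolls)
  expect_gt(counts["pl", 2], counts["pl", 1])            # plain tape grows with blocks
})
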