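# Shared fixtures: small random encoding instances, toy simulated cases, and
# independent brute-force oracles (dense normal operator, windowed SSIM).

rand_complex <- function(...) {
  d <- c(...)
  array(complex(real = rnorm(prod(d)), imaginary = rnorm(prod(d))), d)
}

# random RSS-normalized sensitivities, C x H x W
rand_sens <- function(C, H, W) {
  S <- rand_complex(C, H, W)
  rss <- sqrt(apply(Mod(S)^2, c(2, 3), sum))
  for (ci in seq_len(C)) S[ci, , ] <- S[ci, , ] / rss
  S
}

rand_masks <- function(P, H, W, frac = 0.5) {
  m <- array(runif(P * H * W) < frac, c(P, H, W))
  m[, floor(H / 2), floor(W / 2)] <- TRUE  # never fully empty
  m
}

# materialize Q = E^H E + lambda I columnwise as a dense matrix (oracle)
dense_normal_matrix <- function(S, m, lambda) {
  P <- dim(m)[1]; H <- dim(m)[2]; W <- dim(m)[3]
  n <- P * H * W
  Q <- matrix(0i, n, n)
  for (j in seq_len(n)) {
    e <- array(0i, c(P, H, W)); e[j] <- 1 + 0i
    Q[, j] <- as.vector(normal_op(e, S, m, lambda))
  }
  Q
}

# independent SSIM: per-pixel double loop over Gaussian windows
ssim_bruteforce <- function(pred, ref, win_size = 11L, sigma = 1.5,
                            K1 = 0.01, K2 = 0.03, data_range = max(ref)) {
  h <- (win_size - 1) / 2
  g <- exp(-((-h:h)^2) / (2 * sigma^2))
  kern <- outer(g, g); kern <- kern / sum(kern)
  C1 <- (K1 * data_range)^2; C2 <- (K2 * data_range)^2
  H <- nrow(ref); W <- ncol(ref)
  vals <- c()
  for (i in (h + 1):(H - h)) for (j in (h + 1):(W - h)) {
    wx <- pred[(i - h):(i + h), (j - h):(j + h)]
    wy <- ref[(i - h):(i + h), (j - h):(j + h)]
    mx <- sum(kern * wx); my <- sum(kern * wy)
    vx <- sum(kern * wx^2) - mx^2; vy <- sum(kern * wy^2) - my^2
    vxy <- sum(kern * wx * wy) - mx * my
    vals <- c(vals, (2 * mx * my + C1) * (2 * vxy + C2) /
                ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  mean(vals)
}

# the standard toy suite: a seeded 32x32 MSME case with 4 spread echoes,
# 4 loop coils and random-point undersampling at AF 4 (ACS block 4)
toy_suite_sens <- local({
  cache <- list()
  function(H = 32, W = 32) {
    key <- paste(H, W)
    if (is.null(cache[[key]]))
      cache[[key]] <<- biot_savart_sensitivities(ring_coil_geometry(4, 100, 256), H, W)
    cache[[key]]
  }
})

toy_case <- function(case_seed, strategy = "ZSSSL", H = 32, W = 32,
                     noise_fraction = 1e-4) {
  seqp <- msme_protocol(4)
  ph <- make_tissue_phantom(H, W, seed = case_seed)
  case <- synthesize_case(ph, seqp, toy_suite_sens(H, W),
                          sim_config(c(H, W), 4, noise_fraction, seed = case_seed))
  P <- dim(case$kspace$data)[1]
  spec <- mask_spec("random_points", af = 4, acs = 4, seed = case_seed + 10L)
  omega <- gen_masks(P, H, W, spec)
  acs <- qmapnet:::acs_mask(H, W, spec)
  part <- switch(strategy,
    SL = list(omega = omega),
    SSL = {
      s <- partition_ssdu(omega, seed = case_seed + 20L, acs = acs)
      list(omega = omega, theta = s$theta, lam = s$lam)
    },
    ZSSSL = partition_zsssl(omega, seed = case_seed + 20L, acs = acs))
  list(case = case, tc = training_case(case, part, strategy), part = part,
       seqp = seqp)
}

toy_net <- function() unroll_config(n_unrolls = 3, cg_iters = 8, lambda = 0.05)

# fit maps from a complex contrast stack (magnitudes)
fit_stack <- function(x, seqp) {
  P <- dim(x)[1]
  suppressWarnings(fit_maps(lapply(seq_len(P), function(p)
    Mod(matrix(x[p, , ], dim(x)[2], dim(x)[3]))), seqp))
}

stack_nrmse <- function(a, b) sqrt(sum(Mod(a - b)^2)) / sqrt(sum(Mod(b)^2))
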