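test_that("MSME signal evaluates the mono-exponential decay", {
  expect_equal(msme_signal(1000, 100, 100), 1000 * exp(-1), tolerance = 1e-12)
  expect_equal(msme_signal(1000, 100, 100), 367.8794, tolerance = 1e-4)
  expect_equal(msme_signal(42, 77, 0), 42)
  s <- msme_signal(500, 60, seq(10, 160, 10))
  expect_true(all(diff(s) < 0))
  expect_error(msme_signal(1, -5, 10), class = "qmapnet_invalid_argument")
})

test_that("SPGR signal has the right limits and value", {
  # direct evaluation of the closed form at the two-angle protocol's TR
  expect_equal(spgr_signal(1000, 1000, 18, 24), 70.61483, tolerance = 1e-4)
  expect_lt(spgr_signal(1000, 1000, 18, 0.001), 0.1)          # alpha -> 0
  expect_equal(spgr_signal(1000, 50, 1e6, 30), 1000 * sin(30 * pi / 180),
               tolerance = 1e-6)                               # saturation
  # as-printed form differs exactly by the sin factor
  a <- 24 * pi / 180
  expect_equal(spgr_signal(7, 900, 18, 24, include_sin = FALSE) * sin(a),
               spgr_signal(7, 900, 18, 24, include_sin = TRUE))
})

test_that("qDESS ratio: correction factor, inversion point and limits", {
  qs <- qdess_protocol()
  expect_equal(qmapnet:::qdess_F(qs), 0.776485, tolerance = 1e-5)
  t2_half <- -2 * (17.9 - 5.7) / log(0.5)
  expect_equal(qdess_ratio(t2_half, qs, correction = FALSE), 0.5, tolerance = 1e-9)
  expect_equal(qdess_ratio(1e12, qs, correction = FALSE), 1, tolerance = 1e-9)
  # increasing in T2
  t2s <- seq(10, 400, by = 10)
  expect_true(all(diff(qdess_ratio(t2s, qs)) > 0))
})

test_that("noiseless fits invert the forward models over random parameter draws", {
  set.seed(42)
  msme <- msme_protocol()
  vfa <- vfa_protocol()
  qd <- qdess_protocol()
  for (i in 1:100) {
    I0 <- runif(1, 100, 2000); T2 <- runif(1, 20, 400)
    f <- fit_t2_msme(msme_signal(I0, T2, msme$TE_list), msme$TE_list)
    expect_true(f$valid)
    expect_lt(abs(f$T2 - T2) / T2, 1e-6)
    expect_lt(abs(f$I0 - I0) / I0, 1e-6)

    T1 <- runif(1, 200, 4000)
    sv <- sapply(vfa$flip_angles, function(a) spgr_signal(I0, T1, vfa$TR, a))
    fv <- fit_t1_vfa(sv, vfa$flip_angles, vfa$TR)
    expect_true(fv$valid)
    expect_lt(abs(fv$T1 - T1) / T1, 1e-6)
    expect_lt(abs(fv$I0 - I0) / I0, 1e-6)

    T2q <- runif(1, 10, 80)
    fq <- fit_t2_qdess(matrix(I0, 1, 1), matrix(I0 * qdess_ratio(T2q, qd), 1, 1), qd)
    expect_true(fq$valid[1])
    expect_lt(abs(fq$T2[1] - T2q) / T2q, 1e-6)
  }
})

test_that("degenerate fits are flagged invalid", {
  te <- seq(10, 160, 10)
  flat <- fit_t2_msme(rep(5, 16), te)            # no decay: T2 at upper bound
  expect_false(flat$valid)
  expect_false(fit_t2_msme(c(1, -1, 1, 1), te[1:4])$valid)
  expect_error(fit_t2_msme(5, 10), class = "qmapnet_invalid_argument")

  # signals rising steeply with angle imply a linearization slope >= 1
  expect_false(fit_t1_vfa(c(10, 100), c(4, 24), 18)$valid)
  expect_error(fit_t1_vfa(c(1, 2), c(10, 10), 18),
               class = "qmapnet_invalid_argument")

  qd <- qdess_protocol()
  r_big <- fit_t2_qdess(matrix(1, 1, 1), matrix(0.99, 1, 1), qd)  # r >= F
  expect_false(r_big$valid[1])
  expect_false(fit_t2_qdess(matrix(0, 1, 1), matrix(0, 1, 1), qd)$valid[1])
  expect_error(fit_t2_qdess(matrix(1, 2, 2), matrix(1, 3, 3), qd),
               class = "qmapnet_invalid_argument")
})

test_that("qDESS fit with the correction off inverts the plain FID/echo relation", {
  qd <- qdess_protocol()
  T2 <- c(15, 35, 60, 120)
  r <- qdess_ratio(T2, qd, correction = FALSE)
  f <- fit_t2_qdess(matrix(1, 2, 2), matrix(r, 2, 2), qd, correction = FALSE)
  expect_equal(as.vector(f$T2), T2, tolerance = 1e-9)
})

test_that("noisy MSME fits have small median bias at moderate SNR", {
  te <- seq(10, 160, 10)
  clean <- msme_signal(1000, 80, te)
  set.seed(11)
  t2s <- replicate(400, {
    suppressWarnings(fit_t2_msme(pmax(clean + rnorm(16, 0, 1000 / 50), 1e-6), te)$T2)
  })
  expect_lt(abs(median(t2s) - 80) / 80, 0.02)
})

test_that("sequence parameter invariants are enforced", {
  expect_error(sequence_params("MSME", TE_list = c(10, 10), TR = 4000, flip_angles = 90),
               class = "qmapnet_invalid_argument")
  expect_error(sequence_params("MSME", TE_list = c(10, 20), TR = 15, flip_angles = 90),
               class = "qmapnet_invalid_argument")
  expect_error(sequence_params("MSME", TE_list = c(10, 20), TR = 4000, flip_angles = 120),
               class = "qmapnet_invalid_argument")
  expect_error(sequence_params("VFA_SPGR", TE_list = 8, TR = 18, flip_angles = c(4, 4)),
               class = "qmapnet_invalid_argument")
  # qDESS second echo beyond TR is legitimate
  expect_s3_class(qdess_protocol(), "sequence_params")
})
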