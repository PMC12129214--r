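toy_maps <- function(T2_pred, T2_gt = rep(80, length(T2_pred))) {
  n <- length(T2_pred)
  list(
    gt = parameter_maps(T2 = matrix(T2_gt, 1, n), validity = matrix(TRUE, 1, n)),
    pred = parameter_maps(T2 = matrix(T2_pred, 1, n), validity = matrix(TRUE, 1, n))
  )
}

test_that("outlier and low-intensity exclusion rules carve the evaluation region", {
  m <- toy_maps(c(80, 600, 90))
  contr <- array(1 + 0i, c(1, 1, 3))
  phi <- evaluation_region(m$gt, m$pred, contr, region_spec("whole"))
  expect_identical(as.vector(phi), c(TRUE, FALSE, TRUE))     # T2 > 500 excluded

  m2 <- toy_maps(c(80, 80, 80))
  contr2 <- array(c(1, 0.04, 0.5) + 0i, c(1, 1, 3))
  phi2 <- evaluation_region(m2$gt, m2$pred, contr2, region_spec("whole"))
  expect_identical(as.vector(phi2), c(TRUE, FALSE, TRUE))    # < 5% of max excluded

  phi3 <- evaluation_region(m2$gt, m2$pred, contr, region_spec("whole"))
  expect_true(all(phi3))                                     # nothing to exclude

  # T1 rule
  gt <- parameter_maps(T1 = matrix(c(800, 900), 1, 2), validity = matrix(TRUE, 1, 2))
  pred <- parameter_maps(T1 = matrix(c(900, 6000), 1, 2), validity = matrix(TRUE, 1, 2))
  phi4 <- evaluation_region(gt, pred, array(1 + 0i, c(1, 1, 2)), region_spec("whole"))
  expect_identical(as.vector(phi4), c(TRUE, FALSE))
})

test_that("region variants select by ground-truth thresholds or external mask", {
  gt <- parameter_maps(T1 = matrix(c(800, 1500), 1, 2), T2 = matrix(c(100, 300), 1, 2),
                       validity = matrix(TRUE, 1, 2))
  pred <- parameter_maps(T1 = matrix(c(800, 1500), 1, 2), T2 = matrix(c(100, 300), 1, 2),
                         validity = matrix(TRUE, 1, 2))
  contr <- array(1 + 0i, c(1, 1, 2))
  expect_identical(as.vector(evaluation_region(gt, pred, contr, region_spec("t2_le_120"))),
                   c(TRUE, FALSE))
  expect_identical(as.vector(evaluation_region(gt, pred, contr, region_spec("t1_le_1000"))),
                   c(TRUE, FALSE))
  ext <- matrix(c(FALSE, TRUE), 1, 2)
  expect_identical(as.vector(evaluation_region(gt, pred, contr,
                                               region_spec("external_mask", ext))),
                   c(FALSE, TRUE))
  expect_error(region_spec("external_mask"), class = "qmapnet_invalid_argument")
})

test_that("NRMSE matches brute-force arithmetic and is scale equivariant", {
  gt <- matrix(c(2, 4, 6, 8, 10), 1, 5)
  pred <- matrix(c(2.5, 3, 7, 8, 9), 1, 5)
  phi <- matrix(c(TRUE, TRUE, TRUE, FALSE, TRUE), 1, 5)
  manual <- sqrt(0.5^2 + 1^2 + 1^2 + 1^2) / sqrt(2^2 + 4^2 + 6^2 + 10^2)
  expect_equal(nrmse(pred, gt, phi), manual, tolerance = 1e-12)
  expect_identical(nrmse(gt, gt, phi), 0)
  expect_equal(nrmse(2 * gt, gt, phi), 1, tolerance = 1e-12)
  expect_equal(nrmse(7 * pred, 7 * gt, phi), nrmse(pred, gt, phi), tolerance = 1e-12)
  expect_error(nrmse(pred, gt, phi & FALSE), class = "qmapnet_invalid_argument")
  expect_error(nrmse(pred, 0 * gt, phi), class = "qmapnet_invalid_argument")
})

test_that("SSIM agrees with an independently coded reference implementation", {
  set.seed(1)
  ref <- matrix(abs(rnorm(16 * 16, 5, 2)), 16, 16)
  pred <- ref + matrix(rnorm(16 * 16, 0, 0.5), 16, 16)
  expect_equal(ssim(pred, ref), ssim_bruteforce(pred, ref), tolerance = 1e-6)
  expect_equal(ssim(ref, ref), 1, tolerance = 1e-12)
  noisier <- ref + matrix(rnorm(16 * 16, 0, 2), 16, 16)
  expect_lt(ssim(noisier, ref), ssim(pred, ref))
  expect_error(ssim(matrix(1, 8, 8), matrix(1, 9, 9)),
               class = "qmapnet_invalid_argument")
})

test_that("case evaluation aggregates per-contrast SSIM and per-region NRMSE", {
  set.seed(2)
  H <- 16; W <- 16; P <- 2
  gt_c <- array(complex(real = abs(rnorm(P * H * W, 5, 1))), c(P, H, W))
  maps <- parameter_maps(T2 = matrix(80, H, W), validity = matrix(TRUE, H, W))
  rep1 <- evaluate_case(gt_c, gt_c, maps, maps)
  expect_true(all(rep1$ssim$value == 1))
  expect_true(all(rep1$nrmse$value == 0))
  expect_identical(nrow(rep1$ssim), as.integer(P))

  regions <- list(whole = region_spec("whole"), t2 = region_spec("t2_le_120"))
  rep2 <- evaluate_case(gt_c, gt_c, maps, maps, regions)
  expect_identical(nrow(rep2$nrmse), 2L)   # one map x two regions

  agg <- aggregate_reports(list(
    structure(list(ssim = data.frame(contrast = 1, value = 0.1),
                   nrmse = data.frame(map = "T2", region = "whole", value = 0.1)),
              class = "metrics_report"),
    structure(list(ssim = data.frame(contrast = 1, value = 0.3),
                   nrmse = data.frame(map = "T2", region = "whole", value = 0.3)),
              class = "metrics_report")))
  expect_equal(agg$nrmse$mean, 0.2)
  expect_equal(agg$ssim$mean, 0.2)
})
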