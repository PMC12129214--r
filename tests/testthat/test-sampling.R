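test_that("mask generation honors the acceleration budget and the ACS region", {
  expect_true(all(gen_mask(16, 16, mask_spec("random_lines", af = 1))))

  m <- gen_mask(256, 256, mask_spec("random_lines", af = 4, acs = 16, seed = 3))
  expect_identical(sum(m), 16384L)                      # round(256*256/4)
  ctr <- qmapnet:::center_range(256, 16)
  expect_true(all(m[ctr, ]))

  mp <- gen_mask(64, 64, mask_spec("random_points", af = 8, acs = 6, seed = 4))
  expect_identical(sum(mp), as.integer(round(64 * 64 / 8)))
  expect_true(all(mp[qmapnet:::center_range(64, 6), qmapnet:::center_range(64, 6)]))

  # ACS always sampled regardless of seed
  for (s in 1:10) {
    m2 <- gen_mask(32, 32, mask_spec("random_lines", af = 4, acs = 4, seed = s))
    expect_true(all(m2[qmapnet:::center_range(32, 4), ]))
  }
  expect_error(gen_mask(32, 32, mask_spec("random_lines", af = 16, acs = 8)),
               class = "qmapnet_invalid_argument")
})

test_that("masks are deterministic per seed and independent across contrasts", {
  spec <- mask_spec("random_points", af = 4, acs = 4, seed = 9)
  expect_identical(gen_mask(32, 32, spec), gen_mask(32, 32, spec))
  ms <- gen_masks(3, 32, 32, spec, independent = TRUE)
  expect_false(identical(ms[1, , ], ms[2, , ]))
  msr <- gen_masks(3, 32, 32, spec, independent = FALSE)
  expect_identical(msr[1, , ], msr[3, , ])
})

test_that("the 60/40 split assigns the documented counts", {
  om <- matrix(FALSE, 40, 40)
  om[sample(1600, 1000)] <- TRUE
  sp <- partition_ssdu(om, loss_fraction = 0.4, seed = 1)
  expect_identical(sum(sp$lam), 400L)
  expect_identical(sum(sp$theta), 600L)
  expect_true(all(sp$theta | sp$lam == om))
  expect_identical(sp$theta & sp$lam, matrix(FALSE, 40, 40))
  # different seeds: different draw, identical counts
  sp2 <- partition_ssdu(om, loss_fraction = 0.4, seed = 2)
  expect_false(identical(sp$lam, sp2$lam))
  expect_identical(sum(sp2$lam), 400L)
})

test_that("the nested zero-shot split yields the 20/80 then 60/40 counts", {
  set.seed(5)
  om <- matrix(FALSE, 40, 40)
  om[sample(1600, 1000)] <- TRUE
  pz <- partition_zsssl(om, seed = 3)
  expect_identical(sum(pz$gamma), 200L)
  expect_identical(sum(pz$xi), 800L)
  expect_identical(sum(pz$lam), 320L)
  expect_identical(sum(pz$theta), 480L)
  # theta retains 48% of omega
  expect_equal(sum(pz$theta) / sum(pz$omega), 0.48)
  expect_false(any(pz$theta & pz$lam) || any(pz$xi & pz$gamma) ||
                 any(pz$theta & pz$gamma) || any(pz$lam & pz$gamma))
})

test_that("partitions are disjoint covers of their parent for random masks and seeds", {
  set.seed(6)
  for (i in 1:100) {
    om <- matrix(runif(24 * 24) < runif(1, 0.2, 0.8), 24, 24)
    om[12, 12] <- TRUE
    lf <- runif(1, 0.2, 0.6); vf <- runif(1, 0.1, 0.4)
    sp <- partition_ssdu(om, lf, seed = i)
    expect_identical(sp$theta | sp$lam, om)
    expect_false(any(sp$theta & sp$lam))
    pz <- partition_zsssl(om, vf, lf, seed = i)
    expect_identical(pz$theta | pz$lam, pz$xi)
    expect_identical(pz$xi | pz$gamma, om)
    expect_false(any(pz$xi & pz$gamma))
  }
})

test_that("ACS points stay in the network-input subset", {
  spec <- mask_spec("random_points", af = 4, acs = 6, seed = 2)
  om <- gen_mask(32, 32, spec)
  acs <- qmapnet:::acs_mask(32, 32, spec)
  sp <- partition_ssdu(om, seed = 7, acs = acs)
  expect_true(all(sp$theta[acs]))
  expect_false(any(sp$lam[acs]))
  pz <- partition_zsssl(om, seed = 7, acs = acs)
  expect_true(all(pz$theta[acs]))
  expect_false(any(pz$gamma[acs]))
})

test_that("effective acceleration factors match their reported one-decimal values", {
  expect_equal(effective_af(4, 0.60), 6.6)
  expect_equal(effective_af(4, 0.48), 8.3)
  expect_equal(effective_af(8, 0.60), 13.3)
  expect_equal(effective_af(8, 0.48), 16.6)
  expect_equal(effective_af(1, 1.0), 1.0)
})

test_that("degenerate partition inputs are rejected", {
  om <- matrix(FALSE, 8, 8)
  expect_error(partition_ssdu(om), class = "qmapnet_invalid_argument")
  om[3, 3] <- TRUE
  expect_error(partition_ssdu(om, loss_fraction = 1.2),
               class = "qmapnet_invalid_argument")
  expect_error(partition_zsssl(om, validation_fraction = 0),
               class = "qmapnet_invalid_argument")
})
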