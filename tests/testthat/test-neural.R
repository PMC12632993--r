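test_that("evoked time series are amplitude-scaled HRF kernels", {
  hrf <- c(0, 0.4, 1, 0.6, 0.2)
  betas <- matrix(c(1, 0, 2, -1), nrow = 2)  # 2 voxels x 2 trials
  rd <- reconstruct_timeseries(betas, hrf, onsets = c(1, 10), n_scan = 40)
  expect_equal(rd$trials[[1]][1, ], hrf)        # unit amplitude
  expect_equal(rd$trials[[1]][2, ], rep(0, 5))  # zero amplitude
  # amplitudes (2, -1) on one kernel: scalar multiples with ratio -2
  expect_equal(rd$trials[[2]][1, ], -2 * rd$trials[[2]][2, ])
  expect_equal(rd$trials[[2]][2, ], -hrf)
  expect_error(
    reconstruct_timeseries(betas, hrf, onsets = c(1, 39), n_scan = 40),
    class = "rdmem_bounds"
  )
})

test_that("participation ratio matches its closed-form identities", {
  expect_equal(participation_ratio(c(1, 1, 1, 1)), 4)
  expect_equal(participation_ratio(c(1, 0, 0)), 1)
  expect_equal(participation_ratio(c(2, 1, 1)), 16 / 6)
  expect_error(participation_ratio(matrix(0, 4, 10)),
               class = "rdmem_undefined")
  expect_error(participation_ratio(c(1, -0.5)), class = "rdmem_validation")
})

test_that("participation ratio is scale and rotation invariant", {
  set.seed(8)
  for (i in 1:50) {
    n <- sample(5:20, 1)
    t_len <- n + sample(10:40, 1)
    x <- matrix(rnorm(n * t_len), n)
    pr <- participation_ratio(x)
    expect_gte(pr, 1)
    expect_lte(pr, n + 1e-9)
    expect_equal(participation_ratio(3.7 * x), pr, tolerance = 1e-9)
    q <- qr.Q(qr(matrix(rnorm(n * n), n)))
    expect_equal(participation_ratio(q %*% x), pr, tolerance = 1e-8)
  }
})

test_that("binned mutual information reproduces hand-computed tables", {
  # 2x2 diagonal table [[2,0],[0,2]]: MI = ln 2
  expect_equal(
    as.numeric(binned_mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1),
                                         n_bins = 2)),
    log(2)
  )
  # y = x across 4 equally occupied bins: MI = ln 4
  x <- c(1, 2, 3, 4)
  expect_equal(as.numeric(binned_mutual_information(x, x, n_bins = 4)),
               log(4))
  # constant series: 0 with a warning
  expect_warning(
    m0 <- binned_mutual_information(rep(1, 20), rnorm(20), n_bins = 4),
    "constant"
  )
  expect_equal(as.numeric(m0), 0)
  expect_error(binned_mutual_information(1:5, 1:4, 2),
               class = "rdmem_validation")
})

test_that("mutual information is symmetric and non-negative", {
  set.seed(12)
  for (i in 1:100) {
    n <- sample(50:300, 1)
    x <- rnorm(n)
    y <- if (i %% 2 == 0) rnorm(n) else x + rnorm(n, 0, 0.5)
    bins <- sample(2:16, 1)
    mxy <- as.numeric(binned_mutual_information(x, y, bins))
    myx <- as.numeric(binned_mutual_information(y, x, bins))
    expect_identical(mxy, myx)
    expect_gte(mxy, 0)
  }
})

test_that("regional signatures recover planted dimensionality differences", {
  rd <- gen_voxel_timeseries(150, n_trials_per_class = 15,
                             effective_rank = c(correct = 5,
                                                incorrect = 20),
                             seed = 7)
  sig <- region_signatures(rd, n_voxels = 100, n_iter = 40, seed = 1)
  expect_true(all(sig$iterations$delta_dim < 0))
  expect_equal(nrow(sig$iterations), 40L)
  expect_equal(unname(sig$means["delta_dim"]),
               mean(sig$iterations$delta_dim))
  # deterministic under a fixed seed
  sig2 <- region_signatures(rd, n_voxels = 100, n_iter = 40, seed = 1)
  expect_identical(sig$iterations, sig2$iterations)
  # exchangeable outcomes: expected difference is 0
  rd0 <- gen_voxel_timeseries(120, n_trials_per_class = 15,
                              effective_rank = 10, seed = 9)
  sig0 <- region_signatures(rd0, n_voxels = 80, n_iter = 40, seed = 2)
  expect_lt(abs(mean(sig0$iterations$delta_dim)), 0.05 * 80)
})

test_that("coupled target-lure series carry more mutual information", {
  rc <- gen_voxel_timeseries(120, 15, 10, dependence = "coupled",
                             coupling = 0.9, seed = 3)
  ri <- gen_voxel_timeseries(120, 15, 10, dependence = "independent",
                             seed = 3)
  sc <- region_signatures(rc, n_voxels = 80, n_iter = 15, seed = 5)
  si <- region_signatures(ri, n_voxels = 80, n_iter = 15, seed = 5)
  expect_gt(sc$means[["mi_correct"]], si$means[["mi_correct"]])
})

test_that("the hierarchy gradient is a rank correlation over regions", {
  mk <- function(region, delta) {
    structure(list(region = region,
                   means = c(delta_dim = delta)),
              class = "neural_signature")
  }
  sigs <- list(mk("V1", -0.5), mk("V4", -1.2), mk("IT", -2.0),
               mk("CA1", -3.1))
  g <- region_gradient(sigs, order = c("V1", "V4", "IT", "CA1"))
  expect_equal(g$rho, -1)
  # shuffled planting: small correlation on average
  set.seed(4)
  rhos <- replicate(100, {
    d <- sample(c(-0.5, -1.2, -2.0, -3.1))
    region_gradient(list(mk("a", d[1]), mk("b", d[2]), mk("c", d[3]),
                         mk("d", d[4])))$rho
  })
  expect_lt(abs(mean(rhos)), 0.2)
  # all tied: undefined, flagged
  expect_warning(
    gt <- region_gradient(list(mk("a", -1), mk("b", -1), mk("c", -1))),
    "tied"
  )
  expect_true(is.na(gt$rho))
})
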