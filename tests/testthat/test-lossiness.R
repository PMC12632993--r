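test_that("interpolation endpoints are exact and steps evenly spaced", {
  tg <- c(1, 0, 0, 0)
  lu <- c(0, 1, 0, 0)
  p <- interpolate_path(tg, lu, k = 1)
  expect_identical(p[1, ], tg)
  expect_identical(p[3, ], lu)
  expect_equal(p[2, ], c(0.5, 0.5, 0, 0))
  # degenerate pair: all rows identical
  pd <- interpolate_path(tg, tg, k = 4)
  expect_true(all(apply(pd, 1, identical, tg)))
  # arbitrary pair, k = 10: equal Euclidean steps
  set.seed(3)
  a <- rnorm(12); b <- rnorm(12)
  pp <- interpolate_path(a, b, k = 10)
  steps <- sqrt(rowSums(diff(pp)^2))
  expect_equal(steps, rep(steps[1], 11), tolerance = 1e-12)
  expect_error(interpolate_path(1:3, 1:4), class = "rdmem_validation")
})

test_that("confusion construction matches the hand-computed 2x2 cases", {
  # identical rows: every similarity 1, probabilities uniform
  p <- matrix(rep(c(1, 2, 2), 3), nrow = 3, byrow = TRUE)
  cm <- confusion_from_path(p, n_samples = 30, seed = 1)
  expect_equal(cm$probability, matrix(1 / 3, 3, 3), tolerance = 1e-12)
  # two orthogonal rows: off-diagonal similarity 0, identity probabilities
  cm2 <- confusion_from_path(diag(2), n_samples = 250, seed = 2)
  expect_equal(cm2$probability, diag(2))
  expect_equal(cm2$counts, diag(2) * 250, ignore_attr = TRUE)
  # multinomial budget per row, reproducible under seed
  path <- interpolate_path(c(1, 0, 0), c(0, 1, 0), k = 3)
  c1 <- confusion_from_path(path, n_samples = 250, seed = 9)
  c2 <- confusion_from_path(path, n_samples = 250, seed = 9)
  expect_identical(c1$counts, c2$counts)
  expect_equal(unname(rowSums(c1$counts)), rep(250, 5))
  expect_error(confusion_from_path(matrix(0, 2, 3)),
               class = "rdmem_zero_norm")
})

test_that("optimal channel matches the binary Hamming closed form", {
  # R(D) = ln2 - Hb(D) for a uniform binary source under Hamming cost
  hb <- function(d) -d * log(d) - (1 - d) * log(1 - d)
  for (p0 in c(0.5, 0.3)) {
    src <- c(p0, 1 - p0)
    hsrc <- -sum(src * log(src))
    for (s in seq(0.3, 5, by = 0.1)) {
      ch <- optimal_channel(1 - diag(2), src, s)
      d <- ch$distortion
      if (p0 == 0.5 && d >= 0.05 && d <= 0.45) {
        expect_lt(abs(ch$rate - (log(2) - hb(d))), 1e-3)
      }
      expect_equal(unname(rowSums(ch$channel)), c(1, 1), tolerance = 1e-9)
      expect_gte(ch$rate, 0)
      expect_lte(ch$rate, log(2) + 1e-12)
    }
  }
})

test_that("optimal channel limits: zero trade-off and lossless", {
  cost <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3, byrow = TRUE)
  src <- rep(1 / 3, 3)
  ch0 <- optimal_channel(cost, src, s = 0)
  expect_equal(ch0$rate, 0, tolerance = 1e-12)
  for (i in 1:3) expect_equal(ch0$channel[i, ], ch0$marginal)
  chL <- optimal_channel(cost, src, s = 60)
  expect_equal(unname(chL$channel), diag(3), tolerance = 1e-8)
  expect_equal(chL$distortion, 0, tolerance = 1e-8)
  expect_equal(chL$rate, log(3), tolerance = 1e-6)
  expect_error(optimal_channel(cost, src, s = -1),
               class = "rdmem_invalid_parameter")
})

test_that("the rate-distortion frontier is monotone along an s-sweep", {
  set.seed(11)
  n <- 5
  cost <- matrix(abs(rnorm(n * n)), n)
  cost <- (cost + t(cost)) / 2
  diag(cost) <- 0
  src <- rep(1 / n, n)
  sweep <- lapply(seq(0, 8, by = 0.25), function(s) {
    optimal_channel(cost, src, s)
  })
  rates <- vapply(sweep, `[[`, numeric(1), "rate")
  dists <- vapply(sweep, `[[`, numeric(1), "distortion")
  expect_true(all(diff(rates) >= -1e-9))
  expect_true(all(diff(dists) <= 1e-9))
})

test_that("cost fitting recovers planted structure and behaves at limits", {
  # counts from a known symmetric 3-symbol channel: ordering recovered
  d_true <- matrix(c(0, 1, 3, 1, 0, 2, 3, 2, 0), 3, byrow = TRUE)
  ch <- optimal_channel(d_true, rep(1 / 3, 3), s = 1.5)
  set.seed(1)
  counts <- t(sapply(1:3, function(i) {
    rmultinom(1, 2e4, ch$channel[i, ])[, 1]
  }))
  fit <- fit_cost_matrix(counts, config = list(n_restarts = 4), seed = 2)
  sym <- (fit$cost + t(fit$cost)) / 2
  expect_equal(
    cor(rdmem:::offdiag(sym), rdmem:::offdiag(d_true), method = "spearman"),
    1
  )
  # the log-likelihood trace never decreases
  expect_true(all(diff(fit$trace) >= 0))
  # identity counts: near-diagonal channel, per-observation LL near 0
  idc <- diag(6) * 500
  fid <- fit_cost_matrix(idc, config = list(n_restarts = 2), seed = 3)
  expect_gt(mean(diag(fid$channel)), 0.95)
  expect_gt(fid$logLik / sum(idc), -0.05)
  expect_lte(fid$logLik, 0)
  # uniform counts: symmetric near-constant (small) off-diagonal costs
  unif <- matrix(50, 4, 4)
  fu <- fit_cost_matrix(unif, config = list(n_restarts = 2), seed = 4)
  offd <- rdmem:::offdiag(fu$cost)
  expect_lt(max(offd) - min(offd), 0.05)
  expect_lt(fu$lossiness, 0.1)
  expect_error(fit_cost_matrix(matrix(c(1, -1, 0, 2), 2), seed = 1),
               class = "rdmem_validation")
  expect_error(fit_cost_matrix(matrix(c(0, 0, 1, 2), 2, byrow = TRUE),
                               seed = 1),
               class = "rdmem_validation")
})

test_that("pair lossiness is deterministic and geometry-driven", {
  cfg <- list(n_restarts = 2, n_iter = 60)
  es <- gen_embedding_pairs(1, dim = 16, separation = 1.2, seed = 21)
  tg <- es$items[1, ]
  lu <- es$items[2, ]
  l1 <- pair_lossiness(tg, lu, config = cfg, seed = 7)
  l2 <- pair_lossiness(tg, lu, config = cfg, seed = 7)
  expect_identical(as.numeric(l1), as.numeric(l2))
  # identical pair is less lossy than a well-separated one
  l_same <- pair_lossiness(tg, tg, config = cfg, seed = 7)
  expect_lt(as.numeric(l_same), as.numeric(l1))
  # cosine geometry only: invariant to a joint orthogonal rotation
  set.seed(5)
  q <- qr.Q(qr(matrix(rnorm(256), 16)))
  l_rot <- pair_lossiness(as.vector(tg %*% q), as.vector(lu %*% q),
                          config = cfg, seed = 7)
  expect_equal(as.numeric(l_rot), as.numeric(l1), tolerance = 1e-6)
})
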