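test_that("embedding pairs plant the requested angular separation", {
  es <- gen_embedding_pairs(5, dim = 16, separation = pi / 2, seed = 1)
  for (i in seq_len(5)) {
    tg <- es$items[es$pairs$target[i], ]
    lu <- es$items[es$pairs$lure[i], ]
    expect_equal(1 - sum(tg * lu), 1, tolerance = 1e-9)  # orthogonal
  }
  # near-identity limit: cosine distance tends to 0
  es0 <- gen_embedding_pairs(2, dim = 16, separation = 1e-5, seed = 1)
  d0 <- 1 - sum(es0$items[1, ] * es0$items[2, ])
  expect_lt(d0, 1e-9)
  # rows are unit norm, no zero rows
  expect_equal(unname(sqrt(rowSums(es$items^2))), rep(1, 10))
})

test_that("embedding generation is bitwise reproducible and validates input", {
  a <- gen_embedding_pairs(50, dim = 64,
                           separation = list(min = 0.1, max = 1.5),
                           seed = 1)
  b <- gen_embedding_pairs(50, dim = 64,
                           separation = list(min = 0.1, max = 1.5),
                           seed = 1)
  expect_identical(a$items, b$items)
  expect_error(gen_embedding_pairs(1, dim = 1, separation = 1, seed = 1),
               class = "rdmem_invalid_parameter")
  expect_error(gen_embedding_pairs(1, dim = 4, separation = pi, seed = 1),
               class = "rdmem_invalid_parameter")
  expect_error(gen_embedding_pairs(1, dim = 4, separation = -0.1, seed = 1),
               class = "rdmem_invalid_parameter")
})

test_that("shape images are deterministic and factor changes stay in the mask", {
  f <- data.frame(shape = "circle", hue = 0.1, scale = 0.6,
                  cx = 0.5, cy = 0.5)
  a <- gen_shape_images(1, size = 16, factors = f)
  b <- gen_shape_images(1, size = 16, factors = f)
  expect_identical(a$images, b$images)
  # color-only variant: differences confined to the shape mask
  f2 <- f
  f2$hue <- 0.6
  c2 <- gen_shape_images(1, size = 16, factors = f2)
  diff_mask <- apply(abs(a$images[1, , , ] - c2$images[1, , , ]), c(1, 2),
                     max) > 0
  shape_mask <- apply(a$images[1, , , ], c(1, 2), max) > 0
  expect_true(all(!diff_mask | shape_mask))
  expect_true(any(diff_mask))
  # values bounded, seeded draw reproducible
  r1 <- gen_shape_images(8, size = 16, seed = 9)
  r2 <- gen_shape_images(8, size = 16, seed = 9)
  expect_identical(r1$images, r2$images)
  expect_true(all(r1$images >= 0 & r1$images <= 1))
  expect_error(gen_shape_images(0, size = 16, seed = 1),
               class = "rdmem_invalid_parameter")
})

test_that("task designs respect ordering and bin placement", {
  tc <- gen_task_tables("continuous", seed = 4)
  # every repeat/lure appears after its first presentation
  first_pos <- match(tc$stimulus[tc$condition == "first"], tc$stimulus)
  names(first_pos) <- tc$stimulus[tc$condition == "first"]
  for (i in which(tc$condition %in% c("target", "lure"))) {
    base <- sub("L$", "", tc$stimulus[i])
    expect_lt(first_pos[[base]], i)
  }
  # lure bins only on lure trials
  expect_true(all(is.na(tc$lure_bin[tc$condition %in% c("first", "foil")])))
  expect_true(all(!is.na(tc$lure_bin[tc$condition == "lure"])))
  tm <- gen_task_tables("mst", seed = 5)
  expect_true(all(tm$condition[tm$phase == "study"] == "first"))
  expect_true(all(is.na(tm$lure_bin[tm$condition != "lure"])))
  expect_error(
    gen_task_tables("continuous", params = list(mean_lag = 0.5), seed = 1),
    class = "rdmem_constraint"
  )
  expect_error(
    gen_task_tables("mst", params = list(n_target = 100, n_lure = 100),
                    seed = 1),
    class = "rdmem_constraint"
  )
})

test_that("response policy hits its limit cases", {
  tab <- gen_task_tables("mst", seed = 1)
  # perfect discriminability, no bias toward "similar": LDI = 1
  r1 <- gen_responses(tab, discriminability = 1,
                      bias = c(old = 0, similar = 0, new = 1),
                      target_acc = 1, miss_rate = 0, seed = 2)
  m1 <- compute_metrics(r1)
  expect_equal(m1$ldi, 1)
  expect_equal(m1$recognition, 1)
  expect_equal(m1$lure_fa, 0)
  # zero discriminability with equiprobable bias: LDI is 0 in expectation
  # (exactness checked at scale in the acceptance suite)
  r0 <- gen_responses(tab, discriminability = 0,
                      bias = c(old = 1, similar = 1, new = 1) / 3,
                      target_acc = 0, miss_rate = 0, seed = 3)
  m0 <- compute_metrics(r0)
  expect_lt(abs(m0$ldi), 0.25)
  expect_error(
    gen_responses(tab, discriminability = 1.2, seed = 1),
    class = "rdmem_invalid_parameter"
  )
  expect_error(
    gen_responses(tab, bias = c(old = 0.5, similar = 0.4, new = 0.4),
                  seed = 1),
    class = "rdmem_invalid_parameter"
  )
})

test_that("per-bin discriminability is recovered in rank order", {
  disc <- c("1" = 0.1, "2" = 0.3, "3" = 0.5, "4" = 0.7, "5" = 0.9)
  base <- gen_task_tables("mst", seed = 6)
  tabs <- lapply(1:40, function(p) {
    t1 <- base
    t1$participant <- sprintf("p%03d", p)
    gen_responses(t1, discriminability = disc, miss_rate = 0, seed = 100 + p)
  })
  m <- compute_metrics(do.call(rbind, tabs))
  per_bin <- attr(m, "per_bin")
  bin_ldi <- tapply(per_bin$ldi, per_bin$bin, mean)
  expect_equal(unname(cor(seq_len(5), bin_ldi, method = "spearman")), 1)
})

test_that("voxel generator plants the requested participation ratio", {
  # flat spectrum and rank-one limits of the planted spectrum
  expect_equal(rdmem:::pr_spectrum(10, 10), rep(1, 10))
  expect_equal(participation_ratio(rdmem:::pr_spectrum(1, 5)), 1)
  # planted intermediate ranks are exact
  for (er in c(2.5, 5, 17.3)) {
    expect_equal(participation_ratio(rdmem:::pr_spectrum(er, 40)), er,
                 tolerance = 1e-8)
  }
  # estimator applied to its own generator: within 10% at ~500 points
  rd <- gen_voxel_timeseries(120, n_trials_per_class = 11,
                             effective_rank = 10, n_timepoints = 46,
                             seed = 7)
  keep <- rd$labels$role == "lure" & rd$labels$outcome == "correct"
  x <- do.call(cbind, rd$trials[keep])
  expect_gte(ncol(x), 500)
  expect_equal(participation_ratio(x), 10, tolerance = 0.1)
  expect_error(
    gen_voxel_timeseries(10, 5, effective_rank = 11, seed = 1),
    class = "rdmem_invalid_parameter"
  )
  # reproducibility
  a <- gen_voxel_timeseries(20, 3, 4, seed = 5)
  b <- gen_voxel_timeseries(20, 3, 4, seed = 5)
  expect_identical(a$trials, b$trials)
})
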