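test_that("trial-level QC retains exactly the hand-counted trials", {
  tab <- make_response_table(lure = c(similar = 2, old = 1, new = 1),
                             foil = c(similar = 0, old = 0, new = 3),
                             target = c(similar = 0, old = 3, new = 0))
  # 10 trials: two too fast, one too slow
  tab$rt <- c(0.2, 0.2, rep(1, 6), 3.5, 1)[seq_len(nrow(tab))]
  qc <- apply_qc(tab, thresholds = list(min_recognition = 0,
                                        min_ldi = -1))
  expect_equal(nrow(qc$table), 7L)
  expect_equal(qc$n_trials_removed, 3L)
  expect_true(all(qc$report$rule == "rt_window"))
  # the 3.0 s boundary itself is retained (ceiling is exclusive)
  tab2 <- make_response_table()
  tab2$rt <- 3.0
  qc2 <- apply_qc(tab2, thresholds = list(min_recognition = 0))
  expect_equal(nrow(qc2$table), nrow(tab2))
})

test_that("participant-level QC applies missingness and performance rules", {
  # 25% missing responses: excluded under the 20% rule
  tab <- make_response_table(lure = c(similar = 5, old = 5, new = 2),
                             foil = c(similar = 0, old = 0, new = 4),
                             target = c(similar = 0, old = 4, new = 0))
  tab$response[1:5] <- NA
  expect_equal(mean(is.na(tab$response)), 0.25)
  qc <- apply_qc(tab)
  expect_equal(nrow(qc$table), 0L)
  expect_true("missing_rate" %in% qc$report$rule)
  # LDI exactly 0 is retained (minimum is inclusive)
  t0 <- make_response_table(lure = c(similar = 2, old = 4, new = 4),
                            foil = c(similar = 2, old = 1, new = 7),
                            target = c(similar = 0, old = 9, new = 1))
  m <- compute_metrics(t0)
  expect_equal(m$ldi, 0)
  expect_gte(m$recognition, 0.5)
  expect_gt(nrow(apply_qc(t0)$table), 0L)
  # negative LDI is excluded
  tneg <- make_response_table(lure = c(similar = 0, old = 5, new = 5),
                              foil = c(similar = 5, old = 0, new = 5),
                              target = c(similar = 0, old = 9, new = 1))
  expect_equal(nrow(apply_qc(tneg)$table), 0L)
})

test_that("longitudinal QC judges performance on the immediate session only", {
  good <- make_response_table(session = "immediate")
  bad_delayed <- make_response_table(session = "delayed",
                                     lure = c(similar = 0, old = 5, new = 5),
                                     foil = c(similar = 5, old = 0, new = 5),
                                     target = c(similar = 0, old = 9,
                                                new = 1))
  both <- rbind(good, bad_delayed)
  qc <- apply_qc(both)
  # retained despite negative delayed-session LDI
  expect_equal(sort(unique(qc$table$session)), c("delayed", "immediate"))
})

test_that("QC is idempotent", {
  tab <- gen_responses(gen_task_tables("mst", seed = 2),
                       discriminability = 0.6, seed = 3)
  tab$rt[1:140] <- c(rep(0.1, 5), rep(1, 135))
  once <- apply_qc(tab)
  twice <- apply_qc(once$table)
  expect_equal(once$table, twice$table)
})

test_that("behavioral indices follow their defining algebra", {
  tab <- make_response_table(lure = c(similar = 6, old = 2, new = 2),
                             foil = c(similar = 1, old = 1, new = 8),
                             target = c(similar = 1, old = 8, new = 1))
  m <- compute_metrics(tab)
  expect_equal(m$ldi, 0.6 - 0.1)
  expect_equal(m$recognition, 0.8 - 0.1)
  expect_equal(m$lure_fa, 0.2 - 0.1)
  # identity: LDI + p(similar|foil) = p(similar|lure), and permutation
  # invariance of all indices
  expect_equal(m$ldi + m$p_sim_foil, m$p_sim_lure)
  perm <- tab[sample(nrow(tab)), ]
  mp <- compute_metrics(perm)
  expect_equal(mp$ldi, m$ldi)
  expect_equal(mp$recognition, m$recognition)
  expect_equal(mp$lure_fa, m$lure_fa)
})

test_that("empty denominators are flagged as undefined, not zeroed", {
  tab <- make_response_table()
  no_foil <- tab[tab$condition != "foil", ]
  m <- compute_metrics(no_foil)
  expect_true(is.na(m$ldi))
  expect_true(m$undefined)
  expect_error(compute_metrics(tab[tab$phase != "test", ]),
               class = "rdmem_schema")
})

test_that("bin aggregation joins lossiness and is deterministic", {
  base <- gen_task_tables("mst", seed = 11)
  t1 <- gen_responses(base, discriminability = 0.7, miss_rate = 0,
                      seed = 1)
  t2 <- t1
  t2$participant <- "p02"
  lure_ids <- unique(base$stimulus[base$condition == "lure"])
  loss <- setNames(seq_along(lure_ids) / length(lure_ids), lure_ids)
  bt <- bin_and_aggregate(list(t1, t2), loss)
  expect_equal(sort(unique(bt$bin)), 1:5)
  # identical responses: identical rows apart from participant id
  b1 <- bt[bt$participant == "p01", setdiff(names(bt), "participant")]
  b2 <- bt[bt$participant == "p02", setdiff(names(bt), "participant")]
  expect_equal(b1, b2, ignore_attr = TRUE)
  # bin-level lossiness is the mean over that bin's items
  items1 <- unique(base$stimulus[base$condition == "lure" &
                                   base$lure_bin == 1])
  expect_equal(bt$lossiness[bt$bin == 1][1], mean(loss[items1]))
  # all items in one bin collapses to one row per participant
  one_bin <- base
  one_bin$lure_bin[one_bin$condition == "lure"] <- 1L
  ob <- bin_and_aggregate(gen_responses(one_bin, 0.7, seed = 2), loss)
  expect_equal(nrow(ob), 1L)
  expect_equal(ob$lossiness, mean(loss))
  expect_error(bin_and_aggregate(t1, loss[-1]),
               class = "rdmem_aggregation")
})
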