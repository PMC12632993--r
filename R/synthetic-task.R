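#' Generate Mnemonic Similarity Task trial tables
#'
#' Builds the trial-level design table for either the classic study/test
#' MST (`"mst"`) or the continuous-recognition variant (`"continuous"`).
#'
#' The classic design has an incidental study phase followed by a surprise
#' test in which previously studied items reappear exactly (`target`
#' repeats), as similar-but-different `lure` images, or as unrelated `foil`
#' images; defaults are 128 study trials and 192 test trials split in equal
#' thirds (the test composition is a parameter; no canonical split is
#' assumed). The continuous design interleaves everything in one stream:
#' each block holds 32 first presentations, 16 exact repeats (targets), 16
#' similar lures and 43 unrelated foils (107 stimuli per block; six blocks
#' give 642), with repeat/lure lags drawn from a geometric distribution
#' with configurable mean and every repeat or lure scheduled after its
#' first presentation.
#'
#' @param design `"mst"` or `"continuous"`.
#' @param params named list of overrides. For `"mst"`: `n_study` (128),
#'   `n_target`, `n_lure`, `n_foil` (64 each), `n_bins` (5). For
#'   `"continuous"`: `n_blocks` (6), `n_first` (32), `n_target` (16),
#'   `n_lure` (16), `n_foil` (43), `mean_lag` (19), `n_bins` (5). Shared:
#'   `participant` ("p01"), `session` ("immediate"), `age` (20).
#' @param seed integer seed.
#' @return A `trial_table` data frame with columns `participant`, `session`,
#'   `phase`, `trial`, `stimulus`, `condition` (`first`, `target`, `lure`,
#'   `foil`), `lure_bin` (1..5 on lure trials, NA otherwise), `response`,
#'   `rt`, `age`. Responses and RTs are NA until [gen_responses()] fills
#'   them.
#' @export
gen_task_tables <- function(design = c("mst", "continuous"),
                            params = list(), seed = 1L) {
  design <- match.arg(design)
  p <- utils::modifyList(list(participant = "p01", session = "immediate",
                              age = 20, n_bins = 5L), params)
  tab <- with_seed(seed, {
    if (design == "mst") gen_mst_design(p) else gen_continuous_design(p)
  })
  tab$participant <- p$participant
  tab$session <- p$session
  tab$age <- p$age
  cols <- c("participant", "session", "phase", "trial", "stimulus",
            "condition", "lure_bin", "response", "rt", "age")
  tab$response <- NA_character_
  tab$rt <- NA_real_
  tab <- tab[, cols]
  class(tab) <- c("trial_table", "data.frame")
  tab
}

gen_mst_design <- function(p) {
  n_study <- p$n_study %||% 128L
  n_target <- p$n_target %||% 64L
  n_lure <- p$n_lure %||% 64L
  n_foil <- p$n_foil %||% 64L
  if (n_target + n_lure > n_study) {
    stop_rdmem("more repeats+lures than studied items",
               class = "rdmem_constraint")
  }
  study_ids <- sprintf("s%03d", seq_len(n_study))
  study <- data.frame(
    phase = "study", trial = seq_len(n_study),
    stimulus = sample(study_ids), condition = "first",
    lure_bin = NA_integer_, stringsAsFactors = FALSE
  )
  chosen <- sample(study_ids, n_target + n_lure)
  targets <- chosen[seq_len(n_target)]
  lure_of <- chosen[n_target + seq_len(n_lure)]
  test <- data.frame(
    phase = "test",
    stimulus = c(targets, paste0(lure_of, "L"),
                 sprintf("f%03d", seq_len(n_foil))),
    condition = rep(c("target", "lure", "foil"),
                    c(n_target, n_lure, n_foil)),
    lure_bin = c(rep(NA_integer_, n_target),
                 sample(rep_len(seq_len(p$n_bins), n_lure)),
                 rep(NA_integer_, n_foil)),
    stringsAsFactors = FALSE
  )
  test <- test[sample(nrow(test)), ]
  test$trial <- seq_len(nrow(test))
  rbind(study[, c("phase", "trial", "stimulus", "condition", "lure_bin")],
        test[, c("phase", "trial", "stimulus", "condition", "lure_bin")])
}

gen_continuous_design <- function(p) {
  n_blocks <- p$n_blocks %||% 6L
  n_first <- p$n_first %||% 32L
  n_target <- p$n_target %||% 16L
  n_lure <- p$n_lure %||% 16L
  n_foil <- p$n_foil %||% 43L
  mean_lag <- p$mean_lag %||% 19
  if (mean_lag <= 1) {
    stop_rdmem("mean_lag must exceed 1", class = "rdmem_constraint")
  }
  if (n_target + n_lure > n_first) {
    stop_rdmem("each repeat/lure needs its own first presentation",
               class = "rdmem_constraint")
  }
  blocks <- lapply(seq_len(n_blocks), function(b) {
    first_ids <- sprintf("b%d_i%02d", b, seq_len(n_first))
    # which first presentations are followed by an exact repeat or a lure
    followed <- sample(first_ids, n_target + n_lure)
    follow_type <- stats::setNames(
      rep(c("target", "lure"), c(n_target, n_lure)), followed)
    pool <- data.frame(
      stimulus = c(first_ids, sprintf("b%d_f%02d", b, seq_len(n_foil))),
      condition = rep(c("first", "foil"), c(n_first, n_foil)),
      stringsAsFactors = FALSE
    )
    pool <- pool[sample(nrow(pool)), ]
    n_slots <- n_first + n_target + n_lure + n_foil
    out <- vector("list", n_slots)
    pending <- data.frame(stimulus = character(), condition = character(),
                          due = numeric(), stringsAsFactors = FALSE)
    nxt <- 1L
    for (slot in seq_len(n_slots)) {
      due_now <- which(pending$due <= slot)
      if ((length(due_now) > 0L) || nxt > nrow(pool)) {
        take <- if (length(due_now) > 0L) {
          due_now[which.min(pending$due[due_now])]
        } else {
          which.min(pending$due)
        }
        out[[slot]] <- pending[take, c("stimulus", "condition")]
        pending <- pending[-take, , drop = FALSE]
      } else {
        row <- pool[nxt, , drop = FALSE]
        nxt <- nxt + 1L
        out[[slot]] <- row
        if (row$condition == "first" && row$stimulus %in% followed) {
          typ <- follow_type[[row$stimulus]]
          lag <- 1L + rgeom(1L, prob = 1 / (mean_lag - 1))
          pending <- rbind(pending, data.frame(
            stimulus = if (typ == "lure") paste0(row$stimulus, "L")
                       else row$stimulus,
            condition = typ, due = slot + lag, stringsAsFactors = FALSE
          ))
        }
      }
    }
    blk <- do.call(rbind, out)
    blk$block <- b
    blk
  })
  tab <- do.call(rbind, blocks)
  tab$phase <- "test"
  tab$trial <- seq_len(nrow(tab))
  tab$lure_bin <- NA_integer_
  is_lure <- tab$condition == "lure"
  tab$lure_bin[is_lure] <- sample(rep_len(seq_len(p$n_bins), sum(is_lure)))
  tab[, c("phase", "trial", "stimulus", "condition", "lure_bin")]
}

#' Simulate responses for a trial table
#'
#' Fills the `response` and `rt` columns of a design table with a documented
#' three-alternative policy. On a lure trial with item discriminability
#' `d` in `[0, 1]`, the response is "similar" (correct) with probability
#' `d + (1 - d) * bias["similar"]` and otherwise follows the `bias` vector,
#' so the probability of a correct lure rejection increases monotonically
#' with discriminability. Target (repeat) trials answer "old" with
#' probability `target_acc + (1 - target_acc) * bias["old"]`; foil and
#' first-presentation trials respond from `bias` alone. Responses go
#' missing completely at random at rate `miss_rate`; RTs are lognormal.
#' Study-phase rows are left without old/similar/new responses.
#'
#' @param table a `trial_table` from [gen_task_tables()].
#' @param discriminability single number in `[0,1]`, or a named vector
#'   mapping lure stimulus ids (or `lure_bin` values as names `"1"..."5"`)
#'   to discriminabilities.
#' @param bias probability vector over `c(old, similar, new)` governing the
#'   non-discriminated response component; must sum to 1.
#' @param target_acc probability of answering "old" on a repeat via the
#'   memory route.
#' @param miss_rate probability of a missing response per test trial.
#' @param rt_meanlog,rt_sdlog lognormal RT parameters (seconds).
#' @param seed integer seed.
#' @return the table with `response` and `rt` filled on test-phase rows.
#' @export
gen_responses <- function(table, discriminability = 0.7,
                          bias = c(old = 0.2, similar = 0.2, new = 0.6),
                          target_acc = 0.9, miss_rate = 0.02,
                          rt_meanlog = log(0.9), rt_sdlog = 0.3,
                          seed = 1L) {
  stopifnot(is.data.frame(table))
  bias <- bias[c("old", "similar", "new")]
  if (any(is.na(bias)) || any(bias < 0) || any(bias > 1) ||
      abs(sum(bias) - 1) > 1e-8) {
    stop_rdmem("`bias` must be probabilities over (old, similar, new) summing to 1",
               class = "rdmem_invalid_parameter")
  }
  if (any(discriminability < 0) || any(discriminability > 1)) {
    stop_rdmem("discriminability must lie in [0, 1]",
               class = "rdmem_invalid_parameter")
  }
  if (miss_rate < 0 || miss_rate > 1 || target_acc < 0 || target_acc > 1) {
    stop_rdmem("probabilities must lie in [0, 1]",
               class = "rdmem_invalid_parameter")
  }
  test <- which(table$phase == "test")
  n <- length(test)
  cond <- table$condition[test]
  disc <- rep(0, n)
  is_lure <- cond == "lure"
  if (length(discriminability) == 1L && is.null(names(discriminability))) {
    disc[is_lure] <- discriminability
  } else {
    key <- table$stimulus[test]
    hit <- key %in% names(discriminability)
    # fall back to lure-bin keyed lookup
    bin_key <- as.character(table$lure_bin[test])
    use_bin <- !hit & is_lure & bin_key %in% names(discriminability)
    disc[hit] <- discriminability[key[hit]]
    disc[use_bin] <- discriminability[bin_key[use_bin]]
    if (any(is_lure & !hit & !use_bin)) {
      stop_rdmem("discriminability undefined for some lure items",
                 class = "rdmem_invalid_parameter")
    }
    disc[!is_lure] <- 0
  }
  with_seed(seed, {
    p_old <- rep(bias["old"], n)
    p_sim <- rep(bias["similar"], n)
    p_new <- rep(bias["new"], n)
    p_sim[is_lure] <- disc[is_lure] + (1 - disc[is_lure]) * bias["similar"]
    p_old[is_lure] <- (1 - disc[is_lure]) * bias["old"]
    p_new[is_lure] <- (1 - disc[is_lure]) * bias["new"]
    is_tgt <- cond == "target"
    p_old[is_tgt] <- target_acc + (1 - target_acc) * bias["old"]
    p_sim[is_tgt] <- (1 - target_acc) * bias["similar"]
    p_new[is_tgt] <- (1 - target_acc) * bias["new"]
    u <- runif(n)
    resp <- ifelse(u < p_old, "old",
                   ifelse(u < p_old + p_sim, "similar", "new"))
    miss <- runif(n) < miss_rate
    resp[miss] <- NA_character_
    rt <- rlnorm(n, rt_meanlog, rt_sdlog)
    rt[miss] <- NA_real_
    table$response[test] <- resp
    table$rt[test] <- rt
  })
  table
}
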