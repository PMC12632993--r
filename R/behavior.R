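#' Quality control for Mnemonic Similarity Task trial tables
#'
#' Applies the standard exclusion cascade. Trial level first: test-phase
#' trials with a response faster than `rt_min` seconds or slower than
#' `rt_max` seconds are dropped (the ceiling is exclusive: exactly
#' `rt_max` is retained). Participant level next, computed on the
#' post-trial-QC data: participants missing more than `max_missing` of
#' their test trials, with a lure discrimination index below `min_ldi`, or
#' a recognition score below `min_recognition` are excluded (the minima
#' are inclusive: a participant exactly at the threshold is retained). For
#' longitudinal tables (multiple sessions per participant) the performance
#' thresholds are evaluated on the `"immediate"` session only, and an
#' excluded participant is removed from all sessions.
#'
#' @param table a `trial_table`.
#' @param thresholds named list overriding any of `rt_min` (0.3), `rt_max`
#'   (3), `max_missing` (0.2), `min_ldi` (0), `min_recognition` (0.5).
#'   Setting `count_rt_excluded_as_missed = TRUE` counts trial-QC removals
#'   toward the missing rate in addition to true non-responses.
#' @return list with `table` (the retained trials), `report` (a data
#'   frame listing every exclusion with its rule and value) and
#'   `n_trials_removed`, `participants_removed`.
#' @export
apply_qc <- function(table, thresholds = list()) {
  th <- utils::modifyList(list(
    rt_min = 0.3, rt_max = 3, max_missing = 0.2, min_ldi = 0,
    min_recognition = 0.5, count_rt_excluded_as_missed = FALSE
  ), thresholds)
  need <- c("participant", "session", "phase", "condition", "response", "rt")
  if (!all(need %in% names(table))) {
    stop_rdmem("missing required columns: ",
               paste(setdiff(need, names(table)), collapse = ", "),
               class = "rdmem_schema")
  }
  is_test <- table$phase == "test"
  bad_rt <- is_test & !is.na(table$rt) &
    (table$rt < th$rt_min | table$rt > th$rt_max)
  report <- list()
  if (any(bad_rt)) {
    report[[length(report) + 1L]] <- data.frame(
      participant = table$participant[bad_rt], rule = "rt_window",
      value = table$rt[bad_rt], stringsAsFactors = FALSE)
  }
  kept <- table[!bad_rt, , drop = FALSE]

  # participant-level rules on post-trial-QC data
  per <- split(seq_len(nrow(kept)), kept$participant)
  miss_denom <- split(which(is_test), table$participant[is_test])
  drop_participants <- character(0)
  for (pid in names(per)) {
    rows <- kept[per[[pid]], , drop = FALSE]
    test_rows <- rows[rows$phase == "test", , drop = FALSE]
    n_miss <- sum(is.na(test_rows$response))
    n_all <- if (isTRUE(th$count_rt_excluded_as_missed)) {
      length(miss_denom[[pid]])
    } else {
      nrow(test_rows)
    }
    if (isTRUE(th$count_rt_excluded_as_missed)) {
      n_miss <- n_miss + (length(miss_denom[[pid]]) - nrow(test_rows))
    }
    miss_rate <- if (n_all > 0) n_miss / n_all else 1
    if (miss_rate > th$max_missing) {
      drop_participants <- c(drop_participants, pid)
      report[[length(report) + 1L]] <- data.frame(
        participant = pid, rule = "missing_rate", value = miss_rate,
        stringsAsFactors = FALSE)
      next
    }
    # performance thresholds on the immediate session when present
    perf_rows <- if ("immediate" %in% test_rows$session) {
      test_rows[test_rows$session == "immediate", , drop = FALSE]
    } else {
      test_rows
    }
    m <- metrics_one(perf_rows)
    if (!is.na(m$ldi) && m$ldi < th$min_ldi) {
      drop_participants <- c(drop_participants, pid)
      report[[length(report) + 1L]] <- data.frame(
        participant = pid, rule = "min_ldi", value = m$ldi,
        stringsAsFactors = FALSE)
      next
    }
    if (!is.na(m$recognition) && m$recognition < th$min_recognition) {
      drop_participants <- c(drop_participants, pid)
      report[[length(report) + 1L]] <- data.frame(
        participant = pid, rule = "min_recognition", value = m$recognition,
        stringsAsFactors = FALSE)
    }
  }
  out <- kept[!(kept$participant %in% drop_participants), , drop = FALSE]
  class(out) <- class(table)
  list(
    table = out,
    report = if (length(report)) do.call(rbind, report) else
      data.frame(participant = character(), rule = character(),
                 value = numeric()),
    n_trials_removed = sum(bad_rt),
    participants_removed = unique(drop_participants)
  )
}

# Condition-response probabilities and the three indices for one block of
# test rows. Probabilities condition on responding (missing responses are
# excluded from denominators); empty denominators yield NA, never 0.
metrics_one <- function(rows) {
  p <- function(response, condition) {
    r <- rows$response[rows$condition == condition &
                         !is.na(rows$response)]
    if (length(r) == 0L) return(NA_real_)
    mean(r == response)
  }
  ldi <- p("similar", "lure") - p("similar", "foil")
  recognition <- p("old", "target") - p("old", "foil")
  lure_fa <- p("old", "lure") - p("old", "foil")
  list(ldi = ldi, recognition = recognition, lure_fa = lure_fa,
       p_sim_lure = p("similar", "lure"), p_sim_foil = p("similar", "foil"),
       p_old_target = p("old", "target"), p_old_foil = p("old", "foil"),
       p_old_lure = p("old", "lure"))
}

#' Behavioral indices of mnemonic discrimination
#'
#' Computes, per participant and session, the condition--response
#' probabilities and the three indices: the lure discrimination index
#' `LDI = p("similar"|lure) - p("similar"|foil)` (bias-corrected correct
#' rejections), the recognition score `p("old"|target) - p("old"|foil)`
#' and the lure false alarm rate `p("old"|lure) - p("old"|foil)`.
#' Probabilities are computed over non-missing responses; a condition with
#' no responded trials yields `NA` (flagged in `undefined`), never a
#' silent 0. Per-lure-bin variants of LDI and lure false alarms (against
#' the common foil baseline) are attached.
#'
#' @param table a `trial_table` with test-phase rows.
#' @return a data frame of class `behavior_summary`, one row per
#'   participant x session, with attribute `per_bin` (long data frame:
#'   participant, session, bin, ldi, lure_fa, n_trials).
#' @export
compute_metrics <- function(table) {
  test <- table[table$phase == "test", , drop = FALSE]
  if (nrow(test) == 0L) {
    stop_rdmem("no test-phase rows", class = "rdmem_schema")
  }
  groups <- split(test, list(test$participant, test$session), drop = TRUE)
  rows <- lapply(groups, function(g) {
    m <- metrics_one(g)
    data.frame(
      participant = g$participant[1], session = g$session[1],
      ldi = m$ldi, recognition = m$recognition, lure_fa = m$lure_fa,
      p_sim_lure = m$p_sim_lure, p_sim_foil = m$p_sim_foil,
      p_old_lure = m$p_old_lure, p_old_target = m$p_old_target,
      p_old_foil = m$p_old_foil,
      n_trials = nrow(g), n_missing = sum(is.na(g$response)),
      undefined = is.na(m$ldi) || is.na(m$recognition) || is.na(m$lure_fa),
      age = if ("age" %in% names(g)) g$age[1] else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  bins <- lapply(groups, function(g) {
    b <- g[g$condition == "lure" & !is.na(g$lure_bin), , drop = FALSE]
    if (nrow(b) == 0L) return(NULL)
    mg <- metrics_one(g)
    foil_sim <- mg$p_sim_foil
    foil_old <- mg$p_old_foil
    per <- lapply(split(b, b$lure_bin), function(bb) {
      r <- bb$response[!is.na(bb$response)]
      data.frame(
        participant = g$participant[1], session = g$session[1],
        bin = bb$lure_bin[1],
        ldi = if (length(r)) mean(r == "similar") - foil_sim else NA_real_,
        lure_fa = if (length(r)) mean(r == "old") - foil_old else NA_real_,
        n_trials = nrow(bb), stringsAsFactors = FALSE
      )
    })
    do.call(rbind, per)
  })
  per_bin <- do.call(rbind, bins[!vapply(bins, is.null, logical(1))])
  rownames(per_bin) <- NULL
  structure(out, per_bin = per_bin,
            class = c("behavior_summary", "data.frame"))
}

#' Bin-level aggregation joined to per-item lossiness
#'
#' Produces the analysis table for the mixed-effects and GAM models: one
#' row per participant x session x lure bin, carrying the bin-level LDI
#' and lure false alarm rate, the mean lossiness of the lure items
#' presented in that bin, and age. Bin labels are inputs on the trial
#' table (in the real task they come from an independent normative
#' sample); they are not computed here.
#'
#' @param tables a `trial_table` or list of them (one per participant or
#'   dataset).
#' @param lossiness named numeric vector mapping lure stimulus ids to
#'   lossiness values; every lure item must be present.
#' @return data frame with `participant`, `session`, `bin`, `ldi`,
#'   `lure_fa`, `lossiness`, `age`, `n_trials`.
#' @export
bin_and_aggregate <- function(tables, lossiness) {
  if (is.data.frame(tables)) tables <- list(tables)
  tab <- do.call(rbind, tables)
  lures <- unique(tab$stimulus[tab$condition == "lure"])
  missing <- setdiff(lures, names(lossiness))
  if (length(missing)) {
    stop_rdmem("lossiness undefined for items: ",
               paste(missing, collapse = ", "),
               class = "rdmem_aggregation")
  }
  summary <- compute_metrics(tab)
  per_bin <- attr(summary, "per_bin")
  if (is.null(per_bin)) {
    stop_rdmem("no binned lure trials present", class = "rdmem_aggregation")
  }
  # mean lossiness of the items shown in each bin
  item_bins <- unique(tab[tab$condition == "lure" & !is.na(tab$lure_bin),
                          c("stimulus", "lure_bin")])
  bin_loss <- tapply(lossiness[item_bins$stimulus], item_bins$lure_bin,
                     mean)
  per_bin$lossiness <- as.numeric(bin_loss[as.character(per_bin$bin)])
  ages <- tapply(tab$age, tab$participant, function(a) a[1])
  per_bin$age <- as.numeric(ages[per_bin$participant])
  per_bin[, c("participant", "session", "bin", "ldi", "lure_fa",
              "lossiness", "age", "n_trials")]
}
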