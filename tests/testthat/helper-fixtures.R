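# Hand-built trial tables used across behavior tests.

# One participant, test phase only: counts of each response per condition
# are set exactly so the indices are known in closed form.
make_response_table <- function(participant = "p1", session = "immediate",
                                lure = c(similar = 6, old = 2, new = 2),
                                foil = c(similar = 1, old = 1, new = 8),
                                target = c(similar = 1, old = 8, new = 1),
                                age = 20) {
  expand_cond <- function(cond, counts) {
    data.frame(
      condition = cond,
      response = rep(names(counts), counts),
      stringsAsFactors = FALSE
    )
  }
  tab <- rbind(expand_cond("lure", lure), expand_cond("foil", foil),
               expand_cond("target", target))
  tab$participant <- participant
  tab$session <- session
  tab$phase <- "test"
  tab$trial <- seq_len(nrow(tab))
  tab$stimulus <- sprintf("s%03d", seq_len(nrow(tab)))
  tab$lure_bin <- ifelse(tab$condition == "lure", 1L, NA_integer_)
  tab$rt <- 1.0
  tab$age <- age
  tab[, c("participant", "session", "phase", "trial", "stimulus",
          "condition", "lure_bin", "response", "rt", "age")]
}

# Bin-level table with a planted linear lossiness -> LDI relation and
# optional participant random intercepts.
make_bin_table <- function(n_participants, beta0 = 0.1, beta1 = 0.5,
                           ranef_sd = 0, resid_sd = 0, age_beta = 0,
                           seed = 1) {
  set.seed(seed)
  bt <- expand.grid(participant = sprintf("p%03d", seq_len(n_participants)),
                    bin = 1:5, stringsAsFactors = FALSE)
  bt$lossiness <- bt$bin * 0.2
  bt$age <- rep(runif(n_participants, 20, 80), times = 5)
  u <- rep(rnorm(n_participants, 0, ranef_sd), times = 5)
  bt$ldi <- beta0 + beta1 * bt$lossiness + age_beta * bt$age + u +
    rnorm(nrow(bt), 0, resid_sd)
  bt$session <- "immediate"
  bt
}
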