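# Independent brute-force re-implementation of the D-score pipeline, written
# against the raw trial rows with plain loops. It shares no code with the
# package's scoring path (block pairing is re-derived from the packaged block
# task names, summary statistics are computed by hand) and serves as the
# oracle for equivalence testing.

oracle_mean <- function(x) sum(x) / length(x)

oracle_sd <- function(x) {
  m <- oracle_mean(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

oracle_pairing <- function(task, reversed_first) {
  if (task == "combined") {
    if (reversed_first) "incompatible" else "compatible"
  } else if (task == "combined-reversed") {
    if (reversed_first) "compatible" else "incompatible"
  } else {
    NA_character_
  }
}

oracle_score_session <- function(session, spec, mode,
                                 scored_pairs = "both",
                                 slow_cutoff = 10000, fast_cutoff = 300,
                                 fast_threshold = 0.10) {
  tr <- session$trials
  task_of <- setNames(spec$blocks$task, spec$blocks$index)
  role_of <- setNames(spec$blocks$role, spec$blocks$index)
  rf <- session$variant$reversed_first

  # 1. drop slow trials (strictly greater than the cutoff)
  keep <- rep(TRUE, nrow(tr))
  for (i in seq_len(nrow(tr))) {
    if (tr$latency_ms[i] > slow_cutoff) keep[i] <- FALSE
  }
  tr <- tr[keep, , drop = FALSE]

  # 2. fast-responder rule over combined-task blocks
  n_comb <- 0L
  n_fast <- 0L
  for (i in seq_len(nrow(tr))) {
    task <- task_of[[as.character(tr$block_index[i])]]
    if (task %in% c("combined", "combined-reversed")) {
      n_comb <- n_comb + 1L
      if (tr$latency_ms[i] < fast_cutoff) n_fast <- n_fast + 1L
    }
  }
  share <- n_fast / n_comb
  if (share > fast_threshold) {
    return(list(excluded = TRUE, reason = "fast_responder", fast_share = share,
                d_practice = NA_real_, d_test = NA_real_, d = NA_real_))
  }

  # 3. error handling
  lat <- as.numeric(tr$latency_ms)
  if (mode == "d600") {
    for (b in unique(tr$block_index)) {
      rows <- which(tr$block_index == b)
      correct <- c()
      for (i in rows) if (!tr$is_error[i]) correct <- c(correct, lat[i])
      errs <- rows[tr$is_error[rows]]
      if (length(errs)) {
        if (!length(correct)) {
          task <- task_of[[as.character(b)]]
          if (task %in% c("combined", "combined-reversed")) {
            return(list(excluded = TRUE, reason = "no_correct_trials",
                        fast_share = share, d_practice = NA_real_,
                        d_test = NA_real_, d = NA_real_))
          }
          next
        }
        for (i in errs) lat[i] <- oracle_mean(correct) + 600
      }
    }
  }

  # 4. pair-wise D
  pair_d <- function(role_want) {
    comp <- c()
    inc <- c()
    for (i in seq_len(nrow(tr))) {
      b <- as.character(tr$block_index[i])
      pairing <- oracle_pairing(task_of[[b]], rf)
      if (is.na(pairing) || role_of[[b]] != role_want) next
      if (pairing == "compatible") comp <- c(comp, lat[i]) else inc <- c(inc, lat[i])
    }
    (oracle_mean(inc) - oracle_mean(comp)) / oracle_sd(c(comp, inc))
  }
  d_test <- pair_d("test")
  d_practice <- if (scored_pairs == "both") pair_d("practice") else NA_real_
  d <- if (scored_pairs == "both") (d_practice + d_test) / 2 else d_test
  list(excluded = FALSE, reason = NA_character_, fast_share = share,
       d_practice = d_practice, d_test = d_test, d = d)
}
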