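#' Cleaning and scoring configuration
#'
#' Parameters of the D-score cleaning pipeline. Defaults follow the
#' improved-algorithm conventions: trials slower than 10 s are dropped
#' (strictly greater); a participant is excluded when strictly more than
#' 10 percent of their combined-block responses are faster than 300 ms
#' (strictly less); fast trials are counted for the exclusion rule but not
#' deleted from scoring unless `drop_fast_trials = TRUE`.
#'
#' @param slow_cutoff_ms Drop trials with latency strictly above this (ms).
#' @param fast_cutoff_ms A response is "fast" when strictly below this (ms).
#' @param fast_share_threshold Exclude a participant when their fast share
#'   is strictly above this proportion.
#' @param error_handling_mode `"d600"`, `"built_in_penalty"`, or `NA` to use
#'   the mode recorded on each session.
#' @param scored_pairs `"both"` scores the practice pair (combined practice
#'   blocks) and the test pair (combined test blocks) and averages their Ds;
#'   `"test_only"` scores the test pair alone.
#' @param fast_share_blocks Denominator of the fast share: `"combined"`
#'   (combined-task blocks only, the default) or `"all"`.
#' @param drop_fast_trials Also delete sub-cutoff trials before scoring.
#' @return A list of class `qiat_cleaning_config`.
#' @export
cleaning_config <- function(slow_cutoff_ms = 10000, fast_cutoff_ms = 300,
                            fast_share_threshold = 0.10,
                            error_handling_mode = NA_character_,
                            scored_pairs = c("both", "test_only"),
                            fast_share_blocks = c("combined", "all"),
                            drop_fast_trials = FALSE) {
  stopifnot(slow_cutoff_ms > 0, fast_cutoff_ms > 0,
            fast_share_threshold > 0, fast_share_threshold < 1)
  if (!is.na(error_handling_mode)) {
    error_handling_mode <- match.arg(error_handling_mode,
                                     c("d600", "built_in_penalty"))
  }
  structure(
    list(slow_cutoff_ms = slow_cutoff_ms, fast_cutoff_ms = fast_cutoff_ms,
         fast_share_threshold = fast_share_threshold,
         error_handling_mode = error_handling_mode,
         scored_pairs = match.arg(scored_pairs),
         fast_share_blocks = match.arg(fast_share_blocks),
         drop_fast_trials = isTRUE(drop_fast_trials)),
    class = "qiat_cleaning_config"
  )
}

combined_block_indices <- function(spec) {
  spec$blocks$index[grepl("^combined", spec$blocks$task)]
}

#' Drop slow trials from a session
#'
#' Removes trials with latency strictly greater than the slow cutoff
#' (default 10 s); a trial at exactly the cutoff is retained.
#'
#' @param session A `qiat_session`.
#' @param config A `qiat_cleaning_config`.
#' @return A list with the trimmed `session` and `n_dropped`.
#' @export
drop_slow_trials <- function(session, config = cleaning_config()) {
  keep <- session$trials$latency_ms <= config$slow_cutoff_ms
  out <- session
  out$trials <- session$trials[keep, , drop = FALSE]
  rownames(out$trials) <- NULL
  list(session = out, n_dropped = sum(!keep))
}

#' Share of excessively fast responses
#'
#' Proportion of responses strictly faster than the fast cutoff (default
#' 300 ms), computed over the combined-task blocks by default. A
#' participant whose share is strictly above the threshold (default 10
#' percent) is an excessively fast responder and is excluded from scoring.
#'
#' @inheritParams drop_slow_trials
#' @param spec The `qiat_instrument` (identifies the combined blocks).
#' @return The fast share as a proportion in \[0, 1\].
#' @export
fast_share <- function(session, spec, config = cleaning_config()) {
  tr <- session$trials
  if (config$fast_share_blocks == "combined") {
    tr <- tr[tr$block_index %in% combined_block_indices(spec), , drop = FALSE]
  }
  if (!nrow(tr)) stop("fast share undefined: no retained trials", call. = FALSE)
  mean(tr$latency_ms < config$fast_cutoff_ms)
}

#' Attach scoring latencies under an error-handling scheme
#'
#' Under `"d600"`, each error trial's scoring latency becomes the mean of
#' that block's correct retained latencies plus 600 ms (computed per block
#' over the blocks present in the session). Under `"built_in_penalty"` the
#' recorded latency is used unchanged, because the participant had to
#' self-correct before proceeding and the recorded latency already includes
#' the correction time.
#'
#' @inheritParams fast_share
#' @param mode Optional override of the config/session mode.
#' @return The session with a `scoring_latency_ms` column added to its
#'   trials. Under `"d600"`, a combined block with zero correct trials
#'   raises an error of class `qiat_no_correct_trials`.
#' @export
apply_error_handling <- function(session, spec, config = cleaning_config(),
                                 mode = NULL) {
  mode <- mode %||%
    (if (!is.na(config$error_handling_mode)) config$error_handling_mode else NULL) %||%
    (if (!is.na(session$error_handling_mode)) session$error_handling_mode else NULL)
  if (is.null(mode)) {
    stop("no error handling mode: set it on the session or the config",
         call. = FALSE)
  }
  mode <- match.arg(mode, c("d600", "built_in_penalty"))
  tr <- session$trials
  tr$scoring_latency_ms <- as.numeric(tr$latency_ms)
  if (mode == "d600") {
    for (b in unique(tr$block_index)) {
      in_b <- tr$block_index == b
      err <- in_b & tr$is_error
      if (!any(err)) next
      correct <- tr$scoring_latency_ms[in_b & !tr$is_error]
      if (!length(correct)) {
        if (b %in% combined_block_indices(spec)) {
          stop(structure(
            class = c("qiat_no_correct_trials", "error", "condition"),
            list(message = sprintf("no correct trials in block %d", b),
                 call = NULL)
          ))
        }
        next # unscored single-task block; leave latencies as recorded
      }
      tr$scoring_latency_ms[err] <- mean(correct) + 600
    }
  }
  out <- session
  out$error_handling_mode <- mode
  out$trials <- tr
  out
}

#' Pair-wise D value
#'
#' The elementary IAT statistic: the difference between the mean
#' incompatible-pairing and mean compatible-pairing latency, divided by the
#' inclusive standard deviation — the sample (n-1) standard deviation over
#' the union of both blocks' retained scoring latencies. Positive values
#' mean slower responding under the incompatible pairing, i.e. a stronger
#' association between the construct's positive pole and the self.
#'
#' @param compatible,incompatible Numeric vectors of scoring latencies (ms).
#' @return The D value (dimensionless).
#' @examples
#' compute_pair_d(c(600, 700), c(800, 900)) # 200 / 129.0994 = 1.549
#' @export
compute_pair_d <- function(compatible, incompatible) {
  if (!length(compatible) || !length(incompatible)) {
    stop("both pairing conditions need at least one retained trial", call. = FALSE)
  }
  s <- stats::sd(c(compatible, incompatible))
  if (!is.finite(s) || s == 0) {
    stop("inclusive standard deviation is zero; D undefined", call. = FALSE)
  }
  (mean(incompatible) - mean(compatible)) / s
}

#' Latency summaries per scored block pair
#'
#' @inheritParams fast_share
#' @return Data frame with one row per scored pair: `pair_name`,
#'   `mean_compatible_ms`, `mean_incompatible_ms`, `sd_inclusive_ms`,
#'   `n_compatible`, `n_incompatible`.
#' @export
pair_stats <- function(session, spec, config = cleaning_config()) {
  prep <- prepare_scored_trials(session, spec, config)
  do.call(rbind, lapply(names(prep$pairs), function(p) {
    comp <- prep$pairs[[p]]$compatible
    inc <- prep$pairs[[p]]$incompatible
    data.frame(pair_name = p,
               mean_compatible_ms = mean(comp$scoring_latency_ms),
               mean_incompatible_ms = mean(inc$scoring_latency_ms),
               sd_inclusive_ms = stats::sd(c(comp$scoring_latency_ms,
                                             inc$scoring_latency_ms)),
               n_compatible = nrow(comp), n_incompatible = nrow(inc),
               stringsAsFactors = FALSE)
  }))
}

# Shared cleaning front-end: slow-trial dropping, error handling, optional
# fast-trial deletion, and the split of combined trials into scored pairs.
prepare_scored_trials <- function(session, spec, config, mode = NULL) {
  dropped <- drop_slow_trials(session, config)
  session <- dropped$session
  session <- apply_error_handling(session, spec, config, mode = mode)
  tr <- session$trials
  if (config$drop_fast_trials) {
    tr <- tr[tr$latency_ms >= config$fast_cutoff_ms, , drop = FALSE]
  }
  layout <- block_layout(spec, session$variant)
  pairing_of <- stats::setNames(layout$pairing, layout$index)
  role_of <- stats::setNames(layout$role, layout$index)
  tr$pairing <- unname(pairing_of[as.character(tr$block_index)])
  tr$role <- unname(role_of[as.character(tr$block_index)])
  pair_roles <- switch(config$scored_pairs,
                       both = c(practice = "practice", test = "test"),
                       test_only = c(test = "test"))
  pairs <- lapply(pair_roles, function(role) {
    sub <- tr[!is.na(tr$pairing) & tr$role == role, , drop = FALSE]
    list(compatible = sub[sub$pairing == "compatible", , drop = FALSE],
         incompatible = sub[sub$pairing == "incompatible", , drop = FALSE])
  })
  list(session = session, trials = tr, pairs = pairs,
       n_dropped_slow = dropped$n_dropped)
}

empty_dscore_row <- function(session, reason, fast = NA_real_,
                             err = NA_real_, n_slow = NA_integer_) {
  data.frame(participant_id = session$participant_id,
             session_id = session$session_id,
             d_practice = NA_real_, d_test = NA_real_, d = NA_real_,
             excluded = TRUE, exclusion_reason = reason,
             fast_share = fast, error_rate = err, n_dropped_slow = n_slow,
             stringsAsFactors = FALSE)
}

#' Score one session with the D algorithm
#'
#' Runs the full pipeline in the documented order: drop trials slower than
#' 10 s; exclude the participant if strictly more than 10 percent of
#' combined-block responses are faster than 300 ms; apply the error
#' handling scheme (D600 replacement or built-in penalty); compute the
#' pair-wise D for the practice pair and the test pair; average them. The
#' sign convention is determined by the pairing (not the physical keys):
#' positive D indicates a stronger association between the self and the
#' instrument's positive pole (for the LPFS-qIAT, greater personality
#' functioning impairment).
#'
#' @inheritParams fast_share
#' @return A one-row data frame (`participant_id`, `session_id`,
#'   `d_practice`, `d_test`, `d`, `excluded`, `exclusion_reason`,
#'   `fast_share`, `error_rate`, `n_dropped_slow`). For excluded
#'   participants the D fields are `NA`.
#' @export
score_session <- function(session, spec, config = cleaning_config()) {
  stopifnot(inherits(session, "qiat_session"), inherits(spec, "qiat_instrument"))
  if (!session$complete) {
    return(empty_dscore_row(session, "incomplete"))
  }
  dropped <- drop_slow_trials(session, config)
  fs <- fast_share(dropped$session, spec, config)
  comb <- dropped$session$trials[
    dropped$session$trials$block_index %in% combined_block_indices(spec), ,
    drop = FALSE]
  er <- mean(comb$is_error)
  if (fs > config$fast_share_threshold) {
    return(empty_dscore_row(session, "fast_responder", fs, er,
                            dropped$n_dropped))
  }
  prep <- tryCatch(
    prepare_scored_trials(session, spec, config),
    error = function(e) e
  )
  if (inherits(prep, "error")) {
    return(empty_dscore_row(session, conditionMessage(prep), fs, er,
                            dropped$n_dropped))
  }
  ds <- tryCatch(
    vapply(prep$pairs, function(p) {
      compute_pair_d(p$compatible$scoring_latency_ms,
                     p$incompatible$scoring_latency_ms)
    }, numeric(1)),
    error = function(e) e
  )
  if (inherits(ds, "error")) {
    return(empty_dscore_row(session, conditionMessage(ds), fs, er,
                            dropped$n_dropped))
  }
  data.frame(participant_id = session$participant_id,
             session_id = session$session_id,
             d_practice = if ("practice" %in% names(ds)) ds[["practice"]] else NA_real_,
             d_test = ds[["test"]],
             d = mean(ds),
             excluded = FALSE, exclusion_reason = NA_character_,
             fast_share = fs, error_rate = er,
             n_dropped_slow = prep$n_dropped_slow,
             stringsAsFactors = FALSE)
}

#' Score a cohort and account for exclusions
#'
#' Applies [score_session()] to every session and assembles the participant
#' ledger: started = number of sessions passed in (plus any participants
#' known to have started but produced no session, via `n_started`),
#' incomplete sessions first, then excessively fast responders. Rare
#' scoring-time failures (e.g. a block with no correct trials under D600)
#' appear in the result rows but are counted as retained in the ledger.
#'
#' @param sessions List of `qiat_session` (one per participant).
#' @inheritParams fast_share
#' @param n_started Optional count of participants who started, when larger
#'   than `length(sessions)`.
#' @return A list with `scores` (one row per session) and `ledger`
#'   (a `qiat_ledger`).
#' @export
score_cohort <- function(sessions, spec, config = cleaning_config(),
                         n_started = NULL) {
  scores <- do.call(rbind, lapply(sessions, score_session, spec = spec,
                                  config = config))
  if (is.null(scores)) {
    scores <- empty_dscore_row(
      session_data("x", "x", cb_variant(), spec = spec,
                   trials = data.frame(block_index = integer(0),
                                       latency_ms = numeric(0))), "x")[0, ]
  }
  rownames(scores) <- NULL
  n_started <- n_started %||% length(sessions)
  incomplete <- scores$participant_id[scores$excluded &
                                        scores$exclusion_reason == "incomplete"]
  fast <- scores$participant_id[scores$excluded &
                                  scores$exclusion_reason == "fast_responder"]
  ledger <- summarize_exclusions(n_started, incomplete, fast)
  list(scores = scores, ledger = ledger)
}
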