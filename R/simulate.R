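#' Respondent parameters for the generative latency model
#'
#' One simulated respondent's ground truth. Response latencies follow a
#' shifted lognormal: `latency = shift_ms + Lognormal(mu_log, sigma_log)`,
#' with an additive pairing effect of `d_true * pairing_shift_ms`
#' milliseconds on combined-block trials presented under the incompatible
#' pairing. Classification errors occur independently per trial with
#' probability `error_rate`; under the built-in error penalty the recorded
#' latency of an error trial is inflated by a lognormal correction-time
#' draw. A fast contaminant replaces a share of their responses with
#' sub-300 ms latencies, emulating the excessively fast responders that
#' online IAT data collections must screen out.
#'
#' @param d_true Latent association strength (standardized units; positive
#'   means the self is associated with the instrument's positive pole).
#' @param mu_log,sigma_log Location and scale of the lognormal latency
#'   component (log-ms units).
#' @param shift_ms Non-decision floor in ms.
#' @param pairing_shift_ms Latency increment per unit `d_true` on
#'   incompatible-pairing trials (ms).
#' @param error_rate Per-trial misclassification probability, in \[0, 0.5).
#' @param correction_mu_log,correction_sigma_log Lognormal parameters of
#'   the self-correction time added to error trials under the built-in
#'   penalty.
#' @param is_fast_contaminant Logical; emit excessively fast responses.
#' @param fast_trial_share Share of trials a contaminant answers below
#'   300 ms.
#' @param trait_stability Correlation of `d_true` across two sessions,
#'   in \[-1, 1\].
#' @return An object of class `qiat_respondent`.
#' @export
respondent_params <- function(d_true = 0, mu_log = log(450), sigma_log = 0.4,
                              shift_ms = 300, pairing_shift_ms = 150,
                              error_rate = 0.12,
                              correction_mu_log = log(300),
                              correction_sigma_log = 0.5,
                              is_fast_contaminant = FALSE,
                              fast_trial_share = 0.5,
                              trait_stability = 0.7) {
  stopifnot(sigma_log > 0, shift_ms >= 0, error_rate >= 0, error_rate < 0.5,
            fast_trial_share >= 0, fast_trial_share <= 1,
            trait_stability >= -1, trait_stability <= 1)
  structure(
    list(d_true = d_true, mu_log = mu_log, sigma_log = sigma_log,
         shift_ms = shift_ms, pairing_shift_ms = pairing_shift_ms,
         error_rate = error_rate, correction_mu_log = correction_mu_log,
         correction_sigma_log = correction_sigma_log,
         is_fast_contaminant = isTRUE(is_fast_contaminant),
         fast_trial_share = fast_trial_share,
         trait_stability = trait_stability),
    class = "qiat_respondent"
  )
}

#' Cohort simulation configuration
#'
#' @param n_participants Cohort size.
#' @param spec A `qiat_instrument` (defaults to the packaged LPFS-qIAT).
#' @param error_handling_mode `"built_in_penalty"` (default) or `"d600"`.
#' @param contamination_rate Share of excessively fast responders, in
#'   \[0, 1); the default 0.25 mirrors the prevalence online student
#'   samples of this kind exhibit.
#' @param d_mean,d_sd Population distribution of the latent association
#'   strength (`d_true ~ Normal(d_mean, d_sd)`).
#' @param params Template `qiat_respondent` providing all remaining
#'   respondent-level parameters.
#' @param seed Mandatory integer seed.
#' @return An object of class `qiat_sim_config`.
#' @export
sim_config <- function(n_participants, spec = load_lpfs_qiat(),
                       error_handling_mode = c("built_in_penalty", "d600"),
                       contamination_rate = 0.25, d_mean = 0, d_sd = 1,
                       params = respondent_params(), seed) {
  stopifnot(is_count(n_participants),
            contamination_rate >= 0, contamination_rate < 1, d_sd >= 0)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  structure(
    list(n_participants = as.integer(n_participants), spec = spec,
         error_handling_mode = match.arg(error_handling_mode),
         contamination_rate = contamination_rate,
         d_mean = d_mean, d_sd = d_sd, params = params,
         seed = as.integer(seed)),
    class = "qiat_sim_config"
  )
}

#' Simulate one qIAT session
#'
#' Draws a trial plan with [build_trial_sequence()] and generates latencies
#' and error flags from the respondent's generative model. Latencies are
#' rounded to integer milliseconds (floored at 50 ms, since the additive
#' pairing shift can otherwise push extreme draws negative).
#'
#' @param params A `qiat_respondent`.
#' @param spec A `qiat_instrument`.
#' @param variant A `qiat_variant`.
#' @param mode Error handling mode recorded on the session.
#' @param seed Mandatory integer seed.
#' @param participant_id,session_id Identifiers for the session.
#' @return A `qiat_session` (always complete).
#' @export
simulate_session <- function(params, spec, variant,
                             mode = c("built_in_penalty", "d600"), seed,
                             participant_id = "sim", session_id = "t1") {
  stopifnot(inherits(params, "qiat_respondent"))
  mode <- match.arg(mode)
  plan <- build_trial_sequence(spec, variant, seed = derive_seed(seed, 1L))
  n <- nrow(plan)
  trials <- with_seed(derive_seed(seed, 2L), {
    lat <- params$shift_ms +
      stats::rlnorm(n, meanlog = params$mu_log, sdlog = params$sigma_log)
    inc <- !is.na(plan$pairing) & plan$pairing == "incompatible"
    lat[inc] <- lat[inc] + params$d_true * params$pairing_shift_ms
    is_error <- stats::runif(n) < params$error_rate
    if (mode == "built_in_penalty") {
      lat[is_error] <- lat[is_error] +
        stats::rlnorm(sum(is_error), meanlog = params$correction_mu_log,
                      sdlog = params$correction_sigma_log)
    }
    if (params$is_fast_contaminant) {
      n_fast <- round(params$fast_trial_share * n)
      fast_idx <- sample.int(n, n_fast)
      lat[fast_idx] <- stats::runif(n_fast, 100, 299)
    }
    lat <- pmax(round(lat), 50)
    side <- ifelse(is_error,
                   ifelse(plan$correct_side == "left", "right", "left"),
                   plan$correct_side)
    data.frame(block_index = plan$block_index, block_role = plan$block_role,
               trial_index = plan$trial_index, item_id = plan$item_id,
               category = plan$category, response_side = side,
               is_error = is_error, latency_ms = as.integer(lat),
               stringsAsFactors = FALSE)
  })
  session_data(participant_id, session_id, variant, trials, spec,
               error_handling_mode = mode)
}

draw_respondents <- function(config, d_true) {
  n <- config$n_participants
  lapply(seq_len(n), function(i) {
    p <- config$params
    p$d_true <- d_true[i]
    p
  })
}

#' Simulate a cohort with known ground truth
#'
#' Draws each participant's latent association strength from
#' `Normal(d_mean, d_sd)`, assigns one of the four counterbalance variants
#' uniformly at random, flags a `contamination_rate` share as fast
#' contaminants, and simulates every session.
#'
#' @param config A `qiat_sim_config`.
#' @param session_id Session label (default "t1").
#' @return A list with `sessions` (list of `qiat_session`) and `truth`
#'   (data frame: `participant_id`, `d_true`, `is_fast_contaminant`,
#'   `variant`).
#' @export
simulate_cohort <- function(config, session_id = "t1") {
  stopifnot(inherits(config, "qiat_sim_config"))
  n <- config$n_participants
  if (n == 0L) {
    return(list(sessions = list(),
                truth = data.frame(participant_id = character(0),
                                   d_true = numeric(0),
                                   is_fast_contaminant = logical(0),
                                   variant = integer(0))))
  }
  draws <- with_seed(config$seed, {
    list(d_true = stats::rnorm(n, config$d_mean, config$d_sd),
         variant = sample(0:3, n, replace = TRUE),
         contaminant = stats::runif(n) < config$contamination_rate,
         seeds = sample.int(2^30, n))
  })
  ids <- sprintf("p%04d", seq_len(n))
  sessions <- lapply(seq_len(n), function(i) {
    p <- config$params
    p$d_true <- draws$d_true[i]
    p$is_fast_contaminant <- draws$contaminant[i]
    simulate_session(p, config$spec, variant_from_id(draws$variant[i]),
                     mode = config$error_handling_mode, seed = draws$seeds[i],
                     participant_id = ids[i], session_id = session_id)
  })
  truth <- data.frame(participant_id = ids, d_true = draws$d_true,
                      is_fast_contaminant = draws$contaminant,
                      variant = draws$variant, stringsAsFactors = FALSE)
  list(sessions = sessions, truth = truth)
}

#' Simulate a test-retest design
#'
#' Two sessions per participant. The latent trait at time 2 is a
#' stability-correlated redraw, `d2 = s * d1 + sqrt(1 - s^2) * e` with
#' `e ~ Normal(0, d_sd)` (so the marginal distribution is preserved);
#' session-level latency noise is independent across times. Contaminant
#' status is kept stable across sessions.
#'
#' @param config A `qiat_sim_config`.
#' @param trait_stability Latent correlation `s` in \[-1, 1\]; defaults to
#'   the template respondent's `trait_stability`.
#' @param interval_label Session id for time 2 (default "t2").
#' @return A list with `t1`, `t2` (session lists) and `truth` (data frame
#'   with `d_true_t1`, `d_true_t2`, contaminant flag, variant).
#' @export
simulate_retest <- function(config, trait_stability = NULL,
                            interval_label = "t2") {
  stopifnot(inherits(config, "qiat_sim_config"))
  s <- trait_stability %||% config$params$trait_stability
  stopifnot(s >= -1, s <= 1)
  t1 <- simulate_cohort(config, session_id = "t1")
  n <- config$n_participants
  if (n == 0L) return(list(t1 = t1$sessions, t2 = list(), truth = t1$truth))
  draws2 <- with_seed(derive_seed(config$seed, 7L), {
    list(e = stats::rnorm(n, 0, config$d_sd), seeds = sample.int(2^30, n))
  })
  d2 <- s * (t1$truth$d_true - config$d_mean) +
    sqrt(1 - s^2) * draws2$e + config$d_mean
  t2_sessions <- lapply(seq_len(n), function(i) {
    p <- config$params
    p$d_true <- d2[i]
    p$is_fast_contaminant <- t1$truth$is_fast_contaminant[i]
    simulate_session(p, config$spec, variant_from_id(t1$truth$variant[i]),
                     mode = config$error_handling_mode,
                     seed = draws2$seeds[i],
                     participant_id = t1$truth$participant_id[i],
                     session_id = interval_label)
  })
  truth <- t1$truth
  names(truth)[names(truth) == "d_true"] <- "d_true_t1"
  truth$d_true_t2 <- d2
  list(t1 = t1$sessions, t2 = t2_sessions, truth = truth)
}

#' Parameter-recovery experiment
#'
#' The end-to-end validation harness: simulate a cohort, score it with the
#' D algorithm, join observed D to the latent ground truth, and summarize
#' how well the pipeline recovers the trait and detects contaminants.
#'
#' @param config A `qiat_sim_config`.
#' @param cleaning A `qiat_cleaning_config` for the scoring side.
#' @return A list with `pearson` and `spearman` recovery correlations over
#'   retained participants, `slope` and `intercept` of the regression of D
#'   on `d_true`, `n_retained`, the exclusion `ledger`, and a contaminant
#'   `confusion` list (`tp`, `fp`, `fn`, `tn`, `sensitivity`,
#'   `specificity`).
#' @export
recovery_experiment <- function(config, cleaning = cleaning_config()) {
  sim <- simulate_cohort(config)
  res <- score_cohort(sim$sessions, config$spec, cleaning)
  joined <- merge(res$scores, sim$truth, by = "participant_id")
  kept <- joined[!joined$excluded, , drop = FALSE]
  fast_flag <- joined$excluded & !is.na(joined$exclusion_reason) &
    joined$exclusion_reason == "fast_responder"
  tp <- sum(fast_flag & joined$is_fast_contaminant)
  fp <- sum(fast_flag & !joined$is_fast_contaminant)
  fn <- sum(!fast_flag & joined$is_fast_contaminant)
  tn <- sum(!fast_flag & !joined$is_fast_contaminant)
  fit <- if (nrow(kept) >= 3 && stats::sd(kept$d_true) > 0) {
    stats::coef(stats::lm(d ~ d_true, data = kept))
  } else c(NA_real_, NA_real_)
  list(
    pearson = if (nrow(kept) >= 3) pearson_r(kept$d_true, kept$d) else NA_real_,
    spearman = if (nrow(kept) >= 3) {
      stats::cor(kept$d_true, kept$d, method = "spearman")
    } else NA_real_,
    intercept = unname(fit[1]), slope = unname(fit[2]),
    n_retained = nrow(kept), ledger = res$ledger,
    confusion = list(
      tp = tp, fp = fp, fn = fn, tn = tn,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
    )
  )
}
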