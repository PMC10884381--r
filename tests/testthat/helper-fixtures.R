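# Shared fixture builders. All fixtures are generated in code at test time.

the_spec <- load_lpfs_qiat()

# A deterministic, error-free session with mildly varying latencies (so
# inclusive SDs are nonzero) that tests can then mutate.
fixture_session <- function(spec = the_spec, variant = cb_variant(), seed = 1,
                            base_latency = 700, participant_id = "fix",
                            mode = "built_in_penalty") {
  plan <- build_trial_sequence(spec, variant, seed = seed)
  n <- nrow(plan)
  trials <- data.frame(
    block_index = plan$block_index, block_role = plan$block_role,
    trial_index = plan$trial_index, item_id = plan$item_id,
    category = plan$category, response_side = plan$correct_side,
    is_error = rep(FALSE, n),
    latency_ms = as.integer(base_latency + (seq_len(n) %% 13) * 10),
    stringsAsFactors = FALSE
  )
  session_data(participant_id, "t1", variant, trials, spec,
               error_handling_mode = mode)
}

# Random small sessions for oracle-equivalence checks: random variant, mode,
# latent strength, error rate, occasional fast contaminant.
random_session <- function(seed, spec = the_spec) {
  draws <- with_fixed_seed(seed, list(
    variant = sample(0:3, 1),
    d_true = rnorm(1, 0, 1.2),
    error_rate = runif(1, 0, 0.3),
    sigma = runif(1, 0.2, 0.6),
    contaminant = runif(1) < 0.2,
    mode = sample(c("d600", "built_in_penalty"), 1)
  ))
  params <- respondent_params(d_true = draws$d_true, sigma_log = draws$sigma,
                              error_rate = draws$error_rate,
                              is_fast_contaminant = draws$contaminant,
                              fast_trial_share = 0.3)
  simulate_session(params, spec, variant_from_id(draws$variant),
                   mode = draws$mode, seed = seed + 5000L,
                   participant_id = sprintf("r%03d", seed))
}

with_fixed_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Overwrite the latencies of the i-th trials (row positions) of a session.
set_latency <- function(session, rows, value) {
  session$trials$latency_ms[rows] <- as.integer(value)
  session
}
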