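test_that("slow-trial dropping uses a strict 10 s boundary", {
  s <- fixture_session()
  s <- set_latency(s, 1, 10000)
  s <- set_latency(s, 2, 10001)
  out <- drop_slow_trials(s)
  expect_equal(out$n_dropped, 1)
  expect_true(10000 %in% out$session$trials$latency_ms)
  expect_false(10001 %in% out$session$trials$latency_ms)
  clean <- fixture_session()
  out2 <- drop_slow_trials(clean)
  expect_equal(out2$n_dropped, 0)
  expect_identical(out2$session$trials, clean$trials)
})

test_that("fast-responder rule is strict at the 10 percent boundary", {
  # 120 combined-block trials; 13 fast -> share 0.1083, excluded;
  # exactly 12 -> share 0.10, retained
  s <- fixture_session()
  comb_rows <- which(s$trials$block_index %in% c(3, 4, 6, 7))
  expect_length(comb_rows, 120)
  s13 <- set_latency(s, comb_rows[1:13], 299)
  expect_equal(fast_share(s13, the_spec), 13 / 120, tolerance = 1e-12)
  expect_true(score_session(s13, the_spec)$excluded)
  expect_equal(score_session(s13, the_spec)$exclusion_reason, "fast_responder")
  s12 <- set_latency(s, comb_rows[1:12], 299)
  expect_equal(fast_share(s12, the_spec), 0.10, tolerance = 1e-12)
  expect_false(score_session(s12, the_spec)$excluded)
  expect_equal(fast_share(s, the_spec), 0)
  # a 300 ms response is not "faster than 300 ms"
  s300 <- set_latency(s, comb_rows[1:60], 300)
  expect_equal(fast_share(s300, the_spec), 0)
})

test_that("D600 replaces error latencies with block correct mean plus 600", {
  s <- fixture_session()
  b3 <- which(s$trials$block_index == 3)
  s <- set_latency(s, b3, 700)
  s$trials$is_error[b3[5]] <- TRUE
  s <- set_latency(s, b3[5], 900)
  out <- apply_error_handling(s, the_spec, mode = "d600")
  expect_equal(out$trials$scoring_latency_ms[b3[5]], 1300)
  expect_equal(out$trials$scoring_latency_ms[b3[-5]], rep(700, 19))

  # built-in penalty leaves the recorded latency untouched
  pen <- apply_error_handling(s, the_spec, mode = "built_in_penalty")
  expect_equal(pen$trials$scoring_latency_ms[b3[5]], 900)

  # a combined block with zero correct trials cannot be D600-scored
  all_err <- s
  all_err$trials$is_error[b3] <- TRUE
  expect_error(apply_error_handling(all_err, the_spec, mode = "d600"),
               class = "qiat_no_correct_trials")
  row <- score_session(all_err, the_spec,
                       cleaning_config(error_handling_mode = "d600"))
  expect_true(row$excluded)
  expect_match(row$exclusion_reason, "no correct trials")
})

test_that("pair D matches hand-computed values and is antisymmetric", {
  expect_equal(compute_pair_d(c(600, 700), c(800, 900)),
               200 / sd(c(600, 700, 800, 900)), tolerance = 1e-12)
  expect_equal(round(compute_pair_d(c(600, 700), c(800, 900)), 3), 1.549)
  expect_equal(compute_pair_d(c(500, 700), c(500, 700)), 0)
  a <- c(512, 634, 701)
  b <- c(788, 825, 903, 655)
  expect_equal(compute_pair_d(a, b), -compute_pair_d(b, a), tolerance = 1e-15)
  expect_error(compute_pair_d(numeric(0), b), "at least one")
  expect_error(compute_pair_d(c(700, 700), c(700, 700)), "zero")
})

test_that("D is invariant to trial order, location and scale", {
  s <- fixture_session(seed = 9)
  base <- score_session(s, the_spec)
  # permute trials within blocks
  perm <- s
  perm$trials <- with_fixed_seed(4, {
    do.call(rbind, lapply(split(perm$trials, perm$trials$block_index),
                          function(b) b[sample(nrow(b)), ]))
  })
  rownames(perm$trials) <- NULL
  expect_equal(score_session(perm, the_spec)$d, base$d, tolerance = 1e-12)
  # adding a constant to every latency leaves D unchanged
  shift <- s
  shift$trials$latency_ms <- shift$trials$latency_ms + 250L
  expect_equal(score_session(shift, the_spec)$d, base$d, tolerance = 1e-12)
  # multiplying all latencies by k > 0 leaves D unchanged
  scaled <- s
  scaled$trials$latency_ms <- scaled$trials$latency_ms * 3L
  expect_equal(score_session(scaled, the_spec)$d, base$d, tolerance = 1e-12)
})

test_that("shifting incompatible-block latencies strictly increases D", {
  s <- fixture_session(seed = 10)
  layout <- block_layout(the_spec, s$variant)
  inc_blocks <- layout$index[!is.na(layout$pairing) &
                               layout$pairing == "incompatible"]
  inc_rows <- which(s$trials$block_index %in% inc_blocks)
  ds <- vapply(c(0L, 20L, 50L, 100L), function(shift) {
    sh <- s
    sh$trials$latency_ms[inc_rows] <- sh$trials$latency_ms[inc_rows] + shift
    score_session(sh, the_spec)$d
  }, numeric(1))
  expect_true(all(diff(ds) > 0))
})

test_that("scoring depends on the pairing, not the physical keys", {
  p <- respondent_params(d_true = 0.8)
  a <- simulate_session(p, the_spec, variant_from_id(0), seed = 31)
  b <- simulate_session(p, the_spec, variant_from_id(1), seed = 31)
  expect_identical(a$trials$latency_ms, b$trials$latency_ms)
  expect_equal(score_session(a, the_spec)$d, score_session(b, the_spec)$d,
               tolerance = 1e-15)
})

test_that("score_session agrees with the brute-force oracle", {
  for (seed in 1:15) {
    s <- random_session(seed)
    mode <- s$error_handling_mode
    got <- score_session(s, the_spec,
                         cleaning_config(error_handling_mode = mode))
    want <- oracle_score_session(s, the_spec, mode)
    expect_equal(got$excluded, want$excluded, info = paste("seed", seed))
    if (!want$excluded) {
      expect_equal(got$d, want$d, tolerance = 1e-12, info = paste("seed", seed))
      expect_equal(got$d_practice, want$d_practice, tolerance = 1e-12)
      expect_equal(got$d_test, want$d_test, tolerance = 1e-12)
    }
  }
})

test_that("test_only scoring uses the critical blocks alone", {
  s <- fixture_session(seed = 12)
  both <- score_session(s, the_spec, cleaning_config(scored_pairs = "both"))
  test_only <- score_session(s, the_spec,
                             cleaning_config(scored_pairs = "test_only"))
  expect_equal(test_only$d, both$d_test, tolerance = 1e-12)
  expect_true(is.na(test_only$d_practice))
})

test_that("cohort scoring fills the ledger from the exclusion rules", {
  cfg <- sim_config(10, spec = the_spec, contamination_rate = 0, seed = 21)
  sessions <- simulate_cohort(cfg)$sessions
  res <- score_cohort(sessions, the_spec)
  expect_equal(nrow(res$scores), 10)
  expect_equal(res$ledger$n_started, 10)
  expect_equal(res$ledger$n_fast_excluded, 0)
  expect_equal(res$ledger$n_retained, 10)

  # inject two fast responders and one incomplete run
  fastify <- function(s) {
    rows <- which(s$trials$block_index %in% c(3, 4, 6, 7))
    set_latency(s, rows, 200)
  }
  sessions[[1]] <- fastify(sessions[[1]])
  sessions[[2]] <- fastify(sessions[[2]])
  sessions[[3]]$trials <-
    sessions[[3]]$trials[sessions[[3]]$trials$block_index != 7, ]
  sessions[[3]]$complete <- FALSE
  res2 <- score_cohort(sessions, the_spec)
  expect_equal(res2$ledger$n_fast_excluded, 2)
  expect_equal(res2$ledger$n_incomplete, 1)
  expect_equal(res2$ledger$n_retained, 7)
  expect_equal(sum(res2$scores$excluded), 3)
})

test_that("pair_stats summarizes retained latencies per pair", {
  s <- fixture_session(seed = 13)
  st <- pair_stats(s, the_spec)
  expect_equal(st$pair_name, c("practice", "test"))
  expect_equal(st$n_compatible, c(20, 40))
  expect_equal(st$n_incompatible, c(20, 40))
  expect_true(all(st$sd_inclusive_ms > 0))
  d_hand <- (st$mean_incompatible_ms - st$mean_compatible_ms) / st$sd_inclusive_ms
  row <- score_session(s, the_spec)
  expect_equal(d_hand, c(row$d_practice, row$d_test), tolerance = 1e-12)
})
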