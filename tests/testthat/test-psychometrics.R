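exact_moment_pair <- function(n, r, seed = 1) {
  # sample whose empirical covariance matrix is exactly [[1, r], [r, 1]]
  with_fixed_seed(seed, MASS::mvrnorm(n, c(0, 0),
                                      matrix(c(1, r, r, 1), 2),
                                      empirical = TRUE))
}

test_that("parcels partition the retained trials round-robin", {
  s <- fixture_session(seed = 3)
  p2 <- parcel_d_scores(s, the_spec, K = 2)
  expect_length(p2, 2)
  p4 <- parcel_d_scores(s, the_spec, K = 4)
  expect_length(p4, 4)
  # exhaustiveness + balance: a 40-trial block splits 20/20 under K = 2.
  # Check via the inclusive counts in a direct reconstruction.
  prep <- qiatr:::prepare_scored_trials(s, the_spec, cleaning_config())
  scored <- prep$trials[!is.na(prep$trials$pairing), ]
  expect_equal(nrow(scored), 120)
  # K above the smallest block's trial count is impossible
  expect_error(parcel_d_scores(s, the_spec, K = 21), "exceeds")
  expect_error(parcel_d_scores(s, the_spec, K = 1), ">= 2")
})

test_that("parcel scores average to the session D", {
  # with even, alternation-balanced blocks the mean of K parcel Ds is close
  # to (not exactly) the full D; check they track each other
  cfg <- sim_config(15, spec = the_spec, contamination_rate = 0, seed = 8)
  sessions <- simulate_cohort(cfg)$sessions
  m <- parcel_matrix(sessions, the_spec, K = 2)
  scores <- score_cohort(sessions, the_spec)$scores
  kept <- scores[!scores$excluded, ]
  expect_equal(dim(m), c(nrow(kept), 2))
  expect_equal(rownames(m), kept$participant_id)
  expect_gt(cor(rowMeans(m), kept$d), 0.9)
})

test_that("alpha matches its closed forms", {
  m <- exact_moment_pair(60, 0.5)
  expect_equal(cronbach_alpha(m), 2 * (1 - 2 / 3), tolerance = 1e-10)
  ident <- cbind(rnorm(20), 0)
  ident[, 2] <- ident[, 1]
  expect_equal(cronbach_alpha(ident), 1)
  uncorr <- exact_moment_pair(100, 0)
  expect_equal(cronbach_alpha(uncorr), 0, tolerance = 1e-10)
  expect_error(cronbach_alpha(matrix(1, 5, 2)), "variance")
  expect_error(cronbach_alpha(matrix(rnorm(6), 6, 1)), "two parcels")
})

test_that("split-half reliability applies Spearman-Brown", {
  x <- rnorm(30)
  expect_equal(split_half_reliability(cbind(x, x)),
               list(split_half_r = 1, spearman_brown = 1))
  m <- exact_moment_pair(40, 0.5, seed = 2)
  sh <- split_half_reliability(m)
  expect_equal(sh$split_half_r, 0.5, tolerance = 1e-10)
  expect_equal(sh$spearman_brown, 2 * 0.5 / 1.5, tolerance = 1e-10)
  anti <- cbind(x, -x)
  expect_error(split_half_reliability(anti), "-1")
  expect_error(split_half_reliability(cbind(x, 0 * x)), "constant")
})

test_that("bootstrap CI machinery is exact in degenerate cases", {
  x <- rnorm(20)
  ci <- bootstrap_pearson_ci(x, x, 500, seed = 1)
  expect_equal(ci$r, 1)
  expect_equal(c(ci$lo, ci$hi), c(1, 1))
  expect_true(ci$significant)
  expect_error(bootstrap_pearson_ci(x, rep(1, 20), 100, seed = 1), "constant")
  expect_error(bootstrap_pearson_ci(x, rnorm(19), 100, seed = 1), "equal length")
})

test_that("the point correlation matches the closed form and stats::cor", {
  x <- c(1, 2, 3)
  y <- c(2, 4, 7)
  expect_equal(pearson_r(x, y), 5 / sqrt(2 * 114 / 9), tolerance = 1e-12)
  expect_equal(round(pearson_r(x, y), 4), 0.9934)
  for (seed in 1:5) {
    u <- with_fixed_seed(seed, rnorm(40))
    v <- with_fixed_seed(seed + 100, rnorm(40))
    expect_equal(pearson_r(u, v), stats::cor(u, v), tolerance = 1e-12)
  }
})

test_that("bootstrap intervals are seed-reproducible and antisymmetric", {
  x <- with_fixed_seed(11, rnorm(60))
  y <- with_fixed_seed(12, 0.4 * x + rnorm(60))
  a <- bootstrap_pearson_ci(x, y, 2000, seed = 99)
  b <- bootstrap_pearson_ci(x, y, 2000, seed = 99)
  expect_identical(a, b)
  neg <- bootstrap_pearson_ci(x, -y, 2000, seed = 99)
  expect_equal(neg$r, -a$r, tolerance = 1e-15)
  expect_equal(neg$lo, -a$hi, tolerance = 1e-12)
  expect_equal(neg$hi, -a$lo, tolerance = 1e-12)
})

test_that("pairwise-complete filtering drops missing pairs", {
  x <- c(rnorm(30), NA)
  y <- c(0.5 * x[1:30] + rnorm(30), 2)
  ci <- bootstrap_pearson_ci(x, y, 500, seed = 3)
  expect_equal(ci$n_pairs, 30)
})

test_that("minimum detectable effect sizes match the published table", {
  expect_equal(round(mdes_correlation(806)$mdes, 3), 0.098)
  expect_equal(round(mdes_correlation(209)$mdes, 3), 0.192)
  expect_equal(round(mdes_correlation(236)$mdes, 3), 0.181)
})

test_that("MDES is monotone in n and in power, and methods agree", {
  ns <- c(50, 100, 200, 400, 800)
  m <- vapply(ns, function(n) mdes_correlation(n)$mdes, numeric(1))
  expect_true(all(diff(m) < 0))
  p <- vapply(c(0.5, 0.8, 0.9, 0.95),
              function(pw) mdes_correlation(150, power = pw)$mdes, numeric(1))
  expect_true(all(diff(p) > 0))
  for (n in c(50, 209, 806)) {
    expect_equal(mdes_correlation(n, method = "fisher")$mdes,
                 mdes_correlation(n, method = "exact")$mdes,
                 tolerance = 1e-3)
  }
  expect_error(mdes_correlation(4), "at least 5")
})

test_that("validity report recovers known relations per external column", {
  cfg <- sim_config(120, spec = the_spec, contamination_rate = 0, seed = 17)
  sim <- simulate_cohort(cfg)
  scores <- score_cohort(sim$sessions, the_spec)$scores
  externals <- with_fixed_seed(18, data.frame(
    participant_id = scores$participant_id,
    convergent = scores$d + rnorm(nrow(scores), 0, 0.5),
    unrelated = rnorm(nrow(scores))
  ))
  rep <- validity_report(scores, externals, n_replicates = 2000, seed = 44)
  expect_equal(nrow(rep), 2)
  expect_equal(rep$measure, c("convergent", "unrelated"))
  conv <- rep[rep$measure == "convergent", ]
  expect_true(conv$significant)
  expect_gt(conv$r, 0.5)
  unrel <- rep[rep$measure == "unrelated", ]
  expect_false(unrel$significant)
  expect_true(unrel$lo < 0 && unrel$hi > 0)
  expect_true(all(rep$mdes > 0 & rep$mdes < 1))
  # deterministic given the seed
  expect_identical(rep, validity_report(scores, externals,
                                        n_replicates = 2000, seed = 44))
})

test_that("parcel alpha rises with trials per parcel at fixed noise", {
  scale_blocks <- function(spec, f) {
    spec$blocks$n_trials <- as.integer(spec$blocks$n_trials * f)
    spec
  }
  alpha_at <- function(f, seed) {
    spec <- scale_blocks(the_spec, f)
    cfg <- sim_config(100, spec = spec, contamination_rate = 0, seed = seed)
    sessions <- simulate_cohort(cfg)$sessions
    cronbach_alpha(parcel_matrix(sessions, spec, K = 2))
  }
  alphas <- c(alpha_at(0.5, 301), alpha_at(1, 302), alpha_at(2, 303))
  # Spearman-Brown direction: longer parcels, higher internal consistency
  expect_gt(alphas[3], alphas[1])
  expect_true(all(alphas > 0.5))
})
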