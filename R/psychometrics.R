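#' Parcel D sub-scores for one session
#'
#' Internal-consistency analysis of a latency-based measure needs "items";
#' following the trial-parcel approach, the retained trials of each scored
#' block are dealt round-robin by trial position into `K` parcels, and each
#' parcel is D-scored on its own trials (pair-wise D, averaged over the
#' scored pairs, exactly as in [score_session()]). The parcels are disjoint
#' and exhaust all retained trials.
#'
#' @inheritParams fast_share
#' @param K Number of parcels (>= 2, and no larger than the smallest scored
#'   block's retained trial count).
#' @return A numeric vector of `K` parcel D scores.
#' @export
parcel_d_scores <- function(session, spec, config = cleaning_config(), K = 2L) {
  K <- as.integer(K)
  if (is.na(K) || K < 2L) stop("`K` must be an integer >= 2", call. = FALSE)
  prep <- prepare_scored_trials(session, spec, config)
  scored <- prep$trials[!is.na(prep$trials$pairing) &
                          prep$trials$role %in%
                          (if (config$scored_pairs == "both")
                             c("practice", "test") else "test"), , drop = FALSE]
  min_block <- min(tapply(rep(1L, nrow(scored)), scored$block_index, sum))
  if (K > min_block) {
    stop(sprintf("K = %d exceeds the smallest scored block's %d retained trials",
                 K, min_block), call. = FALSE)
  }
  # round-robin by position within block
  scored <- scored[order(scored$block_index, scored$trial_index), , drop = FALSE]
  pos <- stats::ave(rep(1L, nrow(scored)), scored$block_index, FUN = cumsum)
  scored$parcel <- ((pos - 1L) %% K) + 1L
  vapply(seq_len(K), function(k) {
    sub <- scored[scored$parcel == k, , drop = FALSE]
    roles <- if (config$scored_pairs == "both") c("practice", "test") else "test"
    ds <- vapply(roles, function(role) {
      s <- sub[sub$role == role, , drop = FALSE]
      compute_pair_d(s$scoring_latency_ms[s$pairing == "compatible"],
                     s$scoring_latency_ms[s$pairing == "incompatible"])
    }, numeric(1))
    mean(ds)
  }, numeric(1))
}

#' Parcel matrix for a cohort
#'
#' Applies [parcel_d_scores()] to every scorable session; sessions failing
#' the cleaning rules (fast responders, incomplete runs, degenerate blocks)
#' are skipped.
#'
#' @param sessions List of `qiat_session`.
#' @inheritParams parcel_d_scores
#' @return A numeric matrix (participants x K) with participant ids as row
#'   names.
#' @export
parcel_matrix <- function(sessions, spec, config = cleaning_config(), K = 2L) {
  rows <- lapply(sessions, function(s) {
    sc <- score_session(s, spec, config)
    if (sc$excluded) return(NULL)
    p <- tryCatch(parcel_d_scores(s, spec, config, K), error = function(e) NULL)
    if (is.null(p)) return(NULL)
    stats::setNames(list(p), s$participant_id)
  })
  rows <- unlist(rows, recursive = FALSE)
  if (!length(rows)) stop("no scorable sessions", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- names(rows)
  out
}

#' Cronbach's alpha over parcels
#'
#' `alpha = K/(K-1) * (1 - sum(column variances) / var(row sums))`, the
#' internal-consistency variant used for reaction-time measures when the
#' columns are parcel D sub-scores.
#'
#' @param m Numeric matrix, participants in rows, K >= 2 parcels in columns.
#' @return The alpha coefficient (at most 1; can be negative).
#' @export
cronbach_alpha <- function(m) {
  m <- as.matrix(m)
  K <- ncol(m)
  if (K < 2L) stop("alpha needs at least two parcels", call. = FALSE)
  if (nrow(m) < 3L) stop("alpha needs at least three participants", call. = FALSE)
  total_var <- stats::var(rowSums(m))
  if (!is.finite(total_var) || total_var == 0) {
    stop("total score variance is zero; alpha undefined", call. = FALSE)
  }
  K / (K - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}

#' Split-half reliability with Spearman-Brown correction
#'
#' Pearson correlation of two half-test scores, stepped up to full-test
#' length: `SB = 2r / (1 + r)`.
#'
#' @param m Numeric matrix with exactly two columns (the halves).
#' @return A list with `split_half_r` and `spearman_brown`.
#' @export
split_half_reliability <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) != 2L) stop("split-half needs exactly two columns", call. = FALSE)
  if (any(apply(m, 2, stats::sd) == 0)) {
    stop("a constant half-score column has no reliability", call. = FALSE)
  }
  r <- stats::cor(m[, 1], m[, 2])
  if (r <= -1 + 1e-12) {
    stop("Spearman-Brown is undefined at r = -1", call. = FALSE)
  }
  list(split_half_r = r, spearman_brown = 2 * r / (1 + r))
}

#' Percentile-bootstrap confidence interval for a Pearson correlation
#'
#' Participants are resampled in pairs with replacement; the 95 percent
#' interval is the 2.5 and 97.5 percentiles of the resampled correlations.
#' The effect is deemed significant at p < 0.05 when zero does not fall
#' between the bounds — the decision rule used throughout the validity
#' analyses this package supports.
#'
#' @param x,y Numeric vectors of equal length; pairs with a missing value
#'   in either are dropped.
#' @param n_replicates Number of bootstrap replicates (default 5000).
#' @param seed Mandatory integer seed; results are reproducible given it.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `qiat_boot_ci`: a one-row data frame with
#'   `r`, `lo`, `hi`, `n_replicates`, `seed`, `n_pairs`, `significant`.
#' @export
bootstrap_pearson_ci <- function(x, y, n_replicates = 5000, seed,
                                 conf_level = 0.95) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- as.numeric(x[ok])
  y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant input", call. = FALSE)
  }
  r <- pearson_r(x, y)
  B <- as.integer(n_replicates)
  rb <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
    xb <- matrix(x[idx], nrow = n)
    yb <- matrix(y[idx], nrow = n)
    sx <- colSums(xb); sy <- colSums(yb)
    num <- colSums(xb * yb) - sx * sy / n
    den <- sqrt((colSums(xb^2) - sx^2 / n) * (colSums(yb^2) - sy^2 / n))
    num / den
  })
  rb <- rb[is.finite(rb)] # degenerate resamples (constant draw) carry no information
  a <- (1 - conf_level) / 2
  qs <- unname(stats::quantile(rb, c(a, 1 - a), names = FALSE))
  if (qs[1] > qs[2]) warning("pathological bootstrap interval: lo > hi")
  out <- data.frame(r = r, lo = qs[1], hi = qs[2],
                    n_replicates = B, seed = as.integer(seed), n_pairs = n,
                    significant = qs[1] > 0 | qs[2] < 0)
  class(out) <- c("qiat_boot_ci", class(out))
  out
}

#' Pearson product-moment correlation
#'
#' Thin, explicit implementation used by the bootstrap machinery;
#' numerically identical to `stats::cor(x, y)`.
#'
#' @param x,y Numeric vectors of equal length.
#' @export
pearson_r <- function(x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# ---- minimum detectable effect size -----------------------------------

# log Gaussian hypergeometric 2F1(a, b; c; x) by series; converges for
# 0 <= x < 1 (fast here because c grows with n).
log_hyp2f1 <- function(a, b, cc, x) {
  lterm <- 0
  s <- 1
  for (k in seq_len(20000L)) {
    lterm <- lterm + log(a + k - 1) + log(b + k - 1) -
      log(cc + k - 1) - log(k) + log(x)
    tk <- exp(lterm)
    s <- s + tk
    if (tk < 1e-15 * s) break
  }
  log(s)
}

# Density of the sample correlation r for a bivariate normal sample of size
# n with population correlation rho (Hotelling's exact form).
dcorr <- function(r, rho, n) {
  lf <- log(n - 2) + lgamma(n - 1) + ((n - 1) / 2) * log1p(-rho^2) +
    ((n - 4) / 2) * log1p(-r^2) - 0.5 * log(2 * pi) - lgamma(n - 0.5) -
    (n - 1.5) * log1p(-rho * r) +
    vapply(r, function(ri) log_hyp2f1(0.5, 0.5, n - 0.5, (1 + rho * ri) / 2),
           numeric(1))
  exp(lf)
}

# Two-tailed power of the test of rho = 0 at level alpha, given true rho.
# method "exact": integrate the exact sampling density of r beyond the
# critical values of the t-based test (integration in atanh space for
# numerical stability near |r| = 1). method "fisher": bias-corrected
# Fisher-z normal approximation.
power_corr_test <- function(rho, n, alpha_level = 0.05,
                            method = c("exact", "fisher")) {
  method <- match.arg(method)
  if (method == "fisher") {
    zc <- stats::qnorm(1 - alpha_level / 2)
    m <- (atanh(rho) + rho / (2 * (n - 1))) * sqrt(n - 3)
    return(stats::pnorm(m - zc) + stats::pnorm(-m - zc))
  }
  tc <- stats::qt(1 - alpha_level / 2, df = n - 2)
  rc <- sqrt(tc^2 / (tc^2 + n - 2))
  # integrate in atanh space, where the sampling distribution is close to
  # Normal(atanh(rho), 1/sqrt(n-3)): finite windows around the peak keep
  # the adaptive quadrature from missing a narrow mode
  mu <- atanh(rho)
  sdz <- 1 / sqrt(n - 3)
  lo_all <- mu - 40 * sdz
  hi_all <- mu + 40 * sdz
  f <- function(z) {
    r <- tanh(z)
    dcorr(r, rho, n) * (1 - r^2)
  }
  tail_mass <- function(lower, upper) {
    lower <- max(lower, lo_all)
    upper <- min(upper, hi_all)
    if (lower >= upper) return(0)
    stats::integrate(f, lower, upper, rel.tol = 1e-10, abs.tol = 1e-13,
                     subdivisions = 200L)$value
  }
  tail_mass(atanh(rc), hi_all) + tail_mass(lo_all, atanh(-rc))
}

#' Minimum detectable effect size for a correlation
#'
#' Sensitivity analysis: the smallest population correlation `|rho|` that a
#' two-tailed test of zero correlation detects with the requested power at
#' the requested alpha, for a bivariate-normal sample of size `n`. Solved
#' by bisection on the exact power computed from the sampling distribution
#' of r (Hotelling's density); a bias-corrected Fisher-z approximation is
#' available as `method = "fisher"` and agrees to about 1e-4 at the sample
#' sizes this kind of study uses.
#'
#' @param n Sample size (>= 5).
#' @param alpha_level Two-tailed significance level (default 0.05).
#' @param power Target power (default 0.80).
#' @param method `"exact"` (default) or `"fisher"`.
#' @return An object of class `qiat_mdes`: a list with `n`, `alpha_level`,
#'   `power`, `tails` (always 2), `method`, and `mdes`.
#' @examples
#' mdes_correlation(806)$mdes # 0.098 to 3 decimals
#' @export
mdes_correlation <- function(n, alpha_level = 0.05, power = 0.80,
                             method = c("exact", "fisher")) {
  method <- match.arg(method)
  stopifnot_scalar_number(n, "n")
  if (n < 5) stop("`n` must be at least 5", call. = FALSE)
  stopifnot(alpha_level > 0, alpha_level < 1, power > alpha_level, power < 1)
  f <- function(rho) power_corr_test(rho, n, alpha_level, method) - power
  upper <- 0.999
  while (f(upper) < 0 && upper < 0.9999) upper <- 1 - (1 - upper) / 10
  root <- stats::uniroot(f, c(1e-6, upper), tol = 1e-6)
  structure(
    list(n = as.integer(n), alpha_level = alpha_level, power = power,
         tails = 2L, method = method, mdes = root$root),
    class = "qiat_mdes"
  )
}

#' @export
print.qiat_mdes <- function(x, ...) {
  cat(sprintf(
    "Minimum detectable |r| = %.4f (n = %d, alpha = %g, power = %g, two-tailed)\n",
    x$mdes, x$n, x$alpha_level, x$power))
  invisible(x)
}

#' Validity correlation table
#'
#' Correlates D scores with each numeric column of an external
#' participant-level table, using pairwise-complete cases, the percentile
#' bootstrap for 95 percent confidence intervals, and the CI-based
#' significance rule. Each row also reports the minimum detectable effect
#' size at that cell's effective n.
#'
#' @param dscores Data frame with `participant_id` and `d` columns (e.g.
#'   `score_cohort()$scores`); excluded participants are ignored.
#' @param external_table Data frame with `participant_id` and one column
#'   per external measure.
#' @param n_replicates Bootstrap replicates per cell (default 5000).
#' @param seed Mandatory integer seed; each cell uses a deterministic
#'   substream derived from it.
#' @return A data frame with one row per external measure: `measure`, `r`,
#'   `lo`, `hi`, `n`, `significant`, `mdes`.
#' @export
validity_report <- function(dscores, external_table, n_replicates = 5000, seed) {
  stopifnot("participant_id" %in% names(dscores), "d" %in% names(dscores),
            "participant_id" %in% names(external_table))
  d <- dscores[!is.na(dscores$d), c("participant_id", "d")]
  merged <- merge(d, external_table, by = "participant_id")
  if (!nrow(merged)) stop("no participants in common", call. = FALSE)
  measures <- setdiff(names(external_table), "participant_id")
  rows <- lapply(seq_along(measures), function(i) {
    m <- measures[[i]]
    ci <- bootstrap_pearson_ci(merged$d, merged[[m]],
                               n_replicates = n_replicates,
                               seed = derive_seed(seed, i))
    data.frame(measure = m, r = ci$r, lo = ci$lo, hi = ci$hi,
               n = ci$n_pairs, significant = ci$significant,
               mdes = mdes_correlation(ci$n_pairs)$mdes,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
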