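`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' library code never clobbers the user's random stream. All stochastic
#' operations in the package funnel through this helper, which is why a seed
#' argument is mandatory wherever randomness occurs.
#'
#' @param seed Integer scalar seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed) || length(seed) != 1L || is.na(seed)) {
    stop("a single non-missing integer `seed` is required", call. = FALSE)
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic substream seed, kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + as.double(offset) * 104729) %% 2147483629 + 1)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}

stopifnot_scalar_number <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
}
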