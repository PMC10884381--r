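#' Canonical trial CSV columns
#'
#' The canonical long format stores one row per timed classification
#' response. `variant` is the integer encoding of [variant_id()],
#' `is_error` is 0/1, and `latency_ms` is an integer number of milliseconds
#' from stimulus onset to the first keypress (under the built-in error
#' penalty, to the final, correct keypress).
#'
#' @export
trial_columns <- function() {
  c("participant_id", "session_id", "variant", "block_index", "block_role",
    "trial_index", "item_id", "category", "response_side", "is_error",
    "latency_ms")
}

#' Construct a session
#'
#' A session is one participant's full run of the instrument under one
#' counterbalance variant. `complete` is `TRUE` iff every block of the spec
#' has its full trial count present.
#'
#' @param participant_id,session_id Identifiers (`session_id` e.g. "t1"/"t2").
#' @param variant A `qiat_variant`.
#' @param trials Data frame with columns `block_index`, `block_role`,
#'   `trial_index`, `item_id`, `category`, `response_side`, `is_error`
#'   (logical), `latency_ms`.
#' @param spec The `qiat_instrument` the session was run under (used for the
#'   completeness check).
#' @param error_handling_mode `"d600"`, `"built_in_penalty"`, or `NA` when
#'   the mode is to be supplied at scoring time.
#' @return An object of class `qiat_session`.
#' @export
session_data <- function(participant_id, session_id, variant, trials, spec,
                         error_handling_mode = NA_character_) {
  stopifnot(inherits(variant, "qiat_variant"))
  if (any(trials$latency_ms < 0)) stop("latency_ms must be non-negative", call. = FALSE)
  counts <- tapply(rep(1L, nrow(trials)), trials$block_index, sum)
  complete <- all(vapply(seq_len(nrow(spec$blocks)), function(i) {
    b <- spec$blocks[i, ]
    identical(unname(counts[as.character(b$index)]), b$n_trials)
  }, logical(1)))
  structure(
    list(participant_id = as.character(participant_id),
         session_id = as.character(session_id),
         variant = variant,
         error_handling_mode = error_handling_mode,
         trials = trials,
         complete = complete),
    class = "qiat_session"
  )
}

#' @export
print.qiat_session <- function(x, ...) {
  cat(sprintf("<qiat_session> %s/%s variant=%d trials=%d complete=%s mode=%s\n",
              x$participant_id, x$session_id, variant_id(x$variant),
              nrow(x$trials), x$complete, x$error_handling_mode))
  invisible(x)
}

#' Write sessions to the canonical trial CSV
#'
#' Lossless on the data model: `read_trials()` on the written file yields
#' equal sessions. Latencies are written as integers, `is_error` as 0/1.
#'
#' @param sessions List of `qiat_session`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(sessions, path) {
  cols <- trial_columns()
  if (!length(sessions)) {
    writeLines(paste(cols, collapse = ","), path)
    return(invisible(path))
  }
  rows <- lapply(sessions, function(s) {
    stopifnot(inherits(s, "qiat_session"))
    tr <- s$trials
    data.frame(
      participant_id = s$participant_id, session_id = s$session_id,
      variant = variant_id(s$variant), block_index = tr$block_index,
      block_role = tr$block_role, trial_index = tr$trial_index,
      item_id = tr$item_id, category = tr$category,
      response_side = tr$response_side, is_error = as.integer(tr$is_error),
      latency_ms = as.integer(round(tr$latency_ms)), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sessions from the canonical trial CSV
#'
#' Rows failing validation (negative or non-numeric latency, unknown block
#' index, malformed error flag) are reported with their file line numbers;
#' any session containing a bad row is excluded from the return value with
#' a logged reason. Problems are attached as `attr(x, "problems")` and
#' summarized in a warning.
#'
#' @param path Path to a trial CSV.
#' @param spec The `qiat_instrument` the data were collected under.
#' @return A list of `qiat_session`, ordered by participant then session id,
#'   with a `problems` attribute (data frame of `line`, `message`).
#' @export
read_trials <- function(path, spec) {
  if (!file.exists(path)) stop("trial file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character",
                                       session_id = "character"))
  missing <- setdiff(trial_columns(), names(df))
  if (length(missing)) {
    stop("trial file ", path, " lacks mandatory columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  problems <- data.frame(line = integer(0), message = character(0),
                         stringsAsFactors = FALSE)
  note <- function(lines, msg) {
    problems <<- rbind(problems, data.frame(line = lines, message = msg,
                                            stringsAsFactors = FALSE))
  }
  lat <- suppressWarnings(as.numeric(df$latency_ms))
  bad <- which(is.na(lat) | lat < 0)
  if (length(bad)) note(bad + 1L, "invalid latency_ms (missing or negative)")
  bad_block <- which(!df$block_index %in% spec$blocks$index)
  if (length(bad_block)) note(bad_block + 1L, "block_index not in instrument plan")
  bad_err <- which(!df$is_error %in% c(0L, 1L, TRUE, FALSE))
  if (length(bad_err)) note(bad_err + 1L, "is_error must be 0/1")
  bad_var <- which(!df$variant %in% 0:3)
  if (length(bad_var)) note(bad_var + 1L, "variant id must be 0..3")

  bad_rows <- sort(unique(problems$line - 1L))
  key <- paste(df$participant_id, df$session_id, sep = "\r")
  bad_sessions <- unique(key[bad_rows])
  keep <- !(key %in% bad_sessions)
  if (length(bad_sessions)) {
    warning(sprintf("%d row(s) failed validation; %d session(s) excluded",
                    length(bad_rows), length(bad_sessions)), call. = FALSE)
  }
  df <- df[keep, , drop = FALSE]
  key <- key[keep]

  sessions <- list()
  for (k in unique(key[order(df$participant_id, df$session_id)])) {
    sub <- df[key == k, , drop = FALSE]
    vid <- unique(sub$variant)
    if (length(vid) != 1L) {
      note(NA_integer_, sprintf("session %s has inconsistent variant ids",
                                gsub("\r", "/", k)))
      next
    }
    trials <- data.frame(
      block_index = as.integer(sub$block_index), block_role = sub$block_role,
      trial_index = as.integer(sub$trial_index), item_id = sub$item_id,
      category = sub$category, response_side = sub$response_side,
      is_error = as.logical(sub$is_error),
      latency_ms = as.integer(sub$latency_ms), stringsAsFactors = FALSE
    )
    rownames(trials) <- NULL
    sessions[[length(sessions) + 1L]] <- session_data(
      participant_id = sub$participant_id[1L], session_id = sub$session_id[1L],
      variant = variant_from_id(vid), trials = trials, spec = spec
    )
  }
  attr(sessions, "problems") <- problems
  sessions
}

#' Participant exclusion ledger
#'
#' Accounts for a cohort the way participant flow is reported for this kind
#' of study: participants who started, minus those who did not complete the
#' task, minus excessively fast responders, equals the retained sample.
#' Incompleteness takes precedence: a participant appearing in both id sets
#' is counted as incomplete only.
#'
#' @param n_started Number of participants who started.
#' @param incomplete_ids Character vector of ids, or a single count.
#' @param fast_ids Character vector of ids, or a single count.
#' @return An object of class `qiat_ledger` with fields `n_started`,
#'   `n_incomplete`, `n_fast_excluded`, `n_retained` and a per-participant
#'   `reasons` map (empty when counts were supplied).
#' @examples
#' summarize_exclusions(1043, 3, 234)$n_retained # 806
#' @export
summarize_exclusions <- function(n_started, incomplete_ids = character(0),
                                 fast_ids = character(0)) {
  if (!is_count(n_started)) stop("`n_started` must be a count", call. = FALSE)
  reasons <- character(0)
  if (is.character(incomplete_ids) || is.character(fast_ids)) {
    incomplete_ids <- unique(as.character(incomplete_ids))
    fast_ids <- setdiff(unique(as.character(fast_ids)), incomplete_ids)
    n_incomplete <- length(incomplete_ids)
    n_fast <- length(fast_ids)
    reasons <- c(stats::setNames(rep("incomplete", n_incomplete), incomplete_ids),
                 stats::setNames(rep("fast_responder", n_fast), fast_ids))
  } else {
    if (!is_count(incomplete_ids) || !is_count(fast_ids)) {
      stop("`incomplete_ids` and `fast_ids` must be id vectors or counts",
           call. = FALSE)
    }
    n_incomplete <- as.integer(incomplete_ids)
    n_fast <- as.integer(fast_ids)
  }
  if (n_incomplete + n_fast > n_started) {
    stop("exclusions exceed the number of started participants", call. = FALSE)
  }
  structure(
    list(n_started = as.integer(n_started), n_incomplete = n_incomplete,
         n_fast_excluded = n_fast,
         n_retained = as.integer(n_started) - n_incomplete - n_fast,
         reasons = reasons),
    class = "qiat_ledger"
  )
}

#' @export
print.qiat_ledger <- function(x, ...) {
  cat(sprintf(paste0("<qiat_ledger> started=%d incomplete=%d ",
                     "fast_excluded=%d retained=%d\n"),
              x$n_started, x$n_incomplete, x$n_fast_excluded, x$n_retained))
  invisible(x)
}
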