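#' Construct a qIAT instrument specification
#'
#' An instrument specification is the machine-readable form of a
#' questionnaire-based IAT: the two target category labels (construct pole
#' first), the two logical labels (`True`/`False`), the mirrored statement
#' pool, and the seven-block administration plan with side labels for the
#' base (unswapped, initial-pairing-first) presentation.
#'
#' @param name Instrument name.
#' @param target_labels Character vector of length 2; the construct-positive
#'   pole (the label whose self-association raises the score) first.
#' @param logical_labels Character vector of length 2, e.g. `c("True","False")`.
#' @param positive_pole The target label whose self-association raises the
#'   D score; defaults to the first target label.
#' @param statements Data frame with columns `item_id`, `text`, `category`,
#'   `mirror_of` (`NA` for logical statements).
#' @param blocks Data frame with columns `index`, `role` (one of
#'   `learning`/`practice`/`test`), `task`, `n_trials`, and list columns
#'   `left_labels`, `right_labels`.
#' @param schema_version Serialization schema version string.
#' @return An object of class `qiat_instrument`.
#' @seealso [load_lpfs_qiat()], [validate_instrument()]
#' @export
instrument_spec <- function(name, target_labels, logical_labels, statements,
                            blocks, positive_pole = target_labels[[1]],
                            schema_version = "1.0") {
  statements <- as.data.frame(statements, stringsAsFactors = FALSE)
  blocks <- as.data.frame(blocks, stringsAsFactors = FALSE)
  structure(
    list(
      schema_version = as.character(schema_version),
      name = as.character(name),
      target_labels = as.character(target_labels),
      logical_labels = as.character(logical_labels),
      positive_pole = as.character(positive_pole),
      statements = statements,
      blocks = blocks
    ),
    class = "qiat_instrument"
  )
}

#' @export
print.qiat_instrument <- function(x, ...) {
  tgt <- table(factor(x$statements$category, levels = x$target_labels))
  lgl <- table(factor(x$statements$category, levels = x$logical_labels))
  cat(sprintf("<qiat_instrument> %s (schema %s)\n", x$name, x$schema_version))
  cat(sprintf("  target:  %s\n",
              paste(sprintf("%s (%d)", names(tgt), tgt), collapse = " / ")))
  cat(sprintf("  logical: %s\n",
              paste(sprintf("%s (%d)", names(lgl), lgl), collapse = " / ")))
  cat(sprintf("  blocks:  %d (%s trials; total %d)\n",
              nrow(x$blocks), paste(x$blocks$n_trials, collapse = ","),
              sum(x$blocks$n_trials)))
  invisible(x)
}

#' Load the packaged LPFS-qIAT instrument
#'
#' Returns the Level of Personality Functioning Scale qIAT: 12 statements
#' describing impaired personality functioning, each mirrored by a reversed
#' not-impaired statement, 5 objectively true and 5 objectively false
#' self-related logical statements, and the seven-block plan with trial
#' counts 40, 20, 20, 40, 40, 20, 40 (two learning blocks, three practice
#' blocks, two critical test blocks).
#'
#' @return A validated `qiat_instrument`.
#' @examples
#' spec <- load_lpfs_qiat()
#' sum(spec$blocks$n_trials) # 220 trials per administration
#' @export
load_lpfs_qiat <- function() {
  path <- system.file("extdata", "lpfs_qiat.json", package = "qiatr")
  if (!nzchar(path) || !file.exists(path)) {
    stop("packaged instrument file 'extdata/lpfs_qiat.json' not found; ",
         "the installation appears corrupted", call. = FALSE)
  }
  spec <- read_instrument(path)
  problems <- validate_instrument(spec)
  if (length(problems)) {
    stop("packaged LPFS-qIAT spec failed validation: ",
         paste(problems, collapse = "; "), call. = FALSE)
  }
  spec
}

#' Read an instrument specification from JSON
#'
#' @param path Path to a schema-versioned instrument JSON file.
#' @return A `qiat_instrument`.
#' @export
read_instrument <- function(path) {
  if (!file.exists(path)) stop("instrument file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  needed <- c("schema_version", "name", "target_labels", "logical_labels",
              "positive_pole", "statements", "blocks")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    stop("instrument file ", path, " lacks fields: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  statements <- do.call(rbind, lapply(raw$statements, function(s) {
    data.frame(item_id = s$item_id, text = s$text, category = s$category,
               mirror_of = if (is.null(s$mirror_of)) NA_character_ else s$mirror_of,
               stringsAsFactors = FALSE)
  }))
  blocks <- do.call(rbind, lapply(raw$blocks, function(b) {
    df <- data.frame(index = as.integer(b$index), role = b$role, task = b$task,
                     n_trials = as.integer(b$n_trials), stringsAsFactors = FALSE)
    df$left_labels <- list(unlist(b$left_labels, use.names = FALSE))
    df$right_labels <- list(unlist(b$right_labels, use.names = FALSE))
    df
  }))
  instrument_spec(
    name = raw$name,
    target_labels = unlist(raw$target_labels, use.names = FALSE),
    logical_labels = unlist(raw$logical_labels, use.names = FALSE),
    positive_pole = raw$positive_pole,
    statements = statements,
    blocks = blocks,
    schema_version = raw$schema_version
  )
}

#' Write an instrument specification to JSON
#'
#' `read_instrument(write_instrument(spec, path))` reproduces an equal spec.
#'
#' @param spec A `qiat_instrument`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_instrument <- function(spec, path) {
  stopifnot(inherits(spec, "qiat_instrument"))
  statements <- lapply(seq_len(nrow(spec$statements)), function(i) {
    s <- spec$statements[i, ]
    list(item_id = s$item_id, text = s$text, category = s$category,
         mirror_of = if (is.na(s$mirror_of)) NULL else s$mirror_of)
  })
  blocks <- lapply(seq_len(nrow(spec$blocks)), function(i) {
    b <- spec$blocks[i, ]
    list(index = b$index, role = b$role, task = b$task, n_trials = b$n_trials,
         left_labels = b$left_labels[[1]], right_labels = b$right_labels[[1]])
  })
  doc <- list(schema_version = spec$schema_version, name = spec$name,
              target_labels = spec$target_labels,
              logical_labels = spec$logical_labels,
              positive_pole = spec$positive_pole,
              statements = statements, blocks = blocks)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' Validate an instrument specification
#'
#' Checks the structural invariants of the qIAT design: valid category
#' labels, symmetric one-to-one mirroring of the target statement poles,
#' balanced pole counts, well-formed side labels (one target and one logical
#' label per side in combined blocks), exactly two test blocks, and even
#' trial counts in combined blocks (required for strict category
#' alternation).
#'
#' @param spec A `qiat_instrument`.
#' @return A character vector of violation descriptions; empty when valid.
#' @export
validate_instrument <- function(spec) {
  v <- character(0)
  say <- function(...) v <<- c(v, sprintf(...))
  if (length(spec$target_labels) != 2L || anyDuplicated(spec$target_labels)) {
    say("target_labels must be two distinct labels")
  }
  if (length(spec$logical_labels) != 2L || anyDuplicated(spec$logical_labels)) {
    say("logical_labels must be two distinct labels")
  }
  if (!spec$positive_pole %in% spec$target_labels) {
    say("positive_pole '%s' is not a target label", spec$positive_pole)
  }
  st <- spec$statements
  all_labels <- c(spec$target_labels, spec$logical_labels)
  bad_cat <- st$item_id[!st$category %in% all_labels]
  for (id in bad_cat) say("statement '%s' has an unknown category", id)
  if (anyDuplicated(st$item_id)) say("statement item_ids are not unique")

  # mirroring: every target statement has exactly one symmetric mirror in
  # the opposite target pole
  tgt <- st[st$category %in% spec$target_labels, , drop = FALSE]
  for (i in seq_len(nrow(tgt))) {
    id <- tgt$item_id[i]
    m <- tgt$mirror_of[i]
    if (is.na(m)) {
      say("target statement '%s' has no mirror", id)
      next
    }
    j <- match(m, st$item_id)
    if (is.na(j)) {
      say("target statement '%s' mirrors unknown item '%s'", id, m)
      next
    }
    opposite <- setdiff(spec$target_labels, tgt$category[i])
    if (!identical(st$category[j], opposite)) {
      say("mirror of '%s' ('%s') is not in the opposite target category", id, m)
    }
    if (!identical(st$mirror_of[j], id)) {
      say("mirroring of '%s' and '%s' is not symmetric", id, m)
    }
  }
  n_pole <- vapply(spec$target_labels, function(l) sum(st$category == l), 0L)
  if (length(unique(n_pole)) > 1L) {
    say("target statement counts differ across poles (%s)",
        paste(n_pole, collapse = " vs "))
  }
  n_lgl <- vapply(spec$logical_labels, function(l) sum(st$category == l), 0L)
  if (length(unique(n_lgl)) > 1L) {
    say("logical statement counts differ across poles (%s)",
        paste(n_lgl, collapse = " vs "))
  }

  bl <- spec$blocks
  if (anyDuplicated(bl$index)) say("block indices are not unique")
  if (sum(bl$role == "test") != 2L) say("exactly two test blocks required")
  bad_role <- bl$index[!bl$role %in% c("learning", "practice", "test")]
  for (b in bad_role) say("block %d has an unknown role", b)
  for (i in seq_len(nrow(bl))) {
    b <- bl[i, ]
    if (b$n_trials < 1L) say("block %d has a non-positive trial count", b$index)
    left <- b$left_labels[[1]]
    right <- b$right_labels[[1]]
    combined <- grepl("^combined", b$task)
    if (combined) {
      ok_side <- function(s) {
        sum(s %in% spec$target_labels) == 1L && sum(s %in% spec$logical_labels) == 1L
      }
      if (!ok_side(left) || !ok_side(right)) {
        say("combined block %d must carry one target and one logical label per side",
            b$index)
      }
      if (b$n_trials %% 2L != 0L) {
        say("combined block %d needs an even trial count for category alternation",
            b$index)
      }
    } else {
      if (length(left) != 1L || length(right) != 1L) {
        say("single-task block %d must carry one label per side", b$index)
      }
    }
    if (anyDuplicated(c(left, right))) {
      say("block %d repeats a label across sides", b$index)
    }
  }
  v
}

#' Counterbalance variants
#'
#' A qIAT administration is counterbalanced on two binary factors: which
#' physical key carries which side labels (`keys_swapped`) and whether the
#' reversed pairing is presented before the initial pairing
#' (`reversed_first`). The four combinations enumerate all variants.
#'
#' @param keys_swapped,reversed_first Logical scalars.
#' @return `cb_variant()` returns one `qiat_variant`;
#'   `counterbalance_variants()` returns a list of all four, in the
#'   deterministic order of `variant_id` 0..3.
#' @export
cb_variant <- function(keys_swapped = FALSE, reversed_first = FALSE) {
  stopifnot(is.logical(keys_swapped), is.logical(reversed_first),
            length(keys_swapped) == 1L, length(reversed_first) == 1L,
            !is.na(keys_swapped), !is.na(reversed_first))
  structure(
    list(keys_swapped = keys_swapped, reversed_first = reversed_first),
    class = "qiat_variant"
  )
}

#' @export
print.qiat_variant <- function(x, ...) {
  cat(sprintf("<qiat_variant %d> keys_swapped=%s reversed_first=%s\n",
              variant_id(x), x$keys_swapped, x$reversed_first))
  invisible(x)
}

#' @rdname cb_variant
#' @param spec A valid `qiat_instrument` (the variants do not depend on its
#'   content, only on the two-factor counterbalancing design).
#' @export
counterbalance_variants <- function(spec = NULL) {
  lapply(0:3, variant_from_id)
}

#' Integer encoding of a counterbalance variant
#'
#' `variant_id` maps a variant to `keys_swapped + 2 * reversed_first`
#' (0..3); `variant_from_id` inverts the mapping. This id is what the
#' canonical trial CSV stores in its `variant` column.
#'
#' @param variant A `qiat_variant`.
#' @export
variant_id <- function(variant) {
  as.integer(variant$keys_swapped) + 2L * as.integer(variant$reversed_first)
}

#' @rdname variant_id
#' @param id Integer 0..3.
#' @export
variant_from_id <- function(id) {
  id <- as.integer(id)
  if (is.na(id) || id < 0L || id > 3L) stop("variant id must be 0..3", call. = FALSE)
  cb_variant(keys_swapped = id %% 2L == 1L, reversed_first = id >= 2L)
}

#' Per-block side labels and pairing under a counterbalance variant
#'
#' Applies the variant to the base block plan: `reversed_first` swaps the
#' target labels' sides in every block (so the reversed target assignment is
#' taught first and the blocks marked reversed in the base plan carry the
#' initial assignment); `keys_swapped` then swaps the left and right label
#' sets wholesale. For combined blocks the pairing is `"compatible"` when
#' the positive pole shares a side with the first logical label (`True`),
#' `"incompatible"` otherwise; single-task blocks have pairing `NA`.
#'
#' @param spec A `qiat_instrument`.
#' @param variant A `qiat_variant`.
#' @return The spec's block data frame with variant-adjusted `left_labels`,
#'   `right_labels` and an added `pairing` column.
#' @export
block_layout <- function(spec, variant) {
  bl <- spec$blocks
  swap_target_sides <- function(side, other) {
    # move target labels to the side they occupy in `other`
    c(setdiff(side, spec$target_labels), intersect(other, spec$target_labels))
  }
  if (variant$reversed_first) {
    for (i in seq_len(nrow(bl))) {
      left <- bl$left_labels[[i]]
      right <- bl$right_labels[[i]]
      bl$left_labels[[i]] <- swap_target_sides(left, right)
      bl$right_labels[[i]] <- swap_target_sides(right, left)
    }
  }
  if (variant$keys_swapped) {
    tmp <- bl$left_labels
    bl$left_labels <- bl$right_labels
    bl$right_labels <- tmp
  }
  bl$pairing <- vapply(seq_len(nrow(bl)), function(i) {
    if (!grepl("^combined", bl$task[i])) return(NA_character_)
    left <- bl$left_labels[[i]]
    pos_left <- spec$positive_pole %in% left
    true_left <- spec$logical_labels[[1]] %in% left
    if (pos_left == true_left) "compatible" else "incompatible"
  }, character(1))
  bl
}

#' Unroll an instrument into a trial plan
#'
#' Produces the full administration schedule for one participant: one row
#' per trial with the stimulus, its category, the correct response side
#' under the variant, and the block's pairing. In combined blocks,
#' target-category and logical-category trials strictly alternate (target
#' first); within each category stream stimuli are drawn by reshuffled
#' cycling, so a stimulus repeats only after its pool is exhausted.
#' Single-task blocks cycle over the relevant pool the same way.
#'
#' @param spec A valid `qiat_instrument`.
#' @param variant A `qiat_variant`.
#' @param seed Integer seed; mandatory, the plan is reproducible given
#'   `(spec, variant, seed)`.
#' @return A data frame with columns `block_index`, `block_role`,
#'   `block_task`, `trial_index`, `item_id`, `category`, `correct_side`,
#'   `pairing`.
#' @export
build_trial_sequence <- function(spec, variant, seed) {
  stopifnot(inherits(spec, "qiat_instrument"), inherits(variant, "qiat_variant"))
  layout <- block_layout(spec, variant)
  st <- spec$statements
  target_pool <- st$item_id[st$category %in% spec$target_labels]
  logical_pool <- st$item_id[st$category %in% spec$logical_labels]
  category_of <- st$category
  names(category_of) <- st$item_id

  cycle_draw <- function(pool, n) {
    reps <- ceiling(n / length(pool))
    out <- unlist(lapply(seq_len(reps), function(i) sample(pool)),
                  use.names = FALSE)
    out[seq_len(n)]
  }

  with_seed(seed, {
    rows <- lapply(seq_len(nrow(layout)), function(i) {
      b <- layout[i, ]
      n <- b$n_trials
      if (grepl("^combined", b$task)) {
        tgt <- cycle_draw(target_pool, n %/% 2L)
        lgl <- cycle_draw(logical_pool, n %/% 2L)
        items <- character(n)
        items[seq(1L, n, by = 2L)] <- tgt
        items[seq(2L, n, by = 2L)] <- lgl
      } else if (grepl("^logical", b$task)) {
        items <- cycle_draw(logical_pool, n)
      } else {
        items <- cycle_draw(target_pool, n)
      }
      cats <- unname(category_of[items])
      data.frame(
        block_index = b$index, block_role = b$role, block_task = b$task,
        trial_index = seq_len(n), item_id = items, category = cats,
        correct_side = ifelse(cats %in% b$left_labels[[1]], "left", "right"),
        pairing = b$pairing, stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
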