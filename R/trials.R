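#' Trial-table columns
#'
#' Column order of the canonical trial CSV. One row per nonaborted trial.
#' @return Character vector of column names.
#' @export
trial_columns <- function() {
  c("participant_id", "group", "block_index", "block_type", "feature", "load",
    "side", "w_target", "w_distractor", "key", "response_class",
    "timo_subtype", "correct", "rt")
}

#' Validate a trial table
#'
#' Checks every structural invariant of the trial format: enum domains, value
#' ranges, block-type/load consistency (`switch` iff an `S` block), agreement
#' of `response_class`/`timo_subtype` with the key map, and the definition of
#' `correct` (defined only for relevant presses; `r1` is correct iff the
#' target stimulus `w_target >= 0`, the documented tie rule treating 0 as the
#' positive category).
#'
#' @param trials A data frame with the columns of [trial_columns()].
#' @param keymap Key map, see [key_map()].
#' @return `trials`, invisibly, with `correct` coerced to integer. Throws a
#'   validation error naming the first offending row and rule otherwise.
#' @export
validate_trials <- function(trials, keymap = key_map()) {
  missing_cols <- setdiff(trial_columns(), names(trials))
  if (length(missing_cols)) {
    stop("trial table is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  fail <- function(rows, rule) {
    stop(sprintf("trial validation failed at row %d: %s", rows[1], rule), call. = FALSE)
  }
  chk <- function(ok, rule) if (!all(ok)) fail(which(!ok), rule)

  n <- nrow(trials)
  if (n == 0L) return(invisible(trials))

  chk(!is.na(trials$participant_id) & nzchar(trials$participant_id),
      "participant_id must be a non-empty token")
  chk(trials$group %in% c("adhd", "control", "unknown"), "group must be adhd/control/unknown")
  chk(!is.na(trials$block_index) & trials$block_index %in% 1:8, "block_index must be in 1..8")
  chk(trials$block_type %in% c("O", "C", "S"), "block_type must be O/C/S")
  chk(trials$feature %in% c("ori", "col"), "feature must be ori/col")
  chk(trials$load %in% c("noswitch", "switch"), "load must be noswitch/switch")
  chk(trials$side %in% c("left", "right"), "side must be left/right")
  chk((trials$load == "switch") == (trials$block_type == "S"),
      "load must be switch iff block_type is S")
  chk((trials$block_type != "O" | trials$feature == "ori") &
        (trials$block_type != "C" | trials$feature == "col"),
      "feature must match block_type for O and C blocks")
  chk(is.finite(trials$w_target) & abs(trials$w_target) <= 0.5 + 1e-12,
      "w_target must lie in [-0.5, 0.5]")
  chk(is.finite(trials$w_distractor), "w_distractor must be finite")
  chk(trials$feature != "col" | abs(trials$w_distractor) <= 0.5 + 1e-12,
      "colour w_distractor must lie in [-0.5, 0.5]")
  chk(!is.na(trials$key) & trials$key %in% 1:8, "key must be in 1..8")
  chk(is.finite(trials$rt) & trials$rt > 0, "rt must be a positive number of seconds")

  # derived columns must agree with the key map
  derived <- mapply(function(k, f, sd) {
    cl <- classify_key(k, f, sd, keymap)
    c(cl$response_class, cl$timo_subtype)
  }, trials$key, trials$feature, trials$side)
  chk(trials$response_class == derived[1, ],
      "response_class inconsistent with key and cue pair")
  chk(trials$timo_subtype == derived[2, ],
      "timo_subtype inconsistent with key and cue pair")

  is_timo <- trials$response_class == "timo"
  chk(is_timo | trials$timo_subtype == "none", "timo_subtype must be none unless timo")
  chk(!is_timo | is.na(trials$correct), "correct must be undefined (NA) on timo trials")
  expected_correct <- ifelse(trials$response_class == "r1",
                             as.integer(trials$w_target >= 0),
                             as.integer(trials$w_target < 0))
  chk(is_timo | (!is.na(trials$correct) & trials$correct == expected_correct),
      "correct must equal 1 iff the response sign matches sign(w_target) (0 counts positive)")
  trials$correct <- as.integer(trials$correct)
  invisible(trials)
}

#' Read and write trial tables
#'
#' The trial CSV dialect is comma-separated UTF-8 with one header row and
#' lowercase snake-case column names; `w` columns carry full precision, `rt`
#' is written with 4 decimals (seconds), block indices are 1-based. Only
#' nonaborted trials are stored. `read_trials()` recomputes the derived
#' columns (`response_class`, `timo_subtype`, `correct`) from the key map and
#' validates them against the file.
#'
#' @param path File path.
#' @param trials A valid trial table.
#' @return `read_trials()`: a validated trial data frame.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!identical(header, trial_columns())) {
    stop("malformed trial CSV header; expected columns: ",
         paste(trial_columns(), collapse = ","), call. = FALSE)
  }
  trials <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(participant_id = "character"))
  trials$correct <- suppressWarnings(as.integer(trials$correct))
  validate_trials(trials)
  trials
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  trials <- validate_trials(trials)
  out <- trials[, trial_columns()]
  fmt_num <- function(x) vapply(x, function(v) format(v, digits = 17, scientific = FALSE), "")
  out$w_target <- fmt_num(out$w_target)
  out$w_distractor <- fmt_num(out$w_distractor)
  out$rt <- sprintf("%.4f", out$rt)
  out$correct <- ifelse(is.na(out$correct), "NA", as.character(out$correct))
  con <- file(path, open = "wb")  # binary mode: byte-identical output across platforms
  on.exit(close(con))
  writeLines(paste(trial_columns(), collapse = ","), con)
  if (nrow(out)) {
    lines <- do.call(paste, c(unname(as.list(out)), sep = ","))
    writeLines(lines, con)
  }
  invisible(path)
}
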