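#' The eight-key response map
#'
#' The task uses a split keypad with eight response keys. Four keys sit on the
#' left keypad and four on the right; within a keypad, two keys answer the
#' orientation question (counterclockwise / clockwise) and two the colour
#' question (more blue / more yellow). On any trial, the feature-dimension cue
#' and the spatial cue jointly select exactly two relevant keys; the other six
#' count as task-irrelevant motor output (TIMO) and subdivide into two spatial
#' errors (right feature, wrong side), two feature errors (right side, wrong
#' feature) and two errors that are both.
#'
#' Key indices are abstract 1..8 (the physical keypad layout carries no
#' analytic content); the partition structure is what matters.
#'
#' @return A data frame with columns `key` (1..8), `side` (`"left"`/`"right"`),
#'   `feature` (`"ori"`/`"col"`) and `response` (`"r0"`/`"r1"`). `r1` is the
#'   positive response: clockwise for orientation, more yellow for colour.
#' @examples
#' km <- key_map()
#' relevant_keys("ori", "left")
#' @export
key_map <- function() {
  data.frame(
    key = 1:8,
    side = rep(c("left", "right"), each = 4L),
    feature = rep(rep(c("ori", "col"), each = 2L), 2L),
    response = rep(c("r0", "r1"), 4L),
    stringsAsFactors = FALSE
  )
}

#' @rdname key_map
#' @param feature Cued feature dimension, `"ori"` or `"col"`.
#' @param side Cued side, `"left"` or `"right"`.
#' @param keymap A key map as returned by [key_map()].
#' @return `relevant_keys()`: the two relevant key indices, ordered `r0`, `r1`.
#' @export
relevant_keys <- function(feature, side, keymap = key_map()) {
  feature <- match.arg(feature, c("ori", "col"))
  side <- match.arg(side, c("left", "right"))
  rows <- keymap[keymap$feature == feature & keymap$side == side, ]
  rows <- rows[order(rows$response), ]
  stats::setNames(rows$key, rows$response)
}

#' Classify a key press as relevant or task-irrelevant motor output
#'
#' Given the cue pair in force on a trial, maps a pressed key to its response
#' class: `r0`/`r1` for the two relevant keys, otherwise `timo` with a subtype
#' (`spatial`, `feature`, or `both`) describing which half of the cue was
#' violated.
#'
#' @inheritParams relevant_keys
#' @param key Pressed key index, 1..8.
#' @return A list with elements `response_class` and `timo_subtype`
#'   (`"none"` for relevant presses).
#' @examples
#' classify_key(1, "ori", "left")  # relevant: r0
#' classify_key(5, "ori", "left")  # same feature, wrong side: spatial error
#' @export
classify_key <- function(key, feature, side, keymap = key_map()) {
  if (length(key) != 1L || !key %in% 1:8) {
    stop("`key` must be a single integer in 1..8", call. = FALSE)
  }
  feature <- match.arg(feature, c("ori", "col"))
  side <- match.arg(side, c("left", "right"))
  row <- keymap[keymap$key == key, ]
  same_feat <- row$feature == feature
  same_side <- row$side == side
  if (same_feat && same_side) {
    return(list(response_class = row$response, timo_subtype = "none"))
  }
  subtype <- if (same_feat) "spatial" else if (same_side) "feature" else "both"
  list(response_class = "timo", timo_subtype = subtype)
}

#' @rdname classify_key
#' @param response `"r0"` or `"r1"`.
#' @return `response_key()`: the key index a relevant response maps to.
#' @export
response_key <- function(feature, side, response, keymap = key_map()) {
  relevant_keys(feature, side, keymap)[[match.arg(response, c("r0", "r1"))]]
}

#' @rdname classify_key
#' @param subtype TIMO subtype, one of `"spatial"`, `"feature"`, `"both"`.
#' @return `timo_keys()`: the two key indices producing that TIMO subtype
#'   under the given cue pair.
#' @export
timo_keys <- function(feature, side, subtype, keymap = key_map()) {
  subtype <- match.arg(subtype, c("spatial", "feature", "both"))
  cls <- vapply(1:8, function(k) classify_key(k, feature, side, keymap)$timo_subtype, "")
  which(cls == subtype)
}

#' Condition name from feature and load
#'
#' The four conditions are `Ori` and `Col` (no-switch blocks) and `OriS` and
#' `ColS` (switch blocks).
#'
#' @param feature `"ori"` or `"col"`.
#' @param load `"noswitch"` or `"switch"`.
#' @return Condition name, one of `"Ori"`, `"Col"`, `"OriS"`, `"ColS"`.
#' @export
condition_name <- function(feature, load) {
  base <- ifelse(feature == "ori", "Ori", "Col")
  ifelse(load == "switch", paste0(base, "S"), base)
}

#' @rdname condition_name
#' @param condition Condition name.
#' @return `condition_parts()`: list with `feature` and `load`.
#' @export
condition_parts <- function(condition) {
  condition <- match.arg(condition, c("Ori", "Col", "OriS", "ColS"))
  list(
    feature = if (substr(condition, 1, 3) == "Ori") "ori" else "col",
    load = if (substr(condition, nchar(condition), nchar(condition)) == "S") "switch" else "noswitch"
  )
}

#' @rdname condition_name
#' @return `condition_names()`: the four condition names.
#' @export
condition_names <- function() c("Ori", "Col", "OriS", "ColS")
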