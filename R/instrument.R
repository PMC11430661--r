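#' Load a FLI-P instrument definition
#'
#' The FLI-P is a checklist of 64 statements about a child's listening
#' behaviour, ordered developmentally and organised into six hierarchical
#' skill areas (sound awareness through advanced open-set listening). The
#' packaged default definition carries the published area structure and item
#' order; item wordings that are not public are clearly marked placeholder
#' paraphrases anchored by the published exemplar items.
#'
#' @param source Path to an instrument-definition JSON document
#'   (`{version, areas:[...], items:[{index, area, text}]}`), or `NULL` for
#'   the packaged default.
#' @return An object of class `flip_instrument`: a list with `version`,
#'   `areas` (character vector of 6 area names) and `items` (data frame with
#'   columns `index`, `area`, `text`).
#' @examples
#' instr <- load_instrument()
#' nrow(instr$items)
#' @export
load_instrument <- function(source = NULL) {
  path <- if (is.null(source)) extdata_path("flip_instrument.json") else source
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
    error = function(e) stop_arg("cannot parse instrument definition: ", conditionMessage(e))
  )
  if (is.null(doc$items) || is.null(doc$areas)) {
    stop_arg("instrument definition must contain `areas` and `items`")
  }
  items <- as.data.frame(doc$items)
  required <- c("index", "area", "text")
  missing_col <- setdiff(required, names(items))
  if (length(missing_col)) {
    stop_arg("instrument items lack field(s): ", paste(missing_col, collapse = ", "))
  }
  validate_instrument(list(version = doc$version, areas = doc$areas, items = items))
}

validate_instrument <- function(x) {
  items <- x$items
  if (length(x$areas) != 6L) {
    stop_arg("instrument must define exactly 6 areas, got ", length(x$areas))
  }
  if (nrow(items) != 64L) {
    stop_arg("instrument must define exactly 64 items, got ", nrow(items))
  }
  if (!identical(as.integer(items$index), 1:64)) {
    stop_arg("item indices must be exactly 1..64 in increasing order")
  }
  if (any(!items$area %in% 1:6)) {
    bad <- items$index[!items$area %in% 1:6]
    stop_arg("item(s) ", paste(bad, collapse = ", "), " assigned to an area outside 1..6")
  }
  if (is.unsorted(items$area)) {
    stop_arg("area assignment must be non-decreasing across item indices (hierarchical areas)")
  }
  if (!setequal(unique(items$area), 1:6)) {
    stop_arg("every one of the 6 areas must contain at least one item")
  }
  if (any(!nzchar(items$text))) {
    stop_arg("item text must be non-empty (item ",
             paste(items$index[!nzchar(items$text)], collapse = ", "), ")")
  }
  structure(x, class = "flip_instrument")
}

#' Build a response set for a FLI-P administration
#'
#' Each of the 64 items is rated "mostly" (the child demonstrates the skill
#' regularly, in different places, with different people) or "rarely" (only
#' occasionally, a few times, or not at all). Items with no recorded rating
#' are unanswered.
#'
#' @param mostly,rarely Integer vectors of item indices (1..64) rated
#'   "mostly" and "rarely" respectively; they must not overlap.
#' @return A named character vector of class `flip_responses`; names are item
#'   indices, values are `"mostly"` or `"rarely"`. Unanswered items are
#'   absent.
#' @examples
#' flip_responses(mostly = 1:10, rarely = 11:14)
#' @export
flip_responses <- function(mostly = integer(), rarely = integer()) {
  mostly <- as.integer(mostly)
  rarely <- as.integer(rarely)
  idx <- c(mostly, rarely)
  if (length(idx) && (any(is.na(idx)) || any(idx < 1L) || any(idx > 64L))) {
    stop_arg("item indices must lie in 1..64")
  }
  if (anyDuplicated(idx)) {
    stop_arg("item(s) ", paste(unique(idx[duplicated(idx)]), collapse = ", "),
             " rated more than once")
  }
  out <- setNames(c(rep("mostly", length(mostly)), rep("rarely", length(rarely))),
                  as.character(idx))
  out <- out[order(as.integer(names(out)))]
  structure(out, class = "flip_responses")
}

as_flip_responses <- function(responses) {
  if (inherits(responses, "flip_responses")) return(responses)
  if (is.null(names(responses)) && length(responses)) {
    stop_arg("responses must be named by item index")
  }
  idx <- suppressWarnings(as.integer(names(responses)))
  vals <- as.character(responses)
  if (length(vals) && (any(is.na(idx)) || any(!vals %in% c("mostly", "rarely")))) {
    stop_arg("responses must map item indices to \"mostly\" or \"rarely\"")
  }
  flip_responses(mostly = idx[vals == "mostly"], rarely = idx[vals == "rarely"])
}

#' Locate the ceiling item of a response set
#'
#' Scoring stops at a ceiling: the first item that begins a run of at least
#' `run_length` consecutive "rarely" responses, scanning items in ascending
#' order. Unanswered items interrupt a run.
#'
#' @param responses A [flip_responses] object (or named vector coercible to
#'   one).
#' @param run_length Number of consecutive "rarely" responses that
#'   constitutes a ceiling (default 4, mirroring the four-item basal window).
#' @return The item index starting the ceiling run, or `NA_integer_` if no
#'   such run exists.
#' @examples
#' find_ceiling(flip_responses(mostly = 1:10, rarely = 11:14))
#' @export
find_ceiling <- function(responses, run_length = 4L) {
  if (!is.numeric(run_length) || length(run_length) != 1L || is.na(run_length) ||
      run_length < 1) {
    stop_arg("`run_length` must be a positive integer")
  }
  run_length <- as.integer(run_length)
  responses <- as_flip_responses(responses)
  is_rarely <- logical(64L)
  idx <- as.integer(names(responses))
  is_rarely[idx[responses == "rarely"]] <- TRUE
  run <- 0L
  for (i in 1:64) {
    run <- if (is_rarely[i]) run + 1L else 0L
    if (run == run_length) return(i - run_length + 1L)
  }
  NA_integer_
}

#' Basal window of a response set
#'
#' The basal rule re-checks the four highest-indexed items rated "mostly".
#' It is informational only and never alters the score.
#'
#' @inheritParams find_ceiling
#' @return Integer vector (ascending) of up to four item indices; fewer if
#'   fewer "mostly" responses exist.
#' @examples
#' basal_window(flip_responses(mostly = c(1:3, 10, 12)))
#' @export
basal_window <- function(responses) {
  responses <- as_flip_responses(responses)
  idx <- sort(as.integer(names(responses))[responses == "mostly"])
  utils::tail(idx, 4L)
}

#' Score a FLI-P administration
#'
#' The overall score is the number of items rated "mostly" (0..64). The
#' ceiling and basal fields describe the administration; administration
#' irregularities (no ceiling reached, "mostly" responses above the ceiling,
#' unanswered items below the ceiling) are attached as warnings, never
#' errors.
#'
#' @param child_id Child identifier (string).
#' @param age_months Age at assessment in months (> 0, decimal months
#'   allowed).
#' @param responses A [flip_responses] object.
#' @param instrument A [load_instrument()] definition (packaged default).
#' @inheritParams find_ceiling
#' @return An object of class `flip_assessment`: list with `child_id`,
#'   `age_months`, `score`, `ceiling` (item index or `NA`), `basal`
#'   (integer vector) and `warnings` (character vector).
#' @examples
#' a <- score_assessment("c1", 18, flip_responses(mostly = 1:20, rarely = 21:26))
#' a$score
#' @export
score_assessment <- function(child_id, age_months, responses,
                             instrument = load_instrument(), run_length = 4L) {
  if (!is.character(child_id) || length(child_id) != 1L) {
    stop_arg("`child_id` must be a single string")
  }
  assert_scalar_number(age_months, "age_months")
  if (age_months <= 0) stop_arg("`age_months` must be positive")
  stopifnot(inherits(instrument, "flip_instrument"))
  responses <- as_flip_responses(responses)

  score <- sum(responses == "mostly")
  ceiling_idx <- find_ceiling(responses, run_length)
  basal <- basal_window(responses)
  warnings <- character()

  answered <- as.integer(names(responses))
  if (is.na(ceiling_idx)) {
    warnings <- c(warnings, "no ceiling reached")
    horizon <- 64L
  } else {
    horizon <- ceiling_idx - 1L
    mostly_idx <- answered[responses == "mostly"]
    if (any(mostly_idx > ceiling_idx)) {
      warnings <- c(warnings, "responses above ceiling")
    }
  }
  if (horizon >= 1L && length(setdiff(seq_len(horizon), answered))) {
    warnings <- c(warnings, "unanswered items below ceiling")
  }

  structure(
    list(child_id = child_id, age_months = age_months, score = score,
         ceiling = ceiling_idx, basal = basal, warnings = warnings),
    class = "flip_assessment"
  )
}

#' @export
print.flip_assessment <- function(x, ...) {
  cat(sprintf("FLI-P assessment: child %s, age %.1f months, score %d/64\n",
              x$child_id, x$age_months, x$score))
  cat("  ceiling: ", if (is.na(x$ceiling)) "none" else x$ceiling, "\n", sep = "")
  cat("  basal window: ",
      if (length(x$basal)) paste(x$basal, collapse = ", ") else "(none)", "\n",
      sep = "")
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Read item-level assessment responses from CSV
#'
#' Expects columns `child_id,age_months,item_index,response` with `response`
#' in `{mostly, rarely}`; items not listed for a child are unanswered.
#'
#' @param path CSV file path.
#' @return A named list of lists, one per `child_id`, each with `age_months`
#'   and a [flip_responses] vector.
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("child_id", "age_months", "item_index", "response")
  if (!all(required %in% names(df))) {
    stop_arg("response CSV must have header: ", paste(required, collapse = ","))
  }
  bad <- which(!df$response %in% c("mostly", "rarely"))
  if (length(bad)) {
    stop_arg("invalid response value at data row(s) ", paste(bad, collapse = ", "))
  }
  out <- lapply(split(df, df$child_id), function(d) {
    if (length(unique(d$age_months)) != 1L) {
      stop_arg("child ", d$child_id[1], " has inconsistent age_months")
    }
    list(age_months = d$age_months[1],
         responses = flip_responses(mostly = d$item_index[d$response == "mostly"],
                                    rarely = d$item_index[d$response == "rarely"]))
  })
  out
}
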