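#' Read and write cohort record CSV files
#'
#' Cohort files carry one assessment per row with header
#' `child_id,age_months,score` (UTF-8, comma separator, dot decimal).
#' Reading validates every row and reports offending line numbers; writing
#' then reading is an identity on valid records.
#'
#' @param path CSV file path.
#' @return `read_cohort()`: a validated data frame of cohort records.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_arg("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("child_id", "age_months", "score")
  if (!identical(names(df)[seq_along(required)], required)) {
    stop_arg("cohort CSV must start with header: ", paste(required, collapse = ","))
  }
  problems <- character()
  # data row i is file line i + 1 (header)
  chk <- function(bad, why) {
    if (any(bad)) problems <<- c(problems,
      paste0("line ", paste(which(bad) + 1L, collapse = ", "), ": ", why))
  }
  suppressWarnings({
    age <- as.numeric(df$age_months)
    score <- as.numeric(df$score)
  })
  chk(is.na(age), "non-numeric age_months")
  chk(!is.na(age) & (age <= 0 | age > 72), "age_months outside (0, 72]")
  chk(is.na(score), "non-numeric score")
  chk(!is.na(score) & (score < 0 | score > 64), "score outside [0, 64]")
  if (length(problems)) {
    stop_arg("invalid cohort file ", path, ":\n  ",
             paste(problems, collapse = "\n  "))
  }
  data.frame(child_id = as.character(df$child_id), age_months = age,
             score = score, stringsAsFactors = FALSE)
}

#' @param records Data frame of cohort records.
#' @rdname read_cohort
#' @return `write_cohort()`: `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  validate_records(records, min_n = NULL, min_span = NULL)
  utils::write.csv(records[c("child_id", "age_months", "score")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a child trajectory CSV
#'
#' Expects header `child_id,age_months,score` with an optional `event`
#' column; non-empty `event` cells become annotations. The file must contain
#' exactly one child.
#'
#' @param path CSV file path.
#' @return A [child_trajectory()] object.
#' @export
read_trajectory <- function(path) {
  df <- read_trajectory_frame(path)
  ann <- NULL
  if (!is.null(df$event)) {
    has_event <- !is.na(df$event) & nzchar(df$event)
    if (any(has_event)) {
      ann <- data.frame(age_months = df$age_months[has_event],
                        label = df$event[has_event])
    }
  }
  child_trajectory(df$child_id[1], df$age_months, df$score, annotations = ann)
}

read_trajectory_frame <- function(path) {
  if (!file.exists(path)) stop_arg("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("child_id", "age_months", "score")
  if (!all(required %in% names(df))) {
    stop_arg("trajectory CSV must have header: ", paste(required, collapse = ","))
  }
  if (!nrow(df)) stop_arg("trajectory file is empty: ", path)
  if (length(unique(df$child_id)) != 1L) {
    stop_arg("trajectory file must contain exactly one child_id")
  }
  df
}

#' Packaged demonstration trajectories
#'
#' Two synthetic illustrative trajectories are packaged, modelled on the
#' clinical patterns the norms are designed to surface: `"A"` -- a child
#' implanted early whose scores climb to the median curve and track it; and
#' `"B"` -- a child whose trajectory starts inside the 16th--84th envelope,
#' plateaus well below the median during a period of middle-ear effusion,
#' then converges back after later implantation. Both are synthetic
#' constructions for demonstration, not patient data.
#'
#' @param which `"A"` or `"B"`.
#' @return A [child_trajectory()] object.
#' @examples
#' demo_trajectory("B")
#' @export
demo_trajectory <- function(which = c("A", "B")) {
  which <- match.arg(which)
  read_trajectory(extdata_path(sprintf("trajectory_child_%s_synthetic.csv",
                                       tolower(which))))
}
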