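# A cohort is a tibble with one row per participant: `participant_id`, one
# integer column per layout item (centered Likert values with sentinels) and a
# logical `complete` flag. Optional demographic columns are carried through as
# character and never enter any computation.

#' Assemble a cohort from recoded responses
#'
#' Validates a participant-level table against a layout and computes the
#' completion flag: a record is complete iff every layout item is non-missing
#' ("Don't know" counts as an answer).
#'
#' @param data A data frame with `participant_id` and one integer column per
#'   layout item, already on the centered scale with sentinels.
#' @param layout A [survey_layout()].
#' @return A tibble of class `cohort`.
#' @export
as_cohort <- function(data, layout = default_survey_layout()) {
  data <- as_tibble(data)
  if (!"participant_id" %in% names(data)) {
    abort("Cohort requires a `participant_id` column.")
  }
  if (anyDuplicated(data$participant_id)) {
    dup <- unique(data$participant_id[duplicated(data$participant_id)])
    abort(paste0("Duplicate participant_id: ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  absent <- setdiff(layout$item, names(data))
  if (length(absent) > 0) {
    abort(paste0("Cohort is missing layout item column(s): ",
                 paste(absent, collapse = ", ")))
  }
  for (it in layout$item) {
    v <- data[[it]]
    if (!is.numeric(v)) {
      abort(glue::glue("Item column `{it}` must be numeric."))
    }
    dk <- is_dont_know(v)
    if (any(dk) && !layout$dk_allowed[layout$item == it]) {
      abort(glue::glue(
        "Item `{it}` does not offer a \"Don't know\" option but row(s) ",
        "{paste(head(which(dk), 5), collapse = ', ')} use it."))
    }
    bad <- !is.na(v) & !dk & (v < -2 | v > 2 | v != round(v))
    if (any(bad)) {
      abort(glue::glue(
        "Item `{it}`: value out of the -2..+2 range at row(s) ",
        "{paste(head(which(bad), 5), collapse = ', ')}."))
    }
    data[[it]] <- as.integer(v)
  }
  req <- layout_required_items(layout)
  data$complete <- rowSums(is.na(as.matrix(data[req]))) == 0
  attr(data, "layout") <- layout
  class(data) <- unique(c("cohort", class(data)))
  data
}

cohort_layout <- function(cohort, layout = NULL) {
  layout %||% attr(cohort, "layout") %||% default_survey_layout()
}

#' Read a cohort from a delimited text file
#'
#' Expects one row per participant and a header row naming the items. Missing
#' cells are empty strings; "Don't know" cells are the literal `DK` (on items
#' that offer it). Values may be coded `1..5` or `-2..+2` (see `coding`).
#'
#' @param path Path to a delimited text file (UTF-8).
#' @param layout A [survey_layout()].
#' @param coding Source coding of Likert cells, `"centered"` (default) or
#'   `"raw"`; see [recode_likert()].
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return A `cohort` tibble.
#' @export
read_cohort <- function(path, layout = default_survey_layout(),
                        coding = c("centered", "raw"), delim = ",") {
  coding <- arg_match(coding)
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           na = character(), progress = FALSE,
                           show_col_types = FALSE)
  absent <- setdiff(layout$item, names(raw))
  if (length(absent) > 0) {
    abort(paste0("Input file is missing item column(s): ",
                 paste(absent, collapse = ", ")))
  }
  for (it in layout$item) {
    raw[[it]] <- recode_likert(raw[[it]], coding = coding, item = it)
  }
  as_cohort(raw, layout)
}

#' Write a cohort to a delimited text file
#'
#' Inverse of [read_cohort()] with `coding = "centered"`: missing values become
#' empty cells and the "Don't know" sentinel becomes `DK`, so a write-read
#' round trip reproduces the cohort exactly.
#'
#' @param cohort A `cohort` tibble.
#' @param path Output file path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, delim = ",") {
  layout <- cohort_layout(cohort)
  out <- as_tibble(cohort)
  out$complete <- NULL
  for (it in layout$item) {
    v <- out[[it]]
    ch <- as.character(v)
    ch[is.na(v)] <- ""
    ch[is_dont_know(v)] <- "DK"
    out[[it]] <- ch
  }
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

#' Keep only participants who completed the questionnaire
#'
#' Retains records whose `complete` flag is `TRUE` (every layout item
#' answered; "Don't know" counts as an answer) and reports the retained and
#' dropped counts. Idempotent.
#'
#' @param cohort A `cohort` tibble.
#' @param quiet Suppress the retained/dropped message.
#' @return The filtered `cohort`.
#' @export
filter_complete <- function(cohort, quiet = FALSE) {
  stopifnot("complete" %in% names(cohort))
  keep <- cohort$complete
  out <- cohort[keep, , drop = FALSE]
  if (!quiet) {
    inform(glue::glue(
      "filter_complete: retained {sum(keep)} of {length(keep)} records ",
      "({sum(!keep)} incomplete dropped)."))
  }
  if (nrow(out) == 0) {
    warn("filter_complete: no complete records remain.")
  }
  out
}
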