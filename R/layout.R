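# The survey layout is a plain tibble registry mapping item identifiers to a
# (topic, construct) pair, with a flag for items that offer a "Don't know"
# option. Every layout must cover all nine constructs for both topics; the
# self-reported intention (I) and behavior (B) are single items per topic.

.topics <- c("health", "sustainability")
.topic_suffix <- c(health = "H", sustainability = "S")
.tpb_constructs <- c("A", "SN", "PBC")
.sdt_constructs <- c("RExt", "RIntro", "RId", "RInt")
.constructs <- c(.tpb_constructs, .sdt_constructs, "I", "B")

#' Construct a survey layout
#'
#' Validates and returns the item registry used to interpret a cohort table.
#'
#' @param items A data frame with columns `item` (unique identifier, matching
#'   the cohort's column names), `topic` (`"health"` or `"sustainability"`),
#'   `construct` (one of `A`, `SN`, `PBC`, `RExt`, `RIntro`, `RId`, `RInt`,
#'   `I`, `B`) and `dk_allowed` (logical; may the item be answered
#'   "Don't know").
#' @return A tibble of class `survey_layout`.
#' @seealso [default_survey_layout()]
#' @export
survey_layout <- function(items) {
  stopifnot(is.data.frame(items))
  required <- c("item", "topic", "construct", "dk_allowed")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols) > 0) {
    abort(paste0("Layout is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  items <- as_tibble(items)[required]
  if (anyDuplicated(items$item)) {
    abort("Layout item identifiers must be unique.")
  }
  bad_topic <- setdiff(unique(items$topic), .topics)
  if (length(bad_topic) > 0) {
    abort(paste0("Unknown topic(s): ", paste(bad_topic, collapse = ", ")))
  }
  bad_con <- setdiff(unique(items$construct), .constructs)
  if (length(bad_con) > 0) {
    abort(paste0("Unknown construct(s): ", paste(bad_con, collapse = ", ")))
  }
  for (tp in .topics) {
    for (con in .constructs) {
      k <- sum(items$topic == tp & items$construct == con)
      if (k == 0) {
        abort(glue::glue("Layout has no items for construct {con} ({tp})."))
      }
      if (con %in% c("I", "B") && k != 1) {
        abort(glue::glue(
          "Construct {con} ({tp}) must map to exactly one item, found {k}."))
      }
    }
  }
  class(items) <- c("survey_layout", class(items))
  items
}

#' Default survey layout
#'
#' Three items per TPB construct (attitude A, subjective norm SN, perceived
#' behavioral control PBC) and per SDT regulation (external, introjected,
#' identified, intrinsic), and one item each for self-reported intention and
#' behavior, for both topics. Behavior items offer a "Don't know" option.
#' Item identifiers follow `<construct>_<H|S>[_<k>]`, e.g. `A_H_2`, `B_S`.
#'
#' The per-construct item count is configurable because published analyses of
#' this design report only construct-level (item-mean) scores.
#'
#' @param items_per_construct Number of items per multi-item construct
#'   (default 3).
#' @return A `survey_layout` tibble.
#' @export
default_survey_layout <- function(items_per_construct = 3L) {
  stopifnot(items_per_construct >= 1)
  rows <- purrr::map_dfr(.topics, function(tp) {
    sfx <- .topic_suffix[[tp]]
    multi <- purrr::map_dfr(c(.tpb_constructs, .sdt_constructs), function(con) {
      tibble(
        item = paste0(con, "_", sfx, "_", seq_len(items_per_construct)),
        topic = tp, construct = con, dk_allowed = FALSE
      )
    })
    single <- tibble(
      item = paste0(c("I", "B"), "_", sfx),
      topic = tp, construct = c("I", "B"),
      dk_allowed = c(FALSE, TRUE)
    )
    bind_rows(multi, single)
  })
  survey_layout(rows)
}

#' Read or write a survey layout as YAML
#'
#' The on-disk format is a list of item records with `item`, `topic`,
#' `construct` and `dk_allowed` fields.
#'
#' @param path File path.
#' @return `read_survey_layout()` returns a `survey_layout`;
#'   `write_survey_layout()` returns `path` invisibly.
#' @export
read_survey_layout <- function(path) {
  raw <- yaml::read_yaml(path)
  survey_layout(purrr::map_dfr(raw$items, as_tibble))
}

#' @rdname read_survey_layout
#' @param layout A `survey_layout`.
#' @export
write_survey_layout <- function(layout, path) {
  items <- purrr::pmap(as.list(as_tibble(layout)), list)
  yaml::write_yaml(list(items = items), path)
  invisible(path)
}

# item identifiers for one (topic, construct) pair
layout_items <- function(layout, topic, construct) {
  layout$item[layout$topic == topic & layout$construct == construct]
}

# items whose absence makes a record incomplete: all TPB and SDT items for
# both topics (I and B are part of the relevant sections as well)
layout_required_items <- function(layout) {
  layout$item
}

score_name <- function(construct, topic) {
  paste0(construct, "_", .topic_suffix[topic])
}

# the 18 base score columns in canonical order
base_score_names <- function() {
  c(t(outer(.constructs, c("H", "S"), function(con, sfx) paste0(con, "_", sfx))))
}
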