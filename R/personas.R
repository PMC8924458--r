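# TPB persona segmentation: dichotomizing attitude (positive/negative),
# subjective norm (high/low) and perceived behavioral control (high/low)
# yields 8 segments, indexed:
#   1 +HH   2 +LH   3 +HL   4 +LL   5 -HH   6 -LH   7 -HL   8 -LL
# Low perceived behavioral control corresponds to personas 3, 4, 7, 8.

#' The eight-persona scheme
#'
#' @return A tibble with columns `persona` (1..8), `attitude`
#'   (`positive`/`negative`), `sn` and `pbc` (`high`/`low`).
#' @export
persona_scheme <- function() {
  tibble(
    persona = 1:8,
    attitude = rep(c("positive", "negative"), each = 4),
    sn = rep(c("high", "low", "high", "low"), 2),
    pbc = rep(c("high", "high", "low", "low"), 2)
  )
}

#' Assign TPB personas
#'
#' Vectorized segment assignment from attitude, subjective norm and perceived
#' behavioral control scores. By default a score counts as positive/high iff
#' it is strictly greater than zero, so exact-zero item-mean scores classify
#' as negative/low; set `zero_as_positive = TRUE` to flip that convention
#' (the choice can matter because exact zeros are common in Likert item
#' means). Undefined inputs yield `NA`.
#'
#' @param A,SN,PBC Numeric score vectors on `[-2, +2]`.
#' @param zero_as_positive Classify exact zeros as positive/high
#'   (default `FALSE`).
#' @return An integer vector of persona indices 1..8.
#' @examples
#' assign_persona(1, 1, 1)       # 1
#' assign_persona(2, -1, 0.5)    # 2
#' assign_persona(-0.5, -2, -1)  # 8
#' @export
assign_persona <- function(A, SN, PBC, zero_as_positive = FALSE) {
  hi <- function(x) if (zero_as_positive) x >= 0 else x > 0
  idx <- 4L * as.integer(!hi(A)) + 2L * as.integer(!hi(PBC)) +
    as.integer(!hi(SN)) + 1L
  idx[is.na(A) | is.na(SN) | is.na(PBC)] <- NA_integer_
  idx
}

#' Persona segment tables
#'
#' Tabulates the marginal persona distribution for each topic (over
#' participants with the three TPB constructs defined for that topic —
#' pairwise inclusion) and the 8x8 joint distribution over participants
#' defined on both topics.
#'
#' @param scores A score table from [construct_scores()].
#' @param zero_as_positive Passed to [assign_persona()].
#' @return A list of class `segment_tables`: `health` and `sustainability`
#'   (tibbles persona/attitude/sn/pbc/n/prop), `joint` (tibble
#'   persona_health/persona_sustainability/n/prop), `n_health`,
#'   `n_sustainability`, `n_joint`, `zero_as_positive`.
#' @export
segment_tables <- function(scores, zero_as_positive = FALSE) {
  p <- list()
  for (tp in .topics) {
    sfx <- .topic_suffix[[tp]]
    p[[tp]] <- assign_persona(scores[[paste0("A_", sfx)]],
                              scores[[paste0("SN_", sfx)]],
                              scores[[paste0("PBC_", sfx)]],
                              zero_as_positive = zero_as_positive)
  }
  marginal <- function(idx) {
    n_def <- sum(!is.na(idx))
    counts <- tabulate(idx, nbins = 8L)
    persona_scheme() %>%
      mutate(n = counts,
             prop = if (n_def > 0) counts / n_def else rep(0, 8))
  }
  both <- !is.na(p$health) & !is.na(p$sustainability)
  joint_counts <- table(
    factor(p$health[both], levels = 1:8),
    factor(p$sustainability[both], levels = 1:8)
  )
  joint <- as_tibble(expand.grid(persona_health = 1:8,
                                 persona_sustainability = 1:8)) %>%
    mutate(
      n = as.vector(joint_counts[cbind(persona_health, persona_sustainability)]),
      prop = if (sum(both) > 0) n / sum(both) else 0
    ) %>%
    arrange(persona_health, persona_sustainability)
  structure(
    list(health = marginal(p$health),
         sustainability = marginal(p$sustainability),
         joint = joint,
         n_health = sum(!is.na(p$health)),
         n_sustainability = sum(!is.na(p$sustainability)),
         n_joint = sum(both),
         zero_as_positive = zero_as_positive),
    class = "segment_tables"
  )
}

#' Proportion of participants with low perceived behavioral control
#'
#' The combined share of personas 3, 4, 7 and 8 (the low-PBC half of the
#' scheme) for one topic.
#'
#' @param segments A [segment_tables()] result.
#' @param topic `"health"` or `"sustainability"`.
#' @return A proportion in `[0, 1]`.
#' @export
low_pbc_proportion <- function(segments, topic = c("health", "sustainability")) {
  topic <- arg_match(topic)
  tab <- segments[[topic]]
  sum(tab$prop[tab$persona %in% c(3L, 4L, 7L, 8L)])
}

#' @export
print.segment_tables <- function(x, ...) {
  cat("TPB persona segments",
      if (x$zero_as_positive) "(zeros classified positive/high)" else
        "(zeros classified negative/low)", "\n")
  for (tp in c("health", "sustainability")) {
    cat("\n", tp, " (n = ", x[[paste0("n_", tp)]], "):\n", sep = "")
    print(as.data.frame(x[[tp]]), row.names = FALSE)
  }
  cat("\njoint (n = ", x$n_joint, "): 8x8 table in $joint\n", sep = "")
  invisible(x)
}

#' Plot persona segment distributions
#'
#' Side-by-side bar chart of the marginal persona proportions for both
#' topics.
#'
#' @param segments A [segment_tables()] result.
#' @return A ggplot object.
#' @export
plot_segments <- function(segments) {
  df <- bind_rows(
    mutate(segments$health, topic = "health"),
    mutate(segments$sustainability, topic = "sustainability")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$persona), y = .data$prop,
                                   fill = .data$topic)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "TPB persona", y = "proportion of participants",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
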