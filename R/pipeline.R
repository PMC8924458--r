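# End-to-end analysis: scores -> composites (fixed or calibrated weights) ->
# personas -> the 17-test battery under one Benjamini-Hochberg family.
#
# The battery has the 9 research-question rows (a-g) first, in question
# order, then the 8 auxiliary tests that complete the family: the BI
# level comparison, the five descriptive correlations, the two weight-
# calibration correlations (BI~I; circular by construction, since the
# weights maximize that very correlation — flagged in the report), and the
# Wilcoxon comparison of perceived behavioral control.

#' Analysis configuration
#'
#' @param weights `"calibrate"` (default) to tune TPB weights on the data
#'   via [calibrate_weights()], or `"fixed"` to use the supplied triples.
#' @param weights_health,weights_sustainability [tpb_weights()] used when
#'   `weights = "fixed"` (defaults: the published triples (1.4, 1.0, 0.5)
#'   and (1.6, 0.5, 0.5)).
#' @param grid_step,weight_bound Calibration grid (see [calibrate_weights()]).
#' @param q Benjamini-Hochberg false-discovery rate (default 0.05).
#' @param zero_as_positive Persona treatment of exact-zero scores
#'   (see [assign_persona()]).
#' @param wilcoxon_zero_policy Zero-difference policy for the Wilcoxon test
#'   (see [wilcoxon_signed_rank()]).
#' @param quiet Suppress progress messages.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(weights = c("calibrate", "fixed"),
                            weights_health = tpb_weights(1.4, 1.0, 0.5),
                            weights_sustainability = tpb_weights(1.6, 0.5, 0.5),
                            grid_step = 0.1, weight_bound = 2.0,
                            q = 0.05, zero_as_positive = FALSE,
                            wilcoxon_zero_policy = c("discard", "pratt"),
                            quiet = FALSE) {
  weights <- arg_match(weights)
  wilcoxon_zero_policy <- arg_match(wilcoxon_zero_policy)
  stopifnot(q > 0, q < 1)
  structure(
    list(weights = weights, weights_health = weights_health,
         weights_sustainability = weights_sustainability,
         grid_step = grid_step, weight_bound = weight_bound, q = q,
         zero_as_positive = zero_as_positive,
         wilcoxon_zero_policy = wilcoxon_zero_policy, quiet = quiet),
    class = "analysis_config"
  )
}

score_descriptives <- function(scores, cols) {
  purrr::map_dfr(cols, function(cl) {
    v <- scores[[cl]]
    tibble(score = cl, mean = mean(v, na.rm = TRUE),
           sd = sd(v, na.rm = TRUE), n = sum(!is.na(v)))
  })
}

#' Run the full intention/motivation analysis
#'
#' Computes construct scores, the Behavioral Intention composites (with
#' weights fixed or calibrated against self-reported intention), the
#' Relative Autonomy Indices, the persona segment tables, and the 17-test
#' battery — 6 paired t-tests, 10 Pearson correlations and 1 Wilcoxon
#' signed-rank test — corrected as a single Benjamini-Hochberg family.
#' Incomplete records are dropped first; within the battery every test uses
#' pairwise deletion, so e.g. "Don't know" behavior responders are excluded
#' only from behavior analyses.
#'
#' @param cohort A `cohort` tibble (see [read_cohort()], [generate_cohort()]).
#' @param config An [analysis_config()].
#' @param layout Optional layout override.
#' @return A list of class `intent_analysis` with elements `descriptives`
#'   (18 base scores), `composites` (BI/RAI descriptives), `tests` (the
#'   battery with BH columns), `segments`, `weights`, `scores`, `n_started`,
#'   `n_complete`, `config`.
#' @export
run_full_analysis <- function(cohort, config = analysis_config(),
                              layout = NULL) {
  layout <- cohort_layout(cohort, layout)
  n_started <- nrow(cohort)
  complete <- filter_complete(cohort, quiet = config$quiet)
  if (nrow(complete) == 0) {
    abort("run_full_analysis: no complete records to analyze.")
  }
  scores <- construct_scores(complete, layout)

  if (config$weights == "calibrate") {
    cal_h <- calibrate_weights(scores, "health", config$grid_step,
                               config$weight_bound)
    cal_s <- calibrate_weights(scores, "sustainability", config$grid_step,
                               config$weight_bound)
    w_h <- cal_h$weights
    w_s <- cal_s$weights
    calibration <- list(health = cal_h, sustainability = cal_s)
    if (!config$quiet) {
      inform(glue::glue(
        "Calibrated weights: health ({paste(w_h, collapse = ', ')}) ",
        "r = {round(cal_h$achieved_r, 3)}; sustainability ",
        "({paste(w_s, collapse = ', ')}) r = {round(cal_s$achieved_r, 3)}"))
    }
  } else {
    w_h <- config$weights_health
    w_s <- config$weights_sustainability
    calibration <- NULL
  }
  scores <- add_composites(scores, w_h, w_s)
  segments <- segment_tables(scores, config$zero_as_positive)

  s <- function(cl) scores[[cl]]
  q_rows <- bind_rows(
    mutate(paired_t(s("I_H"), s("I_S"), "I_H vs I_S"), question = "a"),
    mutate(paired_t(s("RAI_H"), s("RAI_S"), "RAI_H vs RAI_S"), question = "b"),
    mutate(paired_t(s("B_H"), s("B_S"), "B_H vs B_S"), question = "c"),
    mutate(paired_t(s("I_H"), s("B_H"), "I_H vs B_H"), question = "d"),
    mutate(paired_t(s("I_S"), s("B_S"), "I_S vs B_S"), question = "d"),
    mutate(pearson_cor(s("RAI_H"), s("RAI_S"), "RAI_H ~ RAI_S"), question = "e"),
    mutate(pearson_cor(s("BI_H"), s("BI_S"), "BI_H ~ BI_S"), question = "f"),
    mutate(pearson_cor(s("BI_H"), s("RAI_H"), "BI_H ~ RAI_H"), question = "g"),
    mutate(pearson_cor(s("BI_S"), s("RAI_S"), "BI_S ~ RAI_S"), question = "g")
  )
  aux_rows <- bind_rows(
    mutate(paired_t(s("BI_H"), s("BI_S"), "BI_H vs BI_S"), question = "aux"),
    mutate(pearson_cor(s("I_H"), s("I_S"), "I_H ~ I_S"), question = "aux"),
    mutate(pearson_cor(s("B_H"), s("B_S"), "B_H ~ B_S"), question = "aux"),
    mutate(pearson_cor(s("I_H"), s("B_H"), "I_H ~ B_H"), question = "aux"),
    mutate(pearson_cor(s("I_S"), s("B_S"), "I_S ~ B_S"), question = "aux"),
    mutate(pearson_cor(s("BI_H"), s("I_H"), "BI_H ~ I_H"),
           question = "aux (calibration)"),
    mutate(pearson_cor(s("BI_S"), s("I_S"), "BI_S ~ I_S"),
           question = "aux (calibration)"),
    mutate(wilcoxon_signed_rank(s("PBC_H"), s("PBC_S"),
                                config$wilcoxon_zero_policy,
                                "PBC_H vs PBC_S"),
           question = "aux")
  )
  tests <- bind_rows(q_rows, aux_rows) %>%
    mutate(r = ifelse(.data$test == "pearson", .data$statistic, NA_real_)) %>%
    select("question", "comparison", "test", "statistic", "df", "n_used",
           "p_value", "d_z", "d_pooled", "d_from_t", "r") %>%
    bh_family(q = config$q)

  structure(
    list(
      descriptives = score_descriptives(scores, base_score_names()),
      composites = score_descriptives(scores, c("BI_H", "BI_S",
                                                "RAI_H", "RAI_S")),
      tests = tests,
      segments = segments,
      weights = list(mode = config$weights, health = w_h,
                     sustainability = w_s, calibration = calibration),
      scores = scores,
      n_started = n_started,
      n_complete = nrow(complete),
      config = config
    ),
    class = "intent_analysis"
  )
}

#' @export
print.intent_analysis <- function(x, ...) {
  cat(glue::glue(
    "Intention/motivation analysis: {x$n_complete} of {x$n_started} ",
    "records complete; {nrow(x$tests)} tests in one BH family ",
    "(q = {x$config$q}); {sum(x$tests$reject)} rejected."), "\n")
  cat(glue::glue(
    "Weights ({x$weights$mode}): health ",
    "({paste(x$weights$health, collapse = ', ')}), sustainability ",
    "({paste(x$weights$sustainability, collapse = ', ')})"), "\n")
  print(as.data.frame(x$tests[, c("question", "comparison", "test",
                                  "statistic", "df", "p_value",
                                  "alpha_bh", "reject")]),
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Tidy the test battery of an analysis
#'
#' @param x An `intent_analysis` object.
#' @param ... Unused.
#' @return The battery tibble: one row per test with statistic, df, n_used,
#'   p-value, effect sizes, BH rank, threshold and rejection flag.
#' @export
tidy.intent_analysis <- function(x, ...) {
  x$tests
}

#' One-row summary of an analysis
#'
#' @inheritParams tidy.intent_analysis
#' @return A one-row tibble: sample sizes, family size, q, rejections, the
#'   weight triples and (when calibrated) the achieved correlations.
#' @export
glance.intent_analysis <- function(x, ...) {
  tibble(
    n_started = x$n_started,
    n_complete = x$n_complete,
    m_tests = nrow(x$tests),
    q = x$config$q,
    n_rejected = sum(x$tests$reject),
    weight_mode = x$weights$mode,
    w_A_health = x$weights$health[["w_A"]],
    w_SN_health = x$weights$health[["w_SN"]],
    w_PBC_health = x$weights$health[["w_PBC"]],
    w_A_sust = x$weights$sustainability[["w_A"]],
    w_SN_sust = x$weights$sustainability[["w_SN"]],
    w_PBC_sust = x$weights$sustainability[["w_PBC"]],
    r_calibration_health =
      x$weights$calibration$health$achieved_r %||% NA_real_,
    r_calibration_sust =
      x$weights$calibration$sustainability$achieved_r %||% NA_real_,
    low_pbc_health = low_pbc_proportion(x$segments, "health"),
    low_pbc_sust = low_pbc_proportion(x$segments, "sustainability")
  )
}

fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "", trimws(formatC(x, digits = digits, format = "g")))
}

#' Render an analysis report to files
#'
#' Writes the descriptive tables, the battery (the machine-readable summary
#' table with BH thresholds rounded to 3 decimals alongside the unrounded
#' values), the persona tables and a plain-text report into a directory.
#' Output bytes are a deterministic function of the report.
#'
#' @param report An `intent_analysis` object.
#' @param dir Output directory (created if needed).
#' @param delim Field delimiter for the tables.
#' @return Named character vector of the files written, invisibly.
#' @export
render_report <- function(report, dir, delim = ",") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    descriptives = file.path(dir, "descriptives.csv"),
    composites = file.path(dir, "composites.csv"),
    tests = file.path(dir, "tests.csv"),
    personas_health = file.path(dir, "personas_health.csv"),
    personas_sustainability = file.path(dir, "personas_sustainability.csv"),
    personas_joint = file.path(dir, "personas_joint.csv"),
    summary = file.path(dir, "report.txt")
  )
  tests_out <- report$tests %>%
    mutate(alpha_bh_3dp = round(.data$alpha_bh, 3))
  readr::write_delim(report$descriptives, paths["descriptives"], delim = delim)
  readr::write_delim(report$composites, paths["composites"], delim = delim)
  readr::write_delim(tests_out, paths["tests"], delim = delim)
  readr::write_delim(report$segments$health, paths["personas_health"],
                     delim = delim)
  readr::write_delim(report$segments$sustainability,
                     paths["personas_sustainability"], delim = delim)
  readr::write_delim(report$segments$joint, paths["personas_joint"],
                     delim = delim)

  seg <- report$segments
  lines <- c(
    "Intention/motivation analysis report",
    "",
    sprintf("records: %d started, %d complete",
            report$n_started, report$n_complete),
    sprintf("weights (%s): health (%s); sustainability (%s)",
            report$weights$mode,
            paste(fmt_num(report$weights$health), collapse = ", "),
            paste(fmt_num(report$weights$sustainability), collapse = ", ")),
    if (report$weights$mode == "calibrate") sprintf(
      "calibration r: health %s (n = %d); sustainability %s (n = %d)",
      fmt_num(report$weights$calibration$health$achieved_r, 4),
      report$weights$calibration$health$n_used,
      fmt_num(report$weights$calibration$sustainability$achieved_r, 4),
      report$weights$calibration$sustainability$n_used),
    "",
    sprintf("test battery: %d tests, one Benjamini-Hochberg family, q = %s",
            nrow(report$tests), fmt_num(report$config$q)),
    "note: the two BI ~ I rows test the correlation the calibrated weights",
    "maximize and are circular by construction; the 17-test family",
    "definition is reconstructed, not prescribed.",
    "",
    sprintf("persona segments (n_health = %d, n_sustainability = %d):",
            seg$n_health, seg$n_sustainability),
    sprintf("  low perceived behavioral control: health %.1f%%, sustainability %.1f%%",
            100 * low_pbc_proportion(seg, "health"),
            100 * low_pbc_proportion(seg, "sustainability")),
    "",
    "tests (statistic, df, p, alpha_BH (3 dp), reject):",
    sprintf("  %-22s %-8s %9s %5s %9s %6s %s",
            "comparison", "test", "stat", "df", "p", "a_BH",
            "reject"),
    sprintf("  %-22s %-8s %9s %5s %9s %6s %s",
            report$tests$comparison, report$tests$test,
            fmt_num(report$tests$statistic, 4),
            ifelse(is.na(report$tests$df), "", report$tests$df),
            fmt_num(report$tests$p_value, 3),
            fmt_num(round(report$tests$alpha_bh, 3), 3),
            ifelse(report$tests$reject, "yes", "no"))
  )
  writeLines(lines, paths["summary"])
  invisible(paths)
}

#' Plot descriptive score means
#'
#' Dot-and-whisker plot (mean +/- SD) of all base and composite scores.
#'
#' @param report An `intent_analysis` object.
#' @return A ggplot object.
#' @export
plot_descriptives <- function(report) {
  df <- bind_rows(report$descriptives, report$composites)
  df$score <- factor(df$score, levels = rev(df$score))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$score)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$mean - .data$sd, xmax = .data$mean + .data$sd),
      height = 0.2) +
    ggplot2::labs(x = "score (mean ± SD)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_descriptives
#' @param object An `intent_analysis` object.
#' @param ... Unused.
#' @export
autoplot.intent_analysis <- function(object, ...) {
  plot_descriptives(object)
}
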