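# Construct-level scoring. Each of the nine constructs (A, SN, PBC, the four
# SDT regulations, I, B) is the arithmetic mean of its items on the centered
# -2..+2 scale; a construct is undefined (NA) for a participant if any of its
# items is missing or answered "Don't know". The composites are
#   BI  = w_A * A + w_SN * SN + w_PBC * PBC          (weights calibrated)
#   RAI = 2 * RInt + RId - RIntro - 2 * RExt          (fixed SDT weights)

rai_weights <- c(RInt = 2, RId = 1, RIntro = -1, RExt = -2)

#' Compute per-participant construct scores
#'
#' Aggregates item responses into the 18 base scores (A, SN, PBC, RExt,
#' RIntro, RId, RInt, I, B for each topic), as item means on the -2..+2
#' scale. A construct with any missing or "Don't know" item is `NA` for that
#' participant, so "Don't know" behavior responders keep all their other
#' scores and are excluded pairwise from behavior analyses only.
#'
#' @param cohort A `cohort` tibble (see [read_cohort()], [as_cohort()]).
#' @param layout Optional layout override; defaults to the cohort's.
#' @return A tibble with `participant_id` and one numeric column per score
#'   (`A_H`, `SN_H`, ..., `B_S`).
#' @export
construct_scores <- function(cohort, layout = NULL) {
  layout <- cohort_layout(cohort, layout)
  out <- tibble(participant_id = cohort$participant_id)
  for (tp in .topics) {
    for (con in .constructs) {
      its <- layout_items(layout, tp, con)
      if (length(its) == 0) {
        abort(glue::glue("No items mapped to construct {con} ({tp})."))
      }
      m <- as.matrix(cohort[its])
      m[m == likert_dk] <- NA  # sentinel -> undefined for scoring
      vals <- rowMeans(m)      # NA if any item NA
      out[[score_name(con, tp)]] <- vals
    }
  }
  out
}

#' TPB composite weights
#'
#' A non-negative weight triple for the Behavioral Intention composite.
#' Weights form a scale class: any positive multiple yields the same Pearson
#' correlation with an external variable, so only the direction is identified.
#'
#' @param w_A,w_SN,w_PBC Non-negative weights for attitude, subjective norm
#'   and perceived behavioral control; not all zero.
#' @return A named numeric vector of class `tpb_weights`.
#' @export
tpb_weights <- function(w_A, w_SN, w_PBC) {
  w <- c(w_A = unname(w_A), w_SN = unname(w_SN), w_PBC = unname(w_PBC))
  if (any(!is.finite(w)) || any(w < 0)) {
    abort("TPB weights must be finite and non-negative.")
  }
  if (sum(w) == 0) {
    abort("TPB weights must not all be zero.")
  }
  structure(w, class = "tpb_weights")
}

#' Behavioral Intention composite
#'
#' Adds the weighted TPB composite `BI = w_A * A + w_SN * SN + w_PBC * PBC`
#' for one topic to a score table. `|BI|` is bounded by `2 * sum(weights)`
#' because every construct lies in `[-2, +2]`. Participants with any
#' undefined input construct get an undefined (NA) composite.
#'
#' @param scores A score table from [construct_scores()].
#' @param weights A [tpb_weights()] triple.
#' @param topic `"health"` or `"sustainability"`.
#' @return `scores` with a `BI_H` or `BI_S` column added.
#' @export
behavioral_intention <- function(scores, weights,
                                 topic = c("health", "sustainability")) {
  topic <- arg_match(topic)
  sfx <- .topic_suffix[[topic]]
  cols <- paste0(c("A", "SN", "PBC"), "_", sfx)
  stopifnot(all(cols %in% names(scores)))
  scores[[paste0("BI_", sfx)]] <-
    weights[["w_A"]] * scores[[cols[1]]] +
    weights[["w_SN"]] * scores[[cols[2]]] +
    weights[["w_PBC"]] * scores[[cols[3]]]
  scores
}

#' Relative Autonomy Index
#'
#' Adds the fixed-weight SDT composite
#' `RAI = 2 * RInt + RId - RIntro - 2 * RExt` for one topic. With each
#' regulation on `[-2, +2]` the RAI lies in `[-12, +12]`; higher values mean
#' more autonomous (intrinsic) motivation. Undefined regulations propagate to
#' an undefined RAI.
#'
#' @inheritParams behavioral_intention
#' @return `scores` with a `RAI_H` or `RAI_S` column added.
#' @export
relative_autonomy_index <- function(scores,
                                    topic = c("health", "sustainability")) {
  topic <- arg_match(topic)
  sfx <- .topic_suffix[[topic]]
  cols <- paste0(names(rai_weights), "_", sfx)
  stopifnot(all(cols %in% names(scores)))
  val <- 0
  for (i in seq_along(rai_weights)) {
    val <- val + rai_weights[[i]] * scores[[cols[i]]]
  }
  scores[[paste0("RAI_", sfx)]] <- val
  scores
}

#' Add both composites for both topics
#'
#' Convenience wrapper applying [behavioral_intention()] (per-topic weights)
#' and [relative_autonomy_index()] to a score table.
#'
#' @param scores A score table from [construct_scores()].
#' @param weights_health,weights_sustainability [tpb_weights()] per topic.
#' @return `scores` with `BI_H`, `BI_S`, `RAI_H`, `RAI_S` columns.
#' @export
add_composites <- function(scores, weights_health, weights_sustainability) {
  scores %>%
    behavioral_intention(weights_health, "health") %>%
    behavioral_intention(weights_sustainability, "sustainability") %>%
    relative_autonomy_index("health") %>%
    relative_autonomy_index("sustainability")
}

#' Calibrate TPB weights against self-reported intention
#'
#' Exhaustive grid search for the non-negative weight triple maximizing the
#' Pearson correlation between the Behavioral Intention composite `BI(w)` and
#' the self-reported intention `I` for a topic, over
#' `w in {0, grid_step, ..., weight_bound}^3` excluding the origin.
#' Participants with any undefined input are excluded pairwise. Since the
#' correlation is invariant under positive scaling of `w`, only the weight
#' direction is identified; ties (within `1e-12` of the maximum) are broken by
#' the smallest weight sum, then lexicographically on `(w_A, w_SN, w_PBC)`.
#'
#' @param scores A score table from [construct_scores()].
#' @param topic `"health"` or `"sustainability"`.
#' @param grid_step Grid spacing (default 0.1, one-decimal weights).
#' @param weight_bound Upper bound of the grid (default 2.0).
#' @return A list of class `tpb_calibration`: `weights` ([tpb_weights()]),
#'   `achieved_r`, `n_used`, `topic`, `grid_step`, `weight_bound`.
#' @export
calibrate_weights <- function(scores, topic = c("health", "sustainability"),
                              grid_step = 0.1, weight_bound = 2.0) {
  topic <- arg_match(topic)
  stopifnot(grid_step > 0, weight_bound >= grid_step)
  sfx <- .topic_suffix[[topic]]
  cols <- paste0(c("A", "SN", "PBC", "I"), "_", sfx)
  stopifnot(all(cols %in% names(scores)))
  x <- as.matrix(scores[cols[1:3]])
  i_score <- scores[[cols[4]]]
  ok <- stats::complete.cases(x) & !is.na(i_score)
  x <- x[ok, , drop = FALSE]
  i_score <- i_score[ok]
  if (nrow(x) < 3) {
    abort("calibrate_weights: need at least 3 participants with defined A, SN, PBC and I.")
  }
  if (sd(i_score) == 0) {
    abort("calibrate_weights: self-reported intention is constant; the correlation is undefined.")
  }

  ticks <- seq(0, weight_bound, by = grid_step)
  grid <- as.matrix(expand.grid(w_PBC = ticks, w_SN = ticks, w_A = ticks))
  grid <- grid[, c("w_A", "w_SN", "w_PBC")]
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]

  # correlation of every candidate composite with I, in one matrix product
  bi <- x %*% t(grid)                       # n x n_grid
  bic <- sweep(bi, 2, colMeans(bi))
  ic <- i_score - mean(i_score)
  denom <- sqrt(colSums(bic^2)) * sqrt(sum(ic^2))
  r <- as.vector(crossprod(bic, ic)) / denom
  r[denom == 0] <- NA  # constant composite (can occur if A=SN=PBC constant)
  if (all(is.na(r))) {
    abort("calibrate_weights: every candidate composite is constant.")
  }

  best <- max(r, na.rm = TRUE)
  cand <- which(!is.na(r) & r >= best - 1e-12)
  o <- order(rowSums(grid[cand, , drop = FALSE]),
             grid[cand, 1], grid[cand, 2], grid[cand, 3])
  pick <- cand[o[1]]
  w <- tpb_weights(grid[pick, 1], grid[pick, 2], grid[pick, 3])
  structure(
    list(weights = w, achieved_r = r[pick], n_used = nrow(x), topic = topic,
         grid_step = grid_step, weight_bound = weight_bound),
    class = "tpb_calibration"
  )
}

#' @export
print.tpb_calibration <- function(x, ...) {
  cat(glue::glue(
    "TPB weight calibration ({x$topic}): w_A = {x$weights[['w_A']]}, ",
    "w_SN = {x$weights[['w_SN']]}, w_PBC = {x$weights[['w_PBC']]}; ",
    "r = {round(x$achieved_r, 3)} on n = {x$n_used} ",
    "(grid step {x$grid_step}, bound {x$weight_bound})"), "\n")
  invisible(x)
}

#' @export
tidy.tpb_calibration <- function(x, ...) {
  tibble(
    topic = x$topic,
    w_A = x$weights[["w_A"]], w_SN = x$weights[["w_SN"]],
    w_PBC = x$weights[["w_PBC"]],
    achieved_r = x$achieved_r, n_used = x$n_used
  )
}
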