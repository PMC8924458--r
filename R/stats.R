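# The statistical battery: paired t-tests with three Cohen's d variants,
# Pearson correlations, the Wilcoxon signed-rank test, and the
# Benjamini-Hochberg step-up family. Every test result is a one-row tibble so
# a battery is just bind_rows() + bh_family().
#
# All tests use pairwise deletion: a participant is dropped only from the
# analyses whose variables are undefined for them. p-values are two-sided.

drop_incomplete_pairs <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  list(x = x[ok], y = y[ok], n = sum(ok))
}

#' Paired t-test with effect sizes
#'
#' Two-sided paired t-test on pairwise-complete observations, reporting three
#' paired effect-size variants, which can differ substantially and are
#' therefore all labeled explicitly:
#' \describe{
#'   \item{d_z}{`mean(d) / sd(d)` on the paired differences `d = x - y`.}
#'   \item{d_pooled}{`(mean(x) - mean(y)) / sqrt((sd(x)^2 + sd(y)^2) / 2)`.}
#'   \item{d_from_t}{`t / sqrt(n)`.}
#' }
#'
#' @param x,y Paired numeric vectors; `NA` pairs are dropped.
#' @param comparison Optional label stored in the result.
#' @return A one-row tibble: `comparison`, `test` (`"paired_t"`),
#'   `statistic` (t), `df` (`n_used - 1`), `n_used`, `p_value`, `d_z`,
#'   `d_pooled`, `d_from_t`.
#' @export
paired_t <- function(x, y, comparison = NULL) {
  p <- drop_incomplete_pairs(x, y)
  if (p$n < 2) {
    abort("paired_t: fewer than 2 complete pairs.")
  }
  d <- p$x - p$y
  if (sd(d) == 0) {
    abort("paired_t: differences have zero variance; t is undefined.")
  }
  ht <- t.test(p$x, p$y, paired = TRUE)
  tval <- unname(ht$statistic)
  tibble(
    comparison = comparison %||% NA_character_,
    test = "paired_t",
    statistic = tval,
    df = unname(ht$parameter),
    n_used = p$n,
    p_value = ht$p.value,
    d_z = mean(d) / sd(d),
    d_pooled = (mean(p$x) - mean(p$y)) / sqrt((sd(p$x)^2 + sd(p$y)^2) / 2),
    d_from_t = tval / sqrt(p$n)
  )
}

#' Pearson correlation test
#'
#' Two-sided Pearson correlation on pairwise-complete observations, with
#' `df = n_used - 2` and the p-value from `t = r * sqrt(df) / sqrt(1 - r^2)`.
#'
#' @inheritParams paired_t
#' @return A one-row tibble: `comparison`, `test` (`"pearson"`,)
#'   `statistic` (r), `df`, `n_used`, `p_value`.
#' @export
pearson_cor <- function(x, y, comparison = NULL) {
  p <- drop_incomplete_pairs(x, y)
  if (p$n < 3) {
    abort("pearson_cor: fewer than 3 complete pairs.")
  }
  if (sd(p$x) == 0 || sd(p$y) == 0) {
    abort("pearson_cor: a constant vector has no defined correlation.")
  }
  ht <- cor.test(p$x, p$y, method = "pearson")
  tibble(
    comparison = comparison %||% NA_character_,
    test = "pearson",
    statistic = unname(ht$estimate),
    df = as.numeric(ht$parameter),
    n_used = p$n,
    p_value = ht$p.value
  )
}

# exact null distribution of the signed-rank statistic W = sum of "positive"
# ranks over uniform sign assignments, by generating-function convolution
# over the (doubled, so integral even with midranks) ranks
signed_rank_exact_p <- function(w, ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  dist <- numeric(total + 1)  # index k+1 = P(2W = k) * 2^n
  dist[1] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), dist[seq_len(total + 1 - r)])
    dist <- dist + shifted
  }
  dist <- dist / sum(dist)
  w2 <- round(2 * w)
  mu2 <- total / 2
  # two-sided: probability of a statistic at least as far from the mean
  dev <- abs(w2 - mu2)
  support <- seq(0, total)
  min(1, sum(dist[abs(support - mu2) >= dev - 1e-9]))
}

#' Wilcoxon signed-rank test for paired scores
#'
#' The signed-rank statistic `W` is the sum of ranks (average ranks on ties)
#' of the positive differences `x - y`. Zero differences are handled per
#' `zero_policy`: `"discard"` (drop zeros, then rank; the classical
#' treatment) or `"pratt"` (rank with zeros included, then drop the zero
#' ranks from both the statistic and its null moments). The p-value is
#' two-sided: exact by enumeration of all sign assignments when the number of
#' nonzero differences is at most 12, otherwise a normal approximation with
#' tie correction (no continuity correction).
#'
#' @inheritParams paired_t
#' @param zero_policy `"discard"` (default) or `"pratt"`.
#' @return A one-row tibble: `comparison`, `test` (`"wilcoxon"`),
#'   `statistic` (W), `df` (`NA`), `n_used` (nonzero pairs used), `p_value`.
#' @export
wilcoxon_signed_rank <- function(x, y, zero_policy = c("discard", "pratt"),
                                 comparison = NULL) {
  zero_policy <- arg_match(zero_policy)
  p <- drop_incomplete_pairs(x, y)
  d <- p$x - p$y
  if (all(d == 0)) {
    abort("wilcoxon_signed_rank: all differences are zero.")
  }
  if (zero_policy == "discard") {
    d <- d[d != 0]
    r <- rank(abs(d))
    w <- sum(r[d > 0])
    used_ranks <- r
    mu <- sum(r) / 2
    sigma2 <- sum(r^2) / 4
  } else {
    r_all <- rank(abs(d))          # zeros included in the ranking
    nz <- d != 0
    w <- sum(r_all[d > 0])
    used_ranks <- r_all[nz]
    mu <- sum(used_ranks) / 2
    sigma2 <- sum(used_ranks^2) / 4
  }
  n_nz <- length(used_ranks)
  p_value <- if (n_nz <= 12) {
    signed_rank_exact_p(w, used_ranks)
  } else {
    z <- (w - mu) / sqrt(sigma2)
    2 * pnorm(-abs(z))
  }
  tibble(
    comparison = comparison %||% NA_character_,
    test = "wilcoxon",
    statistic = w,
    df = NA_real_,
    n_used = n_nz,
    p_value = p_value
  )
}

#' Benjamini-Hochberg step-up family
#'
#' Orders a family of test results by p-value (ties broken by input order),
#' assigns each rank `i` the critical threshold `alpha_bh = i * q / m`
#' (`m` = family size), and flags as rejected every test with rank at most
#' `max{ i : p_(i) <= i * q / m }` — the step-up rule, which can reject a test
#' whose own p-value exceeds its threshold. Rejection uses the unrounded
#' thresholds; `alpha_bh` is reported unrounded (round to 3 decimals for
#' display).
#'
#' @param results A data frame of test results with a `p_value` column, e.g.
#'   rows from [paired_t()], [pearson_cor()], [wilcoxon_signed_rank()].
#' @param q Family-wise false-discovery rate (default 0.05).
#' @return `results` with columns `rank`, `alpha_bh` and `reject` added,
#'   in the original row order.
#' @examples
#' bh_family(tibble::tibble(p_value = c(0.001, 0.04, 0.3)))
#' @export
bh_family <- function(results, q = 0.05) {
  stopifnot(is.data.frame(results), "p_value" %in% names(results),
            q > 0, q < 1)
  m <- nrow(results)
  if (m == 0) {
    abort("bh_family: empty family.")
  }
  p <- results$p_value
  if (any(is.na(p) | p < 0 | p > 1)) {
    abort("bh_family: p-values must be defined and in [0, 1].")
  }
  ord <- order(p, seq_len(m))
  rank_of <- integer(m)
  rank_of[ord] <- seq_len(m)
  alpha <- rank_of * q / m
  sorted_ok <- p[ord] <= seq_len(m) * q / m
  k <- if (any(sorted_ok)) max(which(sorted_ok)) else 0L
  reject <- rank_of <= k
  results$rank <- rank_of
  results$alpha_bh <- alpha
  results$reject <- reject
  results
}
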