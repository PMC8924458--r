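# Independent oracles and small in-code fixtures.

# textbook closed-form paired t on differences
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  t_val <- mean(d) / (sd(d) / sqrt(n))
  list(t = t_val, df = n - 1, p = 2 * pt(-abs(t_val), n - 1))
}

# brute-force signed-rank: full enumeration of all 2^n sign assignments of
# the (discard-policy) ranks; two-sided p as the probability of a statistic
# at least as far from the null mean
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  n <- length(r)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mu <- sum(r) / 2
  list(W = w_obs,
       p = min(1, mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)))
}

# A hand-buildable cohort with one item per construct, so construct scores
# equal the item values exactly. `values` is a named list of integer vectors
# (length n) keyed by score name (I_H, A_H, ...); unspecified scores are 0.
mini_layout <- function() default_survey_layout(items_per_construct = 1L)

mini_cohort <- function(n, values = list()) {
  layout <- mini_layout()
  df <- tibble::tibble(participant_id = sprintf("M%02d", seq_len(n)))
  for (it in layout$item) {
    key <- sub("_1$", "", it)
    df[[it]] <- if (key %in% names(values)) {
      as.integer(values[[key]])
    } else {
      rep(0L, n)
    }
  }
  as_cohort(df, layout)
}

# small pre-calibrated default config shared across tests (calibration is
# deterministic given the seed, so computing it once keeps the suite fast)
shared_default_config <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- calibrate_generator(default_calibration(), seed = 424242)
    }
    cache
  }
})
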