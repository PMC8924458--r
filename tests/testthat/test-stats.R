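test_that("paired t reproduces closed-form arithmetic and effect sizes", {
  # frozen example: differences (1, 0, 1, 2) -> t = 2.449..., df = 3
  x <- c(2, 1, 1, 2); y <- c(1, 1, 0, 0)
  res <- paired_t(x, y)
  expect_equal(res$statistic, 1 / (sqrt(2 / 3) / 2), tolerance = 1e-12)
  expect_equal(round(res$statistic, 3), 2.449)
  expect_identical(res$df, 3)
  expect_identical(res$n_used, 4L)

  # zero-variance differences are an error, not a silent zero
  expect_error(paired_t(c(1, 2, 3), c(1, 2, 3)), "zero variance")

  # d_from_t worked example: t = 0.39 on n = 144 gives d = 0.03 (2 dp)
  expect_equal(round(0.39 / sqrt(144), 2), 0.03)
})

test_that("paired t matches the textbook oracle on random small instances", {
  withr::with_seed(101, {
    for (i in 1:500) {
      n <- sample(3:12, 1)
      x <- round(runif(n, -2, 2), 1)
      y <- round(runif(n, -2, 2), 1)
      if (sd(x - y) == 0) next
      got <- paired_t(x, y)
      want <- oracle_paired_t(x, y)
      expect_equal(got$statistic, want$t, tolerance = 1e-12)
      expect_equal(got$p_value, want$p, tolerance = 1e-12)
      expect_equal(got$d_z, mean(x - y) / sd(x - y), tolerance = 1e-12)
      expect_equal(got$d_from_t, want$t / sqrt(n), tolerance = 1e-12)
    }
  })
})

test_that("pearson test: perfect linearity, df bookkeeping, p identity", {
  x <- c(-1, 0, 0.5, 1, 2)
  res <- pearson_cor(x, 2 * x + 1)
  expect_equal(res$statistic, 1)
  expect_identical(res$df, 3)

  withr::with_seed(55, {
    n <- 144
    a <- rnorm(n); b <- 0.4 * a + rnorm(n)
    res2 <- pearson_cor(a, b)
    expect_identical(res2$df, 142)
    # p(r, n) equals the p of t = r sqrt(n-2)/sqrt(1-r^2) on df = n-2
    r <- res2$statistic
    t_eq <- r * sqrt(n - 2) / sqrt(1 - r^2)
    expect_equal(res2$p_value, 2 * pt(-abs(t_eq), n - 2), tolerance = 1e-12)
    expect_error(pearson_cor(rep(1, 10), rnorm(10)), "constant")
  })
})

test_that("independent data give small r and roughly uniform p", {
  withr::with_seed(77, {
    p_vals <- r_vals <- numeric(400)
    for (i in 1:400) {
      x <- rnorm(30)
      res <- pearson_cor(x, sample(x))
      p_vals[i] <- res$p_value
      r_vals[i] <- res$statistic
    }
    expect_lt(abs(mean(r_vals)), 0.05)
    expect_gt(mean(p_vals), 0.42)  # uniform p has mean 0.5
    expect_lt(mean(p_vals), 0.58)
  })
})

test_that("signed-rank statistic handles signs, ties and zero policies", {
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3), c(0, 0, 0))$statistic, 6)
  expect_equal(wilcoxon_signed_rank(c(-1, -2, -3), c(0, 0, 0))$statistic, 0)
  # ties: |d| = (1, 1, 2, 2, 3) -> average ranks; positives rank-sum 10
  d <- c(1, -1, 2, -2, 3)
  res <- wilcoxon_signed_rank(d, rep(0, 5))
  expect_equal(res$statistic, 1.5 + 3.5 + 5)
  want <- oracle_signed_rank(d)
  expect_equal(res$p_value, want$p, tolerance = 1e-12)
  expect_error(wilcoxon_signed_rank(c(1, 1), c(1, 1)), "all differences")

  # pratt keeps zeros in the ranking, discard drops them first
  x <- c(0, 1, 2, -1, 3); y <- rep(0, 5)
  discard <- wilcoxon_signed_rank(x, y, "discard")
  pratt <- wilcoxon_signed_rank(x, y, "pratt")
  expect_equal(discard$statistic, sum(rank(abs(x[x != 0]))[x[x != 0] > 0]))
  expect_gt(pratt$statistic, discard$statistic)  # zero inflates later ranks
})

test_that("exact signed-rank p matches brute-force enumeration (500 draws)", {
  withr::with_seed(303, {
    for (i in 1:500) {
      n <- sample(3:12, 1)
      d <- sample(c(-3:-1, 1:3), n, replace = TRUE)
      got <- wilcoxon_signed_rank(d, rep(0, n))
      want <- oracle_signed_rank(d)
      expect_equal(got$statistic, want$W)
      expect_equal(got$p_value, want$p, tolerance = 1e-12)
    }
  })
})

test_that("signed-rank agrees with the base implementation where comparable", {
  withr::with_seed(404, {
    for (i in 1:50) {
      n <- 10
      d <- round(runif(n, -5, 5), 3)  # continuous: no ties, no zeros
      got <- wilcoxon_signed_rank(d, rep(0, n))
      ref <- suppressWarnings(wilcox.test(d, exact = TRUE, correct = FALSE))
      expect_equal(got$statistic, unname(ref$statistic))
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
    }
    # large-n normal approximation path
    d <- round(runif(60, -5, 5), 3)
    got <- wilcoxon_signed_rank(d, rep(0, 60))
    ref <- suppressWarnings(wilcox.test(d, exact = FALSE, correct = FALSE))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  })
})

test_that("BH family: thresholds, step-up set and p.adjust equivalence", {
  fam1 <- bh_family(tibble::tibble(p_value = 0.03), q = 0.05)
  expect_equal(fam1$alpha_bh, 0.05)
  expect_true(fam1$reject)

  # the step-up rule can reject a test above its own threshold
  fam <- bh_family(tibble::tibble(p_value = c(0.01, 0.028, 0.05)), q = 0.05)
  expect_identical(fam$reject, c(TRUE, TRUE, TRUE))  # p_(3) = 0.05 <= 3q/3

  withr::with_seed(606, {
    for (i in 1:200) {
      m <- sample(1:25, 1)
      p <- round(runif(m), 3)
      fam <- bh_family(tibble::tibble(p_value = p), q = 0.05)
      expect_identical(fam$reject, p.adjust(p, "BH") <= 0.05)
      expect_equal(sort(fam$alpha_bh), seq_len(m) * 0.05 / m)
    }
  })
  expect_error(bh_family(tibble::tibble(p_value = numeric())), "empty")
  expect_error(bh_family(tibble::tibble(p_value = c(0.1, NA))), "\\[0, 1\\]")
})
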