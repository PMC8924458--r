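test_that("the default calibration encodes the published cohort structure", {
  cfg <- default_calibration()
  expect_identical(cfg$n_participants, 144L)
  expect_identical(cfg$n_starters, 176L)
  expect_equal(cfg$target_means[["I_H"]], 1.38)
  expect_equal(cfg$target_sds[["I_H"]], 0.69)
  expect_equal(cfg$target_means[["B_S"]], -0.37)
  expect_identical(cfg$dk_count_behavior, 6L)
  tc <- cfg$target_correlations
  expect_identical(nrow(tc), 10L)
  expect_equal(tc$r[tc$var1 == "I_H" & tc$var2 == "B_H"], 0.64)
  expect_equal(tc$r[tc$var1 == "BI_H" & tc$var2 == "I_H"], 0.41)
  # composite moments induced by the construct defaults and the equations
  expect_equal(1.4 * 1.2 + 1.0 * 0.7 + 0.5 * (-0.1), 2.33)
  expect_equal(2 * 0.9 + 1.1 - 0.18 - 2 * 0.3, 2.12)
})

test_that("config validation rejects impossible targets", {
  m <- c(x = 0, y = 0); s <- c(x = 1, y = 1)
  expect_error(generator_config(target_means = m,
                                target_sds = c(x = 1, y = 0)), "SD")
  expect_error(generator_config(target_means = c(x = 3, y = 0),
                                target_sds = s), "attainable")
  expect_error(generator_config(
    target_means = m, target_sds = s,
    target_correlations = tibble::tibble(var1 = "x", var2 = "y", r = 1.2)),
    "\\[-1, \\+1\\]")
  expect_error(generator_config(
    target_means = m, target_sds = s,
    target_correlations = tibble::tibble(var1 = "BI_H", var2 = "y", r = 0.5)),
    "requires")
})

test_that("correlation completion preserves feasible entries, rejects cycles", {
  # fully specified identity stays the identity
  id3 <- complete_correlation_matrix(
    tibble::tibble(var1 = c("a", "a", "b"), var2 = c("b", "c", "c"), r = 0),
    vars = c("a", "b", "c"))
  expect_equal(id3, diag(3), ignore_attr = TRUE)

  # a single specified entry survives projection and the result is PD
  m <- complete_correlation_matrix(
    tibble::tibble(var1 = "x", var2 = "y", r = 0.5),
    vars = c("x", "y", "z"))
  expect_equal(m["x", "y"], 0.5, tolerance = 1e-6)
  expect_true(min(eigen(m, symmetric = TRUE)$values) > 0)

  # independent cross-check: Higham's nearest-correlation projection agrees
  # on a mildly infeasible specification
  part <- tibble::tibble(var1 = c("x", "y", "x"), var2 = c("y", "z", "z"),
                         r = c(0.9, 0.9, 0.63))
  ours <- complete_correlation_matrix(part)
  raw <- matrix(c(1, .9, .63, .9, 1, .9, .63, .9, 1), 3)
  ref <- as.matrix(Matrix::nearPD(raw, corr = TRUE)$mat)
  expect_true(max(abs(ours - ref)) < 0.02)

  # contradictory triangle: the raw matrix has a negative eigenvalue and the
  # specified entries cannot survive the projection
  raw <- matrix(c(1, .99, -.99, .99, 1, .99, -.99, .99, 1), 3)
  expect_lt(min(eigen(raw, symmetric = TRUE)$values), 0)
  expect_error(complete_correlation_matrix(
    tibble::tibble(var1 = c("x", "y", "x"), var2 = c("y", "z", "z"),
                   r = c(0.99, 0.99, -0.99))),
    "moved by")
})

test_that("latent score generation hits targets and is seed-reproducible", {
  cfg <- generator_config(
    n_participants = 100000L, n_starters = 100000L,
    target_means = c(u = 0, v = 0), target_sds = c(u = 0.5, v = 0.5),
    target_correlations = tibble::tibble(var1 = "u", var2 = "v", r = 0.3))
  sc <- generate_scores(cfg, seed = 9)
  expect_lt(abs(mean(sc$u)), 0.01)          # CLT bound at n = 1e5
  expect_equal(generate_scores(cfg, seed = 9), sc)
  expect_false(isTRUE(all.equal(generate_scores(cfg, seed = 10), sc)))

  # truncation near the boundary attenuates the SD
  cfg2 <- generator_config(n_participants = 50000L, n_starters = 50000L,
                           target_means = c(u = 1.8), target_sds = c(u = 1))
  sc2 <- generate_scores(cfg2, seed = 9)
  expect_lt(sd(sc2$u), 0.85)
  expect_lte(max(sc2$u), 2)
})

test_that("raising a target correlation raises the realized correlation", {
  realized <- sapply(c(0.2, 0.6), function(r_target) {
    cfg <- generator_config(
      n_participants = 20000L, n_starters = 20000L,
      target_means = c(a = 0, b = 0, c = 0),
      target_sds = c(a = 1, b = 1, c = 1),
      target_correlations = tibble::tibble(
        var1 = c("a", "b"), var2 = c("b", "c"), r = c(r_target, 0.3)))
    sc <- generate_scores(cfg, seed = 12)
    cor(sc$a, sc$b)
  })
  expect_gt(realized[2], realized[1])
})

test_that("generated cohorts honor the layout, DK plan and starter records", {
  cfg <- shared_default_config()
  cohort <- generate_cohort(cfg, seed = 3)
  expect_identical(generate_cohort(cfg, seed = 3), cohort)  # determinism
  expect_identical(nrow(cohort), 176L)
  expect_identical(sum(cohort$complete), 144L)
  expect_identical(sum(is_dont_know(cohort$B_S)), 6L)
  # DK responders are completers: DK counts as an answer
  expect_true(all(cohort$complete[is_dont_know(cohort$B_S)]))
  # starters answered the first self-report section only
  starters <- !cohort$complete
  expect_true(all(!is.na(cohort$I_H[starters])))
  expect_true(all(is.na(cohort$A_H_1[starters])))

  # all items integer-coded on the centered scale
  vals <- unlist(cohort[attr(cohort, "layout")$item])
  vals <- vals[!is.na(vals) & vals != likert_dk]
  expect_true(all(vals %in% -2:2))
})

test_that("zero item noise makes a construct's items identical", {
  cfg <- default_calibration()
  cfg$item_noise_sd <- 0
  cfg$n_cal <- 5000L; cfg$calibration_iterations <- 1L
  cfg <- calibrate_generator(cfg, seed = 5)
  cohort <- generate_cohort(cfg, seed = 5)
  expect_identical(cohort$A_H_1, cohort$A_H_2)
  expect_identical(cohort$A_H_2, cohort$A_H_3)
})

test_that("observed score moments track the targets over replicates", {
  cfg <- shared_default_config()
  reps <- 30
  keys <- c("I_H", "B_H", "I_S", "B_S", "A_H", "PBC_S")
  means <- matrix(NA_real_, reps, length(keys),
                  dimnames = list(NULL, keys))
  for (i in seq_len(reps)) {
    sc <- construct_scores(filter_complete(generate_cohort(cfg, seed = 1000 + i),
                                           quiet = TRUE))
    means[i, ] <- sapply(keys, function(k) mean(sc[[k]], na.rm = TRUE))
  }
  avg <- colMeans(means)
  expect_true(all(abs(avg - cfg$target_means[keys]) < 0.1))
})
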