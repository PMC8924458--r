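test_that("construct scores are item means with strict sentinel propagation", {
  layout <- default_survey_layout(items_per_construct = 3L)
  df <- tibble::tibble(participant_id = c("a", "b"))
  for (it in layout$item) df[[it]] <- c(0L, 1L)
  df$A_H_1 <- c(2L, 1L); df$A_H_2 <- c(1L, 1L); df$A_H_3 <- c(0L, 1L)
  df$SN_H_1 <- c(-2L, NA)  # missing item -> undefined construct for b
  df$B_S <- c(likert_dk, 1L)
  co <- as_cohort(df, layout)
  sc <- construct_scores(co)
  expect_equal(sc$A_H, c(1, 1))
  expect_true(is.na(sc$SN_H[2]))
  expect_true(is.na(sc$B_S[1]))   # "Don't know" undefines B only
  expect_equal(sc$B_H, c(0, 1))   # everything else stays defined
})

test_that("single-item constructs pass values through unchanged", {
  co <- mini_cohort(3, list(A_H = c(-2L, 0L, 2L)))
  sc <- construct_scores(co)
  expect_equal(sc$A_H, c(-2, 0, 2))
})

test_that("behavioral intention is the stated weighted sum with its bound", {
  sc <- tibble::tibble(
    participant_id = c("p", "q", "r"),
    A_H = c(0, 2, 2), SN_H = c(0, 2, -2), PBC_H = c(0, 2, -2)
  )
  w <- tpb_weights(1.4, 1.0, 0.5)
  out <- behavioral_intention(sc, w, "health")
  expect_equal(out$BI_H, c(0, 5.8, 2.8 - 2 - 1))
  # published-weight bound: |BI| <= 2 * sum(w) = 5.8 <= 6
  expect_lte(max(abs(out$BI_H)), 2 * sum(w))

  sc2 <- tibble::tibble(A_S = 2, SN_S = -2, PBC_S = -2)
  out2 <- behavioral_intention(sc2, tpb_weights(1.6, 0.5, 0.5),
                               "sustainability")
  expect_equal(out2$BI_S, 1.2)
})

test_that("the relative autonomy index uses the fixed 2/1/-1/-2 weights", {
  sc <- tibble::tibble(
    RExt_H = c(0, -2, 1), RIntro_H = c(0, -2, 1),
    RId_H = c(0, 2, 1), RInt_H = c(0, 2, 1)
  )
  out <- relative_autonomy_index(sc, "health")
  expect_equal(out$RAI_H, c(0, 12, 0))
})

test_that("BI and RAI are linear and respect their ranges on random scores", {
  withr::with_seed(99, {
    for (rep in 1:20) {
      v <- function() runif(10, -2, 2)
      sc <- tibble::tibble(
        A_H = v(), SN_H = v(), PBC_H = v(),
        RExt_H = v(), RIntro_H = v(), RId_H = v(), RInt_H = v()
      )
      w <- tpb_weights(runif(1, 0, 2), runif(1, 0, 2), runif(1, 0.1, 2))
      bi <- behavioral_intention(sc, w, "health")$BI_H
      rai <- relative_autonomy_index(sc, "health")$RAI_H
      expect_true(all(abs(rai) <= 12))
      expect_true(all(abs(bi) <= 2 * sum(w) + 1e-12))
      # linearity under in-range scaling
      half <- dplyr::mutate(sc, dplyr::across(dplyr::everything(), ~ .x / 2))
      expect_equal(behavioral_intention(half, w, "health")$BI_H, bi / 2)
      expect_equal(relative_autonomy_index(half, "health")$RAI_H, rai / 2)
    }
  })
})

test_that("weight calibration maximizes the BI ~ I correlation on the grid", {
  withr::with_seed(7, {
    n <- 200
    sc <- tibble::tibble(
      A_H = rnorm(n), SN_H = rnorm(n), PBC_H = rnorm(n),
      I_H = NA_real_
    )
    sc$I_H <- sc$A_H + rnorm(n, 0, 0.05)
    cal <- calibrate_weights(sc, "health")
    # direction proportional to (1, 0, 0): A dominates after unit-sum scaling
    dir <- cal$weights / sum(cal$weights)
    expect_gt(dir[["w_A"]], 0.9)
    # independent coarse-grid oracle: no candidate beats the achieved r
    ticks <- seq(0, 2, by = 0.5)
    grid <- expand.grid(a = ticks, s = ticks, p = ticks)
    grid <- grid[rowSums(grid) > 0, ]
    r_all <- apply(grid, 1, function(w) {
      cor(w[1] * sc$A_H + w[2] * sc$SN_H + w[3] * sc$PBC_H, sc$I_H)
    })
    expect_gte(cal$achieved_r + 1e-12, max(r_all))
  })
})

test_that("calibration is scale-invariant and participant-order invariant", {
  withr::with_seed(21, {
    n <- 120
    sc <- tibble::tibble(
      A_H = rnorm(n), SN_H = rnorm(n), PBC_H = rnorm(n),
      I_H = rnorm(n)
    )
    bi1 <- 1.4 * sc$A_H + 1.0 * sc$SN_H + 0.5 * sc$PBC_H
    bi2 <- 2 * bi1
    expect_equal(cor(bi1, sc$I_H), cor(bi2, sc$I_H))

    cal <- calibrate_weights(sc, "health")
    perm <- sc[sample.int(n), ]
    cal_perm <- calibrate_weights(perm, "health")
    expect_equal(cal$weights, cal_perm$weights)
    expect_equal(cal$achieved_r, cal_perm$achieved_r)
  })
})

test_that("calibration errors on degenerate inputs", {
  sc <- tibble::tibble(A_H = c(1, 2, 3), SN_H = c(1, 0, 2),
                       PBC_H = c(0, 1, 1), I_H = c(1, 1, 1))
  expect_error(calibrate_weights(sc, "health"), "constant")
  expect_error(calibrate_weights(sc[1:2, ], "health"), "at least 3")
})
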